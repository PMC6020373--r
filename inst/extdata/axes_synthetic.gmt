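axis_T	synthetic placeholder axis gene set	G0001	G0002	G0003	G0004	G0005	G0006	G0007	G0008	G0009	G0010
axis_B	synthetic placeholder axis gene set	G0011	G0012	G0013	G0014	G0015	G0016	G0017	G0018	G0019	G0020
axis_N	synthetic placeholder axis gene set	G0021	G0022	G0023	G0024	G0025	G0026	G0027	G0028	G0029	G0030
axis_R	synthetic placeholder axis gene set	G0031	G0032	G0033	G0034	G0035	G0036	G0037	G0038	G0039	G0040
axis_I	synthetic placeholder axis gene set	G0041	G0042	G0043	G0044	G0045	G0046	G0047	G0048	G0049	G0050
axis_G	synthetic placeholder axis gene set	G0051	G0052	G0053	G0054	G0055	G0056	G0057	G0058	G0059	G0060
axis_C	synthetic placeholder axis gene set	G0061	G0062	G0063	G0064	G0065	G0066	G0067	G0068	G0069	G0070
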