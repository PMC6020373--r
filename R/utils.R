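`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-sum-exp
#'
#' Numerically stable `log(sum(exp(x)))`; used when combining Bayes factors
#' on the log scale.
#'
#' @param x numeric vector of log-scale values.
#' @return scalar `log(sum(exp(x)))`.
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples.
#' 1 means identical partitions (up to label permutation), 0 the expected
#' agreement of random partitions.
#'
#' @param a,b vectors of cluster labels, same length.
#' @return scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test (sum of probabilities of heterozygote configurations
#' no more likely than the observed one) for genotype counts at a biallelic
#' site.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return exact p-value.
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  # all heterozygote counts with the parity of n_rare
  hets <- seq(n_rare %% 2L, n_rare, by = 2L)
  hom_r <- (n_rare - hets) / 2
  hom_c <- n - hets - hom_r
  logp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(hets) -
    lfactorial(hom_c) + hets * log(2) +
    lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  p <- exp(logp - logsumexp(logp))
  obs <- which(hets == n_het)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Chi-square Hardy-Weinberg test (1 df, no continuity correction)
#'
#' @inheritParams hwe_exact_p
#' @return p-value from the chi-square approximation.
#' @export
hwe_chisq_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  p <- (2 * n_hom1 + n_het) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(e == 0)) return(1)
  x2 <- sum((c(n_hom1, n_het, n_hom2) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Hardy-Weinberg test with automatic exact/chi-square selection
#'
#' Uses the exact test when any expected genotype-class count falls below 5,
#' otherwise the 1-df chi-square approximation.
#'
#' @inheritParams hwe_exact_p
#' @return p-value.
#' @export
hwe_test <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) return(1)
  p <- (2 * n_hom1 + n_het) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (min(expected) < 5) hwe_exact_p(n_hom1, n_het, n_hom2)
  else hwe_chisq_p(n_hom1, n_het, n_hom2)
}

# floor for reported p-values; avoids exact zeros from extreme t statistics
.P_FLOOR <- 1e-300

.floor_p <- function(p) pmax(p, .P_FLOOR)

# mean-impute missing dosages (QC guarantees low missingness)
impute_dosage <- function(x) {
  if (anyNA(x)) {
    m <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- m
  }
  x
}
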