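# Tajima's D and Fu's Fs tests of demographic equilibrium.

# Tajima (1989) normalizing constants for sample size n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' D = (k_bar - S/a1) / sqrt(e1 S + e2 S (S - 1)): the standardized
#' difference between the mean-pairwise-difference and Watterson estimates of
#' theta.  Negative values indicate an excess of rare variants, the signature
#' of population expansion (or purifying selection).
#'
#' @param faln A `filtered_alignment` with n >= 4 and S >= 1.
#' @return Tajima's D.
#' @export
tajimas_d <- function(faln) {
  stopifnot(inherits(faln, "filtered_alignment"))
  n <- nrow(faln$source$mat)
  if (n < 4L) stop("Tajima's D requires n >= 4")
  S <- classify_sites(faln)$S
  k_bar <- mean_pairwise_differences(faln)
  tajima_d_from_summary(n, S, k_bar)
}

# Core formula on (n, S, k_bar) summaries; reused on simulated replicates.
tajima_d_from_summary <- function(n, S, k_bar) {
  if (S < 1) stop("Tajima's D undefined for S = 0")
  k <- tajima_constants(n)
  (k_bar - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# Log unsigned Stirling numbers of the first kind, row n: log |s(n, k)| for
# k = 1..n, by the recurrence |s(n+1, k)| = n |s(n, k)| + |s(n, k-1)| carried
# in log space so large n cannot overflow.
log_stirling_row <- function(n) {
  row <- 0 # log|s(1,1)|
  if (n == 1L) return(row)
  for (m in seq_len(n - 1L)) {
    prev <- row
    k <- seq_len(m + 1L)
    left <- c(-Inf, prev)               # |s(m, k-1)|
    right <- c(prev, -Inf) + log(m)     # m |s(m, k)|
    hi <- pmax(left, right)
    row <- hi + log1p(exp(pmin(left, right) - hi))
    row[!is.finite(hi)] <- -Inf
  }
  row
}

# log P(K = k) for k = 1..n under the Ewens sampling distribution at theta.
log_ewens_pmf <- function(n, theta) {
  ls <- log_stirling_row(n)
  k <- seq_len(n)
  ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Fu's Fs
#'
#' Fs = ln(S'/(1 - S')) with S' = P(K >= Nh | theta = k_bar) under the Ewens
#' sampling distribution: the log-odds of seeing at least the observed number
#' of haplotypes given the mean pairwise difference.  Strongly negative under
#' population expansion (an excess of haplotypes).  All Ewens terms are
#' carried in log space.
#'
#' @param hs A `haplotype_set` (n >= 2).
#' @param k_bar Mean pairwise differences, used as the theta estimate
#'   (must be > 0).
#' @return Fu's Fs; `+Inf` with a warning when Nh = 1 (boundary S' = 1).
#' @export
fus_fs <- function(hs, k_bar) {
  stopifnot(inherits(hs, "haplotype_set"))
  if (hs$n < 2L) stop("Fu's Fs requires n >= 2")
  if (k_bar <= 0) stop("Fu's Fs undefined for k_bar = 0")
  fs_from_summary(hs$n, hs$Nh, k_bar)
}

fs_from_summary <- function(n, Nh, k_bar) {
  if (Nh == 1L) {
    warning("single haplotype: S' = 1 boundary, Fs = +Inf")
    return(Inf)
  }
  lp <- log_ewens_pmf(n, k_bar)
  log_sp <- log_sum_exp(lp[Nh:n])
  log_one_minus_sp <- log_sum_exp(lp[seq_len(Nh - 1L)])
  log_sp - log_one_minus_sp
}

#' Neutrality tests with coalescent-simulation p-values
#'
#' Computes Tajima's D and Fu's Fs and attaches p-values from a parametric
#' bootstrap: `n_sims` neutral constant-size coalescent samples of the same
#' size, conditioned on theta = observed mean pairwise differences, each
#' scored with the same statistics.  p-values are lower-tail
#' ((simulated <= observed) + 1) / (n_sims + 1), the direction in which
#' expansion pushes both statistics.  Significance stars: `**` p < 0.05,
#' `***` p < 0.01, `****` p < 0.001.  For Fs the conventional significance
#' call uses the 2% level (a peculiarity of the statistic's null
#' distribution), reported separately as `Fs_significant`.
#'
#' @param faln A `filtered_alignment`.
#' @param n_sims Number of coalescent replicates.
#' @param seed Integer seed.
#' @return A `neutrality_result` with D, Fs, p_D, p_Fs, stars and the
#'   simulation settings; statistics that are undefined (S = 0 or k_bar = 0)
#'   propagate as NA.
#' @export
neutrality_pvalues <- function(faln, n_sims = 1000, seed) {
  stopifnot(inherits(faln, "filtered_alignment"), n_sims >= 1)
  if (missing(seed)) stop("seed is required")
  n <- nrow(faln$source$mat)
  S <- classify_sites(faln)$S
  if (n < 4L || S == 0L) {
    return(structure(list(D = NA_real_, Fs = NA_real_, p_D = NA_real_,
                          p_Fs = NA_real_, stars_D = "", stars_Fs = "",
                          Fs_significant = NA,
                          method = "coalescent_sim", n_sims = 0L),
                     class = "neutrality_result"))
  }
  k_bar <- mean_pairwise_differences(faln)
  hs <- collapse_haplotypes(faln)
  D_obs <- tajima_d_from_summary(n, S, k_bar)
  Fs_obs <- if (k_bar > 0 && hs$Nh > 1L) fs_from_summary(n, hs$Nh, k_bar)
            else NA_real_
  set.seed(seed)
  sims <- sim_neutral_stats(n, k_bar, n_sims)
  ok_D <- sims$S >= 1
  D_sim <- mapply(tajima_d_from_summary, n, sims$S[ok_D], sims$k_bar[ok_D])
  p_D <- (sum(D_sim <= D_obs) + 1) / (length(D_sim) + 1)
  p_Fs <- NA_real_
  if (!is.na(Fs_obs)) {
    ok_F <- sims$k_bar > 0 & sims$Nh > 1
    Fs_sim <- mapply(fs_from_summary, n, sims$Nh[ok_F], sims$k_bar[ok_F])
    p_Fs <- (sum(Fs_sim <= Fs_obs) + 1) / (length(Fs_sim) + 1)
  }
  structure(list(D = D_obs, Fs = Fs_obs, p_D = p_D, p_Fs = p_Fs,
                 stars_D = significance_stars(p_D),
                 stars_Fs = significance_stars(p_Fs),
                 Fs_significant = if (is.na(p_Fs)) NA else p_Fs < 0.02,
                 method = "coalescent_sim", n_sims = n_sims),
            class = "neutrality_result")
}

significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) return("****")
  if (p < 0.01) return("***")
  if (p < 0.05) return("**")
  ""
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("Tajima's D = %s%s (p = %s), Fu's Fs = %s%s (p = %s)\n",
              fmt_stat(x$D), x$stars_D, fmt_stat(x$p_D),
              fmt_stat(x$Fs), x$stars_Fs, fmt_stat(x$p_Fs)))
  invisible(x)
}

fmt_stat <- function(v) {
  if (is.null(v) || is.na(v)) "—" else formatC(v, digits = 5, format = "f")
}
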