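# Mismatch distribution and the sudden-expansion model: spectrum, model
# fitting (tau, theta0, theta1), SSD, Harpending's raggedness, parametric
# bootstrap and expansion-time conversion.

#' Mismatch spectrum: histogram of pairwise sequence differences
#'
#' @param faln A `filtered_alignment` with n >= 2.
#' @return A `mismatch_spectrum`: `counts` over j = 0..d_max (named by j),
#'   `freqs` (normalized), and `n_pairs` = C(n, 2).
#' @export
mismatch_spectrum <- function(faln) {
  stopifnot(inherits(faln, "filtered_alignment"))
  n <- nrow(faln$source$mat)
  if (n < 2L) stop("mismatch spectrum undefined for n < 2")
  d <- faln_pairwise(faln)$diffs[upper.tri(diag(n))]
  d_max <- max(d)
  counts <- tabulate(d + 1L, nbins = d_max + 1L)
  names(counts) <- 0:d_max
  structure(list(counts = counts, freqs = counts / sum(counts),
                 n_pairs = choose(n, 2), n = n),
            class = "mismatch_spectrum")
}

#' @export
print.mismatch_spectrum <- function(x, ...) {
  cat("Mismatch spectrum over", x$n_pairs, "pairs; mode at j =",
      names(which.max(x$counts)), "\n")
  invisible(x)
}

# Equilibrium pairwise-difference distribution at theta:
# Fhat_j = theta^j / (theta + 1)^(j + 1).
equilibrium_freqs <- function(theta, j) {
  if (theta == 0) return(as.numeric(j == 0))
  exp(j * log(theta) - (j + 1) * log(theta + 1))
}

#' Sudden-expansion model mismatch probabilities
#'
#' Expected pairwise-difference distribution when a population at
#' equilibrium size theta0 grew instantaneously to theta1 at time tau
#' (mutational units) in the past.  Derived from the two-epoch pairwise
#' coalescent:
#' F_j = Fhat_j(theta1) P(Gamma(j+1) <= tau(theta1+1)/theta1)
#'       + e^(-tau/theta1) sum_m Fhat_m(theta0) Pois_(j-m)(tau),
#' with Fhat the equilibrium geometric distribution.  At tau = 0 this
#' collapses to the equilibrium distribution at theta0; with theta0 = 0 and
#' large theta1 it approaches Poisson(tau).  The returned vector is
#' renormalized over 0..j_max.
#'
#' @param tau Expansion age in mutational units (>= 0).
#' @param theta0,theta1 Pre-/post-expansion scaled sizes
#'   (0 <= theta0 <= theta1).
#' @param j_max Largest difference class.
#' @return Probability vector over j = 0..j_max.
#' @export
expansion_model_freqs <- function(tau, theta0, theta1, j_max) {
  if (tau < 0 || theta0 < 0 || theta1 < theta0) {
    stop("invalid parameters: need tau >= 0 and 0 <= theta0 <= theta1")
  }
  stopifnot(j_max >= 1)
  j <- 0:j_max
  if (theta1 == 0) {
    f <- as.numeric(j == 0)
    return(f)
  }
  recent <- equilibrium_freqs(theta1, j) *
    stats::pgamma(tau * (theta1 + 1) / theta1, shape = j + 1)
  eq0 <- equilibrium_freqs(theta0, j)
  pois <- stats::dpois(j, tau)
  ancient <- exp(-tau / theta1) *
    vapply(j, function(jj) {
      m <- 0:jj
      sum(eq0[m + 1] * pois[jj - m + 1])
    }, 0)
  f <- recent + ancient
  f / sum(f)
}

# SSD between an observed frequency vector and the model at given parameters.
mismatch_ssd <- function(obs_freqs, tau, theta0, theta1) {
  f <- expansion_model_freqs(tau, theta0, theta1, length(obs_freqs) - 1L)
  sum((obs_freqs - f)^2)
}

#' Harpending's raggedness index
#'
#' r = sum_{j=1}^{d+1} (x_j - x_{j-1})^2 over the observed relative
#' frequencies, with the boundary convention x_{d+1} = 0 (one step past the
#' largest observed class).  Small under the smooth unimodal spectra of
#' expanded populations, large under the ragged multimodal spectra of
#' stationary ones.
#'
#' @param freqs Relative frequency vector over j = 0..d.
#' @return Raggedness index.
#' @export
raggedness_index <- function(freqs) {
  stopifnot(length(freqs) >= 1, all(freqs >= 0))
  x <- c(freqs, 0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch spectrum
#'
#' Minimizes SSD = sum_j (obs_j - F_j)^2 over (tau, theta0, theta1) by
#' bounded quasi-Newton least squares with multi-start (random restarts from
#' a fixed seed; ties broken toward the smallest tau).  Goodness-of-fit
#' p-values by parametric bootstrap: `B` coalescent datasets of the same
#' sample size are simulated under the fitted parameters, each refit, and
#' exceedances of the observed SSD and raggedness counted
#' (p = (exceedances + 1) / (B + 1)).
#'
#' @param spec A `mismatch_spectrum` (or the one computed from `faln`).
#' @param B Bootstrap replicates (0 skips the bootstrap).
#' @param seed Integer seed.
#' @param theta1_max Upper bound for theta1 (effectively-infinite cap).
#' @param n_starts Multi-start count.
#' @return An `expansion_fit` with tau, theta0, theta1, SSD, raggedness_r,
#'   p_SSD, p_r and the model frequencies at the optimum.
#' @export
fit_sudden_expansion <- function(spec, B = 100, seed, theta1_max = 10000,
                                 n_starts = 10) {
  stopifnot(inherits(spec, "mismatch_spectrum"))
  if (missing(seed)) stop("seed is required")
  obs <- spec$freqs
  if (length(obs) < 2L) {
    warning("degenerate spectrum (all mass at 0): boundary fit tau = 0")
    return(structure(list(tau = 0, theta0 = 0, theta1 = 0, SSD = 0,
                          raggedness_r = raggedness_index(obs),
                          p_SSD = NA_real_, p_r = NA_real_,
                          model_freqs = c(1), n_boot = 0L),
                     class = "expansion_fit"))
  }
  set.seed(seed)
  fit <- fit_expansion_core(obs, theta1_max, n_starts)
  r_obs <- raggedness_index(obs)
  p_SSD <- p_r <- NA_real_
  if (B > 0) {
    boot_ssd <- boot_r <- numeric(B)
    n <- spec$n
    growth <- if (fit$theta0 > 0) max(fit$theta1 / fit$theta0, 1) else 1000
    cfg_exp <- if (fit$tau > 0) list(tau = fit$tau, growth = growth) else NULL
    for (b in seq_len(B)) {
      sims <- sim_mismatch_counts(n, fit$theta1, cfg_exp)
      f_sim <- sims / sum(sims)
      bfit <- fit_expansion_core(f_sim, theta1_max, n_starts = 3)
      boot_ssd[b] <- bfit$SSD
      boot_r[b] <- raggedness_index(f_sim)
    }
    p_SSD <- perm_pvalue(boot_ssd, fit$SSD)
    p_r <- perm_pvalue(boot_r, r_obs)
  }
  structure(list(tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 SSD = fit$SSD, raggedness_r = r_obs,
                 p_SSD = p_SSD, p_r = p_r,
                 model_freqs = expansion_model_freqs(fit$tau, fit$theta0,
                                                     fit$theta1,
                                                     length(obs) - 1L),
                 n_boot = B),
            class = "expansion_fit")
}

# Bounded multi-start minimization of the SSD surface.  Parameters are
# optimized on a transformed scale (sqrt for tau/theta0, log for theta1)
# because the surface is flat in theta1 and multi-modal in tau.
fit_expansion_core <- function(obs, theta1_max, n_starts) {
  if (length(obs) < 2L) obs <- c(obs, 0)  # degenerate single-class spectrum
  j_max <- length(obs) - 1L
  k_obs <- sum((0:j_max) * obs)           # observed mean, seeds tau/theta1
  objective <- function(par) {
    tau <- par[1]^2
    theta0 <- par[2]^2
    theta1 <- theta0 + exp(par[3])
    mismatch_ssd(obs, tau, theta0, min(theta1, theta1_max))
  }
  starts <- cbind(
    sqrt(pmax(c(k_obs, stats::runif(n_starts - 1, 0, 2 * k_obs + 1)), 1e-3)),
    sqrt(stats::runif(n_starts, 0, max(k_obs / 2, 0.5))),
    log(stats::runif(n_starts, 0.5, theta1_max / 10))
  )
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[s, ], objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    cand <- list(tau = opt$par[1]^2, theta0 = opt$par[2]^2,
                 theta1 = min(opt$par[2]^2 + exp(opt$par[3]), theta1_max),
                 SSD = opt$value)
    if (is.null(best) || cand$SSD < best$SSD - 1e-15 ||
        (abs(cand$SSD - best$SSD) <= 1e-15 && cand$tau < best$tau)) {
      best <- cand
    }
  }
  if (is.null(best)) {  # every start failed: boundary fit
    best <- list(tau = 0, theta0 = 0, theta1 = 0,
                 SSD = mismatch_ssd(obs, 0, 0, 0))
  }
  best
}

# Mismatch counts of one simulated coalescent sample at the fitted
# demography (single deme, theta1 present size, optional expansion).
sim_mismatch_counts <- function(n, theta, expansion) {
  cfg <- demography_config(samples_per_deme = n, theta = max(theta, 1e-6),
                           expansion = expansion, L = 1)
  gen <- sim_genealogy(cfg)
  muts <- stats::rpois(length(gen$branch_len), cfg$theta / 2 * gen$branch_len)
  # d(i, j) = mutations on the path between leaves i and j
  #         = r_i + r_j - 2 (Z diag(muts) Z')_{ij},
  # with Z the leaf x branch incidence (leaf below branch) and r = Z muts.
  n_nodes <- length(gen$parent)
  Z <- matrix(0, n, n_nodes)
  for (leaf in seq_len(n)) {
    v <- leaf
    while (gen$parent[v] > 0L) { Z[leaf, v] <- 1; v <- gen$parent[v] }
  }
  r <- as.vector(Z %*% muts)
  C <- tcrossprod(sweep(Z, 2L, muts, "*"), Z)
  d <- round(outer(r, r, "+") - 2 * C)[upper.tri(diag(n))]
  tabulate(d + 1L, nbins = max(d) + 1L)
}

#' Expansion time from tau
#'
#' t = tau / (2 mu k): converts the mutational-time expansion age to absolute
#' time given the per-site mutation rate and sequence length.
#'
#' @param tau Expansion age in mutational units.
#' @param mu Substitution rate per site per Myr.
#' @param k Sequence length in sites.
#' @return Expansion time in Myr.
#' @export
expansion_time <- function(tau, mu, k) {
  stopifnot(tau >= 0)
  if (mu <= 0 || k <= 0) stop("mu and k must be positive")
  tau / (2 * mu * k)
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf(
    "Sudden-expansion fit: tau = %.4f, theta0 = %.4f, theta1 = %.4f\n",
    x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f (p = %s), raggedness r = %.5f (p = %s)\n",
              x$SSD, fmt_stat(x$p_SSD), x$raggedness_r, fmt_stat(x$p_r)))
  invisible(x)
}
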