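# Independent brute-force oracles, written from the textbook definitions
# with explicit loops.  These deliberately avoid the package's internal
# helpers so that agreement is a genuine cross-check.

oracle_hamming <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      d[i, j] <- sum(a != b)
    }
  }
  d
}

oracle_pi <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tot <- tot + sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
    }
  }
  tot / choose(n, 2) / L
}

# Hierarchical AMOVA from first principles: sums of squared distances
# evaluated by explicit enumeration, components from the standard nested
# expected-mean-square coefficients.
oracle_amova3 <- function(d2, pop, grp) {
  n <- nrow(d2)
  ss_set <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  ss_tot <- ss_set(seq_len(n))
  pops <- unique(pop); grps <- unique(grp)
  ss_wp <- sum(sapply(pops, function(p) ss_set(which(pop == p))))
  ss_wg <- sum(sapply(grps, function(g) ss_set(which(grp == g))))
  P <- length(pops); G <- length(grps)
  n_p <- sapply(pops, function(p) sum(pop == p))
  n_g <- sapply(grps, function(g) sum(grp == g))
  grp_of_pop <- sapply(pops, function(p) grp[pop == p][1])
  A <- sum(sapply(grps, function(g) {
    sum(n_p[grp_of_pop == g]^2) / n_g[grps == g]
  }))
  msd_wp <- ss_wp / (n - P)
  msd_ap <- (ss_wg - ss_wp) / (P - G)
  msd_ag <- (ss_tot - ss_wg) / (G - 1)
  n1 <- (n - A) / (P - G)
  n2 <- (A - sum(n_p^2) / n) / (G - 1)
  n3 <- (n - sum(n_g^2) / n) / (G - 1)
  sc <- msd_wp
  sb <- (msd_ap - sc) / n1
  sa <- (msd_ag - sc - n2 * sb) / n3
  tot <- sa + sb + sc
  list(sigma = c(sa, sb, sc),
       phi = c(Phi_CT = sa / tot, Phi_SC = sb / (sb + sc),
               Phi_ST = (sa + sb) / tot))
}

oracle_phist2 <- function(d2, pop) {
  n <- nrow(d2)
  ss_set <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  pops <- unique(pop)
  P <- length(pops)
  n_p <- sapply(pops, function(p) sum(pop == p))
  ss_tot <- ss_set(seq_len(n))
  ss_wp <- sum(sapply(pops, function(p) ss_set(which(pop == p))))
  sc <- ss_wp / (n - P)
  n_c <- (n - sum(n_p^2) / n) / (P - 1)
  sa <- ((ss_tot - ss_wp) / (P - 1) - sc) / n_c
  sa / (sa + sc)
}

# Gst / Nst by direct hand computation of the corrected within/total
# diversities.  `hap` is the haplotype index per individual, `pop` the
# population label per individual, `delta` the haplotype distance matrix
# (per site), already including delta[i, i] = 0.
oracle_gst_nst <- function(hap, pop, delta) {
  pops <- unique(pop)
  K <- length(pops)
  Nh <- nrow(delta)
  n_k <- sapply(pops, function(p) sum(pop == p))
  ntilde <- K / sum(1 / n_k)
  decomposition <- function(dd) {
    within <- numeric(K)
    pbar <- rep(0, Nh)
    for (k in seq_len(K)) {
      pk <- sapply(seq_len(Nh), function(h) {
        sum(hap == h & pop == pops[k])
      }) / n_k[k]
      acc <- 0
      for (i in seq_len(Nh)) for (j in seq_len(Nh)) {
        acc <- acc + pk[i] * pk[j] * dd[i, j]
      }
      within[k] <- acc
      pbar <- pbar + pk / K
    }
    vS <- ntilde / (ntilde - 1) * mean(within)
    vT_raw <- 0
    for (i in seq_len(Nh)) for (j in seq_len(Nh)) {
      vT_raw <- vT_raw + pbar[i] * pbar[j] * dd[i, j]
    }
    vT <- vT_raw + vS / (ntilde * K)
    (vT - vS) / vT
  }
  ones <- matrix(1, Nh, Nh) - diag(Nh)
  c(Gst = decomposition(ones), Nst = decomposition(delta))
}

# Tajima's D coded independently from the published constant definitions.
oracle_tajima <- function(n, S, k_bar) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1^2)
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu's Fs from exact integer Stirling numbers of the first kind (exact in
# doubles for the sample sizes used here).
oracle_stirling_table <- function(n_max) {
  s <- matrix(0, n_max, n_max)
  s[1, 1] <- 1
  if (n_max > 1) {
    for (m in 1:(n_max - 1)) {
      for (k in 1:(m + 1)) {
        s[m + 1, k] <- m * s[m, k] +
          if (k > 1) s[m, k - 1] else 0
      }
    }
  }
  s
}

oracle_fs <- function(n, Nh, theta) {
  s <- oracle_stirling_table(n)[n, ]
  denom <- prod(theta + 0:(n - 1))
  pk <- s * theta^(1:n) / denom
  sp <- sum(pk[Nh:n])
  log(sp / (1 - sp))
}

# Brute-force one-point Steiner search: best additional sequence (over the
# per-column observed states) minimizing the MST total length of the
# augmented set.  Returns the minimal total length and the best candidates.
oracle_steiner1 <- function(seqs) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  state_sets <- lapply(seq_len(ncol(chars)), function(j) unique(chars[, j]))
  cands <- do.call(expand.grid, c(state_sets, stringsAsFactors = FALSE))
  cand_strs <- apply(cands, 1, paste0, collapse = "")
  mst_len <- function(ss) {
    d <- oracle_hamming(ss)
    n <- length(ss)
    in_tree <- c(TRUE, rep(FALSE, n - 1))
    best <- d[1, ]
    tot <- 0
    for (step in seq_len(n - 1)) {
      v <- which(!in_tree)[which.min(best[!in_tree])]
      tot <- tot + best[v]
      in_tree[v] <- TRUE
      best <- pmin(best, d[v, ])
    }
    tot
  }
  base_len <- mst_len(seqs)
  lens <- vapply(cand_strs, function(cs) mst_len(c(seqs, cs)), 0)
  best_len <- min(c(base_len, lens))
  list(base_len = base_len, best_len = best_len,
       best_points = setdiff(cand_strs[lens == best_len], seqs))
}
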