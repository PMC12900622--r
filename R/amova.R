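# Hierarchical analysis of molecular variance on squared pairwise-difference
# distances (Excoffier-style), with Phi-statistics and permutation tests.

# Sum over levels of a partition of (1/n_level) * sum_{i<j in level} d2_ij.
ss_within_partition <- function(d2, f) {
  f <- as.factor(f)
  M <- rowsum(d2, f)
  W <- rowsum(t(M), f)
  n_level <- tabulate(f)
  sum(diag(as.matrix(W)) / (2 * n_level))
}

# Variance components of the three-level design (groups / populations within
# groups / individuals within populations).  `pop` and `grp` are vectors over
# individuals; d2 the squared-distance matrix (for sequences, the number of
# pairwise differences).
amova_components <- function(d2, pop, grp) {
  pop <- as.character(pop); grp <- as.character(grp)
  n <- nrow(d2)
  P <- length(unique(pop)); G <- length(unique(grp))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_wp <- ss_within_partition(d2, pop)
  ss_wg <- ss_within_partition(d2, grp)
  ssd_ap <- ss_wg - ss_wp
  ssd_ag <- ss_total - ss_wg
  df_wp <- n - P; df_ap <- P - G; df_ag <- G - 1
  n_p <- table(pop); n_g <- table(grp)
  grp_of_pop <- tapply(grp, pop, `[`, 1L)
  # A = sum over groups of (sum of n_p^2 in the group) / n_g
  sum_np2_by_g <- tapply(as.numeric(n_p)^2, grp_of_pop[names(n_p)], sum)
  A <- sum(sum_np2_by_g / as.numeric(n_g[names(sum_np2_by_g)]))
  n1 <- if (df_ap > 0) (n - A) / df_ap else NA_real_
  n2 <- if (df_ag > 0) (A - sum(as.numeric(n_p)^2) / n) / df_ag else NA_real_
  n3 <- if (df_ag > 0) (n - sum(as.numeric(n_g)^2) / n) / df_ag else NA_real_
  sigma_c <- if (df_wp > 0) ss_wp / df_wp else 0
  sigma_b <- if (df_ap > 0) (ssd_ap / df_ap - sigma_c) / n1 else 0
  sigma_a <- if (df_ag > 0) {
    (ssd_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  } else 0
  tot <- sigma_a + sigma_b + sigma_c
  list(
    sigma = c(among_groups = sigma_a, among_pops_within_groups = sigma_b,
              within_pops = sigma_c),
    ssd = c(among_groups = ssd_ag, among_pops_within_groups = ssd_ap,
            within_pops = ss_wp),
    df = c(df_ag, df_ap, df_wp),
    phi = c(
      Phi_CT = if (tot > 0) sigma_a / tot else 0,
      Phi_SC = if (sigma_b + sigma_c > 0) sigma_b / (sigma_b + sigma_c) else 0,
      Phi_ST = if (tot > 0) (sigma_a + sigma_b) / tot else 0
    ),
    total = tot
  )
}

# Two-level design: populations / individuals.  Returns Phi_ST and components.
amova2_components <- function(d2, pop) {
  pop <- as.character(pop)
  n <- nrow(d2)
  P <- length(unique(pop))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_wp <- ss_within_partition(d2, pop)
  ssd_ap <- ss_total - ss_wp
  df_wp <- n - P; df_ap <- P - 1
  n_p <- table(pop)
  n_c <- (n - sum(as.numeric(n_p)^2) / n) / df_ap
  sigma_c <- if (df_wp > 0) ss_wp / df_wp else 0
  sigma_a <- (ssd_ap / df_ap - sigma_c) / n_c
  tot <- sigma_a + sigma_c
  list(sigma = c(among = sigma_a, within = sigma_c),
       phi_st = if (tot > 0) sigma_a / tot else 0)
}

#' Hierarchical AMOVA with Phi-statistics and permutation significance
#'
#' Partitions the total molecular variance (squared pairwise-difference
#' distances on retained columns) into among-group, among-population-within-
#' group and within-population components, with the matching Phi-statistics
#' (Phi_CT, Phi_SC, Phi_ST).  Significance by permutation: Phi_ST permutes
#' individuals among populations without restriction, Phi_SC permutes
#' individuals among populations within their group, and Phi_CT permutes
#' whole populations among groups.  p = (exceedances + 1) / (B + 1).
#'
#' @param faln A `filtered_alignment` whose alignment carries group labels
#'   (>= 2 groups, >= 2 populations overall).
#' @param B Permutations per test.
#' @param seed Integer seed.
#' @return An `amova_result`: variance components, percentages (summing to
#'   100), Phi-statistics, permutation p-values, degrees of freedom and a
#'   `degenerate_sc` flag set when some group holds a single population.
#' @export
amova <- function(faln, B = 1000, seed) {
  stopifnot(inherits(faln, "filtered_alignment"), B >= 1)
  if (missing(seed)) stop("seed is required")
  aln <- faln$source
  if (is.null(aln$group_of)) stop("AMOVA requires group labels")
  pop <- aln$population
  grp <- unname(aln$group_of[pop])
  if (length(unique(grp)) < 2L) stop("AMOVA requires >= 2 groups")
  if (length(unique(pop)) < 2L) stop("AMOVA requires >= 2 populations")
  d2 <- faln_pairwise(faln)$diffs
  if (all(d2 == 0)) stop("zero total variance: all sequences identical")
  obs <- amova_components(d2, pop, grp)
  pops_of_grp <- tapply(names(aln$group_of), unname(aln$group_of), c)
  degenerate_sc <- any(lengths(pops_of_grp) < 2L)

  set.seed(seed)
  n <- length(pop)
  # Phi_ST: individuals among populations, unrestricted
  perm_st <- vapply(seq_len(B), function(b) {
    i <- sample.int(n)
    amova_components(d2, pop[i], grp[i])$phi["Phi_ST"]
  }, 0)
  # Phi_SC: individuals among populations within groups
  perm_sc <- vapply(seq_len(B), function(b) {
    newpop <- pop
    for (g in unique(grp)) {
      idx <- which(grp == g)
      newpop[idx] <- pop[idx][sample.int(length(idx))]
    }
    amova_components(d2, newpop, grp)$phi["Phi_SC"]
  }, 0)
  # Phi_CT: whole populations among groups
  pop_labels <- unique(pop)
  grp_of_pop <- unname(aln$group_of[pop_labels])
  perm_ct <- vapply(seq_len(B), function(b) {
    g_perm <- grp_of_pop[sample.int(length(grp_of_pop))]
    names(g_perm) <- pop_labels
    amova_components(d2, pop, unname(g_perm[pop]))$phi["Phi_CT"]
  }, 0)

  sigma <- obs$sigma
  structure(list(
    variance_components = sigma,
    percentages = 100 * sigma / sum(sigma),
    phi = obs$phi,
    p_values = c(
      Phi_CT = perm_pvalue(perm_ct, obs$phi["Phi_CT"]),
      Phi_SC = perm_pvalue(perm_sc, obs$phi["Phi_SC"]),
      Phi_ST = perm_pvalue(perm_st, obs$phi["Phi_ST"])
    ),
    ssd = obs$ssd, df = obs$df,
    degenerate_sc = degenerate_sc,
    n_permutations = B
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA variance components (% of total):\n")
  lab <- c("Among groups", "Among populations within groups",
           "Within populations")
  for (i in 1:3) {
    cat(sprintf("  %-33s %8.4f  (%6.2f%%)\n", lab[i],
                x$variance_components[i], x$percentages[i]))
  }
  cat(sprintf("Phi_CT = %.5f (p = %.4g), Phi_SC = %.5f (p = %.4g), Phi_ST = %.5f (p = %.4g)\n",
              x$phi["Phi_CT"], x$p_values["Phi_CT"],
              x$phi["Phi_SC"], x$p_values["Phi_SC"],
              x$phi["Phi_ST"], x$p_values["Phi_ST"]))
  if (x$degenerate_sc) {
    cat("note: some group contains a single population; Phi_SC is degenerate\n")
  }
  invisible(x)
}

#' Pairwise Fst and gene-flow matrices with permutation p-values
#'
#' Each pair's Fst is the two-level Phi_ST of the AMOVA restricted to that
#' pair of units (populations or groups).  Gene flow Nm fills the companion
#' matrix via [gene_flow()]; negative Fst estimates (possible in small
#' samples) are reported as computed in the Fst matrix but clamped to 0 for
#' Nm with a warning.
#'
#' @param faln A `filtered_alignment`.
#' @param level `"population"` or `"group"`.
#' @param B Permutations per pair.
#' @param seed Integer seed.
#' @return An `fst_matrix`: labels, symmetric `fst` (diagonal 0), `nm`,
#'   and permutation `p_values`.
#' @export
pairwise_fst <- function(faln, level = c("population", "group"), B = 1000,
                         seed) {
  stopifnot(inherits(faln, "filtered_alignment"), B >= 1)
  if (missing(seed)) stop("seed is required")
  level <- match.arg(level)
  aln <- faln$source
  unit <- if (level == "population") {
    aln$population
  } else {
    if (is.null(aln$group_of)) stop("group level requires group labels")
    unname(aln$group_of[aln$population])
  }
  labels <- unique(unit)
  U <- length(labels)
  if (U < 2L) stop("need >= 2 units at the chosen level")
  d2 <- faln_pairwise(faln)$diffs
  fst <- matrix(0, U, U, dimnames = list(labels, labels))
  pmat <- matrix(NA_real_, U, U, dimnames = list(labels, labels))
  set.seed(seed)
  for (i in seq_len(U - 1L)) {
    for (j in seq(i + 1L, U)) {
      idx <- which(unit %in% labels[c(i, j)])
      sub_d2 <- d2[idx, idx, drop = FALSE]
      sub_unit <- unit[idx]
      obs <- amova2_components(sub_d2, sub_unit)$phi_st
      perm <- vapply(seq_len(B), function(b) {
        amova2_components(sub_d2, sample(sub_unit))$phi_st
      }, 0)
      fst[i, j] <- fst[j, i] <- obs
      pmat[i, j] <- pmat[j, i] <- perm_pvalue(perm, obs)
    }
  }
  fst_clamped <- fst
  if (any(fst < 0)) {
    warning("negative pairwise Fst estimates clamped to 0 for Nm")
    fst_clamped[fst_clamped < 0] <- 0
  }
  nm <- matrix(gene_flow(fst_clamped), U, U, dimnames = dimnames(fst))
  diag(nm) <- 0
  structure(list(labels = labels, fst = fst, nm = nm, p_values = pmat,
                 level = level, n_permutations = B),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Pairwise Fst (", x$level, " level, ", length(x$labels),
      " units):\n", sep = "")
  print(round(x$fst, 4))
  invisible(x)
}
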