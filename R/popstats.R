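#' Unbiased haplotype diversity
#'
#' Hd = n/(n-1) * (1 - sum(p_i^2)) with p_i the haplotype relative
#' frequencies: the probability that two randomly drawn sequences carry
#' different haplotypes, with small-sample correction.
#'
#' @param hs A `haplotype_set`.
#' @return Haplotype diversity in \[0, 1\]; 0 exactly when a single haplotype
#'   is present.
#' @export
haplotype_diversity <- function(hs) {
  stopifnot(inherits(hs, "haplotype_set"))
  n <- hs$n
  if (n < 2L) stop("haplotype diversity undefined for n < 2")
  p <- rowSums(hs$count_matrix) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity (pi) per site
#'
#' Mean proportion of differing positions over all sequence pairs.  Under
#' complete deletion every pair is compared over the same `k_eff` columns;
#' under the pairwise policy each pair is scaled by its own number of
#' mutually valid columns.
#'
#' @param faln A `filtered_alignment` with at least two sequences.
#' @return Per-site nucleotide diversity, >= 0.
#' @export
nucleotide_diversity <- function(faln) {
  stopifnot(inherits(faln, "filtered_alignment"))
  n <- nrow(faln$source$mat)
  if (n < 2L) stop("nucleotide diversity undefined for n < 2")
  pc <- faln_pairwise(faln)
  ut <- upper.tri(pc$diffs)
  if (any(pc$valid[ut] == 0)) {
    stop("a sequence pair shares no comparable column")
  }
  mean(pc$diffs[ut] / pc$valid[ut])
}

#' Mean number of pairwise differences (k-bar)
#'
#' @param faln A `filtered_alignment` with at least two sequences.
#' @return Mean absolute number of differences over all sequence pairs.
#' @export
mean_pairwise_differences <- function(faln) {
  stopifnot(inherits(faln, "filtered_alignment"))
  n <- nrow(faln$source$mat)
  if (n < 2L) stop("undefined for n < 2")
  pc <- faln_pairwise(faln)
  mean(pc$diffs[upper.tri(pc$diffs)])
}

#' Watterson's theta per site
#'
#' theta_W = S / (a1 * k_eff) with a1 = sum_{i=1}^{n-1} 1/i.
#'
#' @param S Number of segregating (polymorphic) sites.
#' @param n Sample size (>= 2).
#' @param k_eff Effective number of analyzed columns.
#' @return Per-site Watterson estimate.
#' @export
watterson_theta <- function(S, n, k_eff) {
  if (n < 2L) stop("Watterson's theta undefined for n < 2")
  stopifnot(S >= 0, k_eff >= 1)
  a1 <- sum(1 / seq_len(n - 1))
  S / (a1 * k_eff)
}

#' Per-population diversity summary
#'
#' Convenience wrapper computing n, Nh, Hd, S, pi, theta_W and k-bar for one
#' set of sequences (typically one population or group, already filtered).
#'
#' @param faln A `filtered_alignment`.
#' @return A one-row data.frame.
#' @export
diversity_summary <- function(faln) {
  hs <- collapse_haplotypes(faln)
  sc <- classify_sites(faln)
  n <- hs$n
  k_bar <- mean_pairwise_differences(faln)
  data.frame(
    n = n, Nh = hs$Nh,
    Hd = haplotype_diversity(hs),
    S = sc$S,
    pi = nucleotide_diversity(faln),
    theta_W = watterson_theta(sc$S, n, faln$k_eff),
    k_bar = k_bar
  )
}

# Shared core of the Gst/Nst decomposition: given per-population haplotype
# frequency columns and a haplotype x haplotype distance matrix, return the
# corrected within/total diversity decomposition coefficient.
# With delta = 1 - I this is Nei & Chesser's corrected Gst; with per-site
# haplotype distances it is the Nst of Lynch & Crease.
diversity_decomposition <- function(counts, delta) {
  n_k <- colSums(counts)
  K <- length(n_k)
  ntilde <- harmonic_mean(n_k)
  p <- sweep(counts, 2L, n_k, "/")            # haplotype x population freqs
  within_k <- vapply(seq_len(K), function(k) {
    pk <- p[, k]
    as.numeric(t(pk) %*% delta %*% pk)
  }, 0)
  vS <- ntilde / (ntilde - 1) * mean(within_k)
  pbar <- rowMeans(p)
  vT <- as.numeric(t(pbar) %*% delta %*% pbar) + vS / (ntilde * K)
  if (vT <= 0) return(0)
  (vT - vS) / vT
}

#' Gst and Nst differentiation with a permutation test of Nst > Gst
#'
#' Gst decomposes haplotype-frequency diversity into within- and
#' among-population parts (sample-size-corrected estimators); Nst uses the
#' same decomposition but weights haplotype pairs by their per-site distance,
#' so it also reflects how different the haplotypes are.  Nst significantly
#' exceeding Gst indicates phylogeographic structure: closely related
#' haplotypes co-occur geographically.  Significance is assessed by permuting
#' individuals among populations.
#'
#' Populations with fewer than 2 individuals are excluded (with a warning).
#'
#' @param faln A `filtered_alignment` covering >= 2 populations.
#' @param B Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @return A `gst_nst_result` with Gst, Nst, the permutation p-value of
#'   Nst - Gst and the number of permutations.
#' @export
gst_nst <- function(faln, B = 1000, seed) {
  stopifnot(inherits(faln, "filtered_alignment"), B >= 1)
  if (missing(seed)) stop("seed is required")
  aln <- faln$source
  keep_pops <- names(which(table(aln$population) >= 2L))
  if (length(keep_pops) < length(unique(aln$population))) {
    warning("excluding populations with fewer than 2 individuals")
  }
  if (length(keep_pops) < 2L) {
    stop("Gst/Nst needs at least 2 populations with >= 2 individuals")
  }
  keep <- aln$population %in% keep_pops
  sub <- subset_alignment(faln, keep)
  hs <- collapse_haplotypes(sub)
  hap_delta <- haplotype_distances(hs) / sub$k_eff
  freq_delta <- 1 - diag(nrow(hap_delta))

  stat <- function(pop_index) {
    counts <- hap_counts_by(hs$assignment, pop_index, hs$Nh)
    g <- diversity_decomposition(counts, freq_delta)
    n <- diversity_decomposition(counts, hap_delta)
    c(gst = g, nst = n)
  }
  pop_index <- match(sub$source$population, keep_pops)
  obs <- stat(pop_index)
  observed_gap <- obs["nst"] - obs["gst"]
  set.seed(seed)
  perm_gap <- vapply(seq_len(B), function(b) {
    s <- stat(sample(pop_index))
    s["nst"] - s["gst"]
  }, 0)
  structure(list(Gst = unname(obs["gst"]), Nst = unname(obs["nst"]),
                 p_value = perm_pvalue(perm_gap, observed_gap),
                 n_permutations = B),
            class = "gst_nst_result")
}

#' @export
print.gst_nst_result <- function(x, ...) {
  cat(sprintf("Gst = %.5f, Nst = %.5f (permutation p[Nst > Gst] = %.4g, B = %d)\n",
              x$Gst, x$Nst, x$p_value, x$n_permutations))
  if (x$Nst > x$Gst && x$p_value < 0.05) {
    cat("Nst significantly exceeds Gst: significant phylogeographic structure\n")
  }
  invisible(x)
}

# haplotype x population counts for an arbitrary population indexing
hap_counts_by <- function(assignment, pop_index, Nh) {
  K <- max(pop_index)
  counts <- matrix(0, Nh, K)
  for (i in seq_along(assignment)) {
    counts[assignment[i], pop_index[i]] <-
      counts[assignment[i], pop_index[i]] + 1
  }
  counts
}

# Absolute pairwise difference counts between haplotype sequences.
haplotype_distances <- function(hs) {
  m <- do.call(rbind, strsplit(hs$haplotypes, ""))
  pairwise_counts(seq_codes(m))$diffs
}

# Restrict a filtered alignment to a subset of individuals (logical/indices),
# keeping the retained-column set.
subset_alignment <- function(faln, which_rows) {
  aln <- faln$source
  mat <- aln$mat[which_rows, , drop = FALSE]
  sub <- labeled_alignment(mat,
                           stats::setNames(aln$population, rownames(aln$mat)),
                           aln$group_of)
  structure(list(source = sub, retained_columns = faln$retained_columns,
                 k_eff = faln$k_eff, policy = faln$policy),
            class = "filtered_alignment")
}

#' Island-model gene flow from Fst
#'
#' Nm = (1 - Fst) / (4 Fst): the effective number of migrants per generation
#' under Wright's island model.  Fst = 0 maps to +Inf (panmixia) and Fst = 1
#' to 0.
#'
#' @param fst Fixation index in \[0, 1\].
#' @return Gene-flow estimate (may be `Inf`).
#' @export
gene_flow <- function(fst) {
  if (any(fst < 0 | fst > 1, na.rm = TRUE)) {
    stop("Fst must lie in [0, 1]")
  }
  ifelse(fst == 0, Inf, (1 - fst) / (4 * fst))
}

#' Threshold flags for "high" haplotype and nucleotide diversity
#'
#' High haplotype diversity is Hd > 0.5 and high nucleotide diversity is
#' pi > 0.005 (strict inequalities).
#'
#' @param Hd Haplotype diversity.
#' @param pi Nucleotide diversity per site.
#' @return list(high_Hd, high_pi) of logicals.
#' @export
classify_diversity <- function(Hd, pi) {
  stopifnot(is.finite(Hd), is.finite(pi))
  list(high_Hd = Hd > 0.5, high_pi = pi > 0.005)
}
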