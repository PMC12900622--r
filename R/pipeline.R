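# End-to-end pipeline: read -> filter -> diversity -> differentiation ->
# neutrality/mismatch -> network, writing the full set of report tables.

EMDASH <- "—"

fmt_or_dash <- function(x, digits = 5) {
  if (is.null(x) || length(x) == 0 || is.na(x)) EMDASH
  else formatC(x, digits = digits, format = "f")
}

#' Run the full phylogeography pipeline
#'
#' Stages, in order: read and filter the alignment; per-population and
#' per-group (pooled individuals) diversity tables; Gst/Nst with the
#' phylogeographic-structure verdict; hierarchical AMOVA (if group labels are
#' present); pairwise Fst/Nm half-matrices at population and group level with
#' the differentiation thresholds (Fst > 0.25, Nm > 1) annotated; neutrality
#' and mismatch-distribution tables per group and overall; and the
#' median-joining network edge/node tables.  Populations with fewer than 2
#' individuals are excluded from diversity and permutation statistics and
#' rendered with an em-dash; undefined statistics render the same way.
#' Differentiation stages are skipped (with a logged notice) when only one
#' population is present.  Every number in the reports comes from exactly one
#' call of the underlying operation.
#'
#' @param aln A `labeled_alignment`, or NULL to read from `fasta`/`popmap`.
#' @param fasta,popmap Input paths (used when `aln` is NULL).
#' @param outdir Output directory (created if needed).
#' @param policy Missing-data policy for [filter_sites()].
#' @param perms Permutation count for Gst/Nst, AMOVA and pairwise Fst.
#' @param boot Bootstrap replicates for the mismatch goodness-of-fit.
#' @param n_sims Coalescent replicates for neutrality p-values.
#' @param mu Substitution rate per site per Myr for expansion-time
#'   conversion.
#' @param k Sequence length (sites) for expansion-time conversion; defaults
#'   to the effective alignment length.
#' @param seed Integer seed (mandatory); stage seeds are derived from it.
#' @param epsilon Median-joining relaxation parameter.
#' @return Invisibly, a list with every stage's result objects and the paths
#'   of the written tables.
#' @export
run_pipeline <- function(aln = NULL, fasta = NULL, popmap = NULL, outdir,
                         policy = "complete_deletion", perms = 1000,
                         boot = 100, n_sims = 1000, mu = 0.0177, k = NULL,
                         seed, epsilon = 0) {
  if (missing(seed)) stop("seed is required")
  stopifnot(perms >= 1, boot >= 0, n_sims >= 1)
  if (is.null(aln)) {
    if (is.null(fasta) || is.null(popmap)) {
      stop("provide either `aln` or both `fasta` and `popmap`")
    }
    aln <- read_alignment(fasta, popmap)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(...) {
    cat(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("mtphylogeo %s; seed = %d; policy = %s; perms = %d; boot = %d",
       as.character(utils::packageVersion("mtphylogeo")), seed, policy,
       perms, boot)

  faln <- filter_sites(aln, policy)
  logf("alignment: %d individuals, %d/%d columns retained",
       nrow(aln$mat), faln$k_eff, ncol(aln$mat))
  results <- list(alignment = aln, filtered = faln)
  paths <- character(0)

  pops <- unique(aln$population)
  pop_sizes <- table(aln$population)
  has_groups <- !is.null(aln$group_of)
  groups <- if (has_groups) unique(unname(aln$group_of)) else NULL

  # ---- per-population diversity table (one row per population) ----
  div_rows <- lapply(pops, function(p) {
    idx <- aln$population == p
    n_p <- sum(idx)
    row <- data.frame(population = p,
                      group = if (has_groups) unname(aln$group_of[p])
                              else NA_character_,
                      n = n_p, Nh = NA_integer_, Hd = EMDASH, S = EMDASH,
                      pi = EMDASH)
    sub <- subset_alignment(faln, idx)
    row$Nh <- collapse_haplotypes(sub)$Nh
    if (n_p >= 2L) {
      ds <- diversity_summary(sub)
      row$Hd <- fmt_or_dash(ds$Hd, 3)
      row$S <- as.character(ds$S)
      row$pi <- fmt_or_dash(ds$pi, 5)
    }
    row
  })
  div_tab <- do.call(rbind, div_rows)
  p_div <- file.path(outdir, "diversity_populations.tsv")
  utils::write.table(div_tab, p_div, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p_div)
  results$diversity_populations <- div_tab

  # ---- per-group table (pooled individuals) + ALL row ----
  pool_row <- function(label, idx) {
    sub <- subset_alignment(faln, idx)
    ds <- diversity_summary(sub)
    data.frame(group = label, n = ds$n, Nh = ds$Nh,
               Hd = fmt_or_dash(ds$Hd, 3), pi = fmt_or_dash(ds$pi, 5))
  }
  grp_rows <- list()
  if (has_groups) {
    for (g in groups) {
      idx <- unname(aln$group_of[aln$population]) == g
      grp_rows[[g]] <- if (sum(idx) >= 2L) pool_row(g, idx) else
        data.frame(group = g, n = sum(idx),
                   Nh = collapse_haplotypes(subset_alignment(faln, idx))$Nh,
                   Hd = EMDASH, pi = EMDASH)
    }
  }
  grp_rows$ALL <- pool_row("ALL", rep(TRUE, nrow(aln$mat)))
  grp_tab <- do.call(rbind, grp_rows)
  p_grp <- file.path(outdir, "diversity_groups.tsv")
  utils::write.table(grp_tab, p_grp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p_grp)
  results$diversity_groups <- grp_tab

  # ---- differentiation stages ----
  if (length(pops) < 2L) {
    logf("single population: differentiation stages skipped")
  } else {
    enough <- sum(pop_sizes >= 2L) >= 2L
    if (enough) {
      gn <- suppressWarnings(gst_nst(faln, B = perms, seed = seed + 1L))
      verdict <- if (gn$Nst > gn$Gst && gn$p_value < 0.05) {
        "significant phylogeographic structure (Nst significantly > Gst)"
      } else "no significant phylogeographic structure"
      p_gn <- file.path(outdir, "gst_nst.tsv")
      utils::write.table(
        data.frame(Gst = gn$Gst, Nst = gn$Nst, p_value = gn$p_value,
                   permutations = gn$n_permutations, verdict = verdict),
        p_gn, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p_gn)
      results$gst_nst <- gn
      logf("Gst = %.5f, Nst = %.5f, p = %.4g -> %s", gn$Gst, gn$Nst,
           gn$p_value, verdict)
    } else {
      logf("fewer than two populations with n >= 2: Gst/Nst skipped")
    }

    if (has_groups && length(groups) >= 2L) {
      am <- amova(faln, B = perms, seed = seed + 2L)
      am_tab <- data.frame(
        source = c("Among groups", "Among populations within groups",
                   "Within populations"),
        df = am$df, SSD = am$ssd,
        variance = am$variance_components,
        percentage = am$percentages,
        phi = c(am$phi["Phi_CT"], am$phi["Phi_SC"], am$phi["Phi_ST"]),
        p_value = c(am$p_values["Phi_CT"], am$p_values["Phi_SC"],
                    am$p_values["Phi_ST"]))
      p_am <- file.path(outdir, "amova.tsv")
      utils::write.table(am_tab, p_am, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p_am)
      results$amova <- am
      logf("AMOVA percentages: %.2f / %.2f / %.2f",
           am$percentages[1], am$percentages[2], am$percentages[3])
    }

    fst_pop <- suppressWarnings(
      pairwise_fst(faln, "population", B = perms, seed = seed + 3L))
    p_fp <- file.path(outdir, "fst_nm_populations.tsv")
    write_fst_nm_matrix(fst_pop, p_fp)
    paths <- c(paths, p_fp)
    results$fst_populations <- fst_pop
    if (has_groups && length(groups) >= 2L) {
      fst_grp <- suppressWarnings(
        pairwise_fst(faln, "group", B = perms, seed = seed + 4L))
      p_fg <- file.path(outdir, "fst_nm_groups.tsv")
      write_fst_nm_matrix(fst_grp, p_fg)
      paths <- c(paths, p_fg)
      results$fst_groups <- fst_grp
    }
  }

  # ---- neutrality + mismatch per group and overall ----
  units <- list(ALL = rep(TRUE, nrow(aln$mat)))
  if (has_groups) {
    for (g in groups) {
      units[[g]] <- unname(aln$group_of[aln$population]) == g
    }
  }
  neut_rows <- list()
  for (u in names(units)) {
    idx <- units[[u]]
    n_u <- sum(idx)
    row <- data.frame(group = u, n = n_u, D = EMDASH, D_stars = "",
                      Fs = EMDASH, Fs_stars = "", SSD = EMDASH,
                      p_SSD = EMDASH, r = EMDASH, p_r = EMDASH,
                      tau = EMDASH, theta0 = EMDASH, theta1 = EMDASH,
                      t_Myr = EMDASH)
    if (n_u >= 4L) {
      sub <- subset_alignment(faln, idx)
      if (classify_sites(sub)$S >= 1L) {
        nt <- neutrality_pvalues(sub, n_sims = n_sims, seed = seed + 5L)
        row$D <- fmt_or_dash(nt$D); row$D_stars <- nt$stars_D
        row$Fs <- fmt_or_dash(nt$Fs); row$Fs_stars <- nt$stars_Fs
        ms <- mismatch_spectrum(sub)
        ft <- fit_sudden_expansion(ms, B = boot, seed = seed + 6L)
        row$SSD <- fmt_or_dash(ft$SSD); row$p_SSD <- fmt_or_dash(ft$p_SSD, 3)
        row$r <- fmt_or_dash(ft$raggedness_r, 6)
        row$p_r <- fmt_or_dash(ft$p_r, 3)
        row$tau <- fmt_or_dash(ft$tau, 3)
        row$theta0 <- fmt_or_dash(ft$theta0, 3)
        row$theta1 <- fmt_or_dash(ft$theta1, 3)
        k_use <- if (is.null(k)) faln$k_eff else k
        row$t_Myr <- fmt_or_dash(expansion_time(ft$tau, mu, k_use), 4)
        results$mismatch[[u]] <- list(spectrum = ms, fit = ft)
        results$neutrality[[u]] <- nt
      }
    }
    neut_rows[[u]] <- row
  }
  neut_tab <- do.call(rbind, neut_rows)
  p_nt <- file.path(outdir, "neutrality_mismatch.tsv")
  utils::write.table(neut_tab, p_nt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p_nt)
  results$neutrality_table <- neut_tab

  # ---- haplotype network ----
  hs <- collapse_haplotypes(faln)
  net <- mj_network(hs, epsilon = epsilon)
  p_ne <- file.path(outdir, "network_edges.tsv")
  p_nn <- file.path(outdir, "network_nodes.tsv")
  write_network_tables(net, p_ne, p_nn)
  paths <- c(paths, p_ne, p_nn)
  results$network <- net
  results$network_summary <- network_summary(
    net, group_of = if (has_groups) aln$group_of else NULL)
  logf("network: %d sampled haplotypes, %d median vectors",
       sum(net$nodes$type == "sampled"), sum(net$nodes$type == "median"))

  results$paths <- paths
  logf("done: %d tables written", length(paths))
  invisible(results)
}

# Combined half-matrix: lower triangle Fst, upper triangle Nm, with the
# conventional thresholds noted in header comments.
write_fst_nm_matrix <- function(fst, path) {
  U <- length(fst$labels)
  m <- matrix("0", U, U, dimnames = list(fst$labels, fst$labels))
  for (i in seq_len(U)) {
    for (j in seq_len(U)) {
      if (i > j) m[i, j] <- formatC(fst$fst[i, j], digits = 4, format = "f")
      if (i < j) {
        m[i, j] <- if (is.infinite(fst$nm[i, j])) "Inf"
                   else formatC(fst$nm[i, j], digits = 4, format = "f")
      }
    }
  }
  con <- file(path, "w")
  writeLines(c(
    "# lower triangle: Fst (values > 0.25 indicate significant differentiation)",
    "# upper triangle: Nm (values > 1 indicate frequent gene flow)"), con)
  utils::write.table(cbind(unit = rownames(m), m), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
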