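#' Configure a structured-coalescent simulation
#'
#' Demography: a two-tier island model.  Demes are grouped; migration between
#' demes of the same group runs at scaled rate `M_within` (per lineage,
#' divided equally among same-group targets) and between demes of different
#' groups at `M_between`.  Time is in coalescent units of N (haploid)
#' generations; `theta = 2 N mu_locus` is the per-locus scaled mutation rate.
#' An optional sudden expansion divides the population size by `growth` at
#' time `tau / theta` in the past (i.e. `tau` is the expansion age in
#' mutational units, the same units the mismatch-distribution model uses).
#' At `t_pool` (coalescent units) all structure collapses into a single
#' panmictic deme, which is how deeply diverged groups (isolated refugia that
#' split from one ancestral population) are represented; `t_pool = Inf`
#' keeps the island model stationary.
#'
#' @param n_groups Number of groups.
#' @param demes_per_group Demes per group; scalar or vector of length
#'   `n_groups`.
#' @param samples_per_deme Sampled individuals per deme; scalar or vector
#'   over all demes (group-major order).
#' @param theta Scaled per-locus mutation rate (2 N mu_locus).
#' @param M_within,M_between Scaled migration rates; `M_between` must not
#'   exceed `M_within` in hierarchical scenarios (warning otherwise).
#' @param expansion Optional `list(tau = , growth = )` sudden expansion.
#' @param t_pool Time at which all demes merge into one (default `Inf`).
#' @param L Sequence length in columns.
#' @param mutation_model `"infinite_sites"` (each mutation hits a new column)
#'   or `"jukes_cantor"` (columns drawn with replacement, equal-rate
#'   substitution; allows homoplasy).
#' @return A `demography_config` list.
#' @export
demography_config <- function(n_groups = 1, demes_per_group = 1,
                              samples_per_deme = 10, theta = 5,
                              M_within = 1, M_between = 0,
                              expansion = NULL, t_pool = Inf,
                              L = 1000,
                              mutation_model = c("infinite_sites",
                                                 "jukes_cantor")) {
  mutation_model <- match.arg(mutation_model)
  stopifnot(n_groups >= 1, all(demes_per_group >= 1),
            all(samples_per_deme >= 1), theta >= 0,
            M_within >= 0, M_between >= 0, L >= 1)
  demes_per_group <- rep_len(demes_per_group, n_groups)
  n_demes <- sum(demes_per_group)
  samples_per_deme <- rep_len(samples_per_deme, n_demes)
  if (!is.null(expansion)) {
    stopifnot(is.list(expansion), expansion$tau >= 0, expansion$growth >= 1)
  }
  if (n_groups > 1 && M_between > M_within) {
    warning("M_between exceeds M_within in a hierarchical scenario")
  }
  if (n_demes > 1 && M_within == 0 && M_between == 0 && !is.finite(t_pool)) {
    stop("isolated demes with t_pool = Inf can never find a common ancestor")
  }
  structure(list(
    n_groups = n_groups, demes_per_group = demes_per_group,
    samples_per_deme = samples_per_deme, theta = theta,
    M_within = M_within, M_between = M_between,
    expansion = expansion, t_pool = t_pool, L = L,
    mutation_model = mutation_model,
    group_of_deme = rep(seq_len(n_groups), demes_per_group)
  ), class = "demography_config")
}

# Simulate the genealogy of the configured sample: backward-in-time
# structured coalescent with exponential waiting times.  Returns parent and
# branch-length arrays over 2n-1 nodes (leaves 1..n) plus the deme of each
# leaf.  Uses the current RNG stream.
sim_genealogy <- function(cfg) {
  n_demes <- length(cfg$samples_per_deme)
  n <- sum(cfg$samples_per_deme)
  leaf_deme <- rep(seq_len(n_demes), cfg$samples_per_deme)
  group_of <- cfg$group_of_deme

  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active_node <- seq_len(n)          # node id of each active lineage
  active_deme <- leaf_deme
  t <- 0
  next_node <- n + 1L
  t_exp <- if (is.null(cfg$expansion) || cfg$theta == 0) Inf else
    cfg$expansion$tau / cfg$theta
  growth <- if (is.null(cfg$expansion)) 1 else cfg$expansion$growth
  pooled <- !is.finite(cfg$t_pool) && n_demes == 1L

  while (length(active_node) > 1L) {
    rate_factor <- if (t >= t_exp) growth else 1
    if (is.finite(cfg$t_pool) && t >= cfg$t_pool) {
      active_deme[] <- 1L
      pooled <- TRUE
    }
    k_by_deme <- tabulate(active_deme, nbins = n_demes)
    coal_rate_deme <- k_by_deme * (k_by_deme - 1) / 2 * rate_factor
    coal_rate <- sum(coal_rate_deme)
    mig_rate_per <- if (pooled) 0 else {
      same_targets <- cfg$demes_per_group[group_of[active_deme]] - 1L
      other_targets <- n_demes - same_targets - 1L
      (ifelse(same_targets > 0, cfg$M_within, 0) +
         ifelse(other_targets > 0, cfg$M_between, 0)) / 2
    }
    mig_rate <- if (pooled) 0 else sum(mig_rate_per)
    total <- coal_rate + mig_rate
    if (total == 0) {
      # jump to the next demographic epoch
      nxt <- min(t_exp[t < t_exp], cfg$t_pool[t < cfg$t_pool], Inf)
      if (!is.finite(nxt)) stop("coalescent cannot proceed: zero event rate")
      t <- nxt
      next
    }
    dt <- stats::rexp(1L, total)
    # event must not straddle an epoch boundary where rates change
    boundary <- min(t_exp[t < t_exp], cfg$t_pool[t < cfg$t_pool], Inf)
    if (t + dt > boundary) {
      t <- boundary
      next
    }
    t <- t + dt
    if (stats::runif(1L) < coal_rate / total) {
      d <- sample.int(n_demes, 1L, prob = coal_rate_deme)
      pair <- sample(which(active_deme == d), 2L)
      anc <- next_node; next_node <- next_node + 1L
      parent[active_node[pair]] <- anc
      node_time[anc] <- t
      active_node[pair[1L]] <- anc
      active_node <- active_node[-pair[2L]]
      active_deme <- active_deme[-pair[2L]]
    } else {
      li <- sample.int(length(active_node), 1L,
                       prob = rep_len(mig_rate_per, length(active_node)))
      from <- active_deme[li]
      same <- setdiff(which(group_of == group_of[from]), from)
      other <- which(group_of != group_of[from])
      w <- c(rep(if (length(same)) cfg$M_within / length(same) else 0,
                 length(same)),
             rep(if (length(other)) cfg$M_between / length(other) else 0,
                 length(other)))
      dest <- c(same, other)
      active_deme[li] <- dest[sample.int(length(dest), 1L, prob = w)]
    }
  }
  branch_len <- numeric(n_nodes)
  has_parent <- parent > 0L
  branch_len[has_parent] <- node_time[parent[has_parent]] -
    node_time[seq_len(n_nodes)][has_parent]
  list(n = n, parent = parent, branch_len = branch_len,
       node_time = node_time, leaf_deme = leaf_deme)
}

# Number of sampled descendants below each node.
descendant_counts <- function(gen) {
  n_nodes <- length(gen$parent)
  sz <- c(rep(1L, gen$n), rep(0L, n_nodes - gen$n))
  for (v in order(gen$node_time[seq_len(n_nodes)])) {
    p <- gen$parent[v]
    if (p > 0L) sz[p] <- sz[p] + sz[v]
  }
  sz
}

# Drop mutations on a genealogy and summarize S, k_bar and Nh without
# building sequences (infinite-sites assumption).
genealogy_stats <- function(gen, theta) {
  n <- gen$n
  muts <- stats::rpois(length(gen$branch_len), theta / 2 * gen$branch_len)
  sz <- descendant_counts(gen)
  S <- sum(muts)
  k_bar <- sum(muts * sz * (n - sz)) / choose(n, 2)
  # haplotype classes: leaf label changes across any mutated branch
  n_nodes <- length(gen$parent)
  lab <- integer(n_nodes)
  root <- which(gen$parent == 0L)
  lab[root] <- 1L
  next_lab <- 2L
  for (v in order(gen$node_time[seq_len(n_nodes)], decreasing = TRUE)) {
    p <- gen$parent[v]
    if (p == 0L) next
    if (muts[v] > 0L) {
      lab[v] <- next_lab; next_lab <- next_lab + 1L
    } else {
      lab[v] <- lab[p]
    }
  }
  list(S = S, k_bar = k_bar, Nh = length(unique(lab[seq_len(n)])),
       muts = muts)
}

#' Simulate a dataset under the configured demography
#'
#' Runs the structured coalescent backward in time, drops mutations on the
#' genealogy as a Poisson process with rate `theta/2` per lineage per unit
#' time, and translates them into sequences.  Under `infinite_sites` every
#' mutation occupies a fresh column drawn without replacement from `1..L`;
#' under `jukes_cantor` columns are drawn with replacement and each hit
#' substitutes an equal-rate different nucleotide (allowing homoplasy).
#'
#' @param cfg A `demography_config`.
#' @param seed Integer seed; identical config + seed reproduces the dataset
#'   byte for byte.
#' @return A `simulated_dataset`: `alignment` (a `labeled_alignment` with
#'   populations `P01`, ... and groups `G1`, ...), `genealogy` (an
#'   `ape::phylo` with branch lengths in coalescent units) and `true_params`
#'   (the config).
#' @export
sim_coalescent <- function(cfg, seed) {
  stopifnot(inherits(cfg, "demography_config"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  gen <- sim_genealogy(cfg)
  n <- gen$n
  muts <- stats::rpois(length(gen$branch_len), cfg$theta / 2 * gen$branch_len)
  total_muts <- sum(muts)
  if (cfg$mutation_model == "infinite_sites") {
    if (total_muts > cfg$L) {
      stop("infinite-sites capacity exhausted (", total_muts,
           " mutations > L = ", cfg$L, "); increase L")
    }
    sites <- sample.int(cfg$L, total_muts, replace = FALSE)
  } else {
    sites <- sample.int(cfg$L, total_muts, replace = TRUE)
  }
  ancestral <- sample(ACGT, cfg$L, replace = TRUE)
  # sequences by walking down from the root applying each branch's mutations
  n_nodes <- length(gen$parent)
  seqs <- vector("list", n_nodes)
  root <- which(gen$parent == 0L)
  site_of_branch <- split(sites, rep(seq_len(n_nodes), muts))
  seqs[[root]] <- ancestral
  for (v in order(gen$node_time[seq_len(n_nodes)], decreasing = TRUE)) {
    p <- gen$parent[v]
    if (p == 0L) next
    s <- seqs[[p]]
    hit <- site_of_branch[[as.character(v)]]
    for (col in hit) {
      s[col] <- sample(setdiff(ACGT, s[col]), 1L)
    }
    seqs[[v]] <- s
  }
  mat <- do.call(rbind, seqs[seq_len(n)])
  ids <- sprintf("ind%03d", seq_len(n))
  rownames(mat) <- ids
  pops <- sprintf("P%02d", gen$leaf_deme)
  deme_labels <- sprintf("P%02d", seq_along(cfg$group_of_deme))
  group_of <- stats::setNames(sprintf("G%d", cfg$group_of_deme), deme_labels)
  aln <- labeled_alignment(mat, stats::setNames(pops, ids),
                           if (cfg$n_groups > 1) group_of else NULL)
  structure(list(alignment = aln,
                 genealogy = genealogy_to_phylo(gen),
                 true_params = cfg),
            class = "simulated_dataset")
}

# Convert the internal genealogy arrays to an ape "phylo" object.
genealogy_to_phylo <- function(gen) {
  n <- gen$n
  n_nodes <- length(gen$parent)
  if (n == 1L) {
    return(structure(list(edge = matrix(integer(0), 0, 2),
                          tip.label = "ind001", Nnode = 0L),
                     class = "phylo"))
  }
  # ape numbering: tips 1..n, root n+1, internals follow
  internal <- (n + 1L):n_nodes
  ord <- internal[order(gen$node_time[internal], decreasing = TRUE)]
  new_id <- integer(n_nodes)
  new_id[seq_len(n)] <- seq_len(n)
  new_id[ord] <- n + seq_along(ord)
  child <- which(gen$parent > 0L)
  edge <- cbind(new_id[gen$parent[child]], new_id[child])
  structure(list(edge = edge,
                 edge.length = gen$branch_len[child],
                 tip.label = sprintf("ind%03d", seq_len(n)),
                 Nnode = n - 1L),
            class = "phylo")
}

# Fast replicate summaries (S, k_bar, Nh) for single-deme scenarios; used by
# neutrality p-values and simulator calibration.  Infinite-sites, no
# sequence construction.
sim_neutral_stats <- function(n, theta, reps, expansion = NULL) {
  cfg <- demography_config(n_groups = 1, demes_per_group = 1,
                           samples_per_deme = n, theta = theta,
                           expansion = expansion, L = 1)
  out <- matrix(0, reps, 3, dimnames = list(NULL, c("S", "k_bar", "Nh")))
  for (r in seq_len(reps)) {
    gen <- sim_genealogy(cfg)
    st <- genealogy_stats(gen, theta)
    out[r, ] <- c(st$S, st$k_bar, st$Nh)
  }
  as.data.frame(out)
}

#' Reference multi-population survey design
#'
#' A convenience scenario with the sampling layout of a typical range-wide
#' mitochondrial survey: 97 individuals in 24 populations assigned to 4
#' groups (10 + 12 + 1 + 1 populations of 1-6 individuals each), deeply
#' diverged groups (isolated until far in the past), restricted within-group
#' migration and a recent within-group sudden expansion.  Useful for
#' end-to-end pipeline demonstrations: among-group AMOVA variance dominates,
#' haplotype diversity is high and nucleotide diversity low.
#'
#' @param seed Integer seed.
#' @return A `simulated_dataset`.
#' @export
sim_survey_design <- function(seed) {
  sizes <- c(5, 3, 5, 5, 5, 5, 2, 4, 5, 5,              # group 1 (44)
             5, 5, 6, 4, 5, 5, 2, 5, 5, 1, 2, 1,        # group 2 (46)
             5,                                         # group 3
             2)                                         # group 4
  cfg <- demography_config(
    n_groups = 4, demes_per_group = c(10, 12, 1, 1),
    samples_per_deme = sizes,
    theta = 1.2, M_within = 4, M_between = 0,
    expansion = list(tau = 4, growth = 100),
    t_pool = 15, L = 3409,
    mutation_model = "infinite_sites"
  )
  sim_coalescent(cfg, seed)
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated dataset:\n  ")
  print(x$alignment)
  invisible(x)
}

#' Write a simulated dataset to FASTA + popmap (+ truth JSON if jsonlite is
#' available)
#'
#' @param sim A `simulated_dataset`.
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.popmap.tsv` and `<prefix>.truth.json`.
#' @return Invisibly, the written paths.
#' @export
write_simulated_dataset <- function(sim, prefix) {
  stopifnot(inherits(sim, "simulated_dataset"))
  fasta <- paste0(prefix, ".fasta")
  popmap <- paste0(prefix, ".popmap.tsv")
  write_alignment(sim$alignment, fasta, popmap)
  paths <- c(fasta, popmap)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- paste0(prefix, ".truth.json")
    cfg <- sim$true_params
    cfg$group_of_deme <- NULL
    jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)], truth,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth)
  }
  invisible(paths)
}
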