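# Median-joining haplotype networks: epsilon-relaxed minimum spanning
# network plus iteratively added quasi-median (consensus) vectors.

# Hamming distances between sequence strings (equal length).
string_hamming <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  codes <- match(m, unique(as.vector(m)))
  dim(codes) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (col in seq_len(ncol(m))) {
    d <- d + outer(codes[, col], codes[, col], "!=")
  }
  d
}

# Bottleneck (minimax-path) distances from an MST built by Prim's algorithm.
bottleneck_distances <- function(d) {
  n <- nrow(d)
  b <- matrix(0, n, n)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1, ]; best_from <- rep(1L, n)
  for (step in seq_len(n - 1L)) {
    v <- which(!in_tree)[which.min(best[!in_tree])]
    u <- best_from[v]
    w <- d[u, v]
    # bottleneck to v via u: max(bottleneck(x, u), w) for tree members x
    members <- which(in_tree)
    b[v, members] <- b[members, v] <- pmax(b[u, members], w)
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best
    best[upd] <- d[v, upd]
    best_from[upd] <- v
  }
  b
}

# Edge list of the epsilon-relaxed minimum spanning network: every pair
# (i, j) with d_ij <= bottleneck_ij + epsilon.  epsilon = 0 gives the MSN,
# which contains every minimum spanning tree.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) return(data.frame(from = integer(0), to = integer(0),
                                weight = numeric(0)))
  b <- bottleneck_distances(d)
  idx <- which(upper.tri(d) & d <= b + epsilon, arr.ind = TRUE)
  data.frame(from = idx[, 1], to = idx[, 2], weight = d[idx])
}

# Quasi-median (majority consensus) sequences of a triple.  Columns where
# all three states differ branch into one candidate per state; triples with
# more than `max_free` such columns are skipped (combinatorial blow-up).
quasi_medians <- function(s1, s2, s3, max_free = 2L) {
  a <- strsplit(c(s1, s2, s3), "")
  m <- rbind(a[[1]], a[[2]], a[[3]])
  cons <- character(ncol(m))
  free <- integer(0)
  for (col in seq_len(ncol(m))) {
    states <- m[, col]
    tab <- table(states)
    if (max(tab) >= 2L) {
      cons[col] <- names(tab)[which.max(tab)]
    } else {
      free <- c(free, col)
    }
  }
  if (length(free) > max_free) return(character(0))
  if (length(free) == 0L) return(paste0(cons, collapse = ""))
  combos <- expand.grid(lapply(free, function(col) m[, col]),
                        stringsAsFactors = FALSE)
  out <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    x <- cons
    x[free] <- as.character(combos[r, ])
    out[r] <- paste0(x, collapse = "")
  }
  unique(out)
}

#' Median-joining haplotype network
#'
#' Builds the epsilon-relaxed minimum spanning network over the sampled
#' haplotypes, then iterates: for every connected triple, the quasi-median
#' (column-wise majority consensus) sequence is added as a median vector when
#' novel; the network is recomputed and obsolete median vectors (unsampled,
#' degree <= 2, whose removal does not lengthen the path between their
#' neighbours) are deleted, until a fixed point.  Site weights are uniform;
#' characters are the retained columns of the haplotype set.  The default
#' path is fully deterministic (haplotypes in first-occurrence order, medians
#' deduplicated by sequence); `seed` is accepted for API symmetry only.
#'
#' @param hs A `haplotype_set` with Nh >= 1.
#' @param epsilon Non-negative relaxation parameter (default 0).
#' @param seed Unused in the default deterministic path; kept for API
#'   symmetry.
#' @return A `haplotype_network`: `nodes` (data.frame: node, type
#'   sampled/median, sequence, total count), `edges` (node1, node2, weight in
#'   mutational steps), per-population counts, and `epsilon`.
#' @export
mj_network <- function(hs, epsilon = 0, seed = NULL) {
  stopifnot(inherits(hs, "haplotype_set"))
  if (hs$Nh == 0L) stop("empty haplotype set")
  stopifnot(epsilon >= 0)
  seqs <- hs$haplotypes
  sampled <- rep(TRUE, length(seqs))
  n_mv <- 0L
  mv_names <- character(0)

  for (iter in seq_len(50L)) {
    d <- string_hamming(seqs)
    edges <- msn_edges(d, epsilon)
    # connected triples: two edges sharing a node
    adj <- vector("list", length(seqs))
    for (e in seq_len(nrow(edges))) {
      adj[[edges$from[e]]] <- c(adj[[edges$from[e]]], edges$to[e])
      adj[[edges$to[e]]] <- c(adj[[edges$to[e]]], edges$from[e])
    }
    new_meds <- character(0)
    for (v in seq_along(seqs)) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      pairs <- utils::combn(sort(nb), 2L)
      for (pc in seq_len(ncol(pairs))) {
        qm <- quasi_medians(seqs[v], seqs[pairs[1, pc]], seqs[pairs[2, pc]])
        new_meds <- c(new_meds, qm)
      }
    }
    new_meds <- setdiff(unique(new_meds), seqs)
    changed <- FALSE
    if (length(new_meds) > 0L) {
      seqs <- c(seqs, new_meds)
      sampled <- c(sampled, rep(FALSE, length(new_meds)))
      changed <- TRUE
    }
    # prune obsolete median vectors on the recomputed network
    repeat {
      d <- string_hamming(seqs)
      edges <- msn_edges(d, epsilon)
      deg <- tabulate(c(edges$from, edges$to), nbins = length(seqs))
      drop <- NA_integer_
      for (v in which(!sampled)) {
        if (deg[v] <= 1L) { drop <- v; break }
        if (deg[v] == 2L) {
          nb <- c(edges$to[edges$from == v], edges$from[edges$to == v])
          if (d[nb[1], nb[2]] <= d[nb[1], v] + d[v, nb[2]]) {
            drop <- v; break
          }
        }
      }
      if (is.na(drop)) break
      seqs <- seqs[-drop]
      sampled <- sampled[-drop]
      changed <- TRUE
    }
    if (!changed) break
  }

  d <- string_hamming(seqs)
  edges <- msn_edges(d, epsilon)
  hap_ids <- rownames(hs$count_matrix)
  node_names <- character(length(seqs))
  is_s <- sampled
  node_names[is_s] <- hap_ids[match(seqs[is_s], hs$haplotypes)]
  node_names[!is_s] <- sprintf("mv%d", seq_len(sum(!is_s)))
  counts <- matrix(0L, length(seqs), ncol(hs$count_matrix),
                   dimnames = list(node_names, colnames(hs$count_matrix)))
  counts[is_s, ] <- hs$count_matrix[match(seqs[is_s], hs$haplotypes), ,
                                    drop = FALSE]
  nodes <- data.frame(node = node_names,
                      type = ifelse(is_s, "sampled", "median"),
                      sequence = seqs,
                      count = rowSums(counts))
  edges_named <- data.frame(node1 = node_names[edges$from],
                            node2 = node_names[edges$to],
                            weight = edges$weight)
  structure(list(nodes = nodes, edges = edges_named, counts = counts,
                 epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Median-joining network:", sum(x$nodes$type == "sampled"),
      "sampled haplotypes,", sum(x$nodes$type == "median"),
      "median vectors,", nrow(x$edges), "edges (epsilon =", x$epsilon, ")\n")
  invisible(x)
}

# igraph view of a haplotype network (weighted, undirected).
network_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Summary statistics of a haplotype network
#'
#' Clusters are defined by the population groups of the sampled haplotypes
#' (a haplotype belongs to the group contributing most of its copies); median
#' vectors are unassigned.  Reports per-cluster node and median counts and
#' the matrix of inter-cluster mutational distances: the shortest-path
#' (edge-weight) distance between the closest members of the two clusters,
#' plus the maximum shortest-path distance between any two members.
#'
#' @param net A `haplotype_network`.
#' @param group_of Optional named vector population -> group; when absent,
#'   populations themselves are the clusters.
#' @return A `network_summary` list: `clusters` (data.frame), `min_steps`
#'   and `max_steps` (cluster x cluster matrices).
#' @export
network_summary <- function(net, group_of = NULL) {
  stopifnot(inherits(net, "haplotype_network"))
  counts <- net$counts
  if (!is.null(group_of)) {
    counts <- t(rowsum(t(counts), unname(group_of[colnames(counts)])))
  }
  sampled <- net$nodes$type == "sampled"
  cluster <- rep(NA_character_, nrow(net$nodes))
  cluster[sampled] <- colnames(counts)[max.col(counts[sampled, ,
                                                      drop = FALSE])]
  g <- network_igraph(net)
  dm <- igraph::distances(g, weights = igraph::E(g)$weight)
  dm <- dm[net$nodes$node, net$nodes$node, drop = FALSE]
  labs <- sort(unique(stats::na.omit(cluster)))
  k <- length(labs)
  min_steps <- max_steps <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      block <- dm[cluster %in% labs[i], cluster %in% labs[j], drop = FALSE]
      if (i != j) min_steps[i, j] <- min(block)
      max_steps[i, j] <- max(block)
    }
  }
  clusters <- data.frame(
    cluster = labs,
    n_haplotypes = vapply(labs, function(l) sum(cluster == l, na.rm = TRUE),
                          0L),
    n_individuals = vapply(labs, function(l) {
      sum(net$nodes$count[cluster == l & !is.na(cluster)])
    }, 0)
  )
  structure(list(clusters = clusters,
                 n_medians = sum(net$nodes$type == "median"),
                 min_steps = min_steps, max_steps = max_steps),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  print(x$clusters)
  cat(x$n_medians, "median vectors\n")
  invisible(x)
}

#' Write network edge and node tables (and optional GraphML)
#'
#' @param net A `haplotype_network`.
#' @param edge_path,node_path Output TSVs.
#' @param graphml_path Optional GraphML output.
#' @return Invisibly, the written paths.
#' @export
write_network_tables <- function(net, edge_path, node_path,
                                 graphml_path = NULL) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  node_df <- cbind(net$nodes[, c("node", "type")], net$counts)
  utils::write.table(node_df, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(edge_path, node_path)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network_igraph(net), graphml_path, format = "graphml")
    paths <- c(paths, graphml_path)
  }
  invisible(paths)
}
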