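test_that("two haplotypes one step apart give a single weight-1 edge", {
  hs <- collapse_haplotypes(make_faln(c("AAAA", "AAAT", "AAAT"), rep("p", 3)))
  net <- mj_network(hs)
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 1)
  expect_equal(sum(net$nodes$type == "median"), 0L)
})

test_that("three mutually distant haplotypes gain the brute-force Steiner median", {
  # pairwise distance 2 via disjoint private sites; the optimal Steiner
  # point is the all-A consensus, turning 3 weight-2 links into 3 weight-1
  seqs <- c("TAA", "ATA", "AAT")
  hs <- collapse_haplotypes(make_faln(seqs, rep("p", 3)))
  net <- mj_network(hs)
  medians <- net$nodes$sequence[net$nodes$type == "median"]
  want <- oracle_steiner1(seqs)
  expect_lt(want$best_len, want$base_len)
  expect_equal(medians, want$best_points)
  expect_equal(sort(net$edges$weight), c(1, 1, 1))
  # median joined to all three sampled haplotypes
  mv <- net$nodes$node[net$nodes$type == "median"]
  expect_equal(sum(net$edges$node1 == mv | net$edges$node2 == mv), 3L)
})

test_that("the epsilon = 0 network contains a minimum spanning tree and stays connected", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    seqs <- unique(apply(matrix(sample(c("A", "T", "G"), n * 8, replace = TRUE),
                                n), 1, paste0, collapse = ""))
    hs <- collapse_haplotypes(make_faln(seqs, rep("p", length(seqs))))
    net <- mj_network(hs)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$node)
    expect_true(igraph::is_connected(g))
    expect_true(all(net$edges$weight >= 1))
    # every MST edge over the sampled haplotypes survives in the epsilon = 0
    # minimum spanning network (before medians are added)
    d <- oracle_hamming(seqs)
    msn <- mtphylogeo:::msn_edges(d, epsilon = 0)
    mst <- as.matrix(ape::mst(as.dist(d)))
    mst_edges <- which(mst == 1 & upper.tri(d), arr.ind = TRUE)
    for (e in seq_len(nrow(mst_edges))) {
      i <- mst_edges[e, 1]; j <- mst_edges[e, 2]
      expect_true(any((msn$from == i & msn$to == j) |
                        (msn$from == j & msn$to == i)))
    }
    # graph path lengths can never undercut the direct mutational distance
    hap_ids <- net$nodes$node[net$nodes$type == "sampled"]
    dg <- igraph::distances(g, v = hap_ids, to = hap_ids,
                            weights = igraph::E(g)$weight)
    expect_true(all(dg >= d - 1e-9))
  }
})

test_that("median vectors stay within the site-span of the sampled haplotypes", {
  set.seed(15)
  seqs <- c("AAAA", "TTAA", "ATTA", "TATA", "AATT")
  hs <- collapse_haplotypes(make_faln(seqs, rep("p", 5)))
  net <- mj_network(hs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (mv in net$nodes$sequence[net$nodes$type == "median"]) {
    mvc <- strsplit(mv, "")[[1]]
    for (col in seq_along(mvc)) {
      expect_true(mvc[col] %in% chars[, col])
    }
  }
})

test_that("increasing epsilon never loses the epsilon = 0 sampled structure", {
  seqs <- c("AAAA", "AATT", "TTAA", "ATAT")
  hs <- collapse_haplotypes(make_faln(seqs, rep("p", 4)))
  net0 <- mj_network(hs, epsilon = 0)
  net1 <- mj_network(hs, epsilon = 1)
  expect_true(all(net0$nodes$sequence[net0$nodes$type == "sampled"] %in%
                    net1$nodes$sequence))
  expect_gte(nrow(net1$edges), nrow(net0$edges))
})

test_that("network summary reports cluster sizes and mutational step distances", {
  # single node
  hs1 <- collapse_haplotypes(make_faln(rep("AAAA", 3), rep("p", 3)))
  s1 <- network_summary(mj_network(hs1))
  expect_equal(max(s1$max_steps), 0)
  # two 2-node clusters joined by a long path: inter-cluster distance = 10
  a1 <- paste0(rep("A", 12), collapse = "")
  a2 <- paste0(c("T", rep("A", 11)), collapse = "")          # 1 step from a1
  b1 <- paste0(c(rep("A", 2), rep("T", 10)), collapse = "")  # 10 steps from a1
  b2 <- paste0(c("A", "T", rep("T", 10)), collapse = "")     # 1 step from b1
  hs <- collapse_haplotypes(make_faln(c(a1, a2, b1, b2),
                                      c("pA", "pA", "pB", "pB")))
  net <- mj_network(hs)
  s <- network_summary(net)
  expect_equal(s$min_steps["pA", "pB"], 10)
  expect_gte(s$max_steps["pA", "pB"], 10)
})

test_that("simulated four-group data cluster by group with long inter-group paths", {
  sim <- sim_coalescent(demography_config(
    n_groups = 4, demes_per_group = 2, samples_per_deme = 4,
    theta = 1.5, M_within = 4, M_between = 0, t_pool = 15, L = 3000), seed = 51)
  faln <- filter_sites(sim$alignment)
  hs <- collapse_haplotypes(faln)
  net <- mj_network(hs)
  s <- network_summary(net, group_of = sim$alignment$group_of)
  inter <- s$min_steps[upper.tri(s$min_steps)]
  intra <- diag(s$max_steps)
  expect_true(all(inter > 0))
  expect_gt(min(inter), max(0, min(intra)))
  # no haplotype shared between groups
  grp_counts <- t(rowsum(t(net$counts),
                         unname(sim$alignment$group_of[colnames(net$counts)])))
  sampled <- net$nodes$type == "sampled"
  expect_true(all(rowSums(grp_counts[sampled, ] > 0) == 1))
  expect_error(mj_network(structure(list(Nh = 0L), class = "haplotype_set")),
               "empty")
})
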