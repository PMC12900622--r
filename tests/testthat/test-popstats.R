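test_that("haplotype diversity reproduces the forced textbook values", {
  # 5 pairwise-distinct sequences
  hs <- collapse_haplotypes(make_faln(distinct_seqs(5), rep("p", 5)))
  expect_equal(haplotype_diversity(hs), 1.0, tolerance = 1e-12)
  # monomorphic sample of 5
  hs0 <- collapse_haplotypes(make_faln(rep("ACGTACGTAC", 5), rep("p", 5)))
  expect_identical(haplotype_diversity(hs0), 0)
  # counts {2, 3} at n = 5: 5/4 * (1 - (4 + 9)/25) = 0.600
  hs23 <- collapse_haplotypes(make_faln(
    c("AAAA", "AAAA", "AAAT", "AAAT", "AAAT"), rep("p", 5)))
  expect_equal(haplotype_diversity(hs23), 0.6, tolerance = 1e-12)
  expect_error(haplotype_diversity(
    collapse_haplotypes(make_faln("ACGT", "p", ids = "x"))), "n < 2")
})

test_that("Hd is invariant to haplotype labels and 1 for all-distinct samples", {
  for (n in c(2, 5, 9)) {
    hs <- collapse_haplotypes(make_faln(distinct_seqs(n), rep("p", n)))
    expect_equal(haplotype_diversity(hs), 1.0, tolerance = 1e-12)
  }
  set.seed(3)
  seqs <- sample(c("AAAA", "AATA", "CAAA", "AAAC"), 12, replace = TRUE)
  hs <- collapse_haplotypes(make_faln(seqs, rep("p", 12)))
  hs_perm <- collapse_haplotypes(make_faln(rev(seqs), rep("p", 12)))
  expect_equal(haplotype_diversity(hs), haplotype_diversity(hs_perm))
})

test_that("nucleotide diversity equals brute-force pair enumeration", {
  # two sequences differing at 1 of 10 sites
  faln <- make_faln(c("AAAAAAAAAA", "AAAAAAAAAT"), rep("p", 2))
  expect_equal(nucleotide_diversity(faln), 0.1, tolerance = 1e-12)
  # monomorphic
  expect_equal(nucleotide_diversity(make_faln(rep("ACGT", 5), rep("p", 5))), 0)
  # 4-sequence toy vs exhaustive enumeration
  seqs <- c("ACGTAC", "ACGTAT", "AAGTAC", "TCGAAC")
  faln <- make_faln(seqs, rep("p", 4))
  expect_equal(nucleotide_diversity(faln), oracle_pi(seqs), tolerance = 1e-12)
  # pairwise policy scales each pair by its own valid length
  aln <- make_aln(c("ANAA", "AATA"), rep("p", 2))
  expect_equal(nucleotide_diversity(filter_sites(aln, "pairwise")), 1 / 3)
})

test_that("Watterson's theta follows S / (a1 k_eff)", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(3, 2, 100), 0.03)
  expect_equal(watterson_theta(5, 5, 1000), 5 / ((1 + 1/2 + 1/3 + 1/4) * 1000),
               tolerance = 1e-12)
  expect_error(watterson_theta(3, 1, 100), "n < 2")
})

test_that("gene flow reproduces the printed island-model conversions", {
  pairs <- rbind(c(0.6895, 0.1126), c(0.9043, 0.02645), c(0.7451, 0.08554),
                 c(0.9199, 0.02176), c(0.7957, 0.06419), c(0.9494, 0.01333))
  for (r in seq_len(nrow(pairs))) {
    expect_equal(gene_flow(pairs[r, 1]), pairs[r, 2], tolerance = 5e-4)
  }
  expect_identical(gene_flow(1), 0)
  expect_identical(gene_flow(0), Inf)
  expect_error(gene_flow(-0.1), "\\[0, 1\\]")
  expect_error(gene_flow(1.1), "\\[0, 1\\]")
  # strictly decreasing on (0, 1]
  x <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(gene_flow(x)) < 0))
})

test_that("diversity threshold flags use strict inequalities", {
  expect_equal(classify_diversity(0.994, 0.00371),
               list(high_Hd = TRUE, high_pi = FALSE))
  expect_equal(classify_diversity(0.5, 0.005),
               list(high_Hd = FALSE, high_pi = FALSE))
  expect_equal(classify_diversity(0.938, 0.00133),
               list(high_Hd = TRUE, high_pi = FALSE))
  expect_equal(classify_diversity(0.51, 0.0051),
               list(high_Hd = TRUE, high_pi = TRUE))
})

test_that("Gst/Nst matches the hand-computed diversity decomposition", {
  # mixed compositions: pop A {h1 x3, h2 x2}, pop B {h2 x1, h3 x4},
  # haplotypes at controlled mutational distances
  h1 <- "AAAAAAAAAA"; h2 <- "TAAAAAAAAA"; h3 <- "TTTTTTTAAA"  # d13 = 7
  seqs <- c(h1, h1, h1, h2, h2, h2, h3, h3, h3, h3)
  pops <- c(rep("A", 5), rep("B", 5))
  faln <- make_faln(seqs, pops)
  res <- gst_nst(faln, B = 50, seed = 1)
  hs <- collapse_haplotypes(faln)
  delta <- oracle_hamming(hs$haplotypes) / faln$k_eff
  want <- oracle_gst_nst(unname(hs$assignment), pops, delta)
  expect_equal(res$Gst, unname(want["Gst"]), tolerance = 1e-9)
  expect_equal(res$Nst, unname(want["Nst"]), tolerance = 1e-9)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("populations fixed for distant haplotypes: Gst unchanged, Nst-aware oracle agrees", {
  run_case <- function(h2) {
    seqs <- c(rep("AAAAAAAAAA", 4), rep(h2, 4))
    pops <- rep(c("A", "B"), each = 4)
    faln <- make_faln(seqs, pops)
    res <- gst_nst(faln, B = 20, seed = 5)
    hs <- collapse_haplotypes(faln)
    delta <- oracle_hamming(hs$haplotypes) / faln$k_eff
    want <- oracle_gst_nst(unname(hs$assignment), pops, delta)
    expect_equal(res$Gst, unname(want["Gst"]), tolerance = 1e-9)
    expect_equal(res$Nst, unname(want["Nst"]), tolerance = 1e-9)
    res
  }
  near <- run_case("TAAAAAAAAA")   # 1 mutation apart
  far <- run_case("TTTTTTTTTT")    # 10 mutations apart
  expect_equal(near$Gst, far$Gst, tolerance = 1e-9)
})

test_that("identical population compositions give Gst and Nst near zero", {
  seqs <- rep(c(rep("AAAA", 10), rep("AATT", 10)), 2)
  pops <- rep(c("A", "B"), each = 20)
  faln <- make_faln(seqs, pops)
  res <- gst_nst(faln, B = 50, seed = 2)
  expect_lt(abs(res$Gst), 0.05)
  expect_lt(abs(res$Nst), 0.05)
  expect_gt(res$p_value, 0.05)
})

test_that("Gst/Nst permutation p-values are well calibrated on homogeneous data", {
  set.seed(99)
  pvals <- replicate(20, {
    seqs <- apply(matrix(sample(c("A", "T"), 8 * 12, replace = TRUE), 8),
                  1, paste0, collapse = "")
    faln <- make_faln(seqs, rep(c("A", "B"), each = 4))
    suppressWarnings(gst_nst(faln, B = 49, seed = sample.int(1e6, 1))$p_value)
  })
  # under the null p should not pile up near 0
  expect_gt(mean(pvals), 0.2)
  expect_lt(mean(pvals < 0.05), 0.3)
})
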