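test_that("FASTA + popmap round-trip preserves the alignment", {
  aln <- make_aln(c("ACGTACGTAC", "ACGTACGTAT", "ACGAACGTAC", "ACGTACGTAC"),
                  pops = c("p1", "p1", "p2", "p2"),
                  groups = c("g1", "g1", "g2", "g2"))
  paths <- write_fixture_files(aln)
  back <- read_alignment(paths["fasta"], paths["popmap"])
  expect_identical(back$mat, aln$mat)
  expect_identical(back$population, aln$population)
  expect_identical(back$group_of, aln$group_of)
  expect_equal(ncol(back$mat), 10L)
  expect_equal(nrow(back$mat), 4L)
})

test_that("input validation: unequal lengths, missing IDs, empty files", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "bad.fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), fasta)
  popmap <- file.path(dir, "pm.tsv")
  writeLines(c("a\tp1", "b\tp1"), popmap)
  expect_error(read_alignment(fasta, popmap), "not aligned")

  writeLines(c(">a", "ACGT", ">b", "ACGA"), fasta)
  writeLines("a\tp1", popmap)
  expect_error(read_alignment(fasta, popmap), "absent from population map")

  empty <- file.path(dir, "empty.fasta")
  writeLines(character(0), empty)
  expect_error(suppressWarnings(read_alignment(empty, popmap)))

  writeLines(c("# comment", "a\tp1\tg1", "b\tp1\tg1"), popmap)
  pm <- read_popmap(popmap)
  expect_equal(pm$individual, c("a", "b"))
  expect_equal(pm$group, c("g1", "g1"))
})

test_that("lowercase input is parsed case-insensitively and stored uppercase", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "lc.fasta")
  writeLines(c(">a", "acgt", ">b", "acga"), fasta)
  popmap <- file.path(dir, "pm.tsv")
  writeLines(c("a\tp1", "b\tp1"), popmap)
  aln <- read_alignment(fasta, popmap)
  expect_identical(as.vector(aln$mat[1, ]), c("A", "C", "G", "T"))
})

test_that("complete deletion removes every column with a gap or any IUPAC ambiguity", {
  ambigs <- c("-", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  for (ch in ambigs) {
    seqs <- c(paste0("AAAA", ch, "AAAAA"), "TAAAAAAAAA", "AAAAAAAAAA")
    faln <- make_faln(seqs, pops = rep("p", 3))
    expect_equal(faln$k_eff, 9L, info = ch)
    expect_false(5L %in% faln$retained_columns, info = ch)
  }
  # clean alignment retains everything
  faln <- make_faln(c("ACGT", "ACGA"), pops = c("p", "p"))
  expect_identical(faln$retained_columns, 1:4)
  # all columns dirty -> degenerate
  expect_error(make_faln(c("N-", "-N"), pops = c("p", "p")), "degenerate")
  # pairwise policy keeps all columns
  aln <- make_aln(c("AN", "AA"), pops = c("p", "p"))
  expect_equal(filter_sites(aln, "pairwise")$k_eff, 2L)
})

test_that("haplotype collapse matches brute-force identity classes", {
  faln <- make_faln(c("AAA", "AAT", "AAT", "GAA"), pops = rep("p", 4))
  hs <- collapse_haplotypes(faln)
  expect_equal(hs$Nh, 3L)
  expect_equal(unname(rowSums(hs$count_matrix)), c(1, 2, 1))
  expect_equal(sum(hs$count_matrix), hs$n)

  # monomorphic sample and all-distinct sample
  expect_equal(collapse_haplotypes(make_faln(rep("ACGT", 5), rep("p", 5)))$Nh, 1L)
  expect_equal(collapse_haplotypes(make_faln(distinct_seqs(5), rep("p", 5)))$Nh, 5L)
})

test_that("collapse is idempotent and invariant to row permutation", {
  seqs <- c("AAAA", "AATA", "AATA", "GAAA", "AAAA", "TTTT")
  faln <- make_faln(seqs, pops = rep("p", 6))
  hs <- collapse_haplotypes(faln)
  # collapsing the haplotype sequences again is a fixed point
  faln2 <- make_faln(hs$haplotypes, pops = rep("p", hs$Nh))
  hs2 <- collapse_haplotypes(faln2)
  expect_setequal(hs2$haplotypes, hs$haplotypes)
  expect_equal(hs2$Nh, hs$Nh)
  # permutation invariance of Nh
  set.seed(1)
  for (rep in 1:5) {
    perm <- sample(seq_along(seqs))
    hsp <- collapse_haplotypes(make_faln(seqs[perm], rep("p", 6)))
    expect_equal(hsp$Nh, hs$Nh)
  }
})

test_that("site classification identifies singletons and informative sites", {
  faln <- make_faln(c("AT", "AT", "AA", "TA"), pops = rep("p", 4))
  # column 1: A,A,A,T -> singleton; column 2: T,T,A,A -> informative
  sc <- classify_sites(faln)
  expect_equal(sc$S, 2L)
  expect_equal(sc$singletons, 1L)
  expect_equal(sc$parsimony_informative, 1L)
  expect_equal(unname(sc$per_site), c("singleton", "informative"))
  expect_equal(sc$S, sc$singletons + sc$parsimony_informative)

  mono <- classify_sites(make_faln(rep("ACGT", 4), rep("p", 4)))
  expect_equal(mono$S, 0L)
})

test_that("site counts are invariant under column permutation and commute with deletion", {
  set.seed(42)
  base <- matrix(sample(c("A", "C", "G", "T"), 60, replace = TRUE), nrow = 6)
  base[2, 4] <- "-"
  rownames(base) <- sprintf("i%d", 1:6)
  aln <- labeled_alignment(base, setNames(rep("p", 6), rownames(base)))
  sc1 <- classify_sites(filter_sites(aln))
  # column permutation
  perm <- sample(ncol(base))
  alnp <- labeled_alignment(base[, perm], setNames(rep("p", 6), rownames(base)))
  sc2 <- classify_sites(filter_sites(alnp))
  expect_equal(sc2$S, sc1$S)
  expect_equal(sc2$singletons, sc1$singletons)
  # deleting dirty columns first, then classifying all columns, agrees
  clean <- base[, colSums(!matrix(base %in% c("A", "C", "G", "T"),
                                  nrow = 6)) == 0]
  alnc <- labeled_alignment(clean, setNames(rep("p", 6), rownames(base)))
  sc3 <- classify_sites(filter_sites(alnc))
  expect_equal(sc3$S, sc1$S)
  expect_equal(sc3$parsimony_informative, sc1$parsimony_informative)
})
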