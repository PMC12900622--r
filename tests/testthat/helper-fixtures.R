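# In-code fixtures: small alignments with known properties.

# Alignment from a character vector of equal-length strings.
make_aln <- function(seqs, pops, groups = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("i%02d", seq_along(seqs))
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- ids
  group_of <- NULL
  if (!is.null(groups)) {
    group_of <- tapply(groups, pops, `[`, 1L)
  }
  labeled_alignment(m, stats::setNames(pops, ids), group_of)
}

make_faln <- function(seqs, pops, groups = NULL, ...) {
  filter_sites(make_aln(seqs, pops, groups, ...), "complete_deletion")
}

# n sequences of length L that are pairwise distinct: sequence i carries a
# private T at column i on an all-A background.
distinct_seqs <- function(n, L = max(n, 10)) {
  vapply(seq_len(n), function(i) {
    s <- rep("A", L); s[i] <- "T"; paste0(s, collapse = "")
  }, "")
}

# Write a FASTA + popmap pair into a temp dir; returns the two paths.
write_fixture_files <- function(aln, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  fasta <- file.path(dir, "aln.fasta")
  popmap <- file.path(dir, "popmap.tsv")
  write_alignment(aln, fasta, popmap)
  c(fasta = fasta, popmap = popmap)
}
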