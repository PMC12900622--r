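# Internal numeric helpers shared across modules.

# Integer-code a character matrix of nucleotides; anything outside A/C/G/T
# (gaps, N, IUPAC ambiguities) becomes NA.
seq_codes <- function(m) {
  codes <- match(m, ACGT)
  dim(codes) <- dim(m)
  rownames(codes) <- rownames(m)
  codes
}

# Pairwise difference and valid-comparison counts for all sequence pairs.
# Returns list(diffs, valid): n x n integer matrices.  Computed with four
# per-base crossproducts so large alignments stay in BLAS.
pairwise_counts <- function(codes) {
  n <- nrow(codes)
  valid_ind <- !is.na(codes)
  storage.mode(valid_ind) <- "double"
  valid <- tcrossprod(valid_ind)
  matches <- matrix(0, n, n)
  for (b in 1:4) {
    ind <- !is.na(codes) & codes == b
    storage.mode(ind) <- "double"
    matches <- matches + tcrossprod(ind)
  }
  diffs <- valid - matches
  dimnames(diffs) <- dimnames(valid) <- list(rownames(codes), rownames(codes))
  list(diffs = diffs, valid = valid)
}

# Pairwise difference counts between individuals of a filtered alignment on
# its retained columns.  Under complete deletion every retained column is
# comparable; under the pairwise policy each pair uses its mutually valid
# columns and `valid` varies by pair.
faln_pairwise <- function(faln) {
  pairwise_counts(seq_codes(faln_matrix(faln)))
}

# Harmonic mean.
harmonic_mean <- function(x) length(x) / sum(1 / x)

# Add-one permutation p-value with strict exceedance (perm >= obs counts).
perm_pvalue <- function(perm_stats, observed) {
  (sum(perm_stats >= observed) + 1) / (length(perm_stats) + 1)
}
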