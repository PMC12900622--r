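#' Read an aligned FASTA file together with a population map
#'
#' The alignment must be a true multiple sequence alignment (all records the
#' same length); each record ID must appear in the population map.  The map is
#' a 2- or 3-column tab-separated file: individual ID, population label and an
#' optional group label.  Lines starting with `#` are ignored.  Group labels
#' attach to populations, so every individual of a population must carry the
#' same group label.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param popmap_path Path to the population map TSV.
#' @return A `labeled_alignment` object: a character matrix (individuals x
#'   columns, uppercase) with a population factor and an optional
#'   population-to-group map attached.
#' @export
read_alignment <- function(fasta_path, popmap_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- ape::read.FASTA(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", fasta_path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: lengths range ",
         min(lens), "-", max(lens))
  }
  mat <- toupper(as.character(as.matrix(seqs)))
  pm <- read_popmap(popmap_path)
  missing_ids <- setdiff(rownames(mat), pm$individual)
  if (length(missing_ids) > 0L) {
    stop("individuals absent from population map: ",
         paste(missing_ids, collapse = ", "))
  }
  pm <- pm[match(rownames(mat), pm$individual), , drop = FALSE]
  group_of <- NULL
  if (!is.null(pm$group)) {
    gtab <- unique(pm[, c("population", "group")])
    if (anyDuplicated(gtab$population)) {
      stop("population mapped to more than one group")
    }
    group_of <- stats::setNames(gtab$group, gtab$population)
  }
  labeled_alignment(mat, stats::setNames(pm$population, pm$individual),
                    group_of)
}

#' Construct a labeled alignment from in-memory data
#'
#' @param mat Character matrix, one row per individual (rownames are IDs),
#'   one column per alignment position.  Stored uppercase.
#' @param population_of Named character vector mapping individual ID to
#'   population label; must cover every row of `mat`.
#' @param group_of Optional named character vector mapping population label to
#'   group label; if given it must cover every population.
#' @return A `labeled_alignment`.
#' @export
labeled_alignment <- function(mat, population_of, group_of = NULL) {
  stopifnot(is.matrix(mat), is.character(mat), nrow(mat) >= 1L,
            ncol(mat) >= 1L)
  if (is.null(rownames(mat))) stop("alignment rows must be named")
  if (anyDuplicated(rownames(mat))) stop("duplicate individual IDs")
  mat <- toupper(mat)
  missing <- setdiff(rownames(mat), names(population_of))
  if (length(missing) > 0L) {
    stop("individuals missing from population map: ",
         paste(missing, collapse = ", "))
  }
  pops <- unname(population_of[rownames(mat)])
  if (!is.null(group_of)) {
    nog <- setdiff(unique(pops), names(group_of))
    if (length(nog) > 0L) {
      stop("populations missing a group label: ", paste(nog, collapse = ", "))
    }
    group_of <- group_of[unique(pops)]
    group_of <- stats::setNames(as.character(group_of), names(group_of))
  }
  structure(list(mat = mat, population = pops, group_of = group_of),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("Labeled alignment:", nrow(x$mat), "individuals x", ncol(x$mat),
      "columns;", length(unique(x$population)), "populations")
  if (!is.null(x$group_of)) {
    cat(";", length(unique(x$group_of)), "groups")
  }
  cat("\n")
  invisible(x)
}

# Characters accepted as unambiguous nucleotides everywhere downstream.
ACGT <- c("A", "C", "G", "T")

#' Parse a population map TSV
#'
#' @param path 2-3 column tab-separated file: individual, population,
#'   optional group.  `#` comment lines and blank lines are skipped.
#' @return data.frame with columns individual, population and (optionally)
#'   group.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty population map: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L)) stop("population map rows need >= 2 tab-separated fields")
  out <- data.frame(
    individual = vapply(parts, `[[`, "", 1L),
    population = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
  if (all(ncols >= 3L)) {
    out$group <- vapply(parts, `[[`, "", 3L)
  } else if (any(ncols >= 3L)) {
    stop("population map mixes 2- and 3-column rows")
  }
  if (anyDuplicated(out$individual)) stop("duplicate individual in popmap")
  out
}

#' Apply the missing-data policy to an alignment
#'
#' Under `complete_deletion` (the default used throughout the package) every
#' column containing a gap (`-`), `N` or any IUPAC ambiguity code is removed
#' from all downstream single-pass statistics, so one effective length
#' `k_eff` applies everywhere.  Under `pairwise` all columns are retained and
#' exclusion is deferred to each pairwise comparison.
#'
#' @param aln A `labeled_alignment`.
#' @param policy `"complete_deletion"` or `"pairwise"`.
#' @return A `filtered_alignment`: the source alignment plus the ordered
#'   1-based indices of retained columns and the effective length `k_eff`.
#' @export
filter_sites <- function(aln, policy = c("complete_deletion", "pairwise")) {
  stopifnot(inherits(aln, "labeled_alignment"))
  policy <- match.arg(policy)
  L <- ncol(aln$mat)
  if (policy == "complete_deletion") {
    clean <- colSums(matrix(aln$mat %in% ACGT, nrow = nrow(aln$mat))) ==
      nrow(aln$mat)
    retained <- which(clean)
    if (length(retained) == 0L) {
      stop("degenerate alignment: every column carries a gap or ambiguity")
    }
  } else {
    retained <- seq_len(L)
  }
  structure(list(source = aln, retained_columns = retained,
                 k_eff = length(retained), policy = policy),
            class = "filtered_alignment")
}

#' @export
print.filtered_alignment <- function(x, ...) {
  cat("Filtered alignment (", x$policy, "): ", x$k_eff, "/",
      ncol(x$source$mat), " columns retained\n", sep = "")
  invisible(x)
}

# Retained-column character matrix of a filtered alignment.
faln_matrix <- function(faln) {
  faln$source$mat[, faln$retained_columns, drop = FALSE]
}

#' Collapse an alignment into its distinct haplotypes
#'
#' Haplotypes are equivalence classes of exact string identity over the
#' retained columns.  Ordering is deterministic: first occurrence in the
#' alignment.  Counts are partitioned by population.
#'
#' @param faln A `filtered_alignment`.
#' @return A `haplotype_set`: haplotype sequences (character vector), a
#'   haplotype x population count matrix, `Nh` and the total sample size `n`.
#' @export
collapse_haplotypes <- function(faln) {
  stopifnot(inherits(faln, "filtered_alignment"))
  m <- faln_matrix(faln)
  keys <- apply(m, 1L, paste0, collapse = "")
  uniq <- unique(keys)
  idx <- match(keys, uniq)
  pops <- faln$source$population
  pop_levels <- unique(pops)
  counts <- matrix(0L, nrow = length(uniq), ncol = length(pop_levels),
                   dimnames = list(paste0("H", seq_along(uniq)), pop_levels))
  for (i in seq_along(keys)) {
    counts[idx[i], pops[i]] <- counts[idx[i], pops[i]] + 1L
  }
  structure(list(haplotypes = uniq, count_matrix = counts,
                 Nh = length(uniq), n = length(keys),
                 assignment = stats::setNames(idx, rownames(m))),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", x$Nh, "haplotypes in", x$n, "sequences across",
      ncol(x$count_matrix), "populations\n")
  invisible(x)
}

#' Classify retained alignment columns
#'
#' Each retained column is monomorphic, a singleton (the rarer state in
#' exactly one sequence) or parsimony-informative (at least two states, each
#' carried by at least two sequences).
#'
#' @param faln A `filtered_alignment`.
#' @return A `site_classification` with `S` (polymorphic columns),
#'   `singletons`, `parsimony_informative` and `per_site`, a character vector
#'   over retained columns (named by original 1-based column index).
#' @export
classify_sites <- function(faln) {
  stopifnot(inherits(faln, "filtered_alignment"))
  m <- faln_matrix(faln)
  lab <- apply(m, 2L, function(col) {
    tab <- table(col)
    if (length(tab) < 2L) return("monomorphic")
    if (sum(tab >= 2L) >= 2L) return("informative")
    "singleton"
  })
  names(lab) <- as.character(faln$retained_columns)
  structure(list(
    S = sum(lab != "monomorphic"),
    singletons = sum(lab == "singleton"),
    parsimony_informative = sum(lab == "informative"),
    per_site = lab
  ), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("Sites: S =", x$S, "(", x$singletons, "singletons,",
      x$parsimony_informative, "parsimony-informative )\n")
  invisible(x)
}

#' Write an alignment and matching population map
#'
#' @param aln A `labeled_alignment`.
#' @param fasta_path,popmap_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_alignment <- function(aln, fasta_path, popmap_path) {
  stopifnot(inherits(aln, "labeled_alignment"))
  bin <- ape::as.DNAbin(aln$mat)
  ape::write.FASTA(bin, fasta_path)
  df <- data.frame(individual = rownames(aln$mat),
                   population = aln$population)
  if (!is.null(aln$group_of)) df$group <- unname(aln$group_of[df$population])
  utils::write.table(df, popmap_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta_path, popmap_path))
}

#' Write a haplotype table (haplotype, sequence, per-population counts)
#'
#' @param hs A `haplotype_set`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_haplotype_table <- function(hs, path) {
  stopifnot(inherits(hs, "haplotype_set"))
  df <- data.frame(haplotype = rownames(hs$count_matrix),
                   sequence = hs$haplotypes,
                   hs$count_matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
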