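# Haplotype-resolved expression assembly, CPM normalization, the expression
# filter, read-mapping ambiguity summaries and rank correlations.

#' Counts per million
#'
#' @param counts Numeric matrix (features x columns).
#' @param lib_sizes Reads per column; defaults to the column totals. Library
#'   sizes are conventionally taken from the full pre-filter table so that
#'   filtering does not change the scale.
#' @return Matrix of `count * 1e6 / lib_size`.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(lib_sizes) != ncol(counts))
    stop("lib_sizes must have one entry per column")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2, lib_sizes / 1e6, "/")
}

#' Expression filter on a CPM matrix
#'
#' Keeps a feature iff its CPM exceeds `min_cpm` (strictly, by default) in at
#' least `min_columns` columns. The same implementation, with `strict =
#' FALSE`, backs the transposable-element family filter.
#'
#' @param cpm_matrix CPM matrix with feature rownames.
#' @param min_cpm CPM threshold (default 2).
#' @param min_columns Minimum number of columns above threshold (default 4).
#' @param strict If `TRUE` (default) require CPM strictly greater than
#'   `min_cpm`; if `FALSE` require CPM `>= min_cpm`.
#' @return Character vector of kept feature ids.
#' @export
filter_expressed <- function(cpm_matrix, min_cpm = 2, min_columns = 4, strict = TRUE) {
  if (ncol(cpm_matrix) < min_columns)
    stop("matrix has fewer than min_columns columns")
  hit <- if (strict) cpm_matrix > min_cpm else cpm_matrix >= min_cpm
  keep <- rowSums(hit) >= min_columns
  rownames(cpm_matrix)[keep]
}

#' Summarize read-mapping ambiguity against a combined two-species reference
#'
#' A read with mapping-quality-positive alignments to both species is
#' ambiguous; with alignments to a single species it is assigned to that
#' species. Reads whose alignments all have mapping quality 0 (pure
#' multimappers) are excluded from the denominator.
#'
#' @param read_records `data.frame` with `read_id`, `species` (`"cbr"` or
#'   `"cni"`) and `mapq`.
#' @return List with `n_reads`, `n_ambiguous`, `n_assigned_cbr`,
#'   `n_assigned_cni` and `ambiguous_fraction`.
#' @export
mapping_ambiguity <- function(read_records) {
  need <- c("read_id", "species", "mapq")
  miss <- setdiff(need, names(read_records))
  if (length(miss)) stop("read records are missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(read_records$species), c("cbr", "cni"))
  if (length(bad)) stop("unknown species label: ", paste(bad, collapse = ", "))
  rec <- read_records[read_records$mapq > 0, c("read_id", "species"), drop = FALSE]
  rec <- unique(rec)
  n_sp <- table(factor(rec$species, levels = c("cbr", "cni")), rec$read_id)
  both <- n_sp["cbr", ] > 0 & n_sp["cni", ] > 0
  n_ambiguous <- sum(both)
  n_cbr <- sum(n_sp["cbr", ] > 0 & !both)
  n_cni <- sum(n_sp["cni", ] > 0 & !both)
  n_reads <- n_ambiguous + n_cbr + n_cni
  list(n_reads = n_reads,
       n_ambiguous = n_ambiguous,
       n_assigned_cbr = n_cbr,
       n_assigned_cni = n_cni,
       ambiguous_fraction = if (n_reads > 0) n_ambiguous / n_reads else NA_real_)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average ranks).
#' Constant input is undefined and reported as `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Assemble haplotype-resolved expression groups into an allele count table
#'
#' Collapses a gene-level count table over both species' annotations into one
#' row per one-to-one ortholog pair with one column per haplotype-level
#' measurement: parental columns take counts from the matching species' gene
#' only (counts falling on the other species' haplotype rows are deleted),
#' and each hybrid replicate contributes a `*_cbr` and a `*_cni` column.
#'
#' @param counts Gene-level count matrix (rownames are gene ids of either
#'   species) or path to a counts TSV.
#' @param sample_sheet `data.frame` with `column_id`, `group` (one of `Cni`,
#'   `Cbr`, `BN_cbr`, `BN_cni`, `NB_cbr`, `NB_cni`) and `replicate`, or a
#'   path to such a TSV.
#' @param ortholog_map `data.frame` with `pair_id`, `cbr_gene`, `cni_gene`
#'   and optionally `chromosome`, or a path to such a TSV.
#' @return List of class `allele_count_table` with `counts` (pairs x
#'   columns), `sample_sheet`, `lib_sizes` (pre-collapse column totals of the
#'   full input table), and `chromosome` (named by pair id, when available).
#' @export
assemble_groups <- function(counts, sample_sheet, ortholog_map) {
  if (is.character(counts)) counts <- read_counts_tsv(counts)
  if (is.character(sample_sheet)) sample_sheet <- read_tsv(sample_sheet)
  if (is.character(ortholog_map)) ortholog_map <- read_tsv(ortholog_map)
  if (nrow(sample_sheet) == 0) stop("sample sheet is empty")
  need <- c("column_id", "group")
  miss <- setdiff(need, names(sample_sheet))
  if (length(miss)) stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(sample_sheet$group, ALLELE_GROUPS)
  if (length(bad)) stop("unknown group in sample sheet: ", paste(bad, collapse = ", "))
  absent <- setdiff(colnames(counts), sample_sheet$column_id)
  if (length(absent)) stop("counts column missing from sample sheet: ",
                           paste(absent, collapse = ", "))
  absent <- setdiff(sample_sheet$column_id, colnames(counts))
  if (length(absent)) stop("sample sheet column not in counts: ",
                           paste(absent, collapse = ", "))
  if (anyDuplicated(ortholog_map$pair_id)) stop("duplicate pair ids in ortholog map")

  counts <- counts[, sample_sheet$column_id, drop = FALSE]
  lib_sizes <- colSums(counts)

  cbr_rows <- match(ortholog_map$cbr_gene, rownames(counts))
  cni_rows <- match(ortholog_map$cni_gene, rownames(counts))
  if (any(is.na(cbr_rows)) || any(is.na(cni_rows)))
    stop("ortholog map refers to genes absent from the counts table")

  uses_cbr <- sample_sheet$group %in% c("Cbr", "BN_cbr", "NB_cbr")
  out <- matrix(0, nrow(ortholog_map), nrow(sample_sheet),
                dimnames = list(ortholog_map$pair_id, sample_sheet$column_id))
  for (j in seq_len(ncol(out))) {
    rows <- if (uses_cbr[j]) cbr_rows else cni_rows
    out[, j] <- counts[rows, j]
  }

  chrom <- NULL
  if ("chromosome" %in% names(ortholog_map))
    chrom <- stats::setNames(ortholog_map$chromosome, ortholog_map$pair_id)

  structure(list(counts = out,
                 sample_sheet = sample_sheet,
                 lib_sizes = lib_sizes,
                 chromosome = chrom),
            class = "allele_count_table")
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat(sprintf("Allele count table: %d ortholog pairs x %d columns\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$sample_sheet$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Sum hybrid haplotype columns into total-expression columns
#'
#' Rearranges an allele count table into sample-level totals: parental
#' columns are passed through, and for each hybrid replicate the `*_cbr` and
#' `*_cni` haplotype counts are summed so the hybrid's total expression can
#' be contrasted with the parents. Library sizes of the summed columns are
#' the sums of the haplotype library sizes.
#'
#' @param table An `allele_count_table`.
#' @return List with `counts`, `groups` (one of `Cni`, `Cbr`, `BN`, `NB` per
#'   column) and `lib_sizes`.
#' @export
hybrid_totals <- function(table) {
  stopifnot(inherits(table, "allele_count_table"))
  sheet <- table$sample_sheet
  base_group <- sub("_(cbr|cni)$", "", sheet$group)
  key <- paste(base_group, sheet$replicate, sep = "_")
  ord <- !duplicated(key)
  agg <- t(rowsum(t(table$counts), key))  # sums haplotype pairs, keeps parents
  agg <- agg[, key[ord], drop = FALSE]
  libs <- as.vector(rowsum(unname(table$lib_sizes), key)[key[ord], ])
  # A hybrid replicate's two haplotype columns share one nominal library; when
  # lib sizes are column totals, summing them is the replicate total.
  list(counts = agg,
       groups = stats::setNames(base_group[ord], key[ord]),
       lib_sizes = stats::setNames(libs, key[ord]))
}
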