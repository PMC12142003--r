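# Mitochondria-restricted and transposable-element expression tracks: special
# normalization backgrounds, one-to-n summed term expression, family-level
# filtering, and the BN-versus-NB TE contrast.

#' Library sizes restricted to a mitochondria-related gene set
#'
#' Per-column library size is the sum of counts over the mitochondria-related
#' genes only, used as the CPM denominator for mitochondria-track analyses so
#' the track is normalized within its own background.
#'
#' @param counts Count matrix with feature rownames.
#' @param mito_genes Character vector of mitochondria-related gene ids.
#' @return Named numeric vector of per-column sizes.
#' @export
mito_library_sizes <- function(counts, mito_genes) {
  hit <- intersect(mito_genes, rownames(counts))
  if (length(hit) == 0) stop("no mitochondria-related genes found in the counts table")
  colSums(counts[hit, , drop = FALSE])
}

#' Sum homolog expression per reference term
#'
#' One reference term (for example a human nuclear-encoded mitochondrial gene)
#' may have several homologs; each term's row is the element-wise sum of its
#' members' count rows, so total mass over grouped genes is conserved.
#'
#' @param counts Count matrix with gene rownames.
#' @param term_groups Named list mapping term id to member gene ids (from
#'   [group_one_to_n()]).
#' @return Matrix, one row per term with at least one present member.
#' @export
mito_term_expression <- function(counts, term_groups) {
  rows <- lapply(names(term_groups), function(term) {
    members <- term_groups[[term]]
    present <- intersect(members, rownames(counts))
    if (length(present) < length(members))
      warning("term ", term, ": ", length(members) - length(present),
              " member(s) absent from counts, skipped")
    if (length(present) == 0) return(NULL)
    colSums(counts[present, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(term_groups)[keep]
  out
}

#' Filter transposable-element families by expression
#'
#' Shares the thresholding implementation of [filter_expressed()]: a family
#' is kept iff its CPM is at least `min_cpm` in at least `min_columns`
#' columns (inclusive comparison, anchored to the CPM < 1 "not expressed"
#' convention).
#'
#' @param te_cpm Family-level CPM matrix.
#' @param min_cpm CPM floor (default 1).
#' @param min_columns Minimum columns at or above the floor (default 2).
#' @return Character vector of kept family ids.
#' @export
te_filter <- function(te_cpm, min_cpm = 1, min_columns = 2) {
  filter_expressed(te_cpm, min_cpm = min_cpm, min_columns = min_columns,
                   strict = FALSE)
}

#' BN-versus-NB differential expression of TE families
#'
#' Runs the exact-test engine on family-level counts, normalized against the
#' combined TE counts per column, and flags families by raw p-value (the
#' allele-level convention) and fold change: `up_in_NB` for `log2(BN/NB) <
#' -lfc_cut`, `up_in_BN` for `> lfc_cut`.
#'
#' @param te_counts Family-level count matrix.
#' @param cols_bn,cols_nb Column ids of the BN and NB samples.
#' @param lib_sizes Normalization background per column; defaults to the
#'   combined TE counts (column totals).
#' @param alpha Raw p-value cutoff (default 0.05).
#' @param lfc_cut Log2 fold-change cutoff (default 1).
#' @param ... Passed to [run_de()].
#' @return The [run_de()] table (orientation `log2(BN/NB)`) with a `flag`
#'   column in `{"up_in_BN", "up_in_NB", "ns"}`.
#' @export
te_differential <- function(te_counts, cols_bn, cols_nb,
                            lib_sizes = colSums(te_counts),
                            alpha = 0.05, lfc_cut = 1, ...) {
  de <- run_de(te_counts, cols_bn, cols_nb, lib_sizes = lib_sizes, ...)
  de$flag <- "ns"
  de$flag[de$pvalue < alpha & de$log2fc > lfc_cut] <- "up_in_BN"
  de$flag[de$pvalue < alpha & de$log2fc < -lfc_cut] <- "up_in_NB"
  de
}
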