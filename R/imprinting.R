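# Parent-of-origin imprinting from allelic fractions in the two reciprocal
# hybrids. In BN (Cbr father x Cni mother) the Cbr allele is paternal; in NB
# (Cni father x Cbr mother) the Cbr allele is maternal.

#' C. briggsae allelic expression fraction
#'
#' @param cpm_cbr,cpm_cni Mean CPM of the Cbr and Cni alleles in one hybrid.
#' @param min_total Minimum combined CPM for a callable fraction; below the
#'   floor the fraction is a no-call (`NA`), since ratios of near-zero
#'   expression are noise.
#' @return `cpm_cbr / (cpm_cbr + cpm_cni)`, or `NA` below the floor.
#' @export
allele_fraction <- function(cpm_cbr, cpm_cni, min_total = 5) {
  if (any(cpm_cbr < 0) || any(cpm_cni < 0)) stop("CPM values must be >= 0")
  total <- cpm_cbr + cpm_cni
  ifelse(total >= min_total, cpm_cbr / total, NA_real_)
}

#' Call imprinting status from the two reciprocal allelic fractions
#'
#' A gene is maternally imprinted when the maternal allele contributes at
#' least `cutoff` of the pair's expression in both hybrids: Cni in BN
#' (`1 - f_bn >= cutoff`) and Cbr in NB (`f_nb >= cutoff`). Paternal
#' imprinting is the mirror image. No-call fractions on either side give
#' `"none"`.
#'
#' @param f_bn,f_nb C. briggsae allelic fractions in BN and NB.
#' @param cutoff Minimum allele fraction (default 0.75, inclusive).
#' @return Character vector: `"maternal"`, `"paternal"` or `"none"`.
#' @export
call_imprinting <- function(f_bn, f_nb, cutoff = 0.75) {
  out <- rep("none", length(f_bn))
  callable <- !is.na(f_bn) & !is.na(f_nb)
  out[callable & (1 - f_bn) >= cutoff & f_nb >= cutoff] <- "maternal"
  out[callable & f_bn >= cutoff & (1 - f_nb) >= cutoff] <- "paternal"
  out
}

#' Overall maternal/paternal leaning of a gene
#'
#' The mean of the maternal-allele fractions over the two hybrids,
#' `((1 - f_bn) + f_nb) / 2`, classifies the gene as leaning maternal
#' (> 0.5), paternal (< 0.5) or balanced (equal within 1e-12).
#'
#' @inheritParams call_imprinting
#' @return Character vector: `"maternal"`, `"paternal"` or `"balanced"`
#'   (`NA` where either fraction is a no-call).
#' @export
parental_leaning <- function(f_bn, f_nb) {
  m <- ((1 - f_bn) + f_nb) / 2
  out <- ifelse(m > 0.5 + 1e-12, "maternal",
                ifelse(m < 0.5 - 1e-12, "paternal", "balanced"))
  out[is.na(f_bn) | is.na(f_nb)] <- NA_character_
  out
}

#' Build the imprinting call table from an allele count table
#'
#' Computes group-mean CPM for the four hybrid haplotype groups, the
#' C. briggsae allelic fraction in each hybrid, the >= 75% imprinting call
#' and the maternal/paternal leaning.
#'
#' @param table An `allele_count_table`.
#' @param pairs Optional pair ids to restrict to (e.g. the expressed
#'   universe).
#' @param min_total Combined-CPM floor for [allele_fraction()].
#' @param cutoff Imprinting cutoff for [call_imprinting()].
#' @return `data.frame` with `pair_id`, `f_cbr_BN`, `f_cbr_NB`, `status`,
#'   `leaning`.
#' @export
imprinting_calls <- function(table, pairs = NULL, min_total = 5, cutoff = 0.75) {
  stopifnot(inherits(table, "allele_count_table"))
  cp <- cpm(table$counts, table$lib_sizes)
  if (!is.null(pairs)) cp <- cp[pairs, , drop = FALSE]
  grp <- table$sample_sheet$group
  gmean <- function(g) rowMeans(cp[, grp == g, drop = FALSE])
  f_bn <- allele_fraction(gmean("BN_cbr"), gmean("BN_cni"), min_total)
  f_nb <- allele_fraction(gmean("NB_cbr"), gmean("NB_cni"), min_total)
  data.frame(pair_id = rownames(cp),
             f_cbr_BN = f_bn, f_cbr_NB = f_nb,
             status = call_imprinting(f_bn, f_nb, cutoff),
             leaning = parental_leaning(f_bn, f_nb),
             row.names = NULL, stringsAsFactors = FALSE)
}
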