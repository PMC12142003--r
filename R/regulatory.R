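# Cis/trans regulatory classification: compares the parental expression
# ratio with the allele ratio inside each hybrid.

#' Log2 expression ratio with a pseudo-count prior
#'
#' @param expr_cbr,expr_cni Non-negative mean expressions (CPM) per side.
#' @param prior Pseudo-count added to both sides (default 0.5).
#' @return `log2((expr_cbr + prior) / (expr_cni + prior))`.
#' @export
log_ratio <- function(expr_cbr, expr_cni, prior = 0.5) {
  if (any(expr_cbr < 0) || any(expr_cni < 0)) stop("expressions must be >= 0")
  log2((expr_cbr + prior) / (expr_cni + prior))
}

#' Classify regulatory mode from parental and allele contrasts
#'
#' A pair is *conserved* when neither the parental contrast nor the
#' within-hybrid allele contrast is significant (`fdr > alpha` for both);
#' otherwise *cis* when the parental and hybrid allele log2 ratios diverge by
#' less than `delta` (the hybrid allele ratio mimics the parental ratio), and
#' *trans* for the remainder (the allele ratio deviates from the parental
#' ratio, implicating the hybrid cellular environment).
#'
#' @param fdr_P FDR of the Cbr-vs-Cni parental contrast.
#' @param fdr_H FDR of the within-hybrid allele contrast.
#' @param ratio_P,ratio_H Parental and within-hybrid `log2(Cbr / Cni)`
#'   expression ratios.
#' @param alpha Significance cutoff (default 0.05).
#' @param delta Maximum absolute ratio difference, log2 units, for a cis call
#'   (default 1.8, strict `<`).
#' @return Character vector of categories; missing rows give `NA` with a
#'   warning.
#' @export
classify_regulatory <- function(fdr_P, fdr_H, ratio_P, ratio_H,
                                alpha = 0.05, delta = 1.8) {
  n <- length(fdr_P)
  stopifnot(length(fdr_H) == n, length(ratio_P) == n, length(ratio_H) == n)
  miss <- !is.finite(fdr_P) | !is.finite(fdr_H) | !is.finite(ratio_P) | !is.finite(ratio_H)
  if (any(miss))
    warning(sum(miss), " pair(s) with missing statistics excluded from classification")
  out <- rep("trans", n)
  out[abs(ratio_P - ratio_H) < delta] <- "cis"
  out[fdr_P > alpha & fdr_H > alpha] <- "conserved"
  out[miss] <- NA_character_
  out
}

#' Build a regulatory call table for one hybrid
#'
#' @param de_parental DE table from [run_de()] for Cbr vs Cni (parents).
#' @param de_allele DE table for the hybrid's Cbr-allele vs Cni-allele
#'   contrast, same feature universe and order.
#' @param hybrid `"BN"` or `"NB"`.
#' @param mean_cpm_parents Two-column matrix (Cbr, Cni group-mean CPM) for
#'   the parental ratio; defaults to ratios derived from the DE tables'
#'   `log2fc` (which already carry the prior).
#' @param mean_cpm_alleles Two-column matrix (Cbr-allele, Cni-allele
#'   group-mean CPM) for the hybrid ratio.
#' @param prior Pseudo-count for [log_ratio()].
#' @inheritParams classify_regulatory
#' @return `data.frame` with `pair_id`, `hybrid`, `category`, `ratio_P`,
#'   `ratio_H`, `fdr_P`, `fdr_H`.
#' @export
regulatory_calls <- function(de_parental, de_allele, hybrid,
                             mean_cpm_parents = NULL, mean_cpm_alleles = NULL,
                             prior = 0.5, alpha = 0.05, delta = 1.8) {
  if (!identical(de_parental$feature_id, de_allele$feature_id))
    stop("the two DE tables must cover the same features in the same order")
  ratio_P <- if (is.null(mean_cpm_parents)) de_parental$log2fc
             else log_ratio(mean_cpm_parents[, 1], mean_cpm_parents[, 2], prior)
  ratio_H <- if (is.null(mean_cpm_alleles)) de_allele$log2fc
             else log_ratio(mean_cpm_alleles[, 1], mean_cpm_alleles[, 2], prior)
  cat_ <- classify_regulatory(de_parental$fdr, de_allele$fdr, ratio_P, ratio_H,
                              alpha = alpha, delta = delta)
  out <- data.frame(pair_id = de_parental$feature_id,
                    hybrid = hybrid, category = cat_,
                    ratio_P = ratio_P, ratio_H = ratio_H,
                    fdr_P = de_parental$fdr, fdr_H = de_allele$fdr,
                    stringsAsFactors = FALSE)
  out[!is.na(out$category), , drop = FALSE]
}

#' Cross-tabulate inheritance against regulatory categories
#'
#' @param inh_calls,reg_calls Call tables for the same hybrid and pair
#'   universe.
#' @return Matrix of proportions (inheritance categories x regulatory
#'   categories); each row is normalized by its inheritance-category size and
#'   sums to 1 (empty categories give all-zero rows with a warning).
#' @export
cross_tabulate <- function(inh_calls, reg_calls) {
  if (!setequal(inh_calls$pair_id, reg_calls$pair_id))
    stop("call tables must cover the same pair universe")
  reg <- stats::setNames(reg_calls$category, reg_calls$pair_id)[inh_calls$pair_id]
  tab <- table(factor(inh_calls$category, levels = INHERITANCE_CLASSES),
               factor(reg, levels = REGULATORY_CLASSES))
  tab <- tab[rowSums(tab) > 0 | rownames(tab) %in% unique(inh_calls$category), ,
             drop = FALSE]
  n <- rowSums(tab)
  if (any(n == 0)) warning("empty inheritance category: all-zero row emitted")
  out <- sweep(unclass(tab), 1, pmax(n, 1), "/")
  out
}
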