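# Expression-inheritance classification of ortholog pairs in F1 hybrids:
# no change / Cbr dominant / Cni dominant / additive / overdominant /
# underdominant, from the hybrid-versus-parent contrasts.

#' Classify inheritance mode from the two hybrid-versus-parent contrasts
#'
#' Sequential rules, applied in order per gene:
#' 1. *no change* - not significant against either parent (`fdr > alpha`)
#'    and `|log2 fold change| < lfc_cut` against both;
#' 2. *dominant* - the comparison to exactly one parent satisfies the full
#'    match condition (`fdr > alpha` and `|lfc| < lfc_cut`): matching Cbr
#'    gives `cbr_dominant`, matching Cni gives `cni_dominant`;
#' 3. *underdominant* - significantly below both parents
#'    (`fdr < alpha`, `lfc < 0` against both);
#' 4. *overdominant* - significantly above both parents;
#' 5. otherwise *additive*.
#'
#' @param fdr_b,lfc_b FDR and `log2(hybrid / Cbr)` of the contrast against
#'   the C. briggsae parent.
#' @param fdr_n,lfc_n FDR and `log2(hybrid / Cni)` of the contrast against
#'   the C. nigoni parent.
#' @param alpha Significance cutoff on the FDR (default 0.05, strict `<`).
#' @param lfc_cut Fold-change cutoff in log2 units (default 1, strict `>`
#'   for "changed").
#' @return Character vector of categories. Rows with missing values are
#'   returned as `NA` with a warning so callers can exclude them explicitly.
#' @export
classify_inheritance <- function(fdr_b, lfc_b, fdr_n, lfc_n,
                                 alpha = 0.05, lfc_cut = 1) {
  n <- length(fdr_b)
  stopifnot(length(lfc_b) == n, length(fdr_n) == n, length(lfc_n) == n)
  miss <- !is.finite(fdr_b) | !is.finite(lfc_b) | !is.finite(fdr_n) | !is.finite(lfc_n)
  if (any(miss))
    warning(sum(miss), " pair(s) with missing statistics excluded from classification")

  match_b <- fdr_b > alpha & abs(lfc_b) < lfc_cut
  match_n <- fdr_n > alpha & abs(lfc_n) < lfc_cut

  out <- rep("additive", n)
  under <- fdr_b < alpha & fdr_n < alpha & lfc_b < 0 & lfc_n < 0
  over <- fdr_b < alpha & fdr_n < alpha & lfc_b > 0 & lfc_n > 0
  out[under] <- "underdominant"
  out[over] <- "overdominant"
  out[match_b & !match_n] <- "cbr_dominant"
  out[match_n & !match_b] <- "cni_dominant"
  out[match_b & match_n] <- "no_change"
  out[miss] <- NA_character_
  out
}

#' Build an inheritance call table for one hybrid
#'
#' @param de_vs_cbr,de_vs_cni DE tables from [run_de()] for the hybrid
#'   against each parent (`log2fc` oriented hybrid over parent), on the same
#'   feature universe.
#' @param hybrid `"BN"` or `"NB"`.
#' @inheritParams classify_inheritance
#' @return `data.frame` with `pair_id`, `hybrid`, `category` and the four
#'   supporting statistics; pairs with missing statistics are dropped.
#' @export
inheritance_calls <- function(de_vs_cbr, de_vs_cni, hybrid,
                              alpha = 0.05, lfc_cut = 1) {
  if (!identical(de_vs_cbr$feature_id, de_vs_cni$feature_id))
    stop("the two DE tables must cover the same features in the same order")
  cat_ <- classify_inheritance(de_vs_cbr$fdr, de_vs_cbr$log2fc,
                               de_vs_cni$fdr, de_vs_cni$log2fc,
                               alpha = alpha, lfc_cut = lfc_cut)
  out <- data.frame(pair_id = de_vs_cbr$feature_id,
                    hybrid = hybrid,
                    category = cat_,
                    fdr_vs_cbr = de_vs_cbr$fdr, lfc_vs_cbr = de_vs_cbr$log2fc,
                    fdr_vs_cni = de_vs_cni$fdr, lfc_vs_cni = de_vs_cni$log2fc,
                    stringsAsFactors = FALSE)
  out[!is.na(out$category), , drop = FALSE]
}

#' Compare category membership between the two hybrids
#'
#' @param calls_bn,calls_nb Call tables (`pair_id`, `category`) for BN and NB
#'   on the same pair universe.
#' @param categories Categories to compare; defaults to all categories
#'   present in either table.
#' @return Named list per category with disjoint `shared`, `bn_only`,
#'   `nb_only` id sets whose union is every pair holding the category in at
#'   least one hybrid.
#' @export
compare_hybrids <- function(calls_bn, calls_nb, categories = NULL) {
  if (!setequal(calls_bn$pair_id, calls_nb$pair_id))
    stop("the two call tables must cover the same pair universe")
  if (is.null(categories))
    categories <- sort(unique(c(calls_bn$category, calls_nb$category)))
  out <- lapply(categories, function(cc) {
    a <- calls_bn$pair_id[calls_bn$category == cc]
    b <- calls_nb$pair_id[calls_nb$category == cc]
    list(shared = sort(intersect(a, b)),
         bn_only = sort(setdiff(a, b)),
         nb_only = sort(setdiff(b, a)))
  })
  names(out) <- categories
  out
}

#' Category counts and fractions of the expressed universe
#'
#' @param calls Call table with a `category` column (inheritance or
#'   regulatory calls alike).
#' @return `data.frame` with `category`, `count`, `fraction`; fractions sum
#'   to 1.
#' @export
category_proportions <- function(calls) {
  if (nrow(calls) == 0) stop("empty call table")
  tab <- table(calls$category)
  data.frame(category = names(tab),
             count = as.integer(tab),
             fraction = as.numeric(tab) / nrow(calls),
             row.names = NULL, stringsAsFactors = FALSE)
}
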