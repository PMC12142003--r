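# Exact 2x2 association tests, chromosome-by-category enrichment, and
# hypergeometric gene-set over-representation with normalized gene counts.

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' outcome probabilities no larger than the observed one (relative tolerance
#' `1 + 1e-7`). The odds ratio is the sample estimate `(a d) / (b c)`, with
#' the Haldane-Anscombe 0.5 correction applied to every cell iff any cell is
#' zero, so the log2 odds ratio stays finite for flagging.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`[[a, b], [c, d]]`).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `odds_ratio`, `log2_odds_ratio`, `p`. An all-zero table
#'   gives `p = 1` and an `NA` odds ratio with a warning.
#' @export
fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) stop("cells must be non-negative integers")
  if (all(cells == 0)) {
    warning("all-zero table: odds ratio undefined")
    return(list(odds_ratio = NA_real_, log2_odds_ratio = NA_real_, p = 1))
  }
  p <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE),
                          alternative = alternative)$p.value
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(odds_ratio = or, log2_odds_ratio = log2(or), p = min(p, 1))
}

#' Chromosome-by-category enrichment of classified pairs
#'
#' For every chromosome x category cell, builds the 2x2 table (in-chromosome
#' and in-category, in-chromosome not, out-of-chromosome in-category,
#' out-of-chromosome not) over the expressed pair universe and applies
#' [fisher_2x2()]; a cell is flagged significant iff `p < alpha` and
#' `|log2 odds ratio| > lor_cut`.
#'
#' @param calls Call table with `pair_id` and `category`.
#' @param chromosome_map Named character vector (chromosome by pair id) or
#'   `data.frame` with `pair_id`, `chromosome`.
#' @param alpha P-value cutoff (default 0.01).
#' @param lor_cut Log2 odds-ratio magnitude cutoff (default 0.4).
#' @return `data.frame` with one row per chromosome x category:
#'   `unit_id`, `category`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `log2_odds_ratio`, `p`, `fdr`, `significant`.
#' @export
chromosome_enrichment <- function(calls, chromosome_map, alpha = 0.01, lor_cut = 0.4) {
  if (is.data.frame(chromosome_map))
    chromosome_map <- stats::setNames(chromosome_map$chromosome, chromosome_map$pair_id)
  chrom <- chromosome_map[calls$pair_id]
  if (any(is.na(chrom))) stop("pair(s) without a chromosome label")
  bad <- setdiff(unique(chrom), CHROMOSOMES)
  if (length(bad)) stop("unknown chromosome label: ", paste(bad, collapse = ", "))
  chroms <- intersect(CHROMOSOMES, unique(chrom))
  if (length(chroms) < 2)
    warning("single-chromosome input: all tables are degenerate")
  cats <- sort(unique(calls$category))
  N <- nrow(calls)
  grid <- expand.grid(unit_id = chroms, category = cats,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    on_chr <- chrom == grid$unit_id[i]
    in_cat <- calls$category == grid$category[i]
    k <- sum(on_chr & in_cat)
    ft <- fisher_2x2(k, sum(on_chr) - k, sum(!on_chr & in_cat),
                     sum(!on_chr & !in_cat))
    data.frame(unit_id = grid$unit_id[i], category = grid$category[i],
               k = k, K = sum(on_chr), n = sum(in_cat), N = N,
               odds_ratio = ft$odds_ratio,
               log2_odds_ratio = ft$log2_odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$p < alpha & abs(out$log2_odds_ratio) > lor_cut
  out
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the query contains more set members than
#' expected under hypergeometric sampling from the background:
#' `p = P(X >= k)` with `N` background genes, `K` set members in the
#' background and `n` query genes. FDR is BH-adjusted across sets; the
#' normalized gene count is `k / K` (query hits over the set's background
#' size).
#'
#' @param query_genes Character vector of query ids (intersected with the
#'   background).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); sets are intersected with the background.
#' @param background Character vector: the gene universe.
#' @param fdr_cutoff Sets with FDR below this are flagged `reported`
#'   (default 0.05).
#' @return `data.frame` with `unit_id`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `log2_odds_ratio`, `p`, `fdr`, `normalized_count`, `reported`.
#' @export
overrepresentation <- function(query_genes, gene_sets, background,
                               fdr_cutoff = 0.05) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  query <- intersect(unique(query_genes), background)
  N <- length(background); n <- length(query)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- fisher_2x2(k, n - k, K - k, N - K - (n - k))
    data.frame(unit_id = nm, k = k, K = K, n = n, N = N,
               odds_ratio = or$odds_ratio,
               log2_odds_ratio = or$log2_odds_ratio,
               p = p, normalized_count = if (K > 0) k / K else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p)
  out$reported <- out$fdr < fdr_cutoff
  out[, c("unit_id", "k", "K", "n", "N", "odds_ratio", "log2_odds_ratio",
          "p", "fdr", "normalized_count", "reported")]
}
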