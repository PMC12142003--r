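# Ortholog identification from protein-alignment hit tables: representative
# gene/isoform selection, reciprocal best hits for one-to-one pairs, and
# best-hit grouping of one-to-n homologs under reference terms.

validate_hits <- function(hits) {
  need <- c("query_id", "subject_id", "score", "e_value")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(hits$score))) stop("hit scores must be finite")
  hits
}

#' Select one representative gene and protein per locus
#'
#' Among genes whose coordinate intervals overlap on the same chromosome,
#' only the gene with the longest genomic span is kept (ties broken by the
#' lexicographically smaller `gene_id`); for each kept gene the longest
#' protein isoform is the representative sequence.
#'
#' @param models `data.frame` with `gene_id`, `chromosome`, `start`, `end`.
#' @param isoforms Optional `data.frame` with `gene_id`, `isoform_id`,
#'   `length` (residues). When supplied, the representative isoform per kept
#'   gene is reported.
#' @return `data.frame` of kept genes, with `isoform_id` and `protein_length`
#'   columns when `isoforms` is given.
#' @export
select_representatives <- function(models, isoforms = NULL) {
  need <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(need, names(models))
  if (length(miss)) stop("gene models are missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(models$start)) || any(is.na(models$end)))
    stop("gene models have missing coordinates")
  if (any(models$end < models$start)) stop("gene model end < start")

  kept <- lapply(split(models, models$chromosome), function(chr) {
    chr <- chr[order(chr$start, chr$end, chr$gene_id), , drop = FALSE]
    # Chain overlapping intervals into clusters, then keep the longest span.
    cluster <- integer(nrow(chr)); cur <- 1L; cur_end <- chr$end[1]
    cluster[1] <- 1L
    for (i in seq_len(nrow(chr))[-1]) {
      if (chr$start[i] <= cur_end) {
        cluster[i] <- cur
        cur_end <- max(cur_end, chr$end[i])
      } else {
        cur <- cur + 1L; cluster[i] <- cur; cur_end <- chr$end[i]
      }
    }
    do.call(rbind, lapply(split(chr, cluster), function(cl) {
      span <- cl$end - cl$start
      best <- which(span == max(span))
      if (length(best) > 1) best <- best[order(cl$gene_id[best])[1]]
      cl[best, , drop = FALSE]
    }))
  })
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out <- out[order(out$gene_id), , drop = FALSE]

  if (!is.null(isoforms)) {
    iso <- isoforms[isoforms$gene_id %in% out$gene_id, , drop = FALSE]
    pick <- do.call(rbind, lapply(split(iso, iso$gene_id), function(g) {
      best <- which(g$length == max(g$length))
      if (length(best) > 1) best <- best[order(g$isoform_id[best])[1]]
      g[best, c("gene_id", "isoform_id", "length")]
    }))
    names(pick)[3] <- "protein_length"
    out <- merge(out, pick, by = "gene_id", all.x = TRUE, sort = TRUE)
  }
  rownames(out) <- NULL
  out
}

# Best subject per query: unique top score required (ties disqualify the query).
unique_best <- function(hits) {
  sp <- split(hits, hits$query_id)
  best <- lapply(sp, function(h) {
    top <- h[h$score == max(h$score), , drop = FALSE]
    if (nrow(top) > 1 && length(unique(top$subject_id)) > 1) return(NULL)
    top[1, c("query_id", "subject_id")]
  })
  do.call(rbind, best[!vapply(best, is.null, logical(1))])
}

#' One-to-one orthologs from reciprocal best hits
#'
#' A pair (a, b) is emitted iff b is a's unique top-scoring subject in the
#' forward table and a is b's unique top-scoring subject in the reverse
#' table, after filtering both tables at `e_value < e_cutoff`. Queries whose
#' top score is tied between different subjects are disqualified.
#'
#' @param forward,reverse Hit tables (`query_id`, `subject_id`, `score`,
#'   `e_value`; bit-score-like `score` is the ranking key).
#' @param e_cutoff E-value threshold, default `1e-4`.
#' @return `data.frame` with columns `query_id`, `subject_id`; each gene
#'   appears in at most one pair. Empty input yields an empty table.
#' @export
reciprocal_best_hits <- function(forward, reverse, e_cutoff = 1e-4) {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(forward) == 0 || nrow(reverse) == 0) return(empty)
  forward <- validate_hits(forward); reverse <- validate_hits(reverse)
  forward <- forward[forward$e_value < e_cutoff, , drop = FALSE]
  reverse <- reverse[reverse$e_value < e_cutoff, , drop = FALSE]
  if (nrow(forward) == 0 || nrow(reverse) == 0) return(empty)

  fb <- unique_best(forward)
  rb <- unique_best(reverse)
  if (is.null(fb) || is.null(rb) || nrow(fb) == 0 || nrow(rb) == 0) return(empty)
  back <- stats::setNames(rb$subject_id, rb$query_id)
  mutual <- !is.na(back[fb$subject_id]) & back[fb$subject_id] == fb$query_id
  out <- fb[mutual, , drop = FALSE]
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group genes under reference terms by best hit
#'
#' Every gene with at least one hit below the e-value cutoff is assigned to
#' the term of its single best hit (highest score, then lower e-value, then
#' lexicographically smaller term id), so one reference term may collect many
#' homologs while each gene belongs to exactly one term.
#'
#' @param hits Hit table (`query_id` = gene, `subject_id` = reference term).
#' @param e_cutoff E-value threshold, default `1e-4`.
#' @return Named list mapping term id to a character vector of member genes.
#' @export
group_one_to_n <- function(hits, e_cutoff = 1e-4) {
  if (nrow(hits) == 0) return(list())
  hits <- validate_hits(hits)
  hits <- hits[hits$e_value < e_cutoff, , drop = FALSE]
  if (nrow(hits) == 0) return(list())
  hits <- hits[order(hits$query_id, -hits$score, hits$e_value, hits$subject_id), ,
               drop = FALSE]
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  lapply(split(best$query_id, best$subject_id), sort)
}
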