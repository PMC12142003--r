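# End-to-end orchestration: quantify -> DE contrasts -> inheritance ->
# regulatory -> imprinting -> enrichment -> optional tracks, returning one
# classed result object.

default_thresholds <- function() {
  list(alpha_fdr = 0.05, alpha_raw = 0.05, lfc_cut = 1, reg_delta = 1.8,
       imprint_cutoff = 0.75, imprint_min_total = 5,
       min_cpm = 2, min_columns = 4,
       enrich_alpha = 0.01, lor_cut = 0.4, ora_fdr = 0.05,
       prior_count = 0.5, prior_df = 10,
       te_min_cpm = 1, te_min_columns = 2)
}

#' Full allele-specific expression analysis of a reciprocal hybrid experiment
#'
#' The main fitting function: assembles haplotype-resolved groups, applies
#' the expression filter, runs every two-group exact-test contrast
#' (parental, hybrid-total versus each parent, within-hybrid alleles),
#' classifies each expressed ortholog pair into inheritance and regulatory
#' modes per hybrid, calls imprinted genes from allelic fractions, and
#' computes chromosome and gene-set enrichment. All stages are deterministic
#' functions of the inputs.
#'
#' @param counts Gene-level count matrix or counts TSV path (rows are genes
#'   of both species).
#' @param sample_sheet Sample sheet (`column_id`, `group`, `replicate`) or
#'   TSV path.
#' @param ortholog_map One-to-one ortholog map (`pair_id`, `cbr_gene`,
#'   `cni_gene`, optional `chromosome`) or TSV path.
#' @param gene_sets Optional named list of gene sets (pair ids), or a GMT
#'   path, for over-representation of the shared transgressive and
#'   regulatory sets.
#' @param mito_genes Optional character vector of mitochondria-related pair
#'   ids: adds a mitochondria-restricted normalization track.
#' @param te_counts Optional TE family-level count matrix (columns named as
#'   sample-level columns, e.g. `BN_1`): adds the TE filtering and BN-vs-NB
#'   contrast track.
#' @param thresholds Named list overriding entries of the default threshold
#'   set (FDR 0.05, |log2 FC| 1, regulatory delta 1.8 log2 units, imprint
#'   cutoff 0.75, expression filter CPM > 2 in >= 4 columns, enrichment
#'   p < 0.01 with |log2 OR| > 0.4).
#' @return An object of class `ase_analysis`; see [summary.ase_analysis()].
#' @export
ase_analysis <- function(counts, sample_sheet, ortholog_map,
                         gene_sets = NULL, mito_genes = NULL, te_counts = NULL,
                         thresholds = list()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)

  table <- assemble_groups(counts, sample_sheet, ortholog_map)

  cpm_all <- cpm(table$counts, table$lib_sizes)
  expressed <- filter_expressed(cpm_all, th$min_cpm, th$min_columns)
  ftab <- table
  ftab$counts <- table$counts[expressed, , drop = FALSE]

  totals <- hybrid_totals(ftab)
  gcols <- function(g) names(totals$groups)[totals$groups == g]
  de <- list()
  de$parental <- run_de(totals$counts, gcols("Cbr"), gcols("Cni"),
                        lib_sizes = totals$lib_sizes,
                        prior_count = th$prior_count, prior_df = th$prior_df)
  for (h in c("BN", "NB")) {
    de[[paste0(h, "_vs_Cbr")]] <- run_de(totals$counts, gcols(h), gcols("Cbr"),
                                         lib_sizes = totals$lib_sizes,
                                         prior_count = th$prior_count,
                                         prior_df = th$prior_df)
    de[[paste0(h, "_vs_Cni")]] <- run_de(totals$counts, gcols(h), gcols("Cni"),
                                         lib_sizes = totals$lib_sizes,
                                         prior_count = th$prior_count,
                                         prior_df = th$prior_df)
    de[[paste0(h, "_allele")]] <- run_de(ftab, paste0(h, "_cbr"), paste0(h, "_cni"),
                                         prior_count = th$prior_count,
                                         prior_df = th$prior_df)
  }

  inheritance <- list(
    BN = inheritance_calls(de$BN_vs_Cbr, de$BN_vs_Cni, "BN",
                           alpha = th$alpha_fdr, lfc_cut = th$lfc_cut),
    NB = inheritance_calls(de$NB_vs_Cbr, de$NB_vs_Cni, "NB",
                           alpha = th$alpha_fdr, lfc_cut = th$lfc_cut))
  regulatory <- list(
    BN = regulatory_calls(de$parental, de$BN_allele, "BN",
                          alpha = th$alpha_fdr, delta = th$reg_delta),
    NB = regulatory_calls(de$parental, de$NB_allele, "NB",
                          alpha = th$alpha_fdr, delta = th$reg_delta))

  venn <- compare_hybrids(inheritance$BN, inheritance$NB)
  venn_reg <- compare_hybrids(regulatory$BN, regulatory$NB)
  crosstab <- list(BN = cross_tabulate(inheritance$BN, regulatory$BN),
                   NB = cross_tabulate(inheritance$NB, regulatory$NB))

  imprinting <- imprinting_calls(ftab, min_total = th$imprint_min_total,
                                 cutoff = th$imprint_cutoff)

  enrichment <- list()
  if (!is.null(ftab$chromosome)) {
    enrichment$inheritance_BN <- chromosome_enrichment(
      inheritance$BN, ftab$chromosome, th$enrich_alpha, th$lor_cut)
    enrichment$inheritance_NB <- chromosome_enrichment(
      inheritance$NB, ftab$chromosome, th$enrich_alpha, th$lor_cut)
    enrichment$regulatory_BN <- chromosome_enrichment(
      regulatory$BN, ftab$chromosome, th$enrich_alpha, th$lor_cut)
    enrichment$regulatory_NB <- chromosome_enrichment(
      regulatory$NB, ftab$chromosome, th$enrich_alpha, th$lor_cut)
  }
  if (!is.null(gene_sets)) {
    for (cc in c("overdominant", "underdominant")) {
      if (!is.null(venn[[cc]]))
        enrichment[[paste0("shared_", cc)]] <- overrepresentation(
          venn[[cc]]$shared, gene_sets, expressed, th$ora_fdr)
    }
    for (cc in c("cis", "trans")) {
      if (!is.null(venn_reg[[cc]]))
        enrichment[[paste0("shared_", cc)]] <- overrepresentation(
          venn_reg[[cc]]$shared, gene_sets, expressed, th$ora_fdr)
    }
  }

  alleles <- allele_contrast_summary(de$BN_allele, de$NB_allele,
                                     alpha = th$alpha_raw, lfc_cut = th$lfc_cut)

  grp <- ftab$sample_sheet$group
  lcpm <- log2(cpm(ftab$counts, ftab$lib_sizes) + 1)
  gmean <- function(g) rowMeans(lcpm[, grp == g, drop = FALSE])
  correlations <- c(
    Cbr_vs_Cni = spearman_rho(gmean("Cbr"), gmean("Cni")),
    BN_alleles = spearman_rho(gmean("BN_cbr"), gmean("BN_cni")),
    NB_alleles = spearman_rho(gmean("NB_cbr"), gmean("NB_cni")),
    BN_cbr_vs_Cbr = spearman_rho(gmean("BN_cbr"), gmean("Cbr")),
    BN_cni_vs_Cni = spearman_rho(gmean("BN_cni"), gmean("Cni")),
    NB_cbr_vs_Cbr = spearman_rho(gmean("NB_cbr"), gmean("Cbr")),
    NB_cni_vs_Cni = spearman_rho(gmean("NB_cni"), gmean("Cni")))

  tracks <- list()
  if (!is.null(mito_genes)) {
    msize <- mito_library_sizes(ftab$counts, intersect(mito_genes, expressed))
    tracks$mito <- list(lib_sizes = msize,
                        cpm = cpm(ftab$counts[intersect(mito_genes, expressed), ,
                                              drop = FALSE], msize))
  }
  if (!is.null(te_counts)) {
    te_cpm <- cpm(te_counts)
    kept <- te_filter(te_cpm, th$te_min_cpm, th$te_min_columns)
    te_cols_bn <- grep("^BN", colnames(te_counts), value = TRUE)
    te_cols_nb <- grep("^NB", colnames(te_counts), value = TRUE)
    tracks$te <- list(
      kept_families = kept,
      de = te_differential(te_counts[kept, , drop = FALSE],
                           te_cols_bn, te_cols_nb,
                           lib_sizes = colSums(te_counts),
                           alpha = th$alpha_raw, lfc_cut = th$lfc_cut))
  }

  structure(list(
    table = ftab, expressed = expressed, de = de,
    inheritance = inheritance, regulatory = regulatory,
    venn = venn, venn_regulatory = venn_reg, crosstab = crosstab,
    imprinting = imprinting, enrichment = enrichment,
    allele_contrasts = alleles, correlations = correlations,
    tracks = tracks, thresholds = th
  ), class = "ase_analysis")
}

#' Shared up-regulated allele sets across the two hybrids
#'
#' Per hybrid, classifies each pair from the within-hybrid allele contrast
#' (raw p-value convention): `Cbr up` when the Cbr allele is significantly
#' higher (`p < alpha`, `log2fc > lfc_cut` with orientation log2(Cbr
#' allele / Cni allele)), `Cni up` for the mirror. The `both_*` sets are the
#' intersections across hybrids and are disjoint by sign.
#'
#' @param de_bn_allele,de_nb_allele Allele-contrast DE tables from
#'   [run_de()], oriented `log2(cbr / cni)`.
#' @param alpha Raw p-value cutoff (default 0.05).
#' @param lfc_cut Log2 fold-change cutoff (default 1).
#' @return List of id sets: `BN_cbr_up`, `BN_cni_up`, `NB_cbr_up`,
#'   `NB_cni_up`, `both_cbr_up`, `both_cni_up`.
#' @export
allele_contrast_summary <- function(de_bn_allele, de_nb_allele,
                                    alpha = 0.05, lfc_cut = 1) {
  up <- function(de, sign) {
    sig <- de$pvalue < alpha & sign * de$log2fc > lfc_cut
    sort(de$feature_id[sig])
  }
  bn_cbr <- up(de_bn_allele, 1); bn_cni <- up(de_bn_allele, -1)
  nb_cbr <- up(de_nb_allele, 1); nb_cni <- up(de_nb_allele, -1)
  list(BN_cbr_up = bn_cbr, BN_cni_up = bn_cni,
       NB_cbr_up = nb_cbr, NB_cni_up = nb_cni,
       both_cbr_up = intersect(bn_cbr, nb_cbr),
       both_cni_up = intersect(bn_cni, nb_cni))
}

#' @export
print.ase_analysis <- function(x, ...) {
  cat("Allele-specific expression analysis of reciprocal F1 hybrids\n")
  cat(sprintf("  expressed ortholog pairs: %d (CPM > %g in >= %d of %d columns)\n",
              length(x$expressed), x$thresholds$min_cpm, x$thresholds$min_columns,
              ncol(x$table$counts)))
  for (h in c("BN", "NB")) {
    pr <- category_proportions(x$inheritance[[h]])
    cat(sprintf("  %s inheritance: %s\n", h,
                paste(sprintf("%s %.1f%%", pr$category, 100 * pr$fraction),
                      collapse = ", ")))
  }
  for (h in c("BN", "NB")) {
    pr <- category_proportions(x$regulatory[[h]])
    cat(sprintf("  %s regulatory: %s\n", h,
                paste(sprintf("%s %.1f%%", pr$category, 100 * pr$fraction),
                      collapse = ", ")))
  }
  imp <- table(x$imprinting$status)
  cat(sprintf("  imprinted genes: %d maternal, %d paternal\n",
              imp["maternal"][[1]] %||% 0, imp["paternal"][[1]] %||% 0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Summarize an `ase_analysis`
#'
#' @param object An `ase_analysis`.
#' @param ... Unused.
#' @return List with per-hybrid inheritance and regulatory category counts
#'   and fractions, transgressive Venn cell sizes, imprinting counts and
#'   leaning split, significant enrichment flags, allele-contrast set sizes
#'   and the Spearman correlation summary.
#' @export
summary.ase_analysis <- function(object, ...) {
  venn_sizes <- lapply(object$venn, function(v) vapply(v, length, integer(1)))
  imp <- table(factor(object$imprinting$status,
                      levels = c("maternal", "paternal", "none")))
  lean <- table(factor(object$imprinting$leaning,
                       levels = c("maternal", "paternal", "balanced")))
  flags <- lapply(object$enrichment, function(e) {
    if ("significant" %in% names(e)) e[e$significant, , drop = FALSE]
    else e[e$reported, , drop = FALSE]
  })
  out <- list(
    n_expressed = length(object$expressed),
    inheritance = lapply(object$inheritance, category_proportions),
    regulatory = lapply(object$regulatory, category_proportions),
    venn = venn_sizes,
    imprinting = list(counts = as.list(imp), leaning = as.list(lean)),
    enrichment_flags = flags,
    allele_contrasts = vapply(object$allele_contrasts, length, integer(1)),
    correlations = object$correlations,
    thresholds = object$thresholds)
  class(out) <- "summary.ase_analysis"
  out
}

#' @export
print.summary.ase_analysis <- function(x, ...) {
  cat("Expressed ortholog pairs:", x$n_expressed, "\n\nInheritance modes:\n")
  for (h in names(x$inheritance)) {
    cat(" ", h, "\n")
    print(x$inheritance[[h]], row.names = FALSE)
  }
  cat("\nRegulatory modes:\n")
  for (h in names(x$regulatory)) {
    cat(" ", h, "\n")
    print(x$regulatory[[h]], row.names = FALSE)
  }
  cat("\nImprinting:", x$imprinting$counts$maternal, "maternal,",
      x$imprinting$counts$paternal, "paternal\n")
  cat("\nSpearman correlations (log2 CPM + 1):\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' Plot inheritance and regulatory category proportions
#'
#' Side-by-side barplots of the per-hybrid category fractions, the standard
#' at-a-glance view of an analysis.
#'
#' @param x An `ase_analysis`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ase_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(8, 4, 3, 1))
  on.exit(graphics::par(op))
  for (what in c("inheritance", "regulatory")) {
    props <- sapply(x[[what]], function(calls) {
      pr <- category_proportions(calls)
      stats::setNames(pr$fraction, pr$category)
    })
    graphics::barplot(t(props), beside = TRUE, las = 2,
                      legend.text = colnames(props),
                      ylab = "fraction of expressed pairs",
                      main = what, ...)
  }
  invisible(x)
}

#' Run the pipeline from a configuration and write a report bundle
#'
#' Reads the inputs named in the configuration, runs [ase_analysis()], and
#' writes per-stage TSVs, a JSON summary and a run log to the output
#' directory. Optional stages (gene sets, mitochondria track, TE track) are
#' skipped, and logged as skipped, when their inputs are absent. Re-running
#' with the same configuration produces byte-identical outputs.
#'
#' @param config Named list, or path to a YAML file, with entries `counts`,
#'   `sample_sheet`, `ortholog_map` (paths), optional `gene_sets` (GMT),
#'   `mito_genes` (one id per line), `te_counts` (TSV), optional
#'   `thresholds` (named list) and `outdir`.
#' @return The `ase_analysis` object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (need in c("counts", "sample_sheet", "ortholog_map"))
    if (is.null(config[[need]])) stop("config is missing required entry: ", need)
  outdir <- config$outdir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  th <- config$thresholds %||% list()

  log_lines <- c("hybridASE pipeline run",
                 paste0("thresholds: ",
                        paste(sprintf("%s=%g", names(utils::modifyList(default_thresholds(), th)),
                                      unlist(utils::modifyList(default_thresholds(), th))),
                              collapse = " ")))
  gene_sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
  mito <- if (!is.null(config$mito_genes)) readLines(config$mito_genes)
  te <- if (!is.null(config$te_counts)) read_counts_tsv(config$te_counts)
  for (opt in c("gene_sets", "mito_genes", "te_counts"))
    if (is.null(config[[opt]]))
      log_lines <- c(log_lines, paste("stage skipped (no input):", opt))

  fit <- ase_analysis(config$counts, config$sample_sheet, config$ortholog_map,
                      gene_sets = gene_sets, mito_genes = mito, te_counts = te,
                      thresholds = th)

  write_tsv(rbind(fit$inheritance$BN, fit$inheritance$NB),
            file.path(outdir, "inheritance_calls.tsv"))
  write_tsv(rbind(fit$regulatory$BN, fit$regulatory$NB),
            file.path(outdir, "regulatory_calls.tsv"))
  write_tsv(fit$imprinting, file.path(outdir, "imprinting.tsv"))
  for (nm in names(fit$de))
    write_tsv(fit$de[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))
  for (nm in names(fit$enrichment))
    write_tsv(fit$enrichment[[nm]], file.path(outdir, paste0("enrichment_", nm, ".tsv")))

  s <- summary(fit)
  json <- c(
    list(n_expressed = s$n_expressed),
    list(inheritance = lapply(s$inheritance, function(d)
      stats::setNames(round(d$fraction, 3), d$category))),
    list(regulatory = lapply(s$regulatory, function(d)
      stats::setNames(round(d$fraction, 3), d$category))),
    list(venn = s$venn, imprinting = s$imprinting,
         allele_contrasts = as.list(s$allele_contrasts),
         correlations = as.list(round(s$correlations, 3))))
  jsonlite::write_json(json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(fit)
}
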