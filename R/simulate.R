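# Synthetic allele-resolved count experiments with known per-gene truth.
#
# The generator mirrors the study design it stands in for: two parental
# species (3 Cni replicates, 2 Cbr replicates) and two reciprocal F1 hybrids
# (BN: Cbr father x Cni mother; NB: Cni father x Cbr mother), each hybrid
# replicate split into two haplotype count columns, giving 13 columns in the
# default design. Counts are negative binomial with variance mu + phi * mu^2.

#' Build a scenario configuration for the synthetic generator
#'
#' @param n_orthologs Number of one-to-one ortholog pairs to simulate.
#' @param class_mix Named numeric vector of inheritance-class proportions over
#'   `no_change`, `cbr_dominant`, `cni_dominant`, `additive`, `overdominant`,
#'   `underdominant`. Must sum to 1.
#' @param reg_mix Named numeric vector of regulatory-class proportions over
#'   `conserved`, `cis`, `trans`. Must sum to 1. `conserved` is only
#'   realizable on `no_change` genes and `cis`/`trans` only on genes with
#'   parental divergence, so the two mixes must be jointly feasible (see
#'   [build_truth()]).
#' @param n_imprinted_maternal,n_imprinted_paternal Number of genes whose
#'   hybrid allele ratios are overridden by a parent-of-origin imprint.
#' @param effect_size Minimum parental divergence and the transgressive
#'   offset, in log2 units.
#' @param dispersion Negative-binomial dispersion phi (variance mu + phi mu^2).
#' @param mean_log2_expr_range Range of baseline expression, log2-CPM scale.
#' @param lib_size_mean,lib_size_cv Mean reads per sample and its coefficient
#'   of variation.
#' @param replicates Named integer vector of replicate counts per sample
#'   group (`Cni`, `Cbr`, `BN`, `NB`).
#' @param x_fraction Fraction of genes placed on the X chromosome; the rest
#'   are uniform over autosomes I-V.
#' @param imprint_fraction Maternal (or paternal) allele fraction given to
#'   imprinted genes.
#' @param n_gene_sets Number of gene sets emitted for enrichment analyses.
#' @param seed Root seed; all sub-streams are derived from it.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_orthologs = 3000,
                            class_mix = stats::setNames(rep(1 / 6, 6), INHERITANCE_CLASSES),
                            reg_mix = c(conserved = 1 / 6, cis = 7 / 12, trans = 3 / 12),
                            n_imprinted_maternal = 0,
                            n_imprinted_paternal = 0,
                            effect_size = 2.0,
                            dispersion = 0.05,
                            mean_log2_expr_range = c(3, 10),
                            lib_size_mean = 5e6,
                            lib_size_cv = 0.2,
                            replicates = c(Cni = 3, Cbr = 2, BN = 2, NB = 2),
                            x_fraction = 0.15,
                            imprint_fraction = 0.9,
                            n_gene_sets = 6,
                            seed = 1) {
  if (length(n_orthologs) != 1 || n_orthologs < 1) stop("n_orthologs must be a positive integer")
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix proportions must sum to 1")
  if (abs(sum(reg_mix) - 1) > 1e-9) stop("reg_mix proportions must sum to 1")
  if (!all(names(class_mix) %in% INHERITANCE_CLASSES))
    stop("unknown inheritance class in class_mix: ",
         paste(setdiff(names(class_mix), INHERITANCE_CLASSES), collapse = ", "))
  if (!all(names(reg_mix) %in% REGULATORY_CLASSES))
    stop("unknown regulatory class in reg_mix: ",
         paste(setdiff(names(reg_mix), REGULATORY_CLASSES), collapse = ", "))
  if (any(class_mix < 0) || any(reg_mix < 0)) stop("mix proportions must be non-negative")
  if (n_imprinted_maternal < 0 || n_imprinted_paternal < 0)
    stop("imprinted gene counts must be non-negative")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(mean_log2_expr_range) != 2 || diff(mean_log2_expr_range) < 0)
    stop("mean_log2_expr_range must be an increasing pair")
  if (!all(c("Cni", "Cbr", "BN", "NB") %in% names(replicates)))
    stop("replicates must name Cni, Cbr, BN and NB")
  if (any(replicates < 1)) stop("each group needs at least one replicate")
  if (imprint_fraction <= 0.5 || imprint_fraction >= 1)
    stop("imprint_fraction must lie in (0.5, 1)")
  structure(list(
    n_orthologs = as.integer(n_orthologs),
    class_mix = class_mix, reg_mix = reg_mix,
    n_imprinted_maternal = as.integer(n_imprinted_maternal),
    n_imprinted_paternal = as.integer(n_imprinted_paternal),
    effect_size = effect_size, dispersion = dispersion,
    mean_log2_expr_range = mean_log2_expr_range,
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    replicates = replicates, x_fraction = x_fraction,
    imprint_fraction = imprint_fraction,
    n_gene_sets = as.integer(n_gene_sets), seed = as.integer(seed)
  ), class = "scenario_config")
}

# Allocate n items to categories in exact proportion (largest remainder), so a
# uniform mix over 3000 genes yields exactly 500 per class.
allocate_counts <- function(n, mix) {
  mix <- mix[mix > 0]
  raw <- n * mix / sum(mix)
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1
  }
  k
}

#' Draw per-gene generative parameters and true class labels
#'
#' Samples inheritance and regulatory classes jointly under the
#' class-conditional rules: `no_change` genes have zero parental divergence
#' and zero hybrid offset and are the only genes that can carry the
#' `conserved` regulatory label; `cis`/`trans` genes have `|d| >=
#' effect_size`, with the hybrid allele ratio equal to `d` (cis) or equalized
#' to zero (trans). Dominant genes sit at one parent's level, additive genes
#' at the parental log2 midpoint, and transgressive genes `effect_size`
#' beyond the parental extreme. Infeasible mix combinations (for example
#' `conserved` regulation requested alongside a purely `overdominant`
#' inheritance mix) are rejected with an error naming the conflicting pair.
#'
#' @param config A [scenario_config()].
#' @return A `data.frame` of class `ase_truth`, one row per ortholog pair,
#'   with the generative parameters (baseline `mu`, divergence `d`, hybrid
#'   totals and allele log2 ratios, expected CPM per group) and the true
#'   inheritance, regulatory and imprint labels. Gene sets are attached as
#'   the `gene_sets` attribute.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_orthologs
  cm <- config$class_mix[config$class_mix > 0]
  rm_ <- config$reg_mix[config$reg_mix > 0]

  # Joint feasibility of the two mixes under the class-conditional rules.
  has_nc <- "no_change" %in% names(cm)
  has_div <- length(setdiff(names(cm), "no_change")) > 0
  if ("conserved" %in% names(rm_) && !has_nc)
    stop("inconsistent mixes: regulatory 'conserved' requires inheritance 'no_change', ",
         "but class_mix only requests '", paste(names(cm), collapse = "', '"), "'")
  if (any(c("cis", "trans") %in% names(rm_)) && !has_div)
    stop("inconsistent mixes: regulatory '",
         intersect(c("cis", "trans"), names(rm_))[1],
         "' requires parental divergence, but class_mix is all 'no_change'")
  if (has_nc && !("conserved" %in% names(rm_)))
    stop("inconsistent mixes: inheritance 'no_change' forces regulatory 'conserved', ",
         "which reg_mix assigns zero mass")
  if (has_div && !any(c("cis", "trans") %in% names(rm_)))
    stop("inconsistent mixes: inheritance '", setdiff(names(cm), "no_change")[1],
         "' requires regulatory 'cis' or 'trans', which reg_mix assigns zero mass")

  seeds <- derive_seeds(config$seed, 4L)
  set.seed(seeds[1])

  k_class <- allocate_counts(n, cm)
  inheritance <- sample(rep(names(k_class), k_class))

  regulatory <- character(n)
  regulatory[inheritance == "no_change"] <- "conserved"
  idx_div <- which(inheritance != "no_change")
  if (length(idx_div)) {
    ct <- rm_[intersect(c("cis", "trans"), names(rm_))]
    k_reg <- allocate_counts(length(idx_div), ct)
    regulatory[sample(idx_div)] <- rep(names(k_reg), k_reg)
  }

  mu <- stats::runif(n, config$mean_log2_expr_range[1], config$mean_log2_expr_range[2])
  d <- numeric(n)
  div <- inheritance != "no_change"
  # Divergence directions are balanced within each inheritance class so the
  # two species carry equal shares of up- and down-divergent genes; an
  # uncontrolled sign imbalance would put a composition bias into every
  # contrast that trimmed-mean normalization could not identify.
  sign_d <- numeric(n)
  for (cls in unique(inheritance[div])) {
    idx <- which(inheritance == cls)
    sign_d[idx] <- sample(rep(c(-1, 1), length.out = length(idx)))
  }
  d[div] <- sign_d[div] * (config$effect_size + stats::rexp(sum(div), rate = 2))

  cbr <- mu + d / 2
  cni <- mu - d / 2
  total <- function(cls) {
    t <- mu
    t[cls == "cbr_dominant"] <- cbr[cls == "cbr_dominant"]
    t[cls == "cni_dominant"] <- cni[cls == "cni_dominant"]
    t[cls == "overdominant"] <- pmax(cbr, cni)[cls == "overdominant"] + config$effect_size
    t[cls == "underdominant"] <- pmin(cbr, cni)[cls == "underdominant"] - config$effect_size
    t   # no_change and additive stay at mu, the parental log2 midpoint
  }
  t_bn <- total(inheritance)
  t_nb <- total(inheritance)

  r <- numeric(n)
  r[regulatory == "cis"] <- d[regulatory == "cis"]
  r_bn <- r
  r_nb <- r

  imprint <- rep("none", n)
  n_imp <- config$n_imprinted_maternal + config$n_imprinted_paternal
  if (n_imp > 0) {
    pool <- which(inheritance == "no_change")
    if (length(pool) < n_imp)
      stop("cannot plant ", n_imp, " imprinted genes: only ", length(pool),
           " no_change genes available to carry an imprint")
    picked <- sample(pool, n_imp)
    mat <- picked[seq_len(config$n_imprinted_maternal)]
    pat <- setdiff(picked, mat)
    imprint[mat] <- "maternal"
    imprint[pat] <- "paternal"
    f <- config$imprint_fraction
    lo <- log2((1 - f) / f)   # Cbr-allele log2 ratio when Cbr share is 1 - f
    hi <- -lo
    # In BN the mother is Cni, so the maternal allele is Cni (Cbr share 1 - f);
    # in NB the mother is Cbr (Cbr share f). Paternal imprints mirror this.
    r_bn[mat] <- lo; r_nb[mat] <- hi
    r_bn[pat] <- hi; r_nb[pat] <- lo
  }

  chromosome <- ifelse(stats::runif(n) < config$x_fraction, "X",
                       sample(CHROMOSOMES[1:5], n, replace = TRUE))

  pair_id <- sprintf("pair_%05d", seq_len(n))
  truth <- data.frame(
    pair_id = pair_id,
    cbr_gene = sprintf("cbr_g%05d", seq_len(n)),
    cni_gene = sprintf("cni_g%05d", seq_len(n)),
    chromosome = chromosome,
    mu = mu, d = d,
    offset_bn = t_bn - mu, offset_nb = t_nb - mu,
    r_bn = r_bn, r_nb = r_nb,
    cpm_cbr = 2^cbr, cpm_cni = 2^cni,
    cpm_bn_total = 2^t_bn, cpm_nb_total = 2^t_nb,
    inheritance_bn = inheritance, inheritance_nb = inheritance,
    regulatory_bn = regulatory, regulatory_nb = regulatory,
    imprint = imprint,
    stringsAsFactors = FALSE
  )

  set.seed(seeds[4])
  set_names <- c("oogenic", "spermatogenic", "gender_neutral",
                 "female_biased", "male_biased", "hermaphrodite_biased")
  if (config$n_gene_sets > length(set_names))
    set_names <- c(set_names, sprintf("set_%02d", seq_len(config$n_gene_sets - length(set_names))))
  set_names <- set_names[seq_len(config$n_gene_sets)]
  gene_sets <- lapply(set_names, function(nm) {
    size <- max(5L, stats::rbinom(1, n, stats::runif(1, 0.03, 0.10)))
    sort(sample(pair_id, min(size, n)))
  })
  names(gene_sets) <- set_names

  attr(truth, "gene_sets") <- gene_sets
  attr(truth, "config") <- config
  attr(truth, "count_seed") <- seeds[2]
  attr(truth, "lib_seed") <- seeds[3]
  class(truth) <- c("ase_truth", "data.frame")
  truth
}

#' Simulate an allele-resolved count experiment from a truth table
#'
#' Draws negative-binomial counts (variance `mu + phi * mu^2`; Poisson when
#' `phi = 0`) for every sample column. Parental samples produce counts only on
#' their own species' gene rows; each hybrid replicate produces two haplotype
#' columns whose expected counts split the hybrid total according to the
#' gene's allele log2 ratio.
#'
#' @param truth An `ase_truth` from [build_truth()].
#' @param config The same [scenario_config()] used to build `truth`.
#' @return A list of class `ase_experiment` with elements `counts` (gene-level
#'   matrix, one row per gene of either species), `sample_sheet`,
#'   `lib_sizes` (nominal reads per column), `ortholog_map`, `gene_sets` and
#'   `truth`.
#' @export
simulate_counts <- function(truth, config) {
  if (!inherits(truth, "ase_truth")) stop("truth must be produced by build_truth()")
  stopifnot(inherits(config, "scenario_config"))
  if (config$dispersion < 0) stop("dispersion must be >= 0")
  n <- nrow(truth)
  reps <- config$replicates

  set.seed(attr(truth, "lib_seed"))
  n_samples <- sum(reps)
  sample_group <- rep(names(reps), reps)
  sample_rep <- unlist(lapply(reps, seq_len), use.names = FALSE)
  if (config$lib_size_cv > 0) {
    lib <- stats::rnorm(n_samples, config$lib_size_mean,
                        config$lib_size_cv * config$lib_size_mean)
    lib <- pmax(round(lib), ceiling(0.05 * config$lib_size_mean))
  } else {
    lib <- rep(round(config$lib_size_mean), n_samples)
  }

  draw <- function(mu_counts) {
    if (config$dispersion == 0) stats::rpois(length(mu_counts), mu_counts)
    else stats::rnbinom(length(mu_counts), mu = mu_counts, size = 1 / config$dispersion)
  }

  p_bn <- 2^truth$r_bn / (1 + 2^truth$r_bn)   # Cbr-allele share in BN
  p_nb <- 2^truth$r_nb / (1 + 2^truth$r_nb)

  set.seed(attr(truth, "count_seed"))
  col_ids <- character(0); col_group <- character(0); col_rep <- integer(0)
  col_lib <- numeric(0)
  cols <- list()
  zero <- numeric(n)
  for (s in seq_len(n_samples)) {
    g <- sample_group[s]; rp <- sample_rep[s]; L <- lib[s]
    if (g == "Cni") {
      cnts <- draw(truth$cpm_cni * L / 1e6)
      cols[[length(cols) + 1]] <- c(zero, cnts)       # cbr rows, then cni rows
      col_ids <- c(col_ids, sprintf("Cni_%d", rp))
      col_group <- c(col_group, "Cni"); col_rep <- c(col_rep, rp); col_lib <- c(col_lib, L)
    } else if (g == "Cbr") {
      cnts <- draw(truth$cpm_cbr * L / 1e6)
      cols[[length(cols) + 1]] <- c(cnts, zero)
      col_ids <- c(col_ids, sprintf("Cbr_%d", rp))
      col_group <- c(col_group, "Cbr"); col_rep <- c(col_rep, rp); col_lib <- c(col_lib, L)
    } else {
      p <- if (g == "BN") p_bn else p_nb
      tot <- if (g == "BN") truth$cpm_bn_total else truth$cpm_nb_total
      c_cbr <- draw(tot * p * L / 1e6)
      c_cni <- draw(tot * (1 - p) * L / 1e6)
      cols[[length(cols) + 1]] <- c(c_cbr, zero)
      cols[[length(cols) + 1]] <- c(zero, c_cni)
      col_ids <- c(col_ids, sprintf("%s_cbr_%d", g, rp), sprintf("%s_cni_%d", g, rp))
      col_group <- c(col_group, sprintf("%s_cbr", g), sprintf("%s_cni", g))
      col_rep <- c(col_rep, rp, rp); col_lib <- c(col_lib, L, L)
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(c(truth$cbr_gene, truth$cni_gene), col_ids)

  sheet <- data.frame(column_id = col_ids, group = col_group,
                      replicate = col_rep, stringsAsFactors = FALSE)
  map <- truth[, c("pair_id", "cbr_gene", "cni_gene", "chromosome")]
  class(map) <- "data.frame"

  structure(list(
    counts = counts,
    sample_sheet = sheet,
    lib_sizes = stats::setNames(col_lib, col_ids),
    ortholog_map = map,
    gene_sets = attr(truth, "gene_sets"),
    truth = truth,
    config = config
  ), class = "ase_experiment")
}

#' Simulate a full experiment in one call
#'
#' @param config A [scenario_config()].
#' @return An `ase_experiment`; see [simulate_counts()].
#' @export
simulate_ase_experiment <- function(config = scenario_config()) {
  simulate_counts(build_truth(config), config)
}

#' @export
print.ase_experiment <- function(x, ...) {
  cat("Synthetic allele-resolved expression experiment\n")
  cat(sprintf("  %d ortholog pairs, %d count columns (%s)\n",
              nrow(x$ortholog_map), ncol(x$counts),
              paste(sprintf("%s:%d", names(x$config$replicates), x$config$replicates),
                    collapse = ", ")))
  cat(sprintf("  dispersion phi = %g, effect size = %g log2 units\n",
              x$config$dispersion, x$config$effect_size))
  tab <- table(x$truth$inheritance_bn)
  cat("  inheritance classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated experiment to plain-text fixture files
#'
#' Emits the full on-disk interface consumed by [assemble_groups()] and the
#' pipeline: a gene-level counts TSV, a sample sheet, the ortholog map, a
#' chromosome table, gene sets in GMT format, and the ground-truth table.
#'
#' @param experiment An `ase_experiment`.
#' @param directory Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(experiment, directory) {
  stopifnot(inherits(experiment, "ase_experiment"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  paths <- c(
    counts = file.path(directory, "counts.tsv"),
    sample_sheet = file.path(directory, "sample_sheet.tsv"),
    ortholog_map = file.path(directory, "ortholog_map.tsv"),
    chromosomes = file.path(directory, "chromosomes.tsv"),
    gene_sets = file.path(directory, "gene_sets.gmt"),
    truth = file.path(directory, "truth.tsv")
  )
  write_counts_tsv(experiment$counts, paths["counts"])
  write_tsv(experiment$sample_sheet, paths["sample_sheet"])
  write_tsv(experiment$ortholog_map, paths["ortholog_map"])
  write_tsv(experiment$ortholog_map[, c("pair_id", "chromosome")], paths["chromosomes"])
  write_gmt(experiment$gene_sets, paths["gene_sets"])
  truth_df <- experiment$truth
  class(truth_df) <- "data.frame"
  write_tsv(truth_df, paths["truth"])
  invisible(paths)
}
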