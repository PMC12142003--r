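# Two-group negative-binomial exact differential expression: TMM scaling
# factors, conditional-likelihood dispersion estimation with empirical-Bayes
# shrinkage, the conditional exact test on group pseudo-sums, and BH FDR.

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes one scaling factor per column against a reference column: genes
#' expressed in both columns contribute a log2 expression ratio (M) and a
#' log2 average abundance (A); after trimming 30% of the M-values and 5% of
#' the A-values from each tail, the factor is the precision-weighted mean of
#' the remaining M-values. Factors are normalized to geometric mean 1, so a
#' pure sequencing-depth difference gives factors of 1 and composition bias
#' (a minority of genes inflated in one column) is absorbed by the factor.
#'
#' @param counts Count matrix (>= 2 columns).
#' @param lib_sizes Library sizes per column; default column totals.
#' @param logratio_trim Fraction of M-values trimmed from each tail.
#' @param sum_trim Fraction of A-values trimmed from each tail.
#' @param ref_column Optional reference column (name or index); by default
#'   the column whose upper-quartile count fraction is closest to the mean.
#' @return Numeric vector of factors, one per column.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        logratio_trim = 0.3, sum_trim = 0.05,
                        ref_column = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two columns")
  zero_col <- lib_sizes == 0
  if (any(zero_col)) {
    warning("all-zero column(s): factor set to 1")
    lib_sizes[zero_col] <- 1
  }
  p <- sweep(counts, 2, lib_sizes, "/")

  if (is.null(ref_column)) {
    uq <- apply(p, 2, stats::quantile, probs = 0.75)
    ref_column <- which.min(abs(uq - mean(uq)))
  }
  pr <- p[, ref_column]
  nr <- lib_sizes[ref_column]

  one_factor <- function(j) {
    if (zero_col[j]) return(1)
    ok <- p[, j] > 0 & pr > 0
    if (sum(ok) < 10) return(1)
    pj <- p[ok, j]; pk <- pr[ok]
    M <- log2(pj / pk)
    A <- 0.5 * log2(pj * pk)
    # Delta-method variance of M for the precision weights.
    w <- (1 - pj) / (counts[ok, j]) + (1 - pk) / (counts[ok, ref_column])
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    f <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    if (!is.finite(f) || f <= 0) 1 else f
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  stats::setNames(f / exp(mean(log(f))), colnames(counts))
}

# Conditional NB log-likelihood of a group's counts given their sum, for equal
# library sizes: the only phi-dependent terms of log P(y_1..y_n | sum(y)).
cml_group <- function(y, phi) {
  n <- ncol(y)
  if (phi <= 0) phi <- 1e-8
  a <- 1 / phi
  z <- rowSums(y)
  rowSums(lgamma(y + a)) - n * lgamma(a) + lgamma(n * a) - lgamma(z + n * a)
}

#' Estimate negative-binomial dispersion by conditional maximum likelihood
#'
#' The common dispersion maximizes the conditional NB log-likelihood summed
#' over all features and replicate groups on library-size-equalized counts.
#' Per-feature dispersions maximize a weighted likelihood that adds the
#' common-likelihood curve with a prior weight equivalent to `prior_df`
#' extra degrees of freedom, shrinking noisy feature-wise estimates toward
#' the common value.
#'
#' @param counts Count matrix.
#' @param groups Factor or character vector of group labels per column.
#' @param lib_sizes Library sizes per column; default column totals.
#' @param prior_df Prior degrees of freedom for the shrinkage weight.
#' @return List with `common` (scalar phi) and `tagwise` (per-feature phi).
#'   With no replicated group, both fall back to 0.05 with a warning.
#' @export
estimate_dispersion <- function(counts, groups, lib_sizes = colSums(counts),
                                prior_df = 10) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  groups <- as.character(groups)
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2]
  if (length(rep_groups) == 0) {
    warning("no group with >= 2 replicates: dispersion fixed at 0.05")
    return(list(common = 0.05, tagwise = rep(0.05, nrow(counts))))
  }
  # Equalize library sizes so the conditional likelihood (which assumes equal
  # expected totals within a group) applies.
  eq <- sweep(counts, 2, exp(mean(log(lib_sizes))) / lib_sizes, "*")

  df_res <- sum(tab[rep_groups] - 1)
  phis <- c(1e-6, exp(seq(log(1e-4), log(5), length.out = 60)))
  ll <- matrix(0, nrow(counts), length(phis))
  for (g in rep_groups) {
    y <- eq[, groups == g, drop = FALSE]
    for (i in seq_along(phis)) ll[, i] <- ll[, i] + cml_group(y, phis[i])
  }
  common_curve <- colSums(ll)
  i0 <- which.max(common_curve)
  lo <- phis[max(1, i0 - 1)]; hi <- phis[min(length(phis), i0 + 1)]
  obj <- function(phi) {
    s <- 0
    for (g in rep_groups) s <- s + sum(cml_group(eq[, groups == g, drop = FALSE], phi))
    s
  }
  common <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)$maximum
  if (common_curve[1] >= max(common_curve) - 1e-8) common <- phis[1]

  w <- prior_df / df_res
  score <- ll + w * matrix(common_curve / nrow(counts), nrow(counts),
                           length(phis), byrow = TRUE)
  tagwise <- phis[max.col(score, ties.method = "first")]
  list(common = common, tagwise = tagwise)
}

#' Conditional negative-binomial exact test on group pseudo-sums
#'
#' Conditions on `s = sum_a + sum_b`: under the null the group totals are
#' negative binomial with means proportional to the replicate numbers
#' `n_a : n_b` and dispersion `phi / n`; the two-sided p-value sums the
#' conditional probabilities of all splits `(k, s - k)` whose probability is
#' at most that of the observed split (within relative tolerance `1 + 1e-7`).
#' With `phi = 0` this is the exact binomial two-tail by the probability-mass
#' rule. `s = 0` gives p = 1 by convention.
#'
#' @param sum_a,sum_b Group pseudo-sums (counts scaled to a common library
#'   size and summed within group). Vectors are tested element-wise.
#' @param n_a,n_b Number of replicates per group.
#' @param phi Dispersion; scalar or vector matching `sum_a`.
#' @return Vector of raw p-values in (0, 1].
#' @export
nb_exact_test <- function(sum_a, sum_b, n_a, n_b, phi = 0) {
  if (length(sum_b) != length(sum_a)) stop("sum_a and sum_b lengths differ")
  if (any(phi < 0)) stop("phi must be >= 0")
  phi <- rep_len(phi, length(sum_a))
  prop <- n_a / (n_a + n_b)
  vapply(seq_along(sum_a), function(i) {
    sa <- round(sum_a[i]); sb <- round(sum_b[i]); s <- sa + sb
    if (s == 0) return(1)
    if (phi[i] <= 0) {
      lp <- stats::dbinom(0:s, s, prop, log = TRUE)
    } else {
      size_a <- n_a / phi[i]; size_b <- n_b / phi[i]
      ma <- s * prop; mb <- s - ma
      if (s > 200000) {
        k_lo <- max(0, stats::qnbinom(1e-14, size = size_a, mu = ma) - 2)
        k_hi <- min(s, stats::qnbinom(1e-14, size = size_a, mu = ma,
                                      lower.tail = FALSE) + 2)
        ks <- sort(unique(c(k_lo:k_hi, sa)))
      } else {
        ks <- 0:s
      }
      lp <- stats::dnbinom(ks, size = size_a, mu = ma, log = TRUE) +
        stats::dnbinom(s - ks, size = size_b, mu = mb, log = TRUE)
      if (s > 200000) {
        obs <- match(sa, ks)
        m <- max(lp)
        pr <- exp(lp - m)
        return(min(1, sum(pr[pr <= pr[obs] * (1 + 1e-7)]) / sum(pr)))
      }
    }
    m <- max(lp)
    pr <- exp(lp - m)
    pr <- pr / sum(pr)
    p_obs <- pr[sa + 1]
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of step-up adjusted values (monotone in `p`).
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression with the NB exact test
#'
#' Glues the engine together for one contrast: TMM factors give effective
#' library sizes; columns are scaled to the geometric-mean effective library
#' and summed within group into pseudo-sums; dispersion is estimated by
#' conditional maximum likelihood with shrinkage (unless supplied); the
#' conditional exact test yields raw p-values and BH adjustment the FDR.
#' The log2 fold change is `log2(mean CPM_a + prior) - log2(mean CPM_b +
#' prior)` on TMM-effective library sizes.
#'
#' @param counts Count matrix, or an `allele_count_table`.
#' @param cols_a,cols_b Column ids (or, for an `allele_count_table`, group
#'   names from the sample sheet) of the two disjoint groups.
#' @param lib_sizes Library sizes per column of `counts`; defaults to the
#'   stored pre-filter totals for an `allele_count_table`, else column sums.
#' @param prior_count Prior added to each group mean CPM for the fold change.
#' @param prior_df Shrinkage prior for the dispersion estimator.
#' @param dispersion Optional fixed dispersion (scalar or per feature),
#'   bypassing estimation.
#' @return `data.frame` with `feature_id`, `log2fc` (orientation
#'   `log2(a/b)`), `pvalue`, `fdr`, `log2cpm`.
#' @export
run_de <- function(counts, cols_a, cols_b, lib_sizes = NULL,
                   prior_count = 0.5, prior_df = 10, dispersion = NULL) {
  if (inherits(counts, "allele_count_table")) {
    sheet <- counts$sample_sheet
    if (all(cols_a %in% sheet$group)) cols_a <- sheet$column_id[sheet$group %in% cols_a]
    if (all(cols_b %in% sheet$group)) cols_b <- sheet$column_id[sheet$group %in% cols_b]
    if (is.null(lib_sizes)) lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.character(cols_a)) cols_a <- match(cols_a, colnames(counts))
  if (is.character(cols_b)) cols_b <- match(cols_b, colnames(counts))
  if (any(is.na(cols_a)) || any(is.na(cols_b))) stop("contrast columns not found")
  if (length(intersect(cols_a, cols_b))) stop("contrast groups must be disjoint")
  if (!length(cols_a) || !length(cols_b)) stop("contrast groups must be non-empty")

  use <- c(cols_a, cols_b)
  sub <- counts[, use, drop = FALSE]
  libs <- lib_sizes[use]
  grp <- rep(c("a", "b"), c(length(cols_a), length(cols_b)))

  f <- tmm_factors(sub, libs)
  eff <- libs * f
  cpm_sub <- sweep(sub, 2, eff / 1e6, "/")
  mean_a <- rowMeans(cpm_sub[, grp == "a", drop = FALSE])
  mean_b <- rowMeans(cpm_sub[, grp == "b", drop = FALSE])
  log2fc <- log2(mean_a + prior_count) - log2(mean_b + prior_count)
  log2cpm <- log2((mean_a + mean_b) / 2 + prior_count)

  L <- exp(mean(log(eff)))
  eq <- sweep(sub, 2, L / eff, "*")
  if (is.null(dispersion)) {
    disp <- estimate_dispersion(eq, grp, lib_sizes = rep(L, ncol(eq)),
                                prior_df = prior_df)
    phi <- disp$tagwise
  } else {
    phi <- rep_len(dispersion, nrow(sub))
  }
  ps_a <- round(rowSums(eq[, grp == "a", drop = FALSE]))
  ps_b <- round(rowSums(eq[, grp == "b", drop = FALSE]))
  p <- nb_exact_test(ps_a, ps_b, length(cols_a), length(cols_b), phi)

  data.frame(feature_id = rownames(counts),
             log2fc = log2fc, pvalue = p, fdr = bh_fdr(p),
             log2cpm = log2cpm,
             row.names = NULL, stringsAsFactors = FALSE)
}
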