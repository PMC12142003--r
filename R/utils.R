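#' @keywords internal
"_PACKAGE"

# The six haplotype-level expression groups and the four sample-level groups.
ALLELE_GROUPS <- c("Cni", "Cbr", "BN_cbr", "BN_cni", "NB_cbr", "NB_cni")
INHERITANCE_CLASSES <- c("no_change", "cbr_dominant", "cni_dominant",
                         "additive", "overdominant", "underdominant")
REGULATORY_CLASSES <- c("conserved", "cis", "trans")
CHROMOSOMES <- c("I", "II", "III", "IV", "V", "X")

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by all
#' on-disk interfaces of this package: a header row, tab separation, no quote
#' processing and no factor coercion.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x A `data.frame` or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  ok <- try(utils::write.table(x, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write: ", path)
  invisible(path)
}

# Counts matrix reader/writer: first column `feature_id`, integer counts.
read_counts_tsv <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "feature_id") stop("counts table must start with a 'feature_id' column: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature_id
  m
}

write_counts_tsv <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then member ids,
#'   tab-separated).
#' @return Named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be named")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write: ", path)
  invisible(path)
}

# Draw independent sub-stream seeds from one root seed, so operations that
# consume randomness in sequence stay reproducible if one of them changes.
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

stopifnot_finite <- function(x, what) {
  if (any(!is.finite(x))) stop(what, " must be finite")
  invisible(x)
}
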