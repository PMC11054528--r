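#' Remove constant and near-constant descriptor columns
#'
#' Drops descriptors with zero variance and descriptors whose most frequent
#' value accounts for at least \code{near_constant_fraction} of the
#' compounds. Near-constant descriptors carry almost no information at
#' library sizes of a few dozen compounds and destabilize regression and
#' standardization.
#'
#' @param x numeric matrix or data frame, compounds in rows, descriptors in
#'   named columns.
#' @param near_constant_fraction mode-frequency cut-off in (0, 1]; a column
#'   is dropped when its modal value's fraction is \code{>=} this. Default
#'   0.95.
#' @return List with \code{matrix} (the surviving columns, same row order)
#'   and \code{removed} (character vector of dropped descriptor names).
#' @export
filter_constant <- function(x, near_constant_fraction = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) == 0) stop("empty descriptor matrix")
  stopifnot(near_constant_fraction > 0, near_constant_fraction <= 1)
  mode_frac <- apply(x, 2, function(col) max(table(col)) / length(col))
  zero_var <- apply(x, 2, function(col) stats::var(col) == 0)
  drop <- zero_var | mode_frac >= near_constant_fraction
  if (all(drop))
    stop("all descriptor columns are constant or near-constant")
  list(matrix = x[, !drop, drop = FALSE], removed = colnames(x)[drop])
}

#' Remove highly correlated descriptor columns
#'
#' Greedy pruning in column order: scanning columns left to right, a column
#' is dropped if its absolute Pearson correlation with any earlier surviving
#' column is at least \code{r_threshold}. Earlier columns always survive, so
#' the result is deterministic for a given column order; after pruning no
#' remaining pair violates the threshold.
#'
#' @param x numeric matrix or data frame with at least 2 columns.
#' @param r_threshold absolute-correlation cut-off, default 0.95.
#' @return List with \code{matrix} and \code{removed}, as
#'   [filter_constant()].
#' @export
filter_correlated <- function(x, r_threshold = 0.95) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 descriptor columns")
  r <- abs(suppressWarnings(stats::cor(x)))
  keep <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    earlier <- which(keep)
    keep[j] <- !length(earlier) ||
      all(r[j, earlier] < r_threshold | is.na(r[j, earlier]))
  }
  list(matrix = x[, keep, drop = FALSE], removed = colnames(x)[!keep])
}

#' Column-standardize a descriptor matrix
#'
#' Centres each descriptor to mean 0 and scales to sample standard
#' deviation 1, removing the influence of the disparate natural scales of
#' descriptor blocks before distance-based chemometrics.
#'
#' @param x numeric matrix or data frame with no zero-variance columns.
#' @return Matrix of column z-scores (attributes of \code{scale} dropped).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "),
         " -- run filter_constant() first")
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}
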