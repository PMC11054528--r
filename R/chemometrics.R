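#' Pearson correlation matrix of an index table
#'
#' @param table data frame or matrix of index columns (a compound id column
#'   named \code{compound_id} is dropped automatically).
#' @return Symmetric unit-diagonal matrix of Pearson correlations.
#' @export
correlation_matrix <- function(table) {
  m <- index_matrix(table)
  if (nrow(m) < 3) stop("need at least 3 compounds")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  stats::cor(m)
}

#' Census of which scale gives each compound's minimum LogP
#'
#' For each compound, finds which of the computed-LogP scales attains the
#' row minimum, and tallies the counts per scale. Exact ties are reported
#' fractionally (each tying scale receives 1/k for a k-way tie), so the
#' counts always sum to the number of compounds.
#'
#' @param table data frame containing the computed LogP columns (default
#'   scales from [logp_scales()]; others are ignored).
#' @param scales which columns to census.
#' @return Named numeric vector of counts, one per scale (zeros included),
#'   with attribute \code{"minimizers"}: the per-compound list of
#'   minimizing scale names.
#' @export
#' @examples
#' min_descriptor_census(ipsapirone_logp())
min_descriptor_census <- function(table, scales = logp_scales()) {
  missing <- setdiff(scales, colnames(table))
  if (length(missing))
    stop("missing scale column(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(table[, scales, drop = FALSE])
  counts <- stats::setNames(numeric(length(scales)), scales)
  minimizers <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    winners <- scales[m[i, ] == min(m[i, ])]
    minimizers[[i]] <- winners
    counts[winners] <- counts[winners] + 1 / length(winners)
  }
  attr(counts, "minimizers") <- minimizers
  counts
}

#' Absolute disparity between two scales for one compound
#'
#' @param table index table with a \code{compound_id} column.
#' @param compound_id which compound.
#' @param scale_a,scale_b scale (column) names.
#' @param round round half-away-from-zero to 2 decimals for reporting.
#' @return Absolute difference between the two scale values.
#' @export
#' @examples
#' pairwise_disparity(ipsapirone_logp(), 9, "iLogP", "SilicosIT")  # 1.87
pairwise_disparity <- function(table, compound_id, scale_a, scale_b,
                               round = TRUE) {
  for (s in c(scale_a, scale_b))
    if (!s %in% colnames(table)) stop("unknown scale: ", s)
  row <- match(compound_id, table$compound_id)
  if (is.na(row)) stop("unknown compound_id: ", compound_id)
  d <- abs(table[[scale_a]][row] - table[[scale_b]][row])
  if (round) round_half_away(d, 2) else d
}

#' Hierarchical clustering of lipophilicity scales
#'
#' Agglomerative clustering with Ward's rule (the Ward.D2 variant, which
#' applies the variance-minimizing update to Euclidean input distances) on
#' the standardized index columns, so that scales measuring the same
#' underlying property group together regardless of their native units.
#' By default the objects clustered are the index columns (compounds act
#' as features); set \code{cluster = "compounds"} to cluster compounds
#' instead.
#'
#' @param table index table (a \code{compound_id} column is dropped).
#' @param standardize_first z-score each column before clustering.
#' @param cluster cluster the index \code{"columns"} (default) or the
#'   \code{"compounds"}.
#' @return An \code{hclust} object (merge heights are non-decreasing).
#' @seealso [cut_clusters()]
#' @export
index_hca <- function(table, standardize_first = TRUE,
                      cluster = c("columns", "compounds")) {
  cluster <- match.arg(cluster)
  m <- index_matrix(table)
  if (ncol(m) < 2) stop("need at least 2 index columns")
  if (standardize_first) m <- standardize(m)
  if (cluster == "columns") m <- t(m)
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}

#' Cut a dendrogram into k groups
#'
#' @param hc an \code{hclust} object from [index_hca()].
#' @param k number of clusters; must not exceed the number of leaves.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(hc, k) {
  n_leaves <- length(hc$order)
  if (k > n_leaves)
    stop("cannot cut ", n_leaves, " leaves into ", k, " clusters")
  stats::cutree(hc, k = k)
}

#' Principal component analysis of an index table
#'
#' PCA on (by default) standardized columns. Loadings follow the
#' largest-magnitude-element-positive sign convention so results are
#' reproducible across platforms.
#'
#' @param table index table (a \code{compound_id} column is dropped).
#' @param standardize_first z-score each column first.
#' @return List with \code{scores} (compounds x components),
#'   \code{loadings} (columns x components, orthonormal), and
#'   \code{explained} (variance fractions summing to 1).
#' @export
index_pca <- function(table, standardize_first = TRUE) {
  m <- index_matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize_first)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  list(scores = sweep(pc$x, 2, flip, `*`),
       loadings = sweep(pc$rotation, 2, flip, `*`),
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

index_matrix <- function(table) {
  if (is.data.frame(table))
    table <- table[setdiff(names(table), "compound_id")]
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("index table must be numeric")
  if (anyDuplicated(colnames(m))) stop("duplicate column names")
  m
}
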