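# Chemometrics: per-analyte standardization of peak-area profiles,
# agglomerative hierarchical clustering and heatmap export.

#' Standardize a peak-area table
#'
#' Column z-scores with the sample (n-1) standard deviation: each analyte is
#' centred to mean 0 and scaled to sd 1 so that clustering weighs abundant
#' and trace components equally.
#'
#' @param peaks A [peak_table()] or a numeric matrix with at least two rows
#'   and no missing cells.
#' @return A matrix of class `standardized_matrix` with attributes `center`
#'   and `scale` holding the original column means and sds.
#' @export
standardize <- function(peaks) {
  m <- if (inherits(peaks, "peak_table")) peaks$areas else as.matrix(peaks)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (anyNA(m)) stop("missing cells: impute or drop before standardizing")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column: ", colnames(m)[sds == 0][1L])
  z <- scale(m)
  structure(z, center = attr(z, "scaled:center"),
            scale = attr(z, "scaled:scale"),
            class = c("standardized_matrix", "matrix", "array"))
}

#' Hierarchical cluster analysis of standardized profiles
#'
#' Agglomerative clustering of samples on Euclidean distances between
#' z-scored peak-area profiles. The default Ward linkage (on squared
#' distances, i.e. `hclust`'s `ward.D2`) reproduces the published grouping
#' of the 21-batch reference panel; average and complete linkage are offered
#' as alternatives. Ties are broken deterministically by the merge order of
#' `stats::hclust` (lowest-index pair first).
#'
#' @param z A `standardized_matrix` from [standardize()] (a plain matrix is
#'   accepted and used as-is).
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return An object of class `cluster_result` wrapping the `hclust` tree,
#'   with `merge`, `height`, `labels` and `linkage`.
#' @export
hca <- function(z, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  m <- unclass(z)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  method <- switch(linkage, ward = "ward.D2", linkage)
  tree <- stats::hclust(stats::dist(m), method = method)
  structure(list(tree = tree, linkage = linkage,
                 labels = rownames(m)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$labels), "samples (",
      x$linkage, "linkage, Euclidean distance on z-scores )\n")
  invisible(x)
}

#' @export
plot.cluster_result <- function(x, ...) {
  graphics::plot(stats::as.dendrogram(x$tree), ...)
  invisible(x)
}

#' Cut a dendrogram into k groups
#'
#' Removes the k-1 highest merges, partitioning the samples into k groups.
#'
#' @param result A `cluster_result` from [hca()].
#' @param k Number of groups, `1 <= k <= n`.
#' @return Named integer vector of group labels.
#' @export
cut_tree <- function(result, k) {
  stopifnot(inherits(result, "cluster_result"))
  n <- length(result$labels)
  if (k < 1L || k > n) stop("'k' must lie in 1..", n)
  stats::cutree(result$tree, k = k)
}

#' Export a clustered heatmap and the reordered matrix
#'
#' Writes a PNG heatmap of the standardized matrix with rows in dendrogram
#' leaf order, and the reordered matrix as CSV.
#'
#' @param z A `standardized_matrix`.
#' @param result A `cluster_result` for the same samples.
#' @param image_path Output PNG path.
#' @param matrix_path Output CSV path.
#' @return Invisibly, the leaf-ordered sample ids.
#' @export
export_heatmap <- function(z, result, image_path, matrix_path) {
  stopifnot(inherits(result, "cluster_result"))
  ord <- result$tree$order
  m <- unclass(z)[ord, , drop = FALSE]
  grDevices::png(image_path, width = 800, height = 600)
  op <- graphics::par(mar = c(8, 6, 2, 1))
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 1,
                 cex.axis = 0.8)
  graphics::par(op)
  grDevices::dev.off()
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, matrix_path, row.names = FALSE, quote = FALSE)
  invisible(rownames(m))
}
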