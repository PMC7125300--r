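#' Per-gene z-score normalisation
#'
#' Standardises each gene across the matrix columns:
#' `z_j = (x_j - mean(x_j)) / sd(x_j)` with the population standard
#' deviation, so every row has mean 0 and SD 1. Constant genes cannot be
#' standardised and are dropped with a warning.
#'
#' @param expr An `ExpressionMatrix` or a plain numeric matrix
#'   (genes x columns).
#' @param genes Optional gene subset.
#' @return Numeric matrix of z-scores; dropped constant genes are listed
#'   in attribute `"dropped"`.
#' @export
zscore_normalize <- function(expr, genes = NULL) {
  x <- if (inherits(expr, "ExpressionMatrix")) expr$values else as.matrix(expr)
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans((x - mu)^2))
  constant <- sdev == 0
  if (all(constant)) stop("all genes in the subset are constant")
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) dropped from z-scoring")
  }
  z <- (x[!constant, , drop = FALSE] - mu[!constant]) / sdev[!constant]
  attr(z, "dropped") <- rownames(x)[constant]
  z
}

#' Principal-component trajectory of samples through time
#'
#' Projects the samples (observations) of a z-scored genes x samples
#' matrix onto their first two principal axes via singular value
#' decomposition, averages the per-sample scores across replicates at each
#' time point, and reports the variance explained per component. Each
#' component's sign is fixed so that its loading vector has a positive
#' sum, removing the SVD sign ambiguity.
#'
#' @param expr An `ExpressionMatrix` (z-scored internally by default) or a
#'   numeric genes x samples matrix accompanied by `design`.
#' @param genes Optional gene subset defining the set whose trajectory is
#'   wanted; PCA is refit on the subset.
#' @param design Required when `expr` is a plain matrix: data frame with
#'   `sample_id`, `time_min`, `replicate`.
#' @param zscore Standardise genes first (default TRUE).
#' @return Object of class `PCTrajectory`: list with `trajectory`
#'   (data frame `time_min`, `pc1`, `pc2`), `variance_explained` (all
#'   components, sums to 1), and per-sample `scores`.
#' @export
pc_trajectory <- function(expr, genes = NULL, design = NULL, zscore = TRUE) {
  if (inherits(expr, "ExpressionMatrix")) {
    design <- expr$design
    x <- expr$values
  } else {
    x <- as.matrix(expr)
    if (is.null(design)) stop("design required for a plain matrix")
  }
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples")
  z <- if (zscore) zscore_normalize(x) else x

  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  flip <- colSums(pca$rotation) < 0
  pca$rotation[, flip] <- -pca$rotation[, flip]
  pca$x[, flip] <- -pca$x[, flip]
  ve <- pca$sdev^2 / sum(pca$sdev^2)

  scores <- data.frame(sample_id = colnames(z),
                       pc1 = pca$x[, 1],
                       pc2 = if (ncol(pca$x) >= 2) pca$x[, 2] else 0,
                       stringsAsFactors = FALSE)
  scores <- merge(scores, design, by = "sample_id", sort = FALSE)
  agg <- stats::aggregate(cbind(pc1, pc2) ~ time_min, data = scores, FUN = mean)
  agg <- agg[order(agg$time_min), ]
  rownames(agg) <- NULL

  structure(
    list(trajectory = agg, variance_explained = ve, scores = scores,
         pca = pca),
    class = "PCTrajectory"
  )
}

#' @export
print.PCTrajectory <- function(x, ...) {
  cat(sprintf("PCTrajectory: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$variance_explained[1],
              100 * x$variance_explained[2]))
  print(x$trajectory)
  invisible(x)
}

#' Temporal correlation curves per gene set
#'
#' [temporal_series()] restricted to each named gene set, for each
#' requested metric, stacked into one tidy table.
#'
#' @param expr An `ExpressionMatrix`.
#' @param gene_sets Named list of non-empty gene-id vectors.
#' @param metrics Metrics to compute (default all four).
#' @param bins,n_permutations,seed Histogram MI settings for `"mi_c"`.
#' @return Data frame `set`, `replicate`, `time_min`, `metric`, `value`.
#' @export
set_correlation_curves <- function(expr, gene_sets,
                                   metrics = c("pearson", "spearman",
                                               "bicor", "mi_c"),
                                   bins = 10, n_permutations = 100,
                                   seed = NULL) {
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be a named list")
  }
  if (any(lengths(gene_sets) == 0)) stop("empty gene set")
  out <- list()
  for (set_name in names(gene_sets)) {
    sub <- subset_genes(expr, gene_sets[[set_name]])
    for (m in metrics) {
      s <- temporal_series(sub, m, bins = bins,
                           n_permutations = n_permutations, seed = seed)
      s$set <- set_name
      out[[length(out) + 1]] <- s
    }
  }
  res <- do.call(rbind, out)
  res[, c("set", "replicate", "time_min", "metric", "value")]
}
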