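#' Rank genes by temporal variability
#'
#' Orders genes from the most to the least temporally variable on the
#' replicate-averaged time course. `"sd"` ranks by the (population)
#' standard deviation of expression across time points; `"fold_change"`
#' ranks by the maximum fold change between any two time points; `"rms"`
#' ranks by the root mean square of the raw expression values across time
#' (an amplitude-weighted variant). Ties are broken deterministically by
#' gene identifier.
#'
#' @param expr An `ExpressionMatrix` with at least 2 time points.
#' @param mode `"sd"` (default), `"fold_change"` or `"rms"`.
#' @param pseudocount Added to replicate-averaged expression before fold
#'   ratios (guards zero expression; default 0.5).
#' @return Character vector of gene identifiers, most variable first.
#' @export
rank_genes <- function(expr, mode = c("sd", "fold_change", "rms"),
                       pseudocount = 0.5) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  mode <- match.arg(mode)
  tc <- time_course_matrix(expr)
  if (ncol(tc) < 2) stop("need at least 2 time points")
  stat <- switch(mode,
    sd = sqrt(rowMeans((tc - rowMeans(tc))^2)),
    fold_change = (apply(tc, 1, max) + pseudocount) /
      (apply(tc, 1, min) + pseudocount),
    rms = sqrt(rowMeans(tc^2)))
  expr$gene_ids[order(-stat, expr$gene_ids)]
}

#' Partition ranked genes into transcriptomic elements
#'
#' Splits the ranking into `p = ceiling(N/n)` consecutive blocks of `n`
#' genes. When `n` does not divide `N`, the final block takes the last `n`
#' genes of the ranking and therefore overlaps the previous block.
#'
#' @param ordering Ranked character vector of gene identifiers.
#' @param n Element size (default 100), at most `length(ordering)`.
#' @return Object of class `ElementPartition`: list with `ordering`, `n`,
#'   and `elements` (list of gene-id blocks in rank order).
#' @export
partition_elements <- function(ordering, n = 100) {
  N <- length(ordering)
  if (n > N) stop("element size exceeds the number of genes")
  p <- ceiling(N / n)
  elements <- vector("list", p)
  for (k in seq_len(p)) {
    idx <- if (k < p) ((k - 1) * n + 1):(k * n) else (N - n + 1):N
    elements[[k]] <- ordering[idx]
  }
  structure(list(ordering = ordering, n = n, elements = elements),
            class = "ElementPartition")
}

#' @export
print.ElementPartition <- function(x, ...) {
  cat(sprintf("ElementPartition: %d elements of %d genes (N = %d)\n",
              length(x$elements), x$n, length(x$ordering)))
  invisible(x)
}

#' (R_v, MI_v) trajectories of all transcriptomic elements
#'
#' For every element, the replicate-averaged deviation-correlation
#' trajectory against t = 0.
#'
#' @param partition An [partition_elements()] result.
#' @param expr The `ExpressionMatrix` the partition was built from.
#' @param bins,n_permutations Histogram MI settings.
#' @param seed Integer seed for the MI permutation draws.
#' @return List of data frames (`time_min`, `rv`, `miv`), one per element.
#' @export
element_trajectories <- function(partition, expr, bins = 10,
                                 n_permutations = 100, seed = NULL) {
  stopifnot(inherits(partition, "ElementPartition"))
  if (partition$n < bins) {
    stop("element size is smaller than the MI bin count")
  }
  devs <- lapply(replicates(expr), function(r) deviation_matrix(expr, r))
  with_seed(seed, {
    lapply(partition$elements, function(genes) {
      idx <- match(genes, expr$gene_ids)
      if (anyNA(idx)) stop("partition genes not present in matrix")
      .trajectory_from_devs(devs, idx, bins, n_permutations)
    })
  })
}

#' Classify transcriptomic elements against the attractor basin
#'
#' Each element is labelled by its trajectory endpoint: inside the closed
#' boundary is `in_basin`; outside the boundary on the high-dependence
#' side of the density peak (endpoint MI_v above the peak's MI_v) is
#' `above_basin`; otherwise `below_basin`. Every element also gets the mean pointwise Euclidean
#' distance between its trajectory and the whole-transcriptome trajectory.
#' Below-basin elements closer than the mean distance are pseudo-attractor
#' candidates: their merged gene set is confirmed as pseudo-attractor only
#' if its own trajectory endpoint enters the basin.
#'
#' The attractor gene set is the union of above- and in-basin elements;
#' confirmed pseudo-attractor genes form the second set and everything
#' else is non-attractor. The three sets are disjoint and cover all genes.
#'
#' @param trajectories [element_trajectories()] result.
#' @param boundary [attractor_boundary()] result.
#' @param whole_traj [whole_trajectory()] data frame on the same time grid.
#' @param partition The [partition_elements()] the trajectories came from
#'   (needed for gene membership and the merged-candidate confirmation).
#' @param expr The `ExpressionMatrix`; required to evaluate the merged
#'   candidate trajectory.
#' @param bins,n_permutations,seed Histogram MI settings for the merged
#'   trajectory.
#' @param endpoint `"last"` (default) classifies on the final time point;
#'   `"last2"` requires the last two points inside for `in_basin`.
#' @return Object of class `ClassificationResult`: list with
#'   `element_labels`, `element_distances`, `pseudo_candidates` (element
#'   indices), `merged_in_basin` flag, `merged_trajectory`, and
#'   `gene_sets` (`attractor`, `pseudo_attractor`, `non_attractor`).
#' @export
classify_elements <- function(trajectories, boundary, whole_traj,
                              partition, expr,
                              bins = 10, n_permutations = 100, seed = NULL,
                              endpoint = c("last", "last2")) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(boundary, "AttractorBoundary"),
            inherits(partition, "ElementPartition"))
  top_miv <- boundary$peak["y"]
  p <- length(trajectories)

  in_basin_at <- function(tr, row) {
    point_in_basin(c(tr$rv[row], tr$miv[row]), boundary)
  }
  labels <- character(p)
  for (k in seq_len(p)) {
    tr <- trajectories[[k]]
    last <- nrow(tr)
    inside <- in_basin_at(tr, last)
    if (endpoint == "last2" && last > 1) {
      inside <- inside && in_basin_at(tr, last - 1)
    }
    if (inside) {
      labels[k] <- "in_basin"
    } else if (tr$miv[last] > top_miv) {
      labels[k] <- "above_basin"
    } else {
      labels[k] <- "below_basin"
    }
  }

  dists <- vapply(seq_len(p), function(k) {
    tr <- trajectories[[k]]
    mean(sqrt((tr$rv - whole_traj$rv)^2 + (tr$miv - whole_traj$miv)^2))
  }, numeric(1))

  core_idx <- which(labels %in% c("above_basin", "in_basin"))
  candidates <- which(labels == "below_basin" & dists < mean(dists))

  attractor <- unique(unlist(partition$elements[core_idx]))
  merged_in_basin <- FALSE
  merged_traj <- NULL
  pseudo <- character(0)
  if (length(candidates)) {
    cand_genes <- setdiff(unique(unlist(partition$elements[candidates])),
                          attractor)
    if (length(cand_genes) >= bins) {
      merged_traj <- correlation_trajectory(expr, cand_genes, bins = bins,
                                            n_permutations = n_permutations,
                                            seed = seed)
      last <- nrow(merged_traj)
      merged_in_basin <- point_in_basin(
        c(merged_traj$rv[last], merged_traj$miv[last]), boundary)
      if (merged_in_basin) pseudo <- cand_genes
    }
  }
  all_genes <- unique(unlist(partition$elements))
  non_attractor <- setdiff(all_genes, c(attractor, pseudo))

  structure(
    list(element_labels = labels, element_distances = dists,
         pseudo_candidates = candidates,
         merged_in_basin = merged_in_basin,
         merged_trajectory = merged_traj,
         gene_sets = list(attractor = attractor,
                          pseudo_attractor = pseudo,
                          non_attractor = non_attractor)),
    class = "ClassificationResult"
  )
}

#' @export
print.ClassificationResult <- function(x, ...) {
  tab <- table(factor(x$element_labels,
                      levels = c("above_basin", "in_basin", "below_basin")))
  cat("ClassificationResult:\n")
  cat(sprintf("  elements: %d above, %d in, %d below the basin\n",
              tab["above_basin"], tab["in_basin"], tab["below_basin"]))
  cat(sprintf("  genes: %d attractor, %d pseudo-attractor, %d non-attractor\n",
              length(x$gene_sets$attractor),
              length(x$gene_sets$pseudo_attractor),
              length(x$gene_sets$non_attractor)))
  invisible(x)
}

#' Genes with no temporal response
#'
#' Returns the genes whose maximum fold change between any two time points
#' (replicate-averaged) stays below the threshold; the canonical cut-off
#' of 1.12 separates flat genes from even weakly responding ones.
#'
#' @param expr An `ExpressionMatrix`.
#' @param genes Gene identifiers to screen (defaults to all).
#' @param fold_threshold Maximum fold change below which a gene counts as
#'   non-responding (default 1.12).
#' @param pseudocount Added before ratios (default 0.5).
#' @return Character vector of no-response gene identifiers.
#' @export
no_response_genes <- function(expr, genes = expr$gene_ids,
                              fold_threshold = 1.12, pseudocount = 0.5) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  tc <- time_course_matrix(subset_genes(expr, genes))
  fold <- (apply(tc, 1, max) + pseudocount) /
    (apply(tc, 1, min) + pseudocount)
  genes[fold < fold_threshold]
}
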