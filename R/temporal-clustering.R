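#' Ward clustering of temporal profiles
#'
#' Agglomerative hierarchical clustering with Ward linkage on Euclidean
#' distance of the (z-scored, replicate-averaged) temporal profiles, cut
#' at `k` clusters.
#'
#' @param z Numeric matrix, genes x time, typically z-scored rows.
#' @param k Number of clusters, between 1 and the gene count.
#' @return Named integer vector gene -> cluster id, with the `hclust` tree
#'   in attribute `"hclust"`.
#' @export
ward_cluster <- function(z, k) {
  z <- as.matrix(z)
  if (k < 1 || k > nrow(z)) stop("k must be between 1 and the gene count")
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  names(cl) <- rownames(z)
  attr(cl, "hclust") <- hc
  cl
}

#' Refine clusters into coherent temporal groups
#'
#' Starting from an initial clustering, iteratively (i) merges groups
#' whose mean temporal profiles correlate at or above the threshold,
#' (ii) re-assigns genes correlating below the threshold with their own
#' group mean to the best-matching existing group, and (iii) pools
#' remaining misfits and re-clusters them into new groups. Iteration stops
#' at a fixed point or after `max_iter` passes (with a warning flag).
#'
#' @param clusters Named gene -> cluster vector from [ward_cluster()].
#' @param z The genes x time matrix the clustering was built on.
#' @param r_threshold Pearson correlation threshold a gene must reach with
#'   its group's mean profile (default 0.7).
#' @param max_iter Iteration cap (default 10).
#' @return Object of class `TemporalGrouping`: list with `groups` (named
#'   gene -> group id), `group_profiles` (mean profile per group),
#'   `refinement_threshold`, `iterations`, `converged`.
#' @export
refine_groups <- function(clusters, z, r_threshold = 0.7, max_iter = 10) {
  z <- as.matrix(z)
  genes <- names(clusters)
  if (is.null(genes) || !all(genes %in% rownames(z))) {
    stop("clusters must be named with genes present in z")
  }
  membership <- as.integer(clusters)
  names(membership) <- genes

  group_means <- function(memb) {
    ids <- sort(unique(memb))
    m <- t(vapply(ids, function(g) {
      colMeans(z[names(memb)[memb == g], , drop = FALSE])
    }, numeric(ncol(z))))
    rownames(m) <- ids
    m
  }
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }

  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    changed <- FALSE

    # merge groups whose mean profiles are mutually coherent
    repeat {
      ids <- sort(unique(membership))
      if (length(ids) < 2) break
      means <- group_means(membership)
      best <- c(NA, NA); best_r <- r_threshold
      for (a in seq_along(ids)[-length(ids)]) {
        for (b in (a + 1):length(ids)) {
          r <- safe_cor(means[a, ], means[b, ])
          if (r >= best_r) {
            best_r <- r
            best <- c(ids[a], ids[b])
          }
        }
      }
      if (is.na(best[1])) break
      membership[membership == best[2]] <- best[1]
      changed <- TRUE
    }

    # re-assign misfit genes
    means <- group_means(membership)
    ids <- as.integer(rownames(means))
    r_own <- vapply(genes, function(g) {
      safe_cor(z[g, ], means[as.character(membership[g]), ])
    }, numeric(1))
    misfits <- genes[r_own < r_threshold]
    pool <- character(0)
    for (g in misfits) {
      rs <- vapply(seq_along(ids), function(a) safe_cor(z[g, ], means[a, ]),
                   numeric(1))
      if (max(rs) >= r_threshold) {
        target <- ids[which.max(rs)]
        if (target != membership[g]) {
          membership[g] <- target
          changed <- TRUE
        }
      } else {
        pool <- c(pool, g)
      }
    }

    # misfits that match no existing group form new groups
    if (length(pool)) {
      next_id <- max(membership) + 1L
      if (length(pool) == 1) {
        membership[pool] <- next_id
      } else {
        sub <- z[pool, , drop = FALSE]
        hc <- stats::hclust(stats::dist(sub), method = "ward.D2")
        k_new <- 1
        repeat {
          cl_new <- stats::cutree(hc, k = k_new)
          means_new <- t(vapply(seq_len(k_new), function(g) {
            colMeans(sub[cl_new == g, , drop = FALSE])
          }, numeric(ncol(sub))))
          ok <- all(vapply(seq_along(pool), function(i) {
            safe_cor(sub[i, ], means_new[cl_new[i], ]) >= r_threshold
          }, logical(1)))
          if (ok || k_new >= min(5, length(pool))) break
          k_new <- k_new + 1
        }
        membership[pool] <- next_id + cl_new - 1L
      }
      changed <- TRUE
    }

    if (!changed) {
      converged <- TRUE
      break
    }
  }

  # relabel groups 1..G in size order
  sizes <- sort(table(membership), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  membership <- relabel[as.character(membership)]
  names(membership) <- genes
  profiles <- group_means(membership)

  structure(
    list(groups = membership, group_profiles = profiles,
         refinement_threshold = r_threshold,
         iterations = iter, converged = converged),
    class = "TemporalGrouping"
  )
}

#' @export
print.TemporalGrouping <- function(x, ...) {
  cat(sprintf("TemporalGrouping: %d groups after %d iteration(s)%s\n",
              length(unique(x$groups)), x$iterations,
              if (x$converged) "" else " (iteration cap reached)"))
  print(table(x$groups))
  invisible(x)
}

#' Stringent expression/fold filter
#'
#' Keeps genes whose replicate-averaged expression exceeds `tpm_min` at
#' some time point AND whose maximum fold change between any two time
#' points reaches `fold_min`.
#'
#' @param expr An `ExpressionMatrix` in TPM.
#' @param genes Gene set to screen (defaults to all).
#' @param tpm_min Peak-expression threshold (default 500 TPM).
#' @param fold_min Minimum max fold change (default 3).
#' @param pseudocount Added before ratios (default 0.5).
#' @return Character vector of surviving gene identifiers.
#' @export
stringent_filter <- function(expr, genes = expr$gene_ids, tpm_min = 500,
                             fold_min = 3, pseudocount = 0.5) {
  tc <- time_course_matrix(subset_genes(expr, genes))
  peak <- apply(tc, 1, max)
  fold <- (peak + pseudocount) / (apply(tc, 1, min) + pseudocount)
  genes[peak > tpm_min & fold >= fold_min]
}

#' Genes changing more than a fold threshold
#'
#' The conventional differential-expression selection: genes whose maximum
#' fold change between any two time points (replicate-averaged) exceeds
#' `fold_min`.
#'
#' @param expr An `ExpressionMatrix` with at least 2 time points.
#' @param fold_min Fold-change threshold (default 2, strict inequality).
#' @param genes Gene set to screen (defaults to all).
#' @param pseudocount Added before ratios (default 0.5).
#' @return Character vector of gene identifiers.
#' @export
fold_change_set <- function(expr, fold_min = 2, genes = expr$gene_ids,
                            pseudocount = 0.5) {
  tc <- time_course_matrix(subset_genes(expr, genes))
  if (ncol(tc) < 2) stop("need at least 2 time points")
  fold <- (apply(tc, 1, max) + pseudocount) /
    (apply(tc, 1, min) + pseudocount)
  genes[fold > fold_min]
}

#' Compare two gene sets
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @return List with `common`, `a_only`, `b_only` and a named `counts`
#'   vector.
#' @export
compare_sets <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  common <- intersect(set_a, set_b)
  list(common = common,
       a_only = setdiff(set_a, set_b),
       b_only = setdiff(set_b, set_a),
       counts = c(common = length(common),
                  a_only = length(set_a) - length(common),
                  b_only = length(set_b) - length(common)))
}
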