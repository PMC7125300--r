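#' Deviation-from-temporal-average matrix for one replicate
#'
#' For each gene, subtracts its mean expression over the replicate's time
#' points: `v_j(t_i) = x_j(t_i) - mean_t x_j`. Rows therefore sum to zero.
#'
#' @param expr An `ExpressionMatrix`.
#' @param replicate Replicate label present in the design.
#' @return Object of class `DeviationMatrix`: list with `values`
#'   (genes x time), `gene_ids`, `time_points`, `replicate`.
#' @export
deviation_matrix <- function(expr, replicate) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!replicate %in% expr$design$replicate) {
    stop("replicate not in design: ", replicate)
  }
  des <- expr$design[expr$design$replicate == replicate, , drop = FALSE]
  des <- des[order(des$time_min), , drop = FALSE]
  if (nrow(des) < 2) stop("need at least 2 time points for a replicate")
  x <- expr$values[, des$sample_id, drop = FALSE]
  v <- x - rowMeans(x)
  colnames(v) <- des$time_min
  structure(
    list(values = v, gene_ids = expr$gene_ids,
         time_points = des$time_min, replicate = replicate),
    class = "DeviationMatrix"
  )
}

#' Cosine correlation of two deviation vectors
#'
#' `r_v(V(t_i), V(t_0)) = V(t_i) . V(t_0) / (|V(t_i)| |V(t_0)|)`: the
#' temporal correlation of genome-wide expression deviations from their
#' per-gene averages, insensitive to amplification differences between
#' genes with similar temporal profiles.
#'
#' @param v_ti,v_t0 Numeric deviation vectors of equal length, both with
#'   non-zero norm.
#' @return A value in `[-1, 1]`.
#' @export
rv <- function(v_ti, v_t0) {
  if (length(v_ti) != length(v_t0)) stop("vectors must have equal length")
  n1 <- sqrt(sum(v_ti^2))
  n0 <- sqrt(sum(v_t0^2))
  if (n1 == 0 || n0 == 0) stop("zero-norm deviation vector")
  sum(v_ti * v_t0) / (n1 * n0)
}

#' Normalised mutual information of two deviation vectors
#'
#' The bias-corrected histogram MI between the deviation vectors at `t_i`
#' and `t_0`, normalised by the corrected self-information of `V(t_0)`:
#' `MI_v = MI(V(t_i), V(t_0)) / MI(V(t_0), V(t_0))`, so that the value at
#' the reference time is exactly 1 and replicates are comparable.
#'
#' @inheritParams rv
#' @param K Number of histogram bins (default 10).
#' @param n_permutations Permutations for the bias term (default 100).
#' @param seed Optional integer seed; `NULL` uses the current stream.
#' @return Non-negative MI ratio.
#' @export
miv <- function(v_ti, v_t0, K = 10, n_permutations = 100, seed = NULL) {
  num <- estimate_mi(v_ti, v_t0, K = K, n_permutations = n_permutations,
                     seed = seed)$corrected_mi
  den <- estimate_mi(v_t0, v_t0, K = K, n_permutations = n_permutations,
                     seed = seed)$corrected_mi
  if (den <= 0) stop("self-information of the reference vector is zero")
  num / den
}

# (rv, miv) trajectory of a gene index set: per replicate against the
# replicate's t0, then averaged across replicates. `devs` is a list of
# DeviationMatrix, one per replicate.
.trajectory_from_devs <- function(devs, idx, K, n_permutations) {
  tps <- devs[[1]]$time_points
  acc_rv <- matrix(0, length(devs), length(tps))
  acc_miv <- matrix(0, length(devs), length(tps))
  for (r in seq_along(devs)) {
    v <- devs[[r]]$values[idx, , drop = FALSE]
    v0 <- v[, 1]
    b0 <- rank_bins(v0, K)
    mi_self <- mi_from_bins(b0, b0, K)
    perm_self <- vapply(seq_len(n_permutations), function(i) {
      mi_from_bins(b0, b0[sample.int(length(b0))], K)
    }, numeric(1))
    den <- max(mi_self - min(perm_self), 0)
    if (den <= 0) stop("degenerate element: zero self-information at t0")
    for (ti in seq_along(tps)) {
      vt <- v[, ti]
      acc_rv[r, ti] <- rv(vt, v0)
      if (ti == 1) {
        acc_miv[r, ti] <- 1
      } else {
        bt <- rank_bins(vt, K)
        raw <- mi_from_bins(bt, b0, K)
        perm <- vapply(seq_len(n_permutations), function(i) {
          mi_from_bins(bt, b0[sample.int(length(b0))], K)
        }, numeric(1))
        acc_miv[r, ti] <- max(raw - min(perm), 0) / den
      }
    }
  }
  data.frame(time_min = tps,
             rv = colMeans(acc_rv),
             miv = colMeans(acc_miv))
}

#' (R_v, MI_v) trajectory of a gene set
#'
#' Computes the deviation-based correlation pair against t = 0 at every
#' time point, per replicate, and averages the per-replicate trajectories.
#' Every trajectory starts at (1, 1).
#'
#' @param expr An `ExpressionMatrix`.
#' @param genes Character vector of gene identifiers (defaults to all).
#' @param bins,n_permutations Histogram MI settings.
#' @param seed Optional seed for the MI permutation draws.
#' @return Data frame with columns `time_min`, `rv`, `miv`.
#' @export
correlation_trajectory <- function(expr, genes = expr$gene_ids, bins = 10,
                                   n_permutations = 100, seed = NULL) {
  devs <- lapply(replicates(expr), function(r) deviation_matrix(expr, r))
  idx <- match(genes, expr$gene_ids)
  if (anyNA(idx)) stop("genes not present in matrix")
  with_seed(seed, .trajectory_from_devs(devs, idx, bins, n_permutations))
}

#' Ensemble distribution of (R_v, MI_v) for random gene sets
#'
#' Repeatedly draws `n` genes without replacement and computes the
#' replicate-averaged (R_v, MI_v) pair against t = 0 at every time point.
#' The spread of these ensembles over repeats locates the attractor region
#' and calibrates the transcriptomic element size.
#'
#' @param expr An `ExpressionMatrix`.
#' @param n Element size (genes per draw), at most the gene count.
#' @param repeats Number of random draws (default 100).
#' @param seed Integer seed controlling draws and MI permutations.
#' @param bins,n_permutations Histogram MI settings.
#' @return Object of class `EnsembleDistribution`: list with `n`,
#'   `repeats`, `time_points`, matrices `rv` and `miv`
#'   (repeats x time), their per-time standard deviations `rv_sd` and
#'   `miv_sd`, and `seed`.
#' @export
sample_ensembles <- function(expr, n, repeats = 100, seed = NULL,
                             bins = 10, n_permutations = 100) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  N <- nrow(expr$values)
  if (n > N) stop("element size exceeds gene count")
  devs <- lapply(replicates(expr), function(r) deviation_matrix(expr, r))
  tps <- devs[[1]]$time_points
  rv_m <- matrix(NA_real_, repeats, length(tps))
  miv_m <- matrix(NA_real_, repeats, length(tps))
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      idx <- sample.int(N, n)
      tr <- .trajectory_from_devs(devs, idx, bins, n_permutations)
      rv_m[rep_i, ] <- tr$rv
      miv_m[rep_i, ] <- tr$miv
    }
  })
  colnames(rv_m) <- colnames(miv_m) <- tps
  structure(
    list(n = n, repeats = repeats, time_points = tps,
         rv = rv_m, miv = miv_m,
         rv_sd = apply(rv_m, 2, stats::sd),
         miv_sd = apply(miv_m, 2, stats::sd),
         seed = seed),
    class = "EnsembleDistribution"
  )
}

#' Whole-transcriptome trajectory from an ensemble
#'
#' The mean over ensemble repeats of the per-time (R_v, MI_v) values -- the
#' average of many random-element trajectories, used as the reference
#' whole-transcriptome trajectory.
#'
#' @param ensemble A [sample_ensembles()] result.
#' @return Data frame `time_min`, `rv`, `miv`.
#' @export
whole_trajectory <- function(ensemble) {
  stopifnot(inherits(ensemble, "EnsembleDistribution"))
  data.frame(time_min = ensemble$time_points,
             rv = colMeans(ensemble$rv),
             miv = colMeans(ensemble$miv))
}

#' Law-of-large-numbers fit of ensemble spread
#'
#' Least-squares fit of `SD(n) = alpha / sqrt(n) + c` to the standard
#' deviation of an ensemble statistic as a function of element size.
#'
#' @param n Numeric vector of element sizes (at least 3 distinct values).
#' @param sd Standard deviations matching `n`.
#' @return List with `alpha`, `c`, `rmse` and the fitted values.
#' @export
lln_fit <- function(n, sd) {
  if (length(unique(n)) < 3) stop("need at least 3 distinct element sizes")
  if (length(n) != length(sd)) stop("n and sd must match")
  fit <- stats::lm(sd ~ I(1 / sqrt(n)))
  fitted <- unname(stats::fitted(fit))
  list(alpha = unname(stats::coef(fit)[2]),
       c = unname(stats::coef(fit)[1]),
       rmse = sqrt(mean(stats::residuals(fit)^2)),
       n = n, sd = sd, fitted = fitted)
}

#' Superimposed probability-density landscape on the (R_v, MI_v) plane
#'
#' Estimates a 2-D Gaussian kernel density of the ensemble points for each
#' time point on a shared lattice and superimposes (sums) them. The
#' reference time is excluded by default because every ensemble sits at
#' exactly (1, 1) there, which contributes only a degenerate spike.
#' Bandwidths follow the normal-reference rule per axis on the pooled
#' points, and the lattice spans the pooled range padded by three kernel
#' standard deviations.
#'
#' @param ensemble A [sample_ensembles()] result with at least 2 time
#'   points.
#' @param grid_size Lattice cells per axis (default 100).
#' @param bandwidth Optional length-2 numeric overriding the
#'   normal-reference bandwidths (on the [MASS::kde2d()] scale, i.e. the
#'   kernel standard deviation is `bandwidth/4`).
#' @param include_t0 Superimpose the degenerate reference-time cloud too.
#' @param min_peak_frac Local maxima below this fraction of the global
#'   maximum are not reported as peaks.
#' @return Object of class `DensityLandscape`: list with lattice axes `x`
#'   (R_v) and `y` (MI_v), density matrix `z`, `peaks` data frame, the
#'   `major_peak` row, `bandwidth`, `grid_size` and `times_used`.
#' @export
spd_landscape <- function(ensemble, grid_size = 100, bandwidth = NULL,
                          include_t0 = FALSE, min_peak_frac = 0.05) {
  stopifnot(inherits(ensemble, "EnsembleDistribution"))
  tps <- ensemble$time_points
  use <- if (include_t0) seq_along(tps) else which(tps != min(tps))
  if (length(use) < 2) stop("need at least 2 superimposed time points")
  px <- as.vector(ensemble$rv[, use])
  py <- as.vector(ensemble$miv[, use])
  if (stats::sd(px) == 0 && stats::sd(py) == 0) {
    stop("degenerate ensemble: all points identical")
  }
  nrd_safe <- function(v) {
    h <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
    if (!is.finite(h) || h <= 0) h <- 4 * 1.06 * stats::sd(v) * length(v)^(-1 / 5)
    if (!is.finite(h) || h <= 0) h <- 4 * 0.01 * max(1e-6, diff(range(v)))
    if (h <= 0) h <- 1e-3
    h
  }
  if (is.null(bandwidth)) {
    bandwidth <- c(nrd_safe(px), nrd_safe(py))
  }
  sdx <- bandwidth[1] / 4
  sdy <- bandwidth[2] / 4
  lims <- c(range(px) + c(-3, 3) * sdx, range(py) + c(-3, 3) * sdy)
  z <- matrix(0, grid_size, grid_size)
  for (ti in use) {
    d <- MASS::kde2d(ensemble$rv[, ti], ensemble$miv[, ti],
                     h = bandwidth, n = grid_size, lims = lims)
    z <- z + d$z
  }
  x <- seq(lims[1], lims[2], length.out = grid_size)
  y <- seq(lims[3], lims[4], length.out = grid_size)

  peaks <- .find_peaks(x, y, z, min_peak_frac)
  structure(
    list(x = x, y = y, z = z, peaks = peaks,
         major_peak = peaks[which.max(peaks$z), , drop = FALSE],
         bandwidth = bandwidth, grid_size = grid_size,
         times_used = tps[use]),
    class = "DensityLandscape"
  )
}

# 8-neighbour local maxima on the lattice above a z floor
.find_peaks <- function(x, y, z, min_peak_frac) {
  gi <- nrow(z); gj <- ncol(z)
  floor_z <- min_peak_frac * max(z)
  hits <- list()
  for (i in 2:(gi - 1)) {
    for (j in 2:(gj - 1)) {
      zc <- z[i, j]
      if (zc < floor_z) next
      nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (zc >= max(nb)) {
        hits[[length(hits) + 1]] <- data.frame(
          i = i, j = j, x = x[i], y = y[j], z = zc)
      }
    }
  }
  if (!length(hits)) {
    ij <- which(z == max(z), arr.ind = TRUE)[1, ]
    return(data.frame(i = ij[1], j = ij[2],
                      x = x[ij[1]], y = y[ij[2]], z = max(z)))
  }
  out <- do.call(rbind, hits)
  out[order(-out$z), , drop = FALSE]
}

#' Attractor-basin boundary of a density landscape
#'
#' From the major density peak, scans the lattice outward along the four
#' axis-aligned directions; the inflection point of each scan is where the
#' absolute density gradient is largest. The boundary z-level is the mean
#' density at those four inflection points, and the boundary itself is the
#' closed iso-contour at that level that encloses the major peak.
#'
#' @param landscape A [spd_landscape()] result.
#' @return Object of class `AttractorBoundary`: list with polygon vertices
#'   `x`, `y`, the contour `level`, the `peak` coordinates, and the
#'   `inflections` data frame (direction, position and z of each scan's
#'   inflection point).
#' @export
attractor_boundary <- function(landscape) {
  stopifnot(inherits(landscape, "DensityLandscape"))
  pk <- landscape$major_peak
  x <- landscape$x; y <- landscape$y; z <- landscape$z
  i0 <- pk$i; j0 <- pk$j

  scan_inflection <- function(vals, pos) {
    # vals: density along the ray leaving the peak; returns z midpoint at
    # the steepest drop
    if (length(vals) < 2) return(NULL)
    d <- abs(diff(vals))
    k <- which.max(d)
    list(z = (vals[k] + vals[k + 1]) / 2, at = (pos[k] + pos[k + 1]) / 2)
  }
  rays <- list(
    xplus = list(v = z[i0:nrow(z), j0], p = x[i0:nrow(z)], dir = "x+"),
    xminus = list(v = z[i0:1, j0], p = x[i0:1], dir = "x-"),
    yplus = list(v = z[i0, j0:ncol(z)], p = y[j0:ncol(z)], dir = "y+"),
    yminus = list(v = z[i0, j0:1], p = y[j0:1], dir = "y-")
  )
  infl <- lapply(rays, function(r) {
    res <- scan_inflection(r$v, r$p)
    if (is.null(res)) return(NULL)
    data.frame(direction = r$dir, at = res$at, z = res$z)
  })
  infl <- do.call(rbind, infl)
  level <- mean(infl$z)

  cls <- grDevices::contourLines(x, y, z, levels = level)
  if (!length(cls)) stop("no contour at the inflection level")
  eps_x <- diff(range(x)) * 1e-9
  eps_y <- diff(range(y)) * 1e-9
  closed <- vapply(cls, function(cl) {
    on_border <- any(cl$x <= min(x) + eps_x | cl$x >= max(x) - eps_x |
                       cl$y <= min(y) + eps_y | cl$y >= max(y) - eps_y)
    !on_border
  }, logical(1))
  contains <- vapply(cls, function(cl) {
    .pip_evenodd(pk$x, pk$y, cl$x, cl$y)
  }, logical(1))
  pick <- which(closed & contains)
  if (!length(pick)) {
    stop("degenerate landscape: no closed boundary contour encloses the peak")
  }
  cl <- cls[[pick[1]]]
  structure(
    list(x = cl$x, y = cl$y, level = level,
         peak = c(x = pk$x, y = pk$y), inflections = infl, closed = TRUE),
    class = "AttractorBoundary"
  )
}

# even-odd (ray casting) point-in-polygon
.pip_evenodd <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Is a point inside the attractor basin?
#'
#' Even-odd (ray casting) point-in-polygon test against the closed
#' boundary contour.
#'
#' @param point Numeric length-2 vector `(R_v, MI_v)`.
#' @param boundary An [attractor_boundary()] result.
#' @return Logical flag.
#' @export
point_in_basin <- function(point, boundary) {
  stopifnot(inherits(boundary, "AttractorBoundary"))
  if (!isTRUE(boundary$closed)) stop("boundary polyline is not closed")
  .pip_evenodd(point[1], point[2], boundary$x, boundary$y)
}
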