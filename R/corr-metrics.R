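#' Pairwise correlation between two expression vectors
#'
#' Three of the four temporal metrics used throughout the package:
#' Pearson's r, Spearman's rank correlation (average ranks for ties) and
#' the biweight midcorrelation (bicor), a median/mad-weighted robust
#' correlation. The mad in the bicor weights is the raw median absolute
#' deviation (no consistency constant), as is standard for bicor.
#'
#' @param x,y Numeric vectors of equal length (at least 3), finite values.
#' @param method `"pearson"`, `"spearman"` or `"bicor"`.
#' @return A single correlation value in `[-1, 1]`.
#' @export
corr <- function(x, y, method = c("pearson", "spearman", "bicor")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in input")
  }
  if (method %in% c("pearson", "spearman")) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero variance: ", method, " correlation undefined")
    }
    return(stats::cor(x, y, method = method))
  }
  sum(.bicor_normalize(x) * .bicor_normalize(y))
}

# median/mad biweight normalisation: weights w = (1 - u^2)^2 I(|u| < 1),
# u = (p - med)/(9 mad); returns the unit-norm weighted deviations
.bicor_normalize <- function(p) {
  med <- stats::median(p)
  m <- stats::mad(p, constant = 1)
  if (m == 0) stop("mad is zero: bicor undefined for this vector")
  u <- (p - med) / (9 * m)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  a <- (p - med) * w
  a / sqrt(sum(a^2))
}

# equal-frequency discretisation of ranks into K bins of size ceiling(n/K)
rank_bins <- function(x, K) {
  n <- length(x)
  b <- ceiling(rank(x, ties.method = "average") / ceiling(n / K))
  pmin.int(pmax.int(b, 1L), as.integer(K))
}

# histogram mutual information (nats) from two bin-index vectors
mi_from_bins <- function(bx, by, K) {
  n <- length(bx)
  pj <- tabulate((bx - 1L) * K + by, nbins = K * K) / n
  px <- tabulate(bx, nbins = K) / n
  py <- tabulate(by, nbins = K) / n
  ent <- function(p) {
    p <- p[p > 0]
    sum(p * log(p))
  }
  ent(pj) - ent(px) - ent(py)
}

#' Histogram mutual information with permutation bias correction
#'
#' Rank-transforms both vectors, discretises the ranks into `K`
#' equal-frequency bins, and computes the plug-in mutual information of the
#' K x K contingency table in nats. The systematic (discretisation) error
#' `epsilon` is estimated as the minimum raw MI over random permutations of
#' one vector and subtracted; the corrected value is floored at zero.
#'
#' @param x,y Numeric vectors of equal length.
#' @param K Number of bins (default 10).
#' @param n_permutations Number of random permutations for the bias term
#'   (default 100).
#' @param seed Optional integer seed for the permutations; `NULL` uses the
#'   current RNG stream.
#' @param epsilon_stat `"min"` (default) or `"mean"` over the permutation
#'   MI values.
#' @return Object of class `MIEstimate`: list with `raw_mi`, `epsilon`,
#'   `corrected_mi = max(raw_mi - epsilon, 0)`, `bins`, `n_permutations`
#'   and `seed`, all MI values in nats.
#' @export
estimate_mi <- function(x, y, K = 10, n_permutations = 100, seed = NULL,
                        epsilon_stat = c("min", "mean")) {
  epsilon_stat <- match.arg(epsilon_stat)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  if (n < K) {
    warning("fewer observations than bins; proceeding with occupied bins")
  }
  K <- as.integer(K)
  bx <- rank_bins(x, K)
  by <- rank_bins(y, K)
  raw <- mi_from_bins(bx, by, K)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      mi_from_bins(bx, by[sample.int(n)], K)
    }, numeric(1))
  })
  eps <- if (n_permutations > 0) {
    if (epsilon_stat == "min") min(perm) else mean(perm)
  } else 0
  structure(
    list(raw_mi = raw, epsilon = eps,
         corrected_mi = max(raw - eps, 0),
         bins = K, n_permutations = n_permutations, seed = seed),
    class = "MIEstimate"
  )
}

#' @export
print.MIEstimate <- function(x, ...) {
  cat(sprintf(
    "MIEstimate: raw = %.4f, epsilon = %.4f, corrected = %.4f nats (K = %d)\n",
    x$raw_mi, x$epsilon, x$corrected_mi, x$bins))
  invisible(x)
}

#' Map mutual information to a correlation scale
#'
#' `MI_c = sqrt(1 - exp(-2 MI))`, the MI of a bivariate Gaussian inverted
#' for its correlation magnitude; maps `[0, Inf)` MI monotonically onto
#' `[0, 1)`.
#'
#' @param mi An [estimate_mi()] result or a non-negative MI value in nats.
#' @return Value in `[0, 1]`.
#' @export
mi_correlation <- function(mi) {
  m <- if (inherits(mi, "MIEstimate")) mi$corrected_mi else as.numeric(mi)
  if (any(m < 0)) stop("mutual information must be non-negative")
  sqrt(1 - exp(-2 * m))
}

#' Transcriptome-wide temporal correlation series
#'
#' For every replicate and every time point, the chosen metric between the
#' expression vector at the reference time (t = 0) and the vector at that
#' time, across all genes. The value at the reference time is the metric's
#' self-correlation.
#'
#' @param expr An `ExpressionMatrix`; every replicate must have a t = 0
#'   sample.
#' @param metric `"pearson"`, `"spearman"`, `"bicor"` or `"mi_c"`.
#' @param bins,n_permutations,seed Passed to [estimate_mi()] for
#'   `metric = "mi_c"`.
#' @return Tidy data frame with columns `replicate`, `time_min`, `metric`,
#'   `value`.
#' @export
temporal_series <- function(expr, metric = c("pearson", "spearman",
                                             "bicor", "mi_c"),
                            bins = 10, n_permutations = 100, seed = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  metric <- match.arg(metric)
  tps <- time_points(expr)
  reps <- replicates(expr)
  rows <- list()
  for (rep in reps) {
    s0 <- sample_for(expr, 0, rep)
    if (is.na(s0)) stop("replicate ", rep, " has no t = 0 sample")
    x0 <- expr$values[, s0]
    for (tp in tps) {
      st <- sample_for(expr, tp, rep)
      if (is.na(st)) next
      xt <- expr$values[, st]
      val <- if (metric == "mi_c") {
        mi_correlation(estimate_mi(x0, xt, K = bins,
                                   n_permutations = n_permutations,
                                   seed = seed))
      } else {
        corr(x0, xt, method = metric)
      }
      rows[[length(rows) + 1]] <- data.frame(
        replicate = rep, time_min = tp, metric = metric, value = val,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
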