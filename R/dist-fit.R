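#' @name expression-distributions
#' @title Candidate expression-distribution families
#'
#' @description
#' Density, distribution and quantile functions for the three families not
#' shipped with base R, in the parameterisations standard in loss-model and
#' survival software: single-parameter Pareto with an explicit lower bound
#' `xmin`, the three-parameter Burr XII, and the log-logistic.
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param shape,shape1,shape2,scale,xmin Distribution parameters.
#' @param log,lower.tail Usual conventions of the d/p/q families.
NULL

#' @rdname expression-distributions
#' @export
dpareto <- function(x, shape, xmin = 1, log = FALSE) {
  d <- ifelse(x >= xmin & x > 0,
              log(shape) + shape * log(xmin) - (shape + 1) * log(x), -Inf)
  if (log) d else exp(d)
}

#' @rdname expression-distributions
#' @export
ppareto <- function(q, shape, xmin = 1, lower.tail = TRUE) {
  p <- ifelse(q < xmin, 0, 1 - (xmin / q)^shape)
  if (lower.tail) p else 1 - p
}

#' @rdname expression-distributions
#' @export
qpareto <- function(p, shape, xmin = 1) {
  xmin * (1 - p)^(-1 / shape)
}

#' @rdname expression-distributions
#' @export
dburr <- function(x, shape1, shape2, scale = 1, log = FALSE) {
  # Burr XII: f(x) = (k c / s) (x/s)^(c-1) [1 + (x/s)^c]^(-k-1)
  d <- ifelse(x > 0,
              log(shape1) + log(shape2) - log(scale) +
                (shape2 - 1) * (log(x) - log(scale)) -
                (shape1 + 1) * log1p((x / scale)^shape2),
              -Inf)
  if (log) d else exp(d)
}

#' @rdname expression-distributions
#' @export
pburr <- function(q, shape1, shape2, scale = 1, lower.tail = TRUE) {
  p <- ifelse(q <= 0, 0, 1 - (1 + (q / scale)^shape2)^(-shape1))
  if (lower.tail) p else 1 - p
}

#' @rdname expression-distributions
#' @export
qburr <- function(p, shape1, shape2, scale = 1) {
  scale * ((1 - p)^(-1 / shape1) - 1)^(1 / shape2)
}

#' @rdname expression-distributions
#' @export
dllogis <- function(x, shape, scale = 1, log = FALSE) {
  d <- ifelse(x > 0,
              log(shape) - log(scale) + (shape - 1) * (log(x) - log(scale)) -
                2 * log1p((x / scale)^shape),
              -Inf)
  if (log) d else exp(d)
}

#' @rdname expression-distributions
#' @export
pllogis <- function(q, shape, scale = 1, lower.tail = TRUE) {
  p <- ifelse(q <= 0, 0, 1 / (1 + (q / scale)^(-shape)))
  if (lower.tail) p else 1 - p
}

#' @rdname expression-distributions
#' @export
qllogis <- function(p, shape, scale = 1) {
  scale * (p / (1 - p))^(1 / shape)
}

.fit_families <- c("lognormal", "pareto", "burr", "loglogistic",
                   "weibull", "gamma")

#' Maximum-likelihood fit of one distribution family
#'
#' Fits a candidate family to a positive sample by maximum likelihood.
#' The lognormal, Weibull, gamma, log-logistic and Burr XII families are
#' fitted through numerical likelihood maximisation
#' (\pkg{fitdistrplus}); the Pareto shape has a closed-form MLE once its
#' lower bound is fixed, which defaults to the 5-TPM expression filter
#' threshold and is configurable via `pareto_xmin`.
#'
#' @param values Positive numeric sample, length at least 10.
#' @param family One of `"lognormal"`, `"pareto"`, `"burr"`,
#'   `"loglogistic"`, `"weibull"`, `"gamma"`.
#' @param pareto_xmin Fixed lower bound of the Pareto; all values must be
#'   at or above it.
#' @return Object of class `FitResult`: list with `family`, named `params`,
#'   `loglik`, `aic` (`2 k - 2 loglik`), `n` and `converged`.
#' @export
fit_distribution <- function(values, family = .fit_families,
                             pareto_xmin = 5) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("values must be finite and strictly positive")
  }
  n <- length(values)
  if (n < 10) stop("need at least 10 observations")

  if (family == "pareto") {
    if (any(values < pareto_xmin)) {
      stop("values below the fixed Pareto lower bound (pareto_xmin = ",
           pareto_xmin, ")")
    }
    shape <- n / sum(log(values / pareto_xmin))
    ll <- sum(dpareto(values, shape, pareto_xmin, log = TRUE))
    return(new_fit_result(family, c(shape = shape, xmin = pareto_xmin),
                          n_free = 1, loglik = ll, n = n, converged = TRUE))
  }

  lx <- log(values)
  fit <- switch(
    family,
    lognormal = fitdistrplus::fitdist(values, "lnorm"),
    weibull = fitdistrplus::fitdist(values, "weibull"),
    gamma = {
      m <- mean(values); v <- stats::var(values)
      fitdistrplus::fitdist(values, "gamma",
                            start = list(shape = m^2 / v, rate = m / v),
                            lower = c(1e-8, 1e-12))
    },
    loglogistic = fitdistrplus::fitdist(
      values, "llogis",
      start = list(shape = pi / (sqrt(3) * stats::sd(lx)),
                   scale = exp(stats::median(lx))),
      lower = c(1e-6, 1e-12)),
    burr = fitdistrplus::fitdist(
      values, "burr",
      start = list(shape1 = 1,
                   shape2 = pi / (sqrt(3) * stats::sd(lx)),
                   scale = exp(stats::median(lx))),
      lower = c(1e-4, 1e-4, 1e-12))
  )
  params <- fit$estimate
  new_fit_result(family, params, n_free = length(params),
                 loglik = fit$loglik, n = n,
                 converged = is.null(fit$convergence) || fit$convergence == 0)
}

new_fit_result <- function(family, params, n_free, loglik, n, converged) {
  structure(
    list(family = family, params = params, n_free_params = n_free,
         loglik = loglik, aic = 2 * n_free - 2 * loglik,
         n = n, converged = converged),
    class = "FitResult"
  )
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult [%s]: loglik = %.2f, AIC = %.2f, n = %d%s\n",
              x$family, x$loglik, x$aic, x$n,
              if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}

#' Rank distribution families by AIC
#'
#' Fits each requested family and returns the successful fits sorted by
#' ascending AIC, ties broken in favour of fewer free parameters. A family
#' whose fit fails is reported in `failures` and does not abort the
#' comparison as long as at least one family succeeds.
#'
#' @inheritParams fit_distribution
#' @param families Character vector of families to compare.
#' @return Object of class `FamilyComparison`: list with `results` (ranked
#'   `FitResult`s), `best` (name of the top family) and `failures` (named
#'   character vector of error messages).
#' @export
compare_families <- function(values, families = .fit_families,
                             pareto_xmin = 5) {
  if (length(families) < 1) stop("need at least one family")
  fits <- list()
  failures <- character(0)
  for (fam in families) {
    res <- tryCatch(fit_distribution(values, fam, pareto_xmin = pareto_xmin),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[fam] <- conditionMessage(res)
    } else {
      fits[[fam]] <- res
    }
  }
  if (!length(fits)) {
    stop("all families failed to fit; first error: ", failures[1])
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(fits, `[[`, numeric(1), "n_free_params")
  ord <- order(aics, npar)
  structure(
    list(results = fits[ord], best = names(fits)[ord][1],
         failures = failures),
    class = "FamilyComparison"
  )
}

#' @export
print.FamilyComparison <- function(x, ...) {
  cat("AIC ranking:\n")
  for (r in x$results) {
    cat(sprintf("  %-12s AIC = %.2f\n", r$family, r$aic))
  }
  if (length(x$failures)) {
    cat("failed: ", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

.qfun_for <- function(fit) {
  p <- as.list(fit$params)
  switch(fit$family,
         lognormal = function(q) stats::qlnorm(q, p$meanlog, p$sdlog),
         weibull = function(q) stats::qweibull(q, p$shape, p$scale),
         gamma = function(q) stats::qgamma(q, p$shape, p$rate),
         loglogistic = function(q) qllogis(q, p$shape, p$scale),
         burr = function(q) qburr(q, p$shape1, p$shape2, p$scale),
         pareto = function(q) qpareto(q, p$shape, p$xmin),
         stop("unknown family in fit"))
}

#' Quantile-quantile pairs against a fitted distribution
#'
#' Pairs the sorted sample with the fitted distribution's quantiles at the
#' plotting positions `(i - 0.5)/n`.
#'
#' @param values Positive numeric sample.
#' @param fit A converged [fit_distribution()] result.
#' @return Data frame with sorted `theoretical` and `empirical` columns,
#'   one row per observation.
#' @export
qq_points <- function(values, fit) {
  stopifnot(inherits(fit, "FitResult"))
  if (!fit$converged) stop("fit did not converge")
  n <- length(values)
  pp <- (seq_len(n) - 0.5) / n
  data.frame(theoretical = .qfun_for(fit)(pp),
             empirical = sort(as.numeric(values)))
}
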