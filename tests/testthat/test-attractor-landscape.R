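test_that("deviation matrices are row-centred and linear", {
  m <- toy_expr(matrix(c(2, 4, 6,
                         5, 5, 5,
                         1, 2, 9), 3, byrow = TRUE),
                time_points = c(0, 1, 2))
  d <- deviation_matrix(m, "a")
  expect_equal(unname(d$values[1, ]), c(-2, 0, 2))
  expect_equal(unname(d$values[2, ]), c(0, 0, 0))
  expect_lt(max(abs(rowSums(d$values))), 1e-9)
  # doubling expression doubles the deviations
  m2 <- toy_expr(2 * m$values, time_points = c(0, 1, 2))
  d2 <- deviation_matrix(m2, "a")
  expect_equal(d2$values, 2 * d$values)
  expect_error(deviation_matrix(m, "z"), "replicate")
})

test_that("rv is the cosine of deviation vectors", {
  v <- c(1, -2, 3, -2)
  expect_equal(rv(v, v), 1)
  expect_equal(rv(v, -v), -1)
  expect_equal(rv(c(1, 0, 0, 0), c(0, 1, 0, 0)), 0)
  expect_error(rv(v, rep(0, 4)), "zero-norm")
})

test_that("miv is 1 at the reference, rank-invariant, and near 0 on noise", {
  set.seed(11)
  v0 <- rnorm(1000)
  expect_equal(miv(v0, v0, seed = 1), 1)
  expect_equal(miv(3 * v0, v0, seed = 1), 1)     # monotone transform
  nulls <- replicate(20, miv(sample(v0), v0))
  expect_lt(mean(nulls), 0.05)
})

test_that("gene-set trajectories start at (1, 1)", {
  set.seed(12)
  profiles <- matrix(rlnorm(200 * 4, 3, 1), 200, 4,
                     dimnames = list(sprintf("g%03d", 1:200), c(0, 1, 2, 5)))
  expr <- toy_timecourse(profiles, n_replicates = 2, cv = 0.1)
  tr <- correlation_trajectory(expr, seed = 1)
  expect_equal(tr$rv[1], 1)
  expect_equal(tr$miv[1], 1)
})

test_that("ensemble spread shrinks with element size and is seeded", {
  cfg <- synthetic_config(n_genes = 600, seed = 21)
  sim <- generate_timecourse(cfg)
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  expr <- remove_top_expressed(filter_low_expression(tpm, 5), 2)
  e25 <- sample_ensembles(expr, 25, repeats = 40, seed = 5)
  e100 <- sample_ensembles(expr, 100, repeats = 40, seed = 5)
  # smaller spread for bigger elements at every post-reference time
  expect_true(all(e100$rv_sd[-1] < e25$rv_sd[-1]))
  expect_true(all(e100$miv_sd[-1] < e25$miv_sd[-1]))
  # exhaustive draw: every repeat identical, SD zero
  eAll <- sample_ensembles(expr, nrow(expr$values), repeats = 5, seed = 5)
  expect_equal(unname(eAll$rv_sd), rep(0, length(eAll$rv_sd)))
  # bit-identical under a fixed seed
  e100b <- sample_ensembles(expr, 100, repeats = 40, seed = 5)
  expect_identical(e100$rv, e100b$rv)
  expect_error(sample_ensembles(expr, 10 * nrow(expr$values)), "exceeds")
})

test_that("lln_fit recovers a noiseless alpha/sqrt(n) + c law", {
  n <- c(25, 50, 100, 200, 400, 800)
  f <- lln_fit(n, 2 / sqrt(n) + 0.1)
  expect_equal(f$alpha, 2, tolerance = 1e-9)
  expect_equal(f$c, 0.1, tolerance = 1e-9)
  expect_lt(f$rmse, 1e-9)
  expect_true(all(diff(f$fitted) < 0))
  expect_error(lln_fit(c(10, 20), c(1, 2)), "at least 3")
})

test_that("SDs of iid means fit the LLN law with negligible offset", {
  set.seed(22)
  sizes <- c(25, 50, 100, 200, 400, 800)
  sds <- vapply(sizes, function(n) {
    sd(replicate(300, mean(rnorm(n))))
  }, numeric(1))
  f <- lln_fit(sizes, sds)
  se_c <- summary(lm(sds ~ I(1 / sqrt(sizes))))$coefficients[1, 2]
  expect_lt(abs(f$c), 2 * se_c)
})

# synthetic EnsembleDistribution with Gaussian clouds per time point
fake_ensemble <- function(centres, sd = 0.03, repeats = 150, seed = 1) {
  set.seed(seed)
  tps <- seq(0, by = 1, length.out = nrow(centres) + 1)
  rv <- cbind(1, sapply(seq_len(nrow(centres)), function(i) {
    rnorm(repeats, centres[i, 1], sd)
  }))
  miv <- cbind(1, sapply(seq_len(nrow(centres)), function(i) {
    rnorm(repeats, centres[i, 2], sd)
  }))
  colnames(rv) <- colnames(miv) <- tps
  structure(list(n = 100, repeats = repeats, time_points = tps,
                 rv = rv, miv = miv,
                 rv_sd = apply(rv, 2, sd), miv_sd = apply(miv, 2, sd),
                 seed = seed),
            class = "EnsembleDistribution")
}

test_that("the SPD landscape finds one or two peaks as planted", {
  one <- fake_ensemble(matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 3, 2,
                              byrow = TRUE))
  l1 <- spd_landscape(one)
  expect_equal(nrow(l1$peaks), 1L)
  expect_lt(abs(l1$major_peak$x - 0.5), 0.02)
  expect_lt(abs(l1$major_peak$y - 0.5), 0.02)
  two <- fake_ensemble(matrix(c(0.2, 0.2, 0.2, 0.2,
                                0.8, 0.8, 0.8, 0.8), 4, 2, byrow = TRUE))
  l2 <- spd_landscape(two)
  expect_equal(nrow(l2$peaks), 2L)
  # total lattice mass ~ number of superimposed time points
  cell <- diff(l1$x[1:2]) * diff(l1$y[1:2])
  expect_lt(abs(sum(l1$z) * cell - length(l1$times_used)),
            0.02 * length(l1$times_used))
})

test_that("the boundary sits at the Gaussian inflection radius", {
  # analytic isotropic Gaussian density on a lattice
  sigma <- 0.1
  x <- seq(-0.5, 0.5, length.out = 201)
  z <- outer(x, x, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  ls <- structure(list(x = x, y = x, z = z,
                       peaks = data.frame(i = 101, j = 101, x = 0, y = 0,
                                          z = 1),
                       major_peak = data.frame(i = 101, j = 101, x = 0,
                                               y = 0, z = 1),
                       bandwidth = c(4 * sigma, 4 * sigma), grid_size = 201,
                       times_used = 1),
                  class = "DensityLandscape")
  b <- attractor_boundary(ls)
  expect_equal(b$level, exp(-0.5), tolerance = 0.05)
  radii <- sqrt(b$x^2 + b$y^2)
  cell <- diff(x[1:2])
  expect_lt(max(abs(radii - sigma)), sigma * 0.1 + cell)
  # the boundary encloses the peak
  expect_true(point_in_basin(c(0, 0), b))
  expect_false(point_in_basin(c(0.45, 0.45), b))
})

test_that("shrinking the KDE bandwidth shrinks the enclosed basin", {
  e <- fake_ensemble(matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 3, 2,
                            byrow = TRUE), sd = 0.05)
  area <- vapply(c(0.4, 0.25, 0.15), function(h) {
    b <- attractor_boundary(spd_landscape(e, bandwidth = c(h, h)))
    # shoelace area of the boundary polygon
    n <- length(b$x)
    abs(sum(b$x * c(b$y[-1], b$y[1]) - c(b$x[-1], b$x[1]) * b$y)) / 2
  }, numeric(1))
  expect_true(all(diff(area) < 0))
})

test_that("even-odd containment agrees with a winding-number oracle", {
  e <- fake_ensemble(matrix(c(0.4, 0.5, 0.5, 0.55, 0.6, 0.5), 3, 2,
                            byrow = TRUE), sd = 0.06)
  b <- attractor_boundary(spd_landscape(e))
  set.seed(33)
  pts <- cbind(runif(1000, min(b$x) - 0.2, max(b$x) + 0.2),
               runif(1000, min(b$y) - 0.2, max(b$y) + 0.2))
  ours <- apply(pts, 1, function(p) point_in_basin(p, b))
  oracle <- apply(pts, 1, function(p) pip_winding(p[1], p[2], b$x, b$y))
  expect_gte(mean(ours == oracle), 0.999)
})

test_that("the whole-transcriptome trajectory lands inside its own basin", {
  cfg <- synthetic_config(n_genes = 1500, seed = 31)
  sim <- generate_timecourse(cfg)
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  expr <- remove_top_expressed(filter_low_expression(tpm, 5), 2)
  ens <- sample_ensembles(expr, 100, repeats = 60, seed = 31)
  ls <- spd_landscape(ens)
  b <- attractor_boundary(ls)
  wt <- whole_trajectory(ens)
  last <- nrow(wt)
  expect_true(point_in_basin(c(wt$rv[last], wt$miv[last]), b))
})
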