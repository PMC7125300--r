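test_that("ward clustering recovers planted separable families", {
  set.seed(61)
  tps <- c(0, 0.5, 1, 2, 5, 10)
  mk <- function(lab, n) {
    t(sapply(seq_len(n), function(i) {
      z <- pattern_template(lab, tps)^1.5
      z <- (z - mean(z)) / sd(z)
      z + rnorm(length(tps), 0, 0.1)
    }))
  }
  z <- rbind(mk("A", 40), mk("B", 40))
  rownames(z) <- sprintf("g%02d", 1:80)
  truth <- rep(c("A", "B"), each = 40)
  cl <- ward_cluster(z, 2)
  expect_equal(ari_index(truth, cl), 1)
  expect_length(unique(ward_cluster(z, 1)), 1)
  expect_error(ward_cluster(z, 100), "between 1")
})

test_that("refinement leaves a coherent single-profile group untouched", {
  set.seed(62)
  prof <- pattern_template("B", c(0, 1, 2, 5))
  z <- t(sapply(1:30, function(i) {
    v <- prof + rnorm(4, 0, 0.02)
    (v - mean(v)) / sd(v)
  }))
  rownames(z) <- sprintf("g%02d", 1:30)
  g <- refine_groups(ward_cluster(z, 1), z, 0.7)
  expect_length(unique(g$groups), 1)
  expect_true(g$converged)
})

test_that("an anti-correlated misfit gene is moved out of its group", {
  set.seed(63)
  tps <- c(0, 0.5, 1, 2, 5, 10)
  zb <- t(sapply(1:25, function(i) {
    v <- pattern_template("B", tps) + rnorm(6, 0, 0.03)
    (v - mean(v)) / sd(v)
  }))
  misfit <- -zb[1, ]                       # anti-correlated profile
  z <- rbind(zb, misfit)
  rownames(z) <- sprintf("g%02d", 1:26)
  clusters <- setNames(rep(1L, 26), rownames(z))
  g <- refine_groups(clusters, z, 0.7)
  expect_gt(length(unique(g$groups)), 1)
  expect_false(g$groups["g26"] == g$groups["g01"])
  # every gene ends with r >= threshold to its own group mean
  ok <- vapply(rownames(z), function(gn) {
    grp <- g$groups[gn]
    prof <- g$group_profiles[as.character(grp), ]
    if (sd(prof) == 0) return(TRUE)
    cor(z[gn, ], prof) >= 0.7 - 1e-9 ||
      sum(g$groups == grp) == 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("the six planted families are recovered from 13 initial clusters", {
  cfg <- synthetic_config(n_genes = 1500, seed = 65)
  sim <- generate_timecourse(cfg)
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  att <- intersect(sim$truth$gene_id[sim$truth$is_attractor], tpm$gene_ids)
  z <- zscore_normalize(time_course_matrix(subset_genes(tpm, att)))
  g <- refine_groups(ward_cluster(z, 13), z, 0.7)
  lab <- sim$truth$pattern_label[match(names(g$groups), sim$truth$gene_id)]
  expect_equal(length(unique(g$groups)), 6)
  expect_gte(ari_index(lab, g$groups), 0.9)
  # group mean profiles stay on the z-score scale (mean ~ 0 across time)
  expect_lt(max(abs(rowMeans(g$group_profiles))), 0.1)
})

test_that("the stringent filter keeps high peaks with large folds", {
  profiles <- matrix(c(600, 150, 200,      # 4-fold swing, peak 600: kept
                       1000, 1000, 1000,   # constant: fold fails
                       450, 100, 120,      # peak below 500: removed
                       2000, 500, 700,     # 4-fold, peak 2000: kept
                       550, 300, 400),     # < 3-fold: removed
                     5, byrow = TRUE,
                     dimnames = list(sprintf("g%d", 1:5), NULL))
  m <- toy_expr(profiles, time_points = c(0, 1, 2))
  expect_setequal(stringent_filter(m, tpm_min = 500, fold_min = 3),
                  c("g1", "g4"))
})

test_that("fold-change selection matches a brute-force pair enumeration", {
  set.seed(66)
  profiles <- matrix(rlnorm(40 * 4, 3, 1), 40, 4,
                     dimnames = list(sprintf("g%02d", 1:40), NULL))
  m <- toy_expr(profiles, time_points = c(0, 1, 2, 5))
  got <- fold_change_set(m, fold_min = 2, pseudocount = 0.5)
  keep <- vapply(seq_len(40), function(i) {
    v <- profiles[i, ] + 0.5
    any(outer(v, v, "/") > 2)
  }, logical(1))
  expect_setequal(got, rownames(profiles)[keep])
  # constant matrix gives the empty set; a 2.5-fold gene is included
  flat <- toy_expr(matrix(10, 3, 2), time_points = c(0, 1))
  expect_length(fold_change_set(flat, 2), 0)
  stepg <- toy_expr(matrix(c(10, 25, 10), 1, dimnames = list("gS", NULL)),
                    time_points = c(0, 1, 2))
  expect_identical(fold_change_set(stepg, 2), "gS")
})

test_that("stringent selection nests inside the 3-fold set when unbounded", {
  cfg <- synthetic_config(n_genes = 600, seed = 67)
  sim <- generate_timecourse(cfg)
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  s0 <- stringent_filter(tpm, tpm_min = 0, fold_min = 3)
  f3 <- fold_change_set(tpm, fold_min = 3)
  extra <- setdiff(s0, f3)   # boundary genes with fold exactly 3
  if (length(extra)) {
    tc <- time_course_matrix(subset_genes(tpm, extra))
    folds <- (apply(tc, 1, max) + 0.5) / (apply(tc, 1, min) + 0.5)
    expect_true(all(abs(folds - 3) < 1e-9))
  } else {
    expect_true(all(s0 %in% f3))
  }
})

test_that("set comparison does exact set algebra", {
  a <- c("x", "y", "z"); b <- c("y", "z", "w")
  cmp <- compare_sets(a, b)
  expect_setequal(cmp$common, c("y", "z"))
  expect_identical(cmp$a_only, "x")
  expect_identical(cmp$b_only, "w")
  expect_equal(unname(cmp$counts["common"] + cmp$counts["a_only"]),
               length(a))
  same <- compare_sets(a, a)
  expect_length(same$a_only, 0)
  expect_length(same$b_only, 0)
  disj <- compare_sets(a, "q")
  expect_length(disj$common, 0)
})
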