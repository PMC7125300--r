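test_that("gene ranking orders by temporal variability with stable ties", {
  m <- toy_expr(matrix(c(1, 1, 1,
                         1, 2, 1,
                         1, 9, 1), 3, byrow = TRUE,
                       dimnames = list(c("gA", "gB", "gC"), NULL)),
                time_points = c(0, 1, 2))
  expect_identical(rank_genes(m, "sd"), c("gC", "gB", "gA"))
  expect_identical(rank_genes(m, "fold_change"), c("gC", "gB", "gA"))
  # scaling all profiles preserves the sd-mode order
  m10 <- toy_expr(10 * m$values, time_points = c(0, 1, 2))
  expect_identical(rank_genes(m10, "sd"), rank_genes(m, "sd"))
  # rms mode ranks by amplitude-weighted magnitude
  expect_identical(rank_genes(m, "rms")[1], "gC")
})

test_that("element partition follows the ceiling rule with overlap", {
  ord200 <- sprintf("g%04d", 1:200)
  p <- partition_elements(ord200, 100)
  expect_length(p$elements, 2)
  expect_identical(p$elements[[2]], ord200[101:200])
  ord250 <- sprintf("g%04d", 1:250)
  p <- partition_elements(ord250, 100)
  expect_length(p$elements, 3)
  expect_identical(p$elements[[3]], ord250[151:250])   # 50-gene overlap
  expect_length(intersect(p$elements[[2]], p$elements[[3]]), 50)
  # the published count chain: 3389 ranked genes in elements of 100
  ord3389 <- sprintf("g%04d", 1:3389)
  p <- partition_elements(ord3389, 100)
  expect_length(p$elements, 34)
  expect_identical(p$elements[[34]], ord3389[3290:3389])
  expect_error(partition_elements(ord200, 300), "exceeds")
})

test_that("element partitions cover all genes exactly", {
  ord <- sprintf("g%04d", 1:437)
  p <- partition_elements(ord, 100)
  expect_setequal(unique(unlist(p$elements)), ord)
  expect_true(all(lengths(p$elements) == 100))
  # non-final elements are pairwise disjoint
  for (i in 1:3) for (j in (i + 1):4) {
    if (j < length(p$elements))
      expect_length(intersect(p$elements[[i]], p$elements[[j]]), 0)
  }
})

test_that("element trajectories separate planted signal from noise", {
  set.seed(41)
  tps <- c(0, 0.5, 1, 2, 5, 10)
  n_sig <- 150; n_noise <- 150
  template <- pattern_template("B", tps)
  sig <- t(sapply(seq_len(n_sig), function(i) {
    rlnorm(1, 3, 0.8) * template^runif(1, 1.4, 2)
  }))
  noise <- matrix(rlnorm(n_noise, 3, 0.8), n_noise, length(tps))
  profiles <- rbind(sig, noise)
  rownames(profiles) <- sprintf("g%03d", seq_len(nrow(profiles)))
  colnames(profiles) <- tps
  expr <- toy_timecourse(profiles, n_replicates = 3, cv = 0.15)
  ord <- rank_genes(expr, "fold_change")
  part <- partition_elements(ord, 100)
  trs <- element_trajectories(part, expr, seed = 1)
  expect_true(all(vapply(trs, function(tr) {
    abs(tr$rv[1] - 1) < 1e-12 && abs(tr$miv[1] - 1) < 1e-12
  }, logical(1))))
  # the top element is dominated by signal genes and stays coherent;
  # the bottom element is noise and decays towards the origin
  top <- trs[[1]]; bottom <- trs[[length(trs)]]
  expect_gt(top$miv[length(tps)], bottom$miv[length(tps)])
  expect_lt(bottom$miv[length(tps)], 0.35)
  expect_error(element_trajectories(partition_elements(ord, 5), expr),
               "smaller than the MI bin count")
})

test_that("classification conserves and partitions the gene universe", {
  cfg <- synthetic_config(n_genes = 1200, seed = 43)
  pcfg <- pipeline_config(synthetic = cfg, ensemble_repeats = 40,
                          ranking = "fold_change", seed = 43)
  res <- run_pipeline(pcfg)
  gs <- res$classification$gene_sets
  all_genes <- res$expr$gene_ids
  expect_setequal(c(gs$attractor, gs$pseudo_attractor, gs$non_attractor),
                  all_genes)
  expect_length(intersect(gs$attractor, gs$non_attractor), 0)
  expect_length(intersect(gs$attractor, gs$pseudo_attractor), 0)
  expect_length(intersect(gs$pseudo_attractor, gs$non_attractor), 0)
  expect_true(all(res$classification$element_distances >= 0))
})

test_that("all-noise data yields no systematic above-basin elements", {
  # with no planted signal, elements are statistically exchangeable with
  # the random ensembles; above-basin labels should be rare accidents
  above <- vapply(1:3, function(seed) {
    set.seed(seed)
    profiles <- matrix(rlnorm(800, 3, 1), 800, 6,
                       dimnames = list(sprintf("g%03d", 1:800),
                                       c(0, 0.5, 1, 2, 5, 10)))
    expr <- toy_timecourse(profiles, n_replicates = 3, cv = 0.15)
    ens <- sample_ensembles(expr, 100, repeats = 40, seed = seed)
    b <- attractor_boundary(spd_landscape(ens))
    wt <- whole_trajectory(ens)
    ord <- rank_genes(expr, "sd")
    part <- partition_elements(ord, 100)
    trs <- element_trajectories(part, expr, seed = seed)
    cls <- classify_elements(trs, b, wt, part, expr, seed = seed)
    sum(cls$element_labels == "above_basin")
  }, numeric(1))
  expect_lte(mean(above), 1)
})

test_that("no-response screening applies the fold rule exactly", {
  m <- toy_expr(matrix(c(10, 10, 10,       # constant: included
                         10, 15, 10,       # 1.5-fold step: excluded
                         10, 10.5, 10),    # 1.05-fold: included
                       3, byrow = TRUE,
                       dimnames = list(c("gA", "gB", "gC"), NULL)),
                time_points = c(0, 1, 2))
  expect_setequal(no_response_genes(m, fold_threshold = 1.12),
                  c("gA", "gC"))
})

test_that("planted no-response genes are recovered exactly without noise", {
  cfg <- synthetic_config(n_genes = 2000, noise_cv = 0, seed = 47)
  sim <- generate_timecourse(cfg)
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  # outlier genes buffer the compositional balance, so their (small) fold
  # change is not planted; compare on the non-outlier universe
  genes <- sim$truth$gene_id[!sim$truth$is_outlier]
  rec <- no_response_genes(tpm, genes, 1.12)
  expect_setequal(rec, sim$truth$gene_id[sim$truth$is_no_response])
})
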