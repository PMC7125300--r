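# shared fixtures and independent oracles for the test suite

# small ExpressionMatrix built by hand: genes x (times x replicates)
toy_expr <- function(values, time_points, n_replicates = 1,
                     unit = "TPM") {
  reps <- letters[seq_len(n_replicates)]
  design <- expand.grid(replicate = reps, time_min = time_points,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[order(design$time_min, design$replicate), ]
  design$sample_id <- paste0("t", design$time_min, "_", design$replicate)
  colnames(values) <- design$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  expression_matrix(values, design[, c("sample_id", "time_min", "replicate")],
                    unit = unit)
}

# replicate a genes x time matrix into per-replicate columns with optional
# multiplicative lognormal noise
toy_timecourse <- function(profiles, n_replicates = 3, cv = 0,
                           unit = "TPM") {
  tn <- ncol(profiles)
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  cols <- list()
  tps <- as.numeric(colnames(profiles))
  if (anyNA(tps)) tps <- seq_len(tn) - 1
  for (tp in seq_len(tn)) {
    for (r in seq_len(n_replicates)) {
      noise <- if (sdlog > 0) {
        rlnorm(nrow(profiles), -sdlog^2 / 2, sdlog)
      } else 1
      cols[[paste0("t", tps[tp], "_", letters[r])]] <- profiles[, tp] * noise
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- rownames(profiles)
  reps <- letters[seq_len(n_replicates)]
  design <- data.frame(
    sample_id = colnames(values),
    time_min = rep(tps, each = n_replicates),
    replicate = rep(reps, times = tn),
    stringsAsFactors = FALSE)
  expression_matrix(values, design, unit = unit)
}

# brute-force mutual information oracle: explicit triple loop over the
# K x K contingency table of bin indices
mi_bruteforce <- function(bx, by, K) {
  n <- length(bx)
  mi <- 0
  for (i in seq_len(K)) {
    px <- sum(bx == i) / n
    if (px == 0) next
    for (j in seq_len(K)) {
      py <- sum(by == j) / n
      pxy <- sum(bx == i & by == j) / n
      if (pxy > 0) mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  mi
}

# direct evaluation of the biweight midcorrelation formulas
bicor_oracle <- function(x, y) {
  norm_one <- function(p) {
    med <- median(p)
    m <- median(abs(p - med))           # raw mad, no consistency constant
    u <- (p - med) / (9 * m)
    w <- (1 - u^2)^2 * ifelse(1 - abs(u) > 0, 1, 0)
    a <- (p - med) * w
    a / sqrt(sum(a^2))
  }
  sum(norm_one(x) * norm_one(y))
}

# winding-number point-in-polygon oracle
pip_winding <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (vy[i] <= py) {
      if (vy[j] > py &&
          (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]) > 0)
        wn <- wn + 1
    } else {
      if (vy[j] <= py &&
          (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]) < 0)
        wn <- wn - 1
    }
  }
  wn != 0
}

# adjusted Rand index for clustering-recovery checks (closed form)
ari_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  ex <- si * sj / comb2(sum(tab))
  (sij - ex) / ((si + sj) / 2 - ex)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
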