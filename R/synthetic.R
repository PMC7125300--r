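#' Temporal pattern families for the synthetic generator
#'
#' Six canonical temporal dynamics observed for coherently responding genes
#' during a rapid metabolic state transition:
#' \describe{
#'   \item{A}{gradual decay}
#'   \item{B}{gradual activation}
#'   \item{C}{fast activation, then decay, then re-activation}
#'   \item{D}{early activation followed by decay}
#'   \item{E}{early activation followed by plateau}
#'   \item{F}{early decay followed by plateau}
#' }
#' Templates are anchored on the 0, 0.5, 1, 2, 5, 10 minute grid and
#' linearly interpolated for other time axes; every template starts at 1
#' at t = 0 so that a gene's baseline expression carries the scale.
#' All six families are normalised to span exactly a 3-fold dynamic range
#' at unit scale, so that a single per-gene amplitude exponent `s` sets
#' the fold change (`3^s`) independently of the temporal shape.
#'
#' @format Character vector of the six labels.
#' @export
pattern_labels <- c("A", "B", "C", "D", "E", "F")

.pattern_anchor_times <- c(0, 0.5, 1, 2, 5, 10)
.pattern_anchors <- list(
  A = c(1, 0.90, 0.80, 0.65, 0.45, 0.25),
  B = c(1, 1.10, 1.25, 1.50, 2.00, 2.60),
  C = c(1, 1.80, 1.20, 0.85, 1.05, 1.55),
  D = c(1, 2.00, 1.70, 1.25, 0.85, 0.70),
  E = c(1, 1.75, 1.95, 2.05, 2.08, 2.08),
  F = c(1, 0.40, 0.34, 0.36, 0.38, 0.39)
)
.pattern_base_fold <- 3

# Anaerobic steady-state expression bias per family: machinery that decays
# during aerobiosis (A, F) starts highly expressed, machinery that is
# activated (B, C, D) starts repressed. The values keep the summed
# transcript output of the default gene mix constant through the
# transition to within ~3%, so TPM renormalisation does not distort the
# planted per-gene fold changes.
.baseline_bias <- c(A = 4, B = 0.64, C = 0.4, D = 0.4, E = 0.8, F = 4)

#' Unit-scale temporal profile of a pattern family
#'
#' @param label One of `"A"`..`"F"` (see [pattern_labels]).
#' @param time_points Increasing numeric vector of times in minutes,
#'   starting at 0.
#' @return Numeric vector, one multiplicative expression factor per time
#'   point; the value at t = 0 is exactly 1.
#' @examples
#' pattern_template("A", c(0, 0.5, 1, 2, 5, 10))
#' @export
pattern_template <- function(label, time_points = c(0, 0.5, 1, 2, 5, 10)) {
  if (length(label) != 1 || !label %in% pattern_labels) {
    stop("unknown pattern label: ", paste(label, collapse = ", "))
  }
  if (!is.numeric(time_points) || length(time_points) < 1 ||
      time_points[1] != 0 || is.unsorted(time_points, strictly = TRUE)) {
    stop("time_points must be strictly increasing and start at 0")
  }
  f <- .pattern_anchors[[label]]
  # equalise the dynamic range across families: exponent chosen so the
  # anchor profile spans exactly .pattern_base_fold
  f <- f^(log(.pattern_base_fold) / log(max(f) / min(f)))
  stats::approx(.pattern_anchor_times, f,
                xout = pmin(time_points, max(.pattern_anchor_times)),
                rule = 2)$y
}

#' Configuration for the synthetic time-course generator
#'
#' Defines the statistical structure of a generated experiment: lognormal
#' baseline expression, six planted temporal pattern families, a fraction of
#' strongly and coherently changing ("attractor-like") genes, weakly
#' responding genes, flat no-response genes, multiplicative replicate noise,
#' and a small number of extreme high-expression outlier genes.
#'
#' Pattern strength is a per-gene exponent `s` applied to the
#' fold-normalised template (`template^s`, giving a `3^s`-fold change), so
#' amplitude acts on the fold scale, preserves positivity and is
#' independent of the temporal shape. Attractor genes draw the exponent
#' from `attractor_scale_range` (default 4.7- to 9.3-fold), weakly
#' responding genes from `weak_scale_range` (default 1.23- to 1.39-fold),
#' and no-response genes are flat (exponent 0, noiseless fold change
#' 1 < 1.12).
#'
#' Baselines are lognormal, multiplied by a per-family expression bias
#' reflecting the anaerobic steady state (decaying machinery highly
#' expressed, to-be-activated machinery repressed); the bias values keep
#' the summed transcript output of the default gene mix constant through
#' the transition to within a few percent, and the outlier genes buffer
#' the remaining drift exactly, so that planted fold changes survive TPM
#' renormalisation. See the methods vignette for the full rationale.
#'
#' @param n_genes Number of genes.
#' @param time_points Sampling times in minutes, strictly increasing from 0.
#' @param n_replicates Biological replicates per time point.
#' @param lognormal_mu,lognormal_sigma Location and scale of the log-TPM
#'   baseline distribution.
#' @param group_fractions Named fractions over the six pattern labels;
#'   must sum to 1.
#' @param attractor_fraction Fraction of genes given strong coherent
#'   dynamics.
#' @param no_response_fraction Fraction of flat genes (noiseless maximum
#'   fold change below 1.12).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (lognormal) replicate noise.
#' @param n_outlier_genes Number of extreme high expressors planted with
#'   baseline at least 50x the 99th percentile of the remaining baselines
#'   (stable-RNA analogues); they also absorb the residual compositional
#'   drift, so their own temporal profile is not a planted pattern.
#' @param attractor_scale_range,weak_scale_range Ranges of the per-gene
#'   pattern-strength exponent for attractor and weakly responding genes.
#' @param median_library_size Target median library size used when
#'   back-computing read counts from TPM.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A validated list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_genes = 4000,
                             time_points = c(0, 0.5, 1, 2, 5, 10),
                             n_replicates = 3,
                             lognormal_mu = 3,
                             lognormal_sigma = 1.2,
                             group_fractions = NULL,
                             attractor_fraction = 0.5,
                             no_response_fraction = 0.02,
                             noise_cv = 0.15,
                             n_outlier_genes = 2,
                             attractor_scale_range = c(1.4, 2.0),
                             weak_scale_range = c(0.19, 0.3),
                             median_library_size = 1e7,
                             seed = 1) {
  if (is.null(group_fractions)) {
    group_fractions <- stats::setNames(rep(1 / 6, 6), pattern_labels)
  }
  if (!setequal(names(group_fractions), pattern_labels)) {
    stop("group_fractions must be named with labels A-F")
  }
  group_fractions <- group_fractions[pattern_labels]
  if (abs(sum(group_fractions) - 1) > 1e-8) {
    stop("group_fractions must sum to 1")
  }
  if (n_genes <= 0) stop("n_genes must be positive")
  if (!is.numeric(time_points) || time_points[1] != 0 ||
      is.unsorted(time_points, strictly = TRUE)) {
    stop("time_points must be strictly increasing and start at 0")
  }
  fracs <- c(attractor_fraction, no_response_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  if (attractor_fraction + no_response_fraction > 1) {
    stop("attractor_fraction + no_response_fraction must not exceed 1")
  }
  if (lognormal_sigma <= 0) stop("lognormal_sigma must be positive")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (n_outlier_genes < 0) stop("n_outlier_genes must be non-negative")

  structure(
    list(n_genes = as.integer(n_genes), time_points = time_points,
         n_replicates = as.integer(n_replicates),
         lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
         group_fractions = group_fractions,
         attractor_fraction = attractor_fraction,
         no_response_fraction = no_response_fraction,
         noise_cv = noise_cv, n_outlier_genes = as.integer(n_outlier_genes),
         attractor_scale_range = attractor_scale_range,
         weak_scale_range = weak_scale_range,
         median_library_size = median_library_size,
         seed = as.integer(seed)),
    class = "SyntheticConfig"
  )
}

#' Generate a seeded synthetic time-course experiment
#'
#' Draws lognormal baseline TPM values, applies amplitude-scaled pattern
#' templates to attractor and weakly responding genes, keeps no-response
#' genes flat, multiplies in lognormal replicate noise with the configured
#' coefficient of variation, and back-computes read counts from TPM via
#' per-gene lengths and a library-size constant. Ground-truth labels are
#' returned for recovery testing.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{`ExpressionMatrix` of integer read counts.}
#'     \item{gene_lengths}{Named vector of gene lengths in bases.}
#'     \item{design}{Data frame `sample_id`, `time_min`, `replicate`.}
#'     \item{truth}{Data frame with per-gene `pattern_label`
#'       (`"none"` for no-response genes), `is_attractor`,
#'       `is_no_response`, `is_outlier`, `baseline_tpm` and the
#'       pattern-strength exponent `scale_exponent`.}
#'     \item{tpm_true}{Noise-free genes x time template TPM matrix.}
#'     \item{config}{The configuration used.}
#'   }
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  with_seed(config$seed, {
    n <- config$n_genes
    tps <- config$time_points
    tn <- length(tps)
    reps <- letters[seq_len(config$n_replicates)]

    gene_ids <- sprintf("gene_%05d", seq_len(n))

    n_nr <- round(config$no_response_fraction * n)
    n_att <- round(config$attractor_fraction * n)
    n_weak <- n - n_nr - n_att
    if (n_weak < 0) stop("fractions leave no room for weakly responding genes")

    role <- rep("weak", n)
    shuffled <- sample.int(n)
    role[shuffled[seq_len(n_att)]] <- "attractor"
    if (n_nr > 0) role[shuffled[n_att + seq_len(n_nr)]] <- "no_response"

    label <- rep("none", n)
    responding <- which(role != "no_response")
    label[responding] <- sample(pattern_labels, length(responding),
                                replace = TRUE, prob = config$group_fractions)

    sc <- numeric(n)
    sc[role == "attractor"] <- stats::runif(sum(role == "attractor"),
                                            config$attractor_scale_range[1],
                                            config$attractor_scale_range[2])
    sc[role == "weak"] <- stats::runif(sum(role == "weak"),
                                       config$weak_scale_range[1],
                                       config$weak_scale_range[2])

    baseline <- stats::rlnorm(n, config$lognormal_mu, config$lognormal_sigma)
    bias <- ifelse(label == "none", 1, .baseline_bias[label])
    baseline <- baseline * unname(bias)
    is_outlier <- rep(FALSE, n)
    if (config$n_outlier_genes > 0) {
      weak_idx <- which(role == "weak")
      if (length(weak_idx) < config$n_outlier_genes) {
        stop("not enough weakly responding genes to host the outliers")
      }
      out_idx <- weak_idx[seq_len(config$n_outlier_genes)]
      q99 <- stats::quantile(baseline[-out_idx], 0.99, names = FALSE)
      baseline[out_idx] <- 50 * q99 *
        (1 + 0.25 * (seq_len(config$n_outlier_genes) - 1))
      is_outlier[out_idx] <- TRUE
    }

    templates <- vapply(pattern_labels, pattern_template,
                        numeric(tn), time_points = tps)
    profile <- matrix(1, n, tn)
    for (g in responding) {
      profile[g, ] <- templates[, label[g]]^sc[g]
    }
    tpm_true <- baseline * profile
    dimnames(tpm_true) <- list(gene_ids, tps)

    # The outlier genes buffer the compositional balance: their profile
    # absorbs the residual drift of total transcript output, so every
    # other gene's fold change survives TPM renormalisation exactly.
    if (any(is_outlier)) {
      resp_tot <- colSums(tpm_true[!is_outlier, , drop = FALSE])
      b_out <- baseline[is_outlier]
      target <- resp_tot[1] + sum(b_out)
      out_prof <- (target - resp_tot) / sum(b_out)
      if (any(out_prof <= 0)) {
        stop("outlier genes cannot buffer the compositional drift; ",
             "increase n_outlier_genes or rebalance group_fractions")
      }
      tpm_true[is_outlier, ] <- b_out %o% out_prof
      label[is_outlier] <- "none"
      sc[is_outlier] <- 0
    }

    design <- expand.grid(replicate = reps, time_min = tps,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design <- design[order(design$time_min, design$replicate), ]
    design$sample_id <- paste0("t", design$time_min, "_", design$replicate)
    design <- design[, c("sample_id", "time_min", "replicate")]
    rownames(design) <- NULL

    sdlog <- sqrt(log(1 + config$noise_cv^2))
    tpm <- matrix(0, n, nrow(design),
                  dimnames = list(gene_ids, design$sample_id))
    for (s in seq_len(nrow(design))) {
      tcol <- tpm_true[, as.character(design$time_min[s])]
      noise <- if (sdlog > 0) {
        stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, n)
      tpm[, s] <- tcol * noise
    }

    gene_lengths <- pmax(100, round(stats::rlnorm(n, log(1000), 0.35)))
    names(gene_lengths) <- gene_ids

    # counts ~ TPM x (length/kb) x constant; the constant is one number for
    # the whole experiment, chosen so the median library is ~1e7 reads
    rate <- tpm * (gene_lengths / 1000)
    k <- config$median_library_size / stats::median(colSums(rate))
    counts <- round(rate * k)

    truth <- data.frame(
      gene_id = gene_ids,
      pattern_label = label,
      is_attractor = role == "attractor",
      is_no_response = role == "no_response",
      is_outlier = is_outlier,
      baseline_tpm = baseline,
      scale_exponent = sc,
      stringsAsFactors = FALSE
    )

    list(counts = expression_matrix(counts, design, unit = "counts"),
         gene_lengths = gene_lengths,
         design = design,
         truth = truth,
         tpm_true = tpm_true,
         config = config)
  })
}

#' Write a generated experiment to plain-text files
#'
#' Writes the count matrix and gene lengths as TSV, the design as CSV, the
#' ground truth as TSV and the configuration as JSON, mirroring the layout
#' of deposited count data.
#'
#' @param sim Result of [generate_timecourse()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_timecourse <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    design = file.path(dir, "design.csv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  counts <- data.frame(gene_id = sim$counts$gene_ids,
                       sim$counts$values, check.names = FALSE)
  utils::write.table(counts, paths["counts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(sim$gene_lengths), length = sim$gene_lengths),
    paths["lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$design, paths["design"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
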