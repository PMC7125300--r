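#' Pipeline configuration
#'
#' Collects every tunable threshold of the end-to-end analysis with the
#' canonical defaults: 5 TPM expression filter, top-2 high-expressor
#' removal, element size 100, 100 ensemble repeats, 10 MI bins, 100
#' permutations for the MI bias term, 1.12-fold no-response cut-off, 13
#' initial Ward clusters refined at Pearson 0.7, the stringent
#' 500 TPM / 3-fold filter and the conventional 2-fold comparison set.
#'
#' Input is either a [synthetic_config()] (`synthetic`) or the three file
#' paths of a deposited experiment (`counts_path`, `lengths_path`,
#' `design_path`).
#'
#' @param synthetic Optional [synthetic_config()] used to generate input.
#' @param counts_path,lengths_path,design_path Paths to count matrix, gene
#'   lengths and design tables (used when `synthetic` is NULL).
#' @param tpm_threshold Low-expression filter threshold (default 5).
#' @param drop_top Number of highest-expressed genes removed (default 2).
#' @param element_size Transcriptomic element size (default 100).
#' @param ensemble_repeats Random ensembles for the landscape (default 100).
#' @param mi_bins Histogram MI bins (default 10).
#' @param mi_permutations Permutations for the MI bias term (default 100).
#' @param no_response_fold No-response fold cut-off (default 1.12).
#' @param initial_k Initial Ward cluster count (default 13; 9 is the
#'   common alternative).
#' @param refine_r Refinement correlation threshold (default 0.7).
#' @param stringent_tpm,stringent_fold Stringent filter (defaults 500, 3).
#' @param comparison_fold Conventional fold-change selection (default 2).
#' @param ranking `"sd"` or `"fold_change"` element ranking.
#' @param seed Master seed; every random stage derives from it.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            counts_path = NULL, lengths_path = NULL,
                            design_path = NULL,
                            tpm_threshold = 5, drop_top = 2,
                            element_size = 100, ensemble_repeats = 100,
                            mi_bins = 10, mi_permutations = 100,
                            no_response_fold = 1.12,
                            initial_k = 13, refine_r = 0.7,
                            stringent_tpm = 500, stringent_fold = 3,
                            comparison_fold = 2,
                            ranking = c("sd", "fold_change"),
                            seed = 1) {
  ranking <- match.arg(ranking)
  if (is.null(synthetic) &&
      (is.null(counts_path) || is.null(lengths_path) || is.null(design_path))) {
    stop("provide either a synthetic config or all three input paths")
  }
  thresholds <- c(tpm_threshold, drop_top, element_size, ensemble_repeats,
                  mi_bins, mi_permutations, no_response_fold, initial_k,
                  refine_r, stringent_tpm, stringent_fold, comparison_fold)
  if (any(thresholds < 0)) stop("thresholds must be non-negative")
  structure(
    list(synthetic = synthetic, counts_path = counts_path,
         lengths_path = lengths_path, design_path = design_path,
         tpm_threshold = tpm_threshold, drop_top = drop_top,
         element_size = element_size, ensemble_repeats = ensemble_repeats,
         mi_bins = mi_bins, mi_permutations = mi_permutations,
         no_response_fold = no_response_fold, initial_k = initial_k,
         refine_r = refine_r, stringent_tpm = stringent_tpm,
         stringent_fold = stringent_fold, comparison_fold = comparison_fold,
         ranking = ranking, seed = as.integer(seed)),
    class = "PipelineConfig"
  )
}

#' Run the full attractor-landscape analysis
#'
#' Executes normalisation, expression filtering, temporal correlation
#' series, ensemble landscape and basin boundary, element classification,
#' no-response screening, PCA trajectory validation, temporal clustering
#' with refinement, and the stringent and fold-change gene-set
#' comparisons. Every random stage is driven by `config$seed`, so a given
#' configuration reproduces byte-identical summaries.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, stage tables and the
#'   JSON summary report are written there.
#' @return Object of class `PipelineResult`: list of stage outputs plus a
#'   `summary` list with the gene-count chain.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  with_seed(config$seed, {
    # --- input ---------------------------------------------------------
    if (!is.null(config$synthetic)) {
      sim <- generate_timecourse(config$synthetic)
      counts <- sim$counts
      lengths <- sim$gene_lengths
      truth <- sim$truth
    } else {
      counts <- read_expression(config$counts_path, config$design_path,
                                unit = "counts")
      lengths <- read_gene_lengths(config$lengths_path)
      truth <- NULL
    }

    # --- normalise and filter ------------------------------------------
    tpm <- tpm_normalize(counts, lengths)
    filtered <- filter_low_expression(tpm, config$tpm_threshold)
    n_retained <- nrow(filtered$values)
    expr <- remove_top_expressed(filtered, config$drop_top)
    dropped_top <- attr(expr, "dropped_ids")
    n_kept <- nrow(expr$values)

    # --- temporal correlation series ------------------------------------
    series <- do.call(rbind, lapply(
      c("pearson", "spearman", "bicor", "mi_c"),
      function(m) temporal_series(expr, m, bins = config$mi_bins,
                                  n_permutations = config$mi_permutations)))

    # --- landscape ------------------------------------------------------
    ensemble <- sample_ensembles(expr, n = config$element_size,
                                 repeats = config$ensemble_repeats,
                                 bins = config$mi_bins,
                                 n_permutations = config$mi_permutations)
    landscape <- spd_landscape(ensemble)
    boundary <- attractor_boundary(landscape)
    whole <- whole_trajectory(ensemble)

    # --- elements and classification -----------------------------------
    ordering <- rank_genes(expr, config$ranking)
    partition <- partition_elements(ordering, config$element_size)
    trajs <- element_trajectories(partition, expr, bins = config$mi_bins,
                                  n_permutations = config$mi_permutations)
    cls <- classify_elements(trajs, boundary, whole, partition, expr,
                             bins = config$mi_bins,
                             n_permutations = config$mi_permutations)
    attractor_all <- union(cls$gene_sets$attractor,
                           cls$gene_sets$pseudo_attractor)
    non_attractor <- cls$gene_sets$non_attractor
    no_resp <- no_response_genes(expr, non_attractor,
                                 config$no_response_fold)
    collective <- setdiff(non_attractor, no_resp)

    # --- PCA validation -------------------------------------------------
    pca_sets <- list(whole = expr$gene_ids)
    if (length(attractor_all) >= 3) pca_sets$attractor <- attractor_all
    if (length(non_attractor) >= 3) pca_sets$non_attractor <- non_attractor
    pca <- lapply(pca_sets, function(g) pc_trajectory(expr, genes = g))

    # --- temporal clustering of the attractor genes ---------------------
    grouping <- NULL
    if (length(attractor_all) > config$initial_k) {
      z <- zscore_normalize(time_course_matrix(
        subset_genes(expr, attractor_all)))
      cl0 <- ward_cluster(z, config$initial_k)
      grouping <- refine_groups(cl0, z, config$refine_r)
    }

    # --- stringent and fold-change sets ---------------------------------
    stringent <- stringent_filter(expr, attractor_all,
                                  config$stringent_tpm,
                                  config$stringent_fold)
    fold_set <- fold_change_set(expr, config$comparison_fold)
    venn <- compare_sets(attractor_all, fold_set)

    summary <- list(
      n_input_genes = nrow(counts$values),
      n_retained = n_retained,
      n_low_removed = nrow(counts$values) - n_retained,
      dropped_top = dropped_top,
      n_analysed = n_kept,
      n_elements = length(partition$elements),
      n_elements_above = sum(cls$element_labels == "above_basin"),
      n_elements_in = sum(cls$element_labels == "in_basin"),
      n_elements_below = sum(cls$element_labels == "below_basin"),
      n_pseudo_candidate_elements = length(cls$pseudo_candidates),
      merged_in_basin = cls$merged_in_basin,
      n_attractor_core = length(cls$gene_sets$attractor),
      n_pseudo_attractor = length(cls$gene_sets$pseudo_attractor),
      n_attractor = length(attractor_all),
      n_non_attractor = length(non_attractor),
      n_no_response = length(no_resp),
      n_collective_non_attractor = length(collective),
      pct_attractor = round(100 * length(attractor_all) / n_kept),
      n_temporal_groups = if (is.null(grouping)) NA_integer_ else
        length(unique(grouping$groups)),
      n_stringent = length(stringent),
      n_fold_change = length(fold_set),
      n_common = unname(venn$counts["common"]),
      seed = config$seed,
      version = as.character(utils::packageVersion("attractorscape"))
    )

    result <- structure(
      list(config = config, expr = expr, truth = truth, series = series,
           ensemble = ensemble, landscape = landscape, boundary = boundary,
           whole_trajectory = whole, partition = partition,
           element_trajectories = trajs, classification = cls,
           gene_sets = list(attractor = attractor_all,
                            attractor_core = cls$gene_sets$attractor,
                            pseudo_attractor = cls$gene_sets$pseudo_attractor,
                            non_attractor = non_attractor,
                            no_response = no_resp,
                            collective_non_attractor = collective,
                            stringent = stringent,
                            fold_change = fold_set),
           pca = pca, grouping = grouping, venn = venn,
           summary = summary),
      class = "PipelineResult"
    )
    if (!is.null(output_dir)) write_report(result, output_dir)
    result
  })
}

#' @export
print.PipelineResult <- function(x, ...) {
  s <- x$summary
  cat("PipelineResult\n")
  cat(sprintf("  genes: %d input -> %d above threshold -> %d analysed\n",
              s$n_input_genes, s$n_retained, s$n_analysed))
  cat(sprintf("  elements: %d (%d above / %d in / %d below basin)\n",
              s$n_elements, s$n_elements_above, s$n_elements_in,
              s$n_elements_below))
  cat(sprintf("  attractor %d (core %d + pseudo %d), non-attractor %d,\n",
              s$n_attractor, s$n_attractor_core, s$n_pseudo_attractor,
              s$n_non_attractor))
  cat(sprintf("  no-response %d, collective non-attractor %d (%d%% attractor)\n",
              s$n_no_response, s$n_collective_non_attractor,
              s$pct_attractor))
  invisible(x)
}

#' Write pipeline stage outputs and the JSON summary
#'
#' Writes the gene sets, element table, whole-transcriptome trajectory,
#' correlation series and boundary polyline as TSV plus the machine-
#' readable summary as `summary.json` in `output_dir`.
#'
#' @param result A [run_pipeline()] result.
#' @param output_dir Directory to write into (created if needed).
#' @return Invisibly, the path of the JSON summary.
#' @export
write_report <- function(result, output_dir) {
  stopifnot(inherits(result, "PipelineResult"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(output_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$series, "correlation_series.tsv")
  wt(result$whole_trajectory, "whole_trajectory.tsv")
  wt(data.frame(element = seq_along(result$classification$element_labels),
                label = result$classification$element_labels,
                distance = result$classification$element_distances),
     "elements.tsv")
  wt(data.frame(rv = result$boundary$x, miv = result$boundary$y),
     "boundary.tsv")
  for (nm in names(result$gene_sets)) {
    wt(data.frame(gene_id = result$gene_sets[[nm]]),
       paste0("genes_", nm, ".tsv"))
  }
  path <- file.path(output_dir, "summary.json")
  jsonlite::write_json(result$summary, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
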