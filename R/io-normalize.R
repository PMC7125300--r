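#' Read a count/expression table with its sample design
#'
#' The table must have gene identifiers in the first column and one column
#' per sample; the design file must cover every sample column with
#' `sample_id`, `time_min` and `replicate`. Separator is inferred from the
#' file extension (`.csv` is comma, anything else tab).
#'
#' @param table_path Path to the TSV/CSV expression table.
#' @param design_path Path to the TSV/CSV design table.
#' @param unit Unit of the stored values (`"counts"` or `"TPM"`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(table_path, design_path,
                            unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  sep_for <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(table_path, header = TRUE, sep = sep_for(table_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a gene column plus samples")
  gene_ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in table")
  if (anyNA(values)) stop("missing values in expression table")
  rownames(values) <- gene_ids
  design <- utils::read.table(design_path, header = TRUE,
                              sep = sep_for(design_path),
                              check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(values, design, unit = unit, gene_ids = gene_ids)
}

#' Read a two-column gene-length table
#'
#' @param path TSV/CSV with gene identifiers in column 1 and lengths in
#'   bases in column 2.
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Transcripts-per-million normalisation
#'
#' Per sample, counts are first converted to per-kilobase rates
#' `count / (length/1000)` and then scaled so that each sample column sums
#' to one million.
#'
#' @param counts An `ExpressionMatrix` with `unit = "counts"`.
#' @param gene_lengths Named vector of positive gene lengths in bases
#'   covering every gene of `counts`.
#' @return An `ExpressionMatrix` with `unit = "TPM"`; every column sums to
#'   `1e6` (up to floating-point error).
#' @export
tpm_normalize <- function(counts, gene_lengths) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "counts") stop("input must be in counts")
  lens <- gene_lengths[counts$gene_ids]
  if (anyNA(lens)) {
    stop("gene lengths missing for some genes")
  }
  if (any(lens <= 0)) stop("gene lengths must be positive")
  rate <- counts$values / (lens / 1000)
  totals <- colSums(rate)
  if (any(totals <= 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(rate)[totals <= 0], collapse = ", "))
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  expression_matrix(tpm, counts$design, unit = "TPM",
                    gene_ids = counts$gene_ids)
}

#' Drop lowly expressed genes
#'
#' Keeps genes whose summary expression across all samples exceeds the
#' threshold. The default summary is the mean over all samples (all times
#' and replicates); `min` and `max` are available for stricter or more
#' permissive filtering.
#'
#' @param tpm An `ExpressionMatrix` in TPM.
#' @param threshold Expression threshold in TPM (default 5).
#' @param rule Summary rule across samples: `"mean"` (default), `"min"`
#'   or `"max"`.
#' @return The filtered `ExpressionMatrix`. A filter report (counts
#'   retained/removed, rule, threshold) is attached as attribute
#'   `"filter_report"`.
#' @export
filter_low_expression <- function(tpm, threshold = 5,
                                  rule = c("mean", "min", "max")) {
  stopifnot(inherits(tpm, "ExpressionMatrix"))
  rule <- match.arg(rule)
  if (threshold < 0) stop("threshold must be non-negative")
  summ <- switch(rule,
                 mean = rowMeans(tpm$values),
                 min = apply(tpm$values, 1, min),
                 max = apply(tpm$values, 1, max))
  keep <- summ > threshold
  out <- subset_genes(tpm, tpm$gene_ids[keep])
  attr(out, "filter_report") <- list(
    threshold = threshold, rule = rule,
    retained = sum(keep), removed = sum(!keep),
    removed_ids = tpm$gene_ids[!keep])
  out
}

#' Remove the top expressed genes
#'
#' Drops the `k` genes with the highest overall expression, where "highest
#' expressed" is by default the maximum TPM over all samples (extreme
#' single-sample outliers count), optionally the mean.
#'
#' @param tpm An `ExpressionMatrix` in TPM.
#' @param k Number of genes to drop (default 2).
#' @param statistic `"max"` (default) or `"mean"` across samples.
#' @return The reduced `ExpressionMatrix`, with the dropped identifiers in
#'   attribute `"dropped_ids"`.
#' @export
remove_top_expressed <- function(tpm, k = 2, statistic = c("max", "mean")) {
  stopifnot(inherits(tpm, "ExpressionMatrix"))
  statistic <- match.arg(statistic)
  if (k < 0) stop("k must be non-negative")
  if (k >= nrow(tpm$values)) stop("k must be smaller than the gene count")
  if (k == 0) {
    attr(tpm, "dropped_ids") <- character(0)
    return(tpm)
  }
  stat <- switch(statistic,
                 max = apply(tpm$values, 1, max),
                 mean = rowMeans(tpm$values))
  ord <- order(-stat, tpm$gene_ids)
  drop <- tpm$gene_ids[ord[seq_len(k)]]
  out <- subset_genes(tpm, setdiff(tpm$gene_ids, drop))
  attr(out, "dropped_ids") <- drop
  out
}
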