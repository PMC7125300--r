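#' Expression matrix with attached sample design
#'
#' A light container for a genes x samples numeric table together with the
#' sample design (time point in minutes and replicate label per sample).
#' All downstream operations in the package consume and return this class.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#'   Row names (or `gene_ids`) identify genes; column names must match
#'   `design$sample_id`.
#' @param design Data frame with columns `sample_id`, `time_min`,
#'   `replicate`; one row per sample column of `values`.
#' @param unit Either `"counts"` or `"TPM"`.
#' @param gene_ids Optional character vector of gene identifiers
#'   (defaults to `rownames(values)`).
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `unit` and `design`.
#' @export
expression_matrix <- function(values, design, unit = c("counts", "TPM"),
                              gene_ids = rownames(values)) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (anyNA(values)) {
    stop("expression values contain missing entries")
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative")
  }
  if (is.null(gene_ids)) {
    stop("gene identifiers are required (row names or `gene_ids`)")
  }
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(utils::head(gene_ids[duplicated(gene_ids)], 3), collapse = ", "))
  }
  rownames(values) <- gene_ids

  design <- as.data.frame(design, stringsAsFactors = FALSE)
  needed <- c("sample_id", "time_min", "replicate")
  if (!all(needed %in% names(design))) {
    stop("design needs columns: ", paste(needed, collapse = ", "))
  }
  design$sample_id <- as.character(design$sample_id)
  design$replicate <- as.character(design$replicate)
  if (is.null(colnames(values))) {
    stop("sample columns must be named")
  }
  missing_design <- setdiff(colnames(values), design$sample_id)
  if (length(missing_design)) {
    stop("samples absent from design: ",
         paste(missing_design, collapse = ", "))
  }
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  if (anyDuplicated(design[, c("time_min", "replicate")])) {
    stop("each (time, replicate) pair may occur only once in the design")
  }

  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = colnames(values),
         unit = unit, design = design),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat(sprintf("  time points (min): %s\n",
              paste(sort(unique(x$design$time_min)), collapse = ", ")))
  cat(sprintf("  replicates: %s\n",
              paste(sort(unique(x$design$replicate)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Time points of an expression matrix
#'
#' @param expr An `ExpressionMatrix`.
#' @return Sorted unique time points in minutes.
#' @export
time_points <- function(expr) sort(unique(expr$design$time_min))

#' Replicate labels of an expression matrix
#'
#' @param expr An `ExpressionMatrix`.
#' @return Sorted unique replicate labels.
#' @export
replicates <- function(expr) sort(unique(expr$design$replicate))

#' Restrict an expression matrix to a gene subset
#'
#' @param expr An `ExpressionMatrix`.
#' @param genes Character vector of gene identifiers to keep (order kept).
#' @return An `ExpressionMatrix` with only the requested genes.
#' @export
subset_genes <- function(expr, genes) {
  genes <- as.character(genes)
  missing <- setdiff(genes, expr$gene_ids)
  if (length(missing)) {
    stop("genes not present in matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  expression_matrix(expr$values[genes, , drop = FALSE], expr$design,
                    unit = expr$unit, gene_ids = genes)
}

# sample id for a given (time, replicate); NA when absent
sample_for <- function(expr, time_min, replicate) {
  hit <- expr$design$time_min == time_min & expr$design$replicate == replicate
  if (!any(hit)) return(NA_character_)
  expr$design$sample_id[hit][1]
}

#' Replicate-averaged time-course matrix
#'
#' Collapses replicates so each gene is summarised by one value per time
#' point (the mean over replicates measured at that time).
#'
#' @param expr An `ExpressionMatrix`.
#' @return Numeric matrix, genes x time points, columns ordered by time and
#'   named with the time in minutes.
#' @export
time_course_matrix <- function(expr) {
  tps <- time_points(expr)
  out <- vapply(tps, function(tp) {
    cols <- expr$design$sample_id[expr$design$time_min == tp]
    rowMeans(expr$values[, cols, drop = FALSE])
  }, numeric(nrow(expr$values)))
  out <- matrix(out, nrow = nrow(expr$values),
                dimnames = list(expr$gene_ids, tps))
  out
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no-op wrapper).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
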