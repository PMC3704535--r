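#' Expression cohort container
#'
#' Bundles one cohort's gene-by-sample expression matrix with per-sample
#' subtype labels and the measurement-scale dialect. Values are expected on a
#' log2 scale: absolute intensities for one-color platforms
#' (`scale = "absolute"`) or log2 tumor/reference ratios for two-color
#' platforms (`scale = "log_ratio"`). For ratio data, a higher value is taken
#' to mean higher tumor expression.
#'
#' @param cohort_id Single string identifying the cohort.
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). No missing values are allowed; reject
#'   and fix upstream rather than impute.
#' @param subtypes Named character vector mapping every sample id to a subtype
#'   label. Every subtype must have at least two samples.
#' @param scale `"absolute"` or `"log_ratio"`.
#'
#' @return An object of class `expression_cohort`: a list with elements
#'   `cohort_id`, `values`, `subtypes`, `scale`.
#' @export
expression_cohort <- function(cohort_id, values, subtypes, scale = c("absolute", "log_ratio")) {
  scale <- match.arg(scale)
  if (!is.character(cohort_id) || length(cohort_id) != 1L || !nzchar(cohort_id))
    stop("`cohort_id` must be a single non-empty string", call. = FALSE)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite; missing values are not supported", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix (merge probes first)", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("format error: duplicate sample ids", call. = FALSE)
  subtypes <- validate_labels(colnames(values), subtypes)
  structure(
    list(cohort_id = cohort_id, values = values, subtypes = subtypes, scale = scale),
    class = "expression_cohort"
  )
}

validate_labels <- function(sample_ids, subtypes) {
  if (is.null(names(subtypes)) || !is.character(subtypes))
    stop("`subtypes` must be a character vector named by sample id", call. = FALSE)
  missing <- setdiff(sample_ids, names(subtypes))
  if (length(missing) > 0L)
    stop("label error: samples without a subtype label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  subtypes <- subtypes[sample_ids]
  counts <- table(subtypes)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L)
    stop("label error: subtypes with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  subtypes
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort '%s': %d genes x %d samples (%s scale)\n",
              x$cohort_id, nrow(x$values), ncol(x$values), x$scale))
  st <- table(x$subtypes)
  cat("subtypes:", paste(sprintf("%s (n=%d)", names(st), as.integer(st)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' Gene set collection (GMT semantics)
#'
#' @param sets Named list of character vectors of gene ids; duplicate genes
#'   within a set are removed.
#' @param descriptions Optional named character vector of free-text
#'   descriptions, one per set.
#'
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets))
    stop("`sets` must be a named list of character vectors", call. = FALSE)
  if (length(sets) > 0L && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    stop("all gene sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names", call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(vapply(sets, length, 1L) == 0L))
    stop("empty gene sets are not allowed", call. = FALSE)
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- "na"
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, length, 1L)
  cat(sprintf("gene_set_collection: %d sets", length(x$sets)))
  if (length(sizes) > 0L)
    cat(sprintf(" (sizes %d-%d)", min(sizes), max(sizes)))
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Pathway profile container
#'
#' Gene-set by sample matrix of single-sample GSEA enrichment scores. Scores
#' are unitless; positive means the set's genes are coordinately upregulated
#' in that sample.
#'
#' @param scores Numeric matrix, sets in rows, samples in columns.
#' @param alpha Rank weighting exponent used to compute the scores.
#' @param cohort_id Cohort the samples belong to.
#' @param dropped Character vector of set names dropped for insufficient
#'   overlap with the cohort's gene universe.
#'
#' @return An object of class `pathway_profile` (a matrix with attributes).
#' @export
pathway_profile_matrix <- function(scores, alpha, cohort_id = NA_character_, dropped = character()) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (any(!is.finite(scores)))
    stop("pathway profile scores must be finite", call. = FALSE)
  structure(scores, alpha = alpha, cohort_id = cohort_id, dropped = dropped,
            class = c("pathway_profile", "matrix"))
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("pathway_profile: %d sets x %d samples (alpha = %g)\n",
              nrow(x), ncol(x), attr(x, "alpha")))
  if (length(attr(x, "dropped")) > 0L)
    cat("dropped sets:", paste(attr(x, "dropped"), collapse = ", "), "\n")
  invisible(x)
}
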