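#' Merge probe-level rows to gene level by averaging
#'
#' Rows of a probe-by-sample matrix mapping to the same gene are collapsed to
#' their arithmetic mean, per sample. Every probe must be mapped.
#'
#' @param probe_matrix Numeric matrix with probe ids as rownames.
#' @param probe_map Named character vector (probe id -> gene id) or a
#'   two-column data frame (probe_id, gene_id).
#' @return Gene-by-sample numeric matrix, rows sorted by gene id.
#' @export
merge_probes_by_gene <- function(probe_matrix, probe_map) {
  stopifnot(is.matrix(probe_matrix), is.numeric(probe_matrix))
  if (is.data.frame(probe_map))
    probe_map <- stats::setNames(as.character(probe_map[[2L]]), as.character(probe_map[[1L]]))
  probes <- rownames(probe_matrix)
  unmapped <- setdiff(probes, names(probe_map))
  if (length(unmapped) > 0L)
    stop("mapping error: unmapped probes: ", paste(head(unmapped, 5L), collapse = ", "),
         call. = FALSE)
  genes <- probe_map[probes]
  sums <- rowsum(probe_matrix, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Median-center every gene within a cohort
#'
#' Subtracts from each gene row its median across the cohort's samples, so
#' every row has median zero. Applied per cohort, to both scale dialects.
#' Idempotent.
#'
#' @param cohort An [expression_cohort()] or a numeric matrix.
#' @return Same type as the input, centered.
#' @export
median_center_genes <- function(cohort) {
  if (is.matrix(cohort)) {
    med <- apply(cohort, 1L, median)
    return(cohort - med)
  }
  stopifnot(inherits(cohort, "expression_cohort"))
  cohort$values <- median_center_genes(cohort$values)
  cohort
}

#' Intersect gene universes across cohorts
#'
#' Builds the common gene set across cohorts, excluding (greedily, in input
#' order) any cohort whose overlap with the running intersection falls below
#' `min_common`. Exclusions are recorded with reason
#' `"insufficient_common_genes"`.
#'
#' @param cohorts List of [expression_cohort()] objects (>= 2).
#' @param min_common Minimum acceptable common-gene count for a cohort to be
#'   kept (default 5000, the scale of overlap between mainstream microarray
#'   platforms).
#' @return A `common_gene_index`: list with `cohorts_included`, `genes`
#'   (sorted), and `excluded` (data frame of cohort_id, reason).
#' @export
intersect_genes <- function(cohorts, min_common = 5000L) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2L)
  ids <- vapply(cohorts, function(x) x$cohort_id, "")
  universes <- lapply(cohorts, function(x) rownames(x$values))
  included <- character()
  excluded <- character()
  common <- NULL
  for (i in seq_along(cohorts)) {
    candidate <- if (is.null(common)) universes[[i]] else intersect(common, universes[[i]])
    if (!is.null(common) && length(candidate) < min_common) {
      excluded <- c(excluded, ids[i])
      warning(sprintf("cohort '%s' excluded: only %d common genes (< %d)",
                      ids[i], length(candidate), min_common), call. = FALSE)
      next
    }
    common <- candidate
    included <- c(included, ids[i])
  }
  if (length(included) < 2L || length(common) == 0L)
    stop("pipeline error: fewer than 2 cohorts share a usable gene universe", call. = FALSE)
  structure(
    list(cohorts_included = included,
         genes = sort(common),
         excluded = data.frame(cohort_id = excluded,
                               reason = rep("insufficient_common_genes", length(excluded)),
                               stringsAsFactors = FALSE)),
    class = "common_gene_index"
  )
}

#' @export
print.common_gene_index <- function(x, ...) {
  cat(sprintf("common_gene_index: %d genes across %d cohorts\n",
              length(x$genes), length(x$cohorts_included)))
  if (nrow(x$excluded) > 0L)
    cat("excluded:", paste(x$excluded$cohort_id, collapse = ", "), "\n")
  invisible(x)
}
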