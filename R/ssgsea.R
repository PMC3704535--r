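#' Single-sample GSEA enrichment score for one sample and one gene set
#'
#' Genes are ranked by decreasing expression (ties broken by gene id order).
#' Walking down the ranked list, the score accumulates the difference between
#' the weighted cumulative distribution of in-set genes and the cumulative
#' fraction of out-of-set genes:
#' \deqn{score = \sum_j P_{in}(j) - P_{out}(j)}
#' where in-set gene i carries weight \eqn{|x_i|^\alpha} (all weights 1 at
#' \eqn{\alpha = 0}). Positive scores mean the set's genes are coordinately
#' upregulated in the sample.
#'
#' @param expr Named numeric vector of one sample's expression values.
#' @param gene_set Character vector of gene ids.
#' @param alpha Weighting exponent (>= 0). Default 0.25, the conventional
#'   ssGSEA weight.
#' @return Single numeric enrichment score.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  genes <- names(expr)
  if (is.null(genes)) stop("`expr` must be named by gene id", call. = FALSE)
  in_set <- genes %in% gene_set
  k <- sum(in_set)
  n <- length(expr)
  if (k == 0L) stop("gene set has no overlap with the expression vector", call. = FALSE)
  if (k == n) stop("degenerate-set error: gene set covers every gene", call. = FALSE)
  ord <- order(-expr, genes)
  hit <- in_set[ord]
  w <- if (alpha > 0) abs(expr[ord])^alpha else rep(1, n)
  p_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  p_out <- cumsum(!hit) / (n - k)
  sum(p_in - p_out)
}

#' Pathway profile: ssGSEA scores for every set and sample
#'
#' Computes the single-sample enrichment score of every retained gene set in
#' every sample of a cohort. Sets with fewer than `min_set_size` genes present
#' in the expression matrix are dropped (recorded in the `dropped` attribute).
#'
#' Scores are identical to looping [ssgsea_score()] but computed through a
#' closed form: an in-set gene at rank position p contributes its normalized
#' weight to all positions from p onward, so the summed in-set cumulative
#' distribution is \eqn{\sum_i w_i (n - p_i + 1) / W} and the out-of-set term
#' follows from the total \eqn{n(n+1)/2}.
#'
#' @param x An [expression_cohort()] or a genes-by-samples numeric matrix.
#' @param collection A [gene_set_collection()].
#' @param alpha Weighting exponent, default 0.25.
#' @param min_set_size Minimum surviving set size, default 5.
#' @return A [pathway_profile_matrix()] (sets x samples).
#' @export
pathway_profile <- function(x, collection, alpha = 0.25, min_set_size = 5L) {
  mat <- if (inherits(x, "expression_cohort")) x$values else x
  cohort_id <- if (inherits(x, "expression_cohort")) x$cohort_id else NA_character_
  stopifnot(is.matrix(mat), is.numeric(mat))
  genes <- rownames(mat)
  n <- length(genes)
  idx <- lapply(collection$sets, function(s) which(genes %in% s))
  sizes <- vapply(idx, length, 1L)
  keep <- sizes >= min_set_size & sizes < n
  dropped <- names(idx)[!keep]
  if (length(dropped) > 0L)
    warning("sets dropped (too few overlapping genes or degenerate): ",
            paste(head(dropped, 10L), collapse = ", "), call. = FALSE)
  idx <- idx[keep]
  if (length(idx) == 0L)
    stop("pipeline error: every gene set was dropped", call. = FALSE)

  scores <- matrix(NA_real_, length(idx), ncol(mat),
                   dimnames = list(names(idx), colnames(mat)))
  total_pos <- n * (n + 1) / 2
  for (j in seq_len(ncol(mat))) {
    xj <- mat[, j]
    ord <- order(-xj, genes)
    pos <- integer(n)
    pos[ord] <- seq_len(n)               # rank position of each gene row
    wj <- if (alpha > 0) abs(xj)^alpha else rep(1, n)
    tail_len <- n - pos + 1
    for (s in seq_along(idx)) {
      i <- idx[[s]]
      k <- length(i)
      w <- wj[i]
      sum_in <- sum(w * tail_len[i]) / sum(w)
      sum_out <- (total_pos - sum(tail_len[i])) / (n - k)
      scores[s, j] <- sum_in - sum_out
    }
  }
  pathway_profile_matrix(scores, alpha = alpha, cohort_id = cohort_id, dropped = dropped)
}
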