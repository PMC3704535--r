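#' Spearman rank correlation of two profiles
#'
#' Pearson correlation of the average-rank vectors (ties receive average
#' ranks). Errors on constant input, where the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("undefined-correlation error: constant vector has zero rank variance", call. = FALSE)
  cor(rx, ry)
}

#' Between-sample Spearman correlation across two cohorts
#'
#' Correlates every sample of cohort A with every sample of cohort B on their
#' common features: genes for the transcriptional profile, gene-set scores for
#' the pathway profile. Output rows/columns are grouped by subtype, then
#' sample id, for display.
#'
#' @param a,b [expression_cohort()] objects, or plain features-by-samples
#'   matrices for pathway profiles. `b` may equal `a` for the within-cohort
#'   map.
#' @param features Character vector of common feature ids to use.
#' @param profile_kind `"transcriptional"` or `"pathway"` (metadata only).
#' @param labels_a,labels_b Named subtype vectors; taken from the cohorts when
#'   omitted.
#' @return A `correlation_map`: rho matrix (samples of `a` x samples of `b`)
#'   with `profile_kind` attribute.
#' @export
cross_cohort_correlation <- function(a, b, features, profile_kind = c("transcriptional", "pathway"),
                                     labels_a = NULL, labels_b = NULL) {
  profile_kind <- match.arg(profile_kind)
  ma <- if (inherits(a, "expression_cohort")) a$values else a
  mb <- if (inherits(b, "expression_cohort")) b$values else b
  if (is.null(labels_a) && inherits(a, "expression_cohort")) labels_a <- a$subtypes
  if (is.null(labels_b) && inherits(b, "expression_cohort")) labels_b <- b$subtypes
  features <- intersect(features, intersect(rownames(ma), rownames(mb)))
  if (length(features) < 3L)
    stop("pipeline error: fewer than 3 common features", call. = FALSE)
  ca <- order_by_subtype(colnames(ma), labels_a)
  cb <- order_by_subtype(colnames(mb), labels_b)
  rho <- cor(ma[features, ca, drop = FALSE], mb[features, cb, drop = FALSE],
             method = "spearman")
  structure(rho, profile_kind = profile_kind,
            subtype_row_order = if (!is.null(labels_a)) labels_a[ca],
            subtype_col_order = if (!is.null(labels_b)) labels_b[cb],
            class = c("correlation_map", "matrix"))
}

order_by_subtype <- function(sample_ids, labels) {
  if (is.null(labels)) return(sort(sample_ids))
  sample_ids[order(labels[sample_ids], sample_ids)]
}

#' Median between-subtype Spearman correlation across cohorts
#'
#' Summarises sample-level Spearman correlations into one number per subtype
#' pair: the median rho over all sample pairs with one sample in each subtype.
#' Subtypes are keyed `(cohort, subtype)`. Entries between subtypes of
#' different cohorts use cross-cohort sample pairs; entries between subtypes
#' of the same cohort use within-cohort pairs. The diagonal is the median over
#' distinct within-subtype pairs (self-correlations excluded).
#'
#' @param profiles Named list (by cohort id) of features-by-samples matrices,
#'   already restricted/alignable to common features (genes for the
#'   transcriptional profile, set names for the pathway profile).
#' @param labels Named list (by cohort id) of subtype label vectors, named by
#'   sample id.
#' @param features Optional feature ids to restrict to; defaults to the
#'   intersection of all profiles' rownames.
#' @return A `subtype_similarity`: list with `subtypes` (data frame of
#'   cohort_id, subtype), `median_rho` and `n_pairs` matrices.
#' @export
subtype_median_correlation <- function(profiles, labels, features = NULL) {
  stopifnot(is.list(profiles), is.list(labels),
            !is.null(names(profiles)), all(names(profiles) %in% names(labels)))
  cohorts <- names(profiles)
  if (is.null(features))
    features <- Reduce(intersect, lapply(profiles, rownames))
  if (length(features) < 3L)
    stop("pipeline error: fewer than 3 common features across cohorts", call. = FALSE)

  # drop subtypes with < 2 samples (medians would rest on single pairs)
  keys <- list()
  for (cid in cohorts) {
    lab <- labels[[cid]]
    lab <- lab[intersect(names(lab), colnames(profiles[[cid]]))]
    counts <- table(lab)
    small <- names(counts)[counts < 2L]
    if (length(small) > 0L)
      warning(sprintf("cohort '%s': subtypes with < 2 samples excluded: %s",
                      cid, paste(small, collapse = ", ")), call. = FALSE)
    for (st in sort(names(counts)[counts >= 2L]))
      keys[[length(keys) + 1L]] <- list(cohort = cid, subtype = st,
                                        samples = names(lab)[lab == st])
  }
  m <- length(keys)
  if (m < 2L) stop("pipeline error: fewer than 2 usable subtypes", call. = FALSE)

  maps <- list()  # per cohort pair, computed lazily
  map_for <- function(c1, c2) {
    key <- paste(c1, c2, sep = "\r")
    if (is.null(maps[[key]])) {
      rho <- cor(profiles[[c1]][features, , drop = FALSE],
                 profiles[[c2]][features, , drop = FALSE], method = "spearman")
      maps[[key]] <<- rho
    }
    maps[[key]]
  }

  med <- matrix(NA_real_, m, m)
  npairs <- matrix(0L, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      ki <- keys[[i]]; kj <- keys[[j]]
      rho <- map_for(ki$cohort, kj$cohort)[ki$samples, kj$samples, drop = FALSE]
      if (i == j) {
        vals <- rho[upper.tri(rho)]      # distinct unordered pairs, no self-pairs
      } else {
        vals <- as.vector(rho)           # all (a, b) pairs, a in i, b in j
      }
      med[i, j] <- med[j, i] <- median(vals)
      npairs[i, j] <- npairs[j, i] <- length(vals)
    }
  }
  key_df <- data.frame(cohort_id = vapply(keys, `[[`, "", "cohort"),
                       subtype = vapply(keys, `[[`, "", "subtype"),
                       n_samples = vapply(keys, function(k) length(k$samples), 1L),
                       stringsAsFactors = FALSE)
  lab <- paste(key_df$cohort_id, key_df$subtype, sep = ".")
  dimnames(med) <- dimnames(npairs) <- list(lab, lab)
  structure(list(subtypes = key_df, median_rho = med, n_pairs = npairs),
            class = "subtype_similarity")
}

#' @export
print.subtype_similarity <- function(x, ...) {
  cat(sprintf("subtype_similarity: %d subtypes across %d cohorts\n",
              nrow(x$subtypes), length(unique(x$subtypes$cohort_id))))
  print(round(x$median_rho, 3))
  invisible(x)
}
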