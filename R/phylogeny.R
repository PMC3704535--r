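#' Convert a subtype similarity to a dissimilarity matrix
#'
#' The median between-subtype Spearman correlation is subtracted from 1, so
#' entries lie in \[0, 2\]; the diagonal is set to 0 for clustering.
#'
#' @param similarity A `subtype_similarity` from
#'   [subtype_median_correlation()], or a symmetric correlation matrix.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
to_dissimilarity <- function(similarity) {
  rho <- if (inherits(similarity, "subtype_similarity")) similarity$median_rho else similarity
  stopifnot(is.matrix(rho))
  if (any(rho < -1 - 1e-9 | rho > 1 + 1e-9, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering with deterministic tie-breaking
#'
#' UPGMA-style agglomeration: at every step the pair of clusters with the
#' smallest average inter-cluster dissimilarity is merged, at a height equal
#' to that average. Exact ties are broken by the lexicographically smallest
#' pair of cluster labels (a cluster is labelled by its smallest leaf label),
#' so the tree does not depend on input order.
#'
#' @param d Symmetric non-negative dissimilarity matrix with zero diagonal and
#'   labelled rows, or a `dist` object.
#' @return A `subtype_tree`, which is also a valid `hclust` object (`merge`,
#'   `height`, `order`, `labels`, `method = "average"`).
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  if (any(!is.finite(d))) stop("non-finite dissimilarities", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(d < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))

  act <- seq_len(n)                  # active cluster slots
  size <- rep(1L, n)
  node <- -seq_len(n)                # hclust ids: negative leaf, positive merge
  clab <- labels                     # cluster label = smallest member leaf label
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in (ii + 1L):length(act)) {
        a <- act[ii]; b <- act[jj]
        dd <- D[a, b]
        pair <- sort(c(clab[a], clab[b]))
        if (is.null(best) || dd < best$d - 1e-15 ||
            (abs(dd - best$d) <= 1e-15 &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(d = dd, i = a, j = b, pair = pair)
        }
      }
    }
    a <- best$i; b <- best$j
    merge[step, ] <- sort(c(node[a], node[b]))   # hclust convention: leaves first
    height[step] <- best$d
    # Lance-Williams update for average linkage
    for (k in act) {
      if (k == a || k == b) next
      D[a, k] <- D[k, a] <- (size[a] * D[a, k] + size[b] * D[b, k]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    node[a] <- step
    clab[a] <- min(clab[a], clab[b])
    act <- act[act != b]
  }

  tree <- list(merge = merge, height = height, order = integer(0),
               labels = labels, method = "average",
               call = match.call(), dist.method = "1 - median spearman rho")
  tree$order <- dendro_order(merge, n)
  class(tree) <- c("subtype_tree", "hclust")
  tree
}

dendro_order <- function(merge, n) {
  leaves <- function(i) {
    if (i < 0L) return(-i)
    c(leaves(merge[i, 1L]), leaves(merge[i, 2L]))
  }
  leaves(n - 1L)
}

#' Build the subtype phylogeny from a similarity object
#'
#' Convenience wrapper: converts the median-correlation similarity to the
#' 1 - rho dissimilarity and clusters it with average linkage.
#'
#' @param similarity A `subtype_similarity`.
#' @return A `subtype_tree`.
#' @export
subtype_phylogeny <- function(similarity) {
  average_linkage(to_dissimilarity(similarity))
}

#' Merge table of a subtype tree
#'
#' @param tree A `subtype_tree` (or `hclust`).
#' @return Data frame with one row per merge: the two children (leaf labels or
#'   `node<k>` for earlier merges) and the merge height.
#' @export
merge_table <- function(tree) {
  child_name <- function(i) if (i < 0L) tree$labels[-i] else paste0("node", i)
  data.frame(
    step = seq_along(tree$height),
    left = vapply(tree$merge[, 1L], child_name, ""),
    right = vapply(tree$merge[, 2L], child_name, ""),
    height = tree$height,
    stringsAsFactors = FALSE
  )
}
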