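#' Cluster samples by their pathway profiles
#'
#' Hierarchical clustering of the columns of a pooled sets-by-samples score
#' matrix, using `1 - Spearman rho` between sample score vectors as the
#' dissimilarity and average linkage (via [average_linkage()], with its
#' deterministic tie-breaking). Scores are used raw, without rescaling.
#' Constant columns, whose correlation is undefined, are dropped with a
#' warning.
#'
#' @param pathway_matrix Sets-by-samples numeric matrix (e.g. several
#'   [pathway_profile()] results bound by column).
#' @return A `subtype_tree` over the sample columns.
#' @export
cluster_columns <- function(pathway_matrix) {
  stopifnot(is.matrix(pathway_matrix), ncol(pathway_matrix) >= 2L)
  const <- apply(pathway_matrix, 2L, function(x) diff(range(x)) == 0)
  if (any(const)) {
    warning("constant score columns dropped (undefined correlation): ",
            paste(head(colnames(pathway_matrix)[const], 5L), collapse = ", "),
            call. = FALSE)
    pathway_matrix <- pathway_matrix[, !const, drop = FALSE]
    if (ncol(pathway_matrix) < 2L)
      stop("pipeline error: fewer than 2 non-constant samples", call. = FALSE)
  }
  d <- 1 - cor(pathway_matrix, method = "spearman")
  diag(d) <- 0
  average_linkage(d)
}

#' Split a dendrogram into its two root branches
#'
#' Cuts the tree at the root: the two children of the final merge define the
#' two groups. The group containing the lexicographically smallest sample id
#' is labelled `K1`.
#'
#' @param tree A `subtype_tree` / `hclust` over samples.
#' @return Named character vector (sample id -> `"K1"` or `"K2"`).
#' @export
split_two <- function(tree) {
  n <- length(tree$labels)
  stopifnot(n >= 2L)
  root <- nrow(tree$merge)
  members <- function(i) {
    if (i < 0L) return(-i)
    c(members(tree$merge[i, 1L]), members(tree$merge[i, 2L]))
  }
  left <- tree$labels[members(tree$merge[root, 1L])]
  right <- tree$labels[members(tree$merge[root, 2L])]
  groups <- c(stats::setNames(rep("K1", length(left)), left),
              stats::setNames(rep("K2", length(right)), right))
  if (min(right) < min(left)) {
    groups[] <- ifelse(groups == "K1", "K2", "K1")
  }
  groups[order(names(groups))]
}

#' Per-subtype overrepresentation in a two-group split
#'
#' For every subtype, tests independence of subtype membership and group
#' membership in the 2x2 table (this subtype vs others) x (K1 vs K2) with
#' Pearson's chi-squared test without continuity correction. When any expected
#' cell count falls below 5 the test switches to Fisher's exact test and is
#' flagged in the `method` column. The enriched group is the one where the
#' subtype's observed count exceeds its expectation.
#'
#' @param groups Named vector (sample id -> `"K1"`/`"K2"`) from [split_two()].
#' @param labels Named vector (sample id -> subtype); keys may be
#'   `(cohort, subtype)` composites when cohorts are pooled.
#' @return A `group_split` data frame: subtype, n, in_k1, in_k2, statistic,
#'   p_value, enriched_group, method.
#' @export
subtype_enrichment <- function(groups, labels) {
  samples <- names(groups)
  missing <- setdiff(samples, names(labels))
  if (length(missing) > 0L)
    stop("label error: samples without a subtype label: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  labels <- labels[samples]
  out <- lapply(sort(unique(labels)), function(st) {
    tab <- table(factor(labels == st, levels = c(TRUE, FALSE)),
                 factor(groups, levels = c("K1", "K2")))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      warning(sprintf("subtype '%s': degenerate 2x2 table, test skipped", st),
              call. = FALSE)
      return(data.frame(subtype = st, n = sum(labels == st),
                        in_k1 = tab[1L, 1L], in_k2 = tab[1L, 2L],
                        statistic = NA_real_, p_value = NA_real_,
                        enriched_group = NA_character_, method = "skipped",
                        stringsAsFactors = FALSE))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ht <- fisher.test(tab)
      stat <- NA_real_
      method <- "fisher"
    } else {
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      stat <- unname(ht$statistic)
      method <- "chisq"
    }
    data.frame(subtype = st, n = sum(labels == st),
               in_k1 = tab[1L, 1L], in_k2 = tab[1L, 2L],
               statistic = stat, p_value = ht$p.value,
               enriched_group = if (tab[1L, 1L] > expected[1L, 1L]) "K1" else "K2",
               method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("group_split", "data.frame")
  out
}
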