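#' Signal-to-noise differential expression metric
#'
#' Per gene: `(mean_in - mean_rest) / (sd_in + sd_rest)` with the conventional
#' variance stabilization: each class sd is floored at `0.2 * |class mean|`,
#' and set to 0.2 outright when both the sd and the mean are zero, so constant
#' genes cannot produce infinite metrics. Intended for absolute-scale cohorts.
#'
#' @param values Genes-by-samples numeric matrix.
#' @param in_class Logical vector over samples: TRUE for the subtype of
#'   interest, FALSE for the rest. Both classes need >= 2 samples.
#' @return Named numeric vector of per-gene metrics.
#' @export
signal_to_noise <- function(values, in_class) {
  stopifnot(is.matrix(values), length(in_class) == ncol(values))
  if (sum(in_class) < 2L || sum(!in_class) < 2L)
    stop("signal-to-noise needs >= 2 samples per class", call. = FALSE)
  m1 <- rowMeans(values[, in_class, drop = FALSE])
  m0 <- rowMeans(values[, !in_class, drop = FALSE])
  s1 <- apply(values[, in_class, drop = FALSE], 1L, sd)
  s0 <- apply(values[, !in_class, drop = FALSE], 1L, sd)
  (m1 - m0) / (s2n_floor(s1, m1) + s2n_floor(s0, m0))
}

s2n_floor <- function(s, m) {
  s <- pmax(s, 0.2 * abs(m))
  s[s == 0] <- 0.2                       # both sd and mean zero
  s
}

#' Difference of class means
#'
#' Per-gene `mean_in - mean_rest`, the fold-change metric for log-ratio
#' cohorts where a signal-to-noise denominator is not meaningful.
#'
#' @inheritParams signal_to_noise
#' @return Named numeric vector of per-gene metrics.
#' @export
class_mean_difference <- function(values, in_class) {
  stopifnot(is.matrix(values), length(in_class) == ncol(values))
  if (sum(in_class) < 1L || sum(!in_class) < 1L)
    stop("both classes must be non-empty", call. = FALSE)
  rowMeans(values[, in_class, drop = FALSE]) - rowMeans(values[, !in_class, drop = FALSE])
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Genes are ordered by decreasing metric (ties broken by gene id). Walking
#' the ranked list, in-set genes increment the running sum by their weight
#' `|metric|^p` (normalized by the total in-set weight) and out-of-set genes
#' decrement it by `1/(N - |S|)`. The enrichment score is the running-sum
#' value of maximal absolute deviation, signed; when the positive and negative
#' extremes tie in magnitude the positive one is reported.
#'
#' @param metric Named numeric vector of per-gene metric values (any order).
#' @param gene_set Character vector of gene ids.
#' @param weight_p Hit weight exponent; 1 is the classic weighted statistic,
#'   0 the unweighted Kolmogorov-Smirnov form.
#' @return List with `es`, `running` (the running sum over ranked positions),
#'   and `ranked` (gene ids in walk order).
#' @export
enrichment_score <- function(metric, gene_set, weight_p = 1) {
  genes <- names(metric)
  if (is.null(genes)) stop("`metric` must be named by gene id", call. = FALSE)
  in_set <- genes %in% gene_set
  k <- sum(in_set)
  n <- length(metric)
  if (k == 0L) stop("gene set has no overlap with the ranked list", call. = FALSE)
  if (k == n) stop("degenerate error: gene set covers every gene", call. = FALSE)
  ord <- order(-metric, genes)
  hit <- in_set[ord]
  w <- abs(metric[ord])^weight_p
  tot <- sum(w[hit])
  inc <- if (tot > 0) w * hit / tot else hit / k
  running <- cumsum(ifelse(hit, inc, -1 / (n - k)))
  maxdev <- max(running)
  mindev <- min(running)
  # positive deviation wins when |max| and |min| tie (to within float noise)
  es <- if (maxdev + mindev >= -1e-12 * (maxdev - mindev)) maxdev else mindev
  list(es = unname(es), running = unname(running), ranked = genes[ord])
}

#' One-vs-rest GSEA with phenotype-permutation null for every subtype
#'
#' For each subtype of a cohort, genes are scored against all other samples of
#' the same cohort (signal-to-noise for absolute-scale cohorts, difference of
#' class means for log-ratio cohorts), each gene set gets a weighted KS
#' enrichment score, and significance is assessed against `n_perm` label
#' permutations of the one-vs-rest phenotype:
#' \itemize{
#'   \item NES = ES / mean(|null ES| of matching sign), per set;
#'   \item nominal p = fraction of matching-sign null ES at least as extreme;
#'   \item FDR q = ratio of tail fractions of the sign-separated null and
#'     observed NES pools across all sets of the run, made monotone in NES by
#'     a running minimum and capped at 1.
#' }
#'
#' @param cohort An [expression_cohort()]. GSEA runs on the cohort's own
#'   (uncentered) values; centering is irrelevant for the class-difference
#'   metrics up to the identical shift of both class means.
#' @param collection A [gene_set_collection()].
#' @param n_perm Number of label permutations (>= 100), default 1000.
#' @param weight_p Hit weight exponent, default 1.
#' @param seed Integer seed; each subtype uses `seed + subtype index` so runs
#'   are reproducible regardless of which subtypes are requested.
#' @param min_set_size Sets with fewer overlapping genes are dropped.
#' @param min_class_size Subtypes smaller than this are skipped with a
#'   warning (hard floor 3; a warning is also issued below 7 where the
#'   permutation null is coarse).
#' @param metric `"auto"` picks by the cohort's scale flag; or force
#'   `"s2n"` / `"mean_diff"`.
#' @return A `gsea_table` data frame: cohort_id, subtype, set_name, size, es,
#'   nes, p_nominal, fdr_q, direction.
#' @export
gsea_one_vs_rest <- function(cohort, collection, n_perm = 1000L, weight_p = 1,
                             seed = 1L, min_set_size = 5L, min_class_size = 3L,
                             metric = c("auto", "s2n", "mean_diff")) {
  stopifnot(inherits(cohort, "expression_cohort"))
  metric <- match.arg(metric)
  if (metric == "auto")
    metric <- if (cohort$scale == "absolute") "s2n" else "mean_diff"
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  min_class_size <- max(min_class_size, 3L)

  X <- cohort$values
  genes <- rownames(X)
  n <- ncol(X)
  set_idx <- lapply(collection$sets, function(s) which(genes %in% s))
  sizes <- vapply(set_idx, length, 1L)
  keep <- sizes >= min_set_size & sizes < length(genes)
  if (any(!keep))
    warning("sets dropped (overlap < min_set_size or degenerate): ",
            paste(head(names(set_idx)[!keep], 10L), collapse = ", "), call. = FALSE)
  set_idx <- set_idx[keep]
  if (length(set_idx) == 0L) stop("pipeline error: every gene set was dropped", call. = FALSE)
  tie_rank <- rank(genes, ties.method = "first")

  subtypes <- sort(unique(cohort$subtypes))
  out <- list()
  for (si in seq_along(subtypes)) {
    st <- subtypes[si]
    in_class <- cohort$subtypes == st
    if (sum(in_class) < min_class_size || sum(!in_class) < min_class_size) {
      warning(sprintf("subtype '%s' skipped: class size below %d", st, min_class_size),
              call. = FALSE)
      next
    }
    if (sum(in_class) < 7L)
      warning(sprintf("subtype '%s' has only %d samples; permutation null is coarse",
                      st, sum(in_class)), call. = FALSE)
    set.seed(seed + si)
    perm <- vapply(seq_len(n_perm), function(i) in_class[sample.int(n)], logical(n))
    metric_mat <- metric_columns(X, cbind(obs = in_class, perm), metric)
    es_mat <- cpp_es_batch(metric_mat, unname(set_idx), weight_p, tie_rank)
    stats <- gsea_stats(es_mat)
    out[[length(out) + 1L]] <- data.frame(
      cohort_id = cohort$cohort_id, subtype = st, set_name = names(set_idx),
      size = vapply(set_idx, length, 1L), stats,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) stop("pipeline error: no subtype large enough for GSEA", call. = FALSE)
  tab <- do.call(rbind, out)
  class(tab) <- c("gsea_table", "data.frame")
  tab
}

# Class means / sds for many phenotype assignments at once via matrix products.
metric_columns <- function(X, indicators, metric) {
  k1 <- sum(indicators[, 1L])
  k0 <- nrow(indicators) - k1
  I <- matrix(as.numeric(indicators), nrow(indicators))
  S1 <- X %*% I
  tot <- rowSums(X)
  M1 <- S1 / k1
  M0 <- (tot - S1) / k0
  if (metric == "mean_diff") return(M1 - M0)
  X2 <- X^2
  S2 <- X2 %*% I
  E1 <- S2 / k1
  E0 <- (rowSums(X2) - S2) / k0
  sd1 <- sqrt(pmax(E1 - M1^2, 0) * k1 / (k1 - 1))
  sd0 <- sqrt(pmax(E0 - M0^2, 0) * k0 / (k0 - 1))
  (M1 - M0) / (s2n_floor(sd1, M1) + s2n_floor(sd0, M0))
}

# NES, nominal p and FDR q from an ES matrix whose first column is observed.
gsea_stats <- function(es_mat) {
  es <- es_mat[, 1L]
  null_es <- es_mat[, -1L, drop = FALSE]

  n_sets <- length(es)
  nes <- numeric(n_sets)
  p_nom <- numeric(n_sets)
  null_nes <- matrix(NA_real_, n_sets, ncol(null_es))
  for (s in seq_len(n_sets)) {
    ns <- null_es[s, ]
    pos <- ns[ns >= 0]
    neg <- ns[ns < 0]
    mpos <- if (length(pos) > 0) mean(pos) else mean(abs(ns))
    mneg <- if (length(neg) > 0) mean(abs(neg)) else mean(abs(ns))
    # per-set normalization of observed and null ES by same-sign null mean
    null_nes[s, ] <- ifelse(ns >= 0, ns / mpos, ns / mneg)
    if (es[s] >= 0) {
      nes[s] <- es[s] / mpos
      p_nom[s] <- if (length(pos) > 0) mean(pos >= es[s]) else 1
    } else {
      nes[s] <- es[s] / mneg
      p_nom[s] <- if (length(neg) > 0) mean(neg <= es[s]) else 1
    }
  }

  q <- rep(NA_real_, n_sets)
  null_pool <- as.vector(null_nes)
  null_pos <- null_pool[null_pool >= 0]
  null_neg <- null_pool[null_pool < 0]
  obs_pos <- nes[nes >= 0]
  obs_neg <- nes[nes < 0]
  for (s in seq_len(n_sets)) {
    if (nes[s] >= 0) {
      num <- if (length(null_pos) > 0) mean(null_pos >= nes[s]) else 0
      den <- mean(obs_pos >= nes[s])
    } else {
      num <- if (length(null_neg) > 0) mean(null_neg <= nes[s]) else 0
      den <- mean(obs_neg <= nes[s])
    }
    q[s] <- min(num / den, 1)
  }
  # q-value monotonicity: q(s) = min FDR over rejection thresholds c <= NES(s),
  # i.e. the running minimum from the least extreme NES up, so a more extreme
  # NES never gets a larger q
  for (sgn in c(1, -1)) {
    sel <- which(if (sgn > 0) nes >= 0 else nes < 0)
    if (length(sel) == 0L) next
    ord <- sel[order(sgn * nes[sel])]        # least extreme first
    q[ord] <- cummin(q[ord])
  }

  data.frame(es = es, nes = nes, p_nominal = p_nom, fdr_q = q,
             direction = ifelse(es >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Run one-vs-rest GSEA over several cohorts
#'
#' Each cohort runs at seed `seed + 100 * (cohort index - 1)`, a fixed fan-out
#' so per-cohort permutation streams are distinct but reproducible.
#'
#' @param cohorts List of [expression_cohort()] objects.
#' @param collection A [gene_set_collection()].
#' @param seed Base seed.
#' @param ... Passed to [gsea_one_vs_rest()].
#' @return Combined `gsea_table`.
#' @export
gsea_all_cohorts <- function(cohorts, collection, seed = 1L, ...) {
  tabs <- lapply(seq_along(cohorts), function(i)
    gsea_one_vs_rest(cohorts[[i]], collection = collection,
                     seed = seed + 100L * (i - 1L), ...))
  tab <- do.call(rbind, tabs)
  class(tab) <- c("gsea_table", "data.frame")
  tab
}

#' Retain gene sets significant in at least one subtype
#'
#' Keeps every row of the sets whose minimum FDR q over all (cohort, subtype)
#' rows is strictly below the threshold.
#'
#' @param table A `gsea_table`.
#' @param q_threshold FDR cutoff, default 0.25.
#' @return Filtered `gsea_table`.
#' @export
retain_significant <- function(table, q_threshold = 0.25) {
  if (nrow(table) == 0L) return(table)
  minq <- tapply(table$fdr_q, table$set_name, min)
  keep_sets <- names(minq)[minq < q_threshold]
  out <- table[table$set_name %in% keep_sets, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gsea_table", "data.frame")
  out
}

#' Tabulate cross-tissue recurrence of dysregulated gene sets
#'
#' Counts, per gene set, the (tissue, subtype, direction) hits with
#' `fdr_q < q_threshold` and classifies each set as `tissue_specific`
#' (dysregulated in exactly one tissue), `common` (at least `common_tissues`
#' tissues) or `intermediate`.
#'
#' @param table A `gsea_table` (typically after [retain_significant()]).
#' @param tissue_of_cohort Named character vector mapping cohort id -> tissue.
#' @param q_threshold Per-row significance cutoff, default 0.25.
#' @param common_tissues Tissue count from which a set counts as common,
#'   default 5.
#' @return A `recurrence_table` data frame: set_name, n_subtypes, n_tissues,
#'   class, hits (semicolon-separated `tissue:subtype:direction`).
#' @export
tabulate_recurrence <- function(table, tissue_of_cohort, q_threshold = 0.25,
                                common_tissues = 5L) {
  unmapped <- setdiff(unique(table$cohort_id), names(tissue_of_cohort))
  if (length(unmapped) > 0L)
    stop("config error: cohorts without a tissue mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  hits <- table[table$fdr_q < q_threshold, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(structure(data.frame(set_name = character(), n_subtypes = integer(),
                                n_tissues = integer(), class = character(),
                                hits = character(), stringsAsFactors = FALSE),
                     class = c("recurrence_table", "data.frame")))
  hits$tissue <- tissue_of_cohort[hits$cohort_id]
  by_set <- split(hits, hits$set_name)
  out <- do.call(rbind, lapply(by_set, function(h) {
    h <- h[order(h$tissue, h$subtype), ]
    data.frame(
      set_name = h$set_name[1L],
      n_subtypes = nrow(unique(h[, c("cohort_id", "subtype")])),
      n_tissues = length(unique(h$tissue)),
      class = NA_character_,
      hits = paste(sprintf("%s:%s:%s", h$tissue, h$subtype, h$direction), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  out$class <- ifelse(out$n_tissues == 1L, "tissue_specific",
                      ifelse(out$n_tissues >= common_tissues, "common", "intermediate"))
  out <- out[order(-out$n_subtypes, out$set_name), ]
  rownames(out) <- NULL
  class(out) <- c("recurrence_table", "data.frame")
  out
}
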