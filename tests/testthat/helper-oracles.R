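# Independent brute-force oracles, written against the definitions rather
# than the package's code paths.

# Average ranks without rank(): walk tie groups of the sorted vector.
brute_avg_ranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Pearson via raw sums, applied to the brute ranks.
brute_spearman <- function(x, y) {
  rx <- brute_avg_ranks(x)
  ry <- brute_avg_ranks(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt((n * sum(rx^2) - sum(rx)^2) * (n * sum(ry^2) - sum(ry)^2))
  num / den
}

# ssGSEA score by stepping through the two cumulative distributions position
# by position.
brute_ssgsea <- function(expr, gene_set, alpha) {
  genes <- names(expr)
  ord <- order(-expr, genes)
  score <- 0
  cum_in <- 0
  cum_out <- 0
  k <- sum(genes %in% gene_set)
  n <- length(expr)
  w_total <- 0
  for (g in genes[ord])
    if (g %in% gene_set) w_total <- w_total + (if (alpha > 0) abs(expr[[g]])^alpha else 1)
  for (g in genes[ord]) {
    if (g %in% gene_set) {
      cum_in <- cum_in + (if (alpha > 0) abs(expr[[g]])^alpha else 1) / w_total
    } else {
      cum_out <- cum_out + 1 / (n - k)
    }
    score <- score + (cum_in - cum_out)
  }
  score
}

# Weighted KS walk, position by position; ES = value of max |deviation|,
# positive deviation preferred on (near-)ties.
brute_es <- function(metric, gene_set, p) {
  genes <- names(metric)
  ord <- order(-metric, genes)
  n <- length(metric)
  k <- sum(genes %in% gene_set)
  w_total <- 0
  for (g in genes[ord])
    if (g %in% gene_set) w_total <- w_total + abs(metric[[g]])^p
  running <- 0
  maxdev <- 0
  mindev <- 0
  for (g in genes[ord]) {
    if (g %in% gene_set) {
      running <- running + (if (w_total > 0) abs(metric[[g]])^p / w_total else 1 / k)
    } else {
      running <- running - 1 / (n - k)
    }
    maxdev <- max(maxdev, running)
    mindev <- min(mindev, running)
  }
  if (maxdev + mindev >= -1e-12 * (maxdev - mindev)) maxdev else mindev
}

# Naive average-linkage agglomerator: recompute every inter-cluster average
# from the original matrix at every step (no Lance-Williams update), same
# smallest-label tie-break.
brute_average_linkage_heights <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        pair <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        if (is.null(best) || avg < best$avg - 1e-15 ||
            (abs(avg - best$avg) <= 1e-15 &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(avg = avg, i = i, j = j, pair = pair)
        }
      }
    }
    heights <- c(heights, best$avg)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  heights
}

# Small labelled cohort for io / correlation tests.
toy_cohort <- function(seed = 1L, n_genes = 12L, n_samples = 6L,
                       scale = "absolute", cohort_id = "toy") {
  set.seed(seed)
  vals <- matrix(round(rnorm(n_genes * n_samples, 8), 4), n_genes, n_samples,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("S%02d", seq_len(n_samples))))
  labels <- stats::setNames(rep(c("a", "b"), each = ceiling(n_samples / 2))[seq_len(n_samples)],
                            colnames(vals))
  expression_cohort(cohort_id, vals, labels, scale)
}

# Compact design for fast GSEA tests.
mini_design <- function(seed = 1L, ...) {
  synthetic_design(n_genes = 400L, n_samples = 30L, module_size = 30L,
                   seed = seed, ...)
}
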