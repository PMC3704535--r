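#' Describe a synthetic multi-cohort study design
#'
#' Specifies the generator for multi-cohort expression data with planted
#' ground truth: partially overlapping gene universes, subtypes within each
#' cohort, and "programs" — gene modules added (or subtracted) in designated
#' (cohort, subtype) slots. A program with members in two or more cohorts
#' plants a cross-tissue subtype partnership; a single-member program plants a
#' subtype-specific dysregulated set.
#'
#' Defaults describe a desk-scale study: 3 cohorts of 60 samples over 2,000
#' genes (80% of each cohort's universe shared by all cohorts), 3 subtypes per
#' cohort, four 50-gene programs at effect size delta = 1 log2 unit over
#' Gaussian noise of sd 1 — three cross-cohort partner programs (up) and one
#' single-subtype program (down).
#'
#' @param n_cohorts Number of cohorts.
#' @param n_genes Genes per cohort universe.
#' @param core_fraction Fraction of each cohort's universe drawn from the
#'   shared core; the rest is cohort-private.
#' @param n_samples Samples per cohort.
#' @param n_subtypes Subtypes per cohort (equal proportions; remainders go to
#'   the last subtype).
#' @param scales Per-cohort scale dialect, recycled; default makes the last
#'   cohort a two-color log-ratio cohort and the rest absolute-scale.
#' @param module_size Genes per planted module.
#' @param delta Planted effect size in log2 units (>= 0).
#' @param noise_sd Gaussian noise standard deviation.
#' @param programs Optional custom program list; each element is a list with
#'   `name`, `genes` (character), `members` (data frame cohort_id, subtype),
#'   `direction` (`"up"`/`"down"`), and optionally `group` (for two-group
#'   designs). `NULL` builds the default four programs.
#' @param null_mode If TRUE, no effects are planted (delta treated as 0);
#'   ground truth is empty and the data are pure noise, for type-I error
#'   calibration.
#' @param seed Integer seed stored with the design.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_cohorts = 3L, n_genes = 2000L, core_fraction = 0.8,
                             n_samples = 60L, n_subtypes = 3L, scales = NULL,
                             module_size = 50L, delta = 1.0, noise_sd = 1.0,
                             programs = NULL, null_mode = FALSE, seed = 1L) {
  stopifnot(n_cohorts >= 2L, n_subtypes >= 2L, delta >= 0, noise_sd > 0,
            core_fraction > 0, core_fraction <= 1)
  if (is.null(scales))
    scales <- c(rep("absolute", n_cohorts - 1L), "log_ratio")
  scales <- rep_len(scales, n_cohorts)
  stopifnot(all(scales %in% c("absolute", "log_ratio")))
  design <- list(
    n_cohorts = n_cohorts, n_genes = n_genes, core_fraction = core_fraction,
    n_samples = n_samples, n_subtypes = n_subtypes, scales = scales,
    module_size = module_size, delta = delta, noise_sd = noise_sd,
    null_mode = null_mode, seed = as.integer(seed)
  )
  design$cohort_ids <- sprintf("cohort%d", seq_len(n_cohorts))
  design$subtype_ids <- sprintf("s%d", seq_len(n_subtypes))
  design$tissue_of_cohort <- stats::setNames(sprintf("tissue%d", seq_len(n_cohorts)),
                                             design$cohort_ids)
  n_core <- round(core_fraction * n_genes)
  n_private <- n_genes - n_core
  total <- n_core + n_cohorts * n_private
  universe <- sprintf("g%05d", seq_len(total))
  design$core_genes <- universe[seq_len(n_core)]
  design$private_genes <- lapply(seq_len(n_cohorts), function(i) {
    if (n_private == 0L) return(character())
    universe[n_core + (i - 1L) * n_private + seq_len(n_private)]
  })
  design$programs <- if (is.null(programs)) default_programs(design) else programs
  validate_programs(design)
  class(design) <- "synthetic_design"
  design
}

# Three cross-cohort partner programs (up) cycling over cohort pairs and
# subtypes, plus one single-member program (down) in a free slot.
default_programs <- function(design) {
  nc <- design$n_cohorts
  ns <- design$n_subtypes
  n_pair <- min(3L, nc * (nc - 1L) / 2)
  progs <- list()
  used <- character()
  for (k in seq_len(n_pair)) {
    ca <- ((k - 1L) %% nc) + 1L
    cb <- (k %% nc) + 1L
    st <- design$subtype_ids[((k - 1L) %% ns) + 1L]
    members <- data.frame(cohort_id = design$cohort_ids[c(ca, cb)],
                          subtype = st, stringsAsFactors = FALSE)
    progs[[k]] <- list(name = sprintf("MODULE_%d", k),
                       genes = module_genes(design, k),
                       members = members, direction = "up")
    used <- c(used, paste(members$cohort_id, members$subtype))
  }
  # one subtype-specific down program in the first unused (cohort, subtype) slot
  slots <- expand.grid(cohort_id = design$cohort_ids, subtype = design$subtype_ids,
                       stringsAsFactors = FALSE)
  free <- slots[!(paste(slots$cohort_id, slots$subtype) %in% used), , drop = FALSE]
  if (nrow(free) > 0L) {
    k <- n_pair + 1L
    progs[[k]] <- list(name = sprintf("MODULE_%d", k),
                       genes = module_genes(design, k),
                       members = free[1L, , drop = FALSE], direction = "down")
  }
  progs
}

module_genes <- function(design, k) {
  i <- (k - 1L) * design$module_size + seq_len(design$module_size)
  if (max(i) > length(design$core_genes))
    stop("design error: not enough core genes for the requested modules", call. = FALSE)
  design$core_genes[i]
}

validate_programs <- function(design) {
  for (p in design$programs) {
    stopifnot(is.character(p$genes), length(p$genes) > 0L,
              p$direction %in% c("up", "down"))
    if (!all(p$members$subtype %in% design$subtype_ids) ||
        !all(p$members$cohort_id %in% design$cohort_ids))
      stop("design error: program member outside the design's cohorts/subtypes",
           call. = FALSE)
    for (ci in match(unique(p$members$cohort_id), design$cohort_ids)) {
      uni <- c(design$core_genes, design$private_genes[[ci]])
      if (!all(p$genes %in% uni))
        stop(sprintf("design error: module genes of '%s' absent from cohort '%s'",
                     p$name, design$cohort_ids[ci]), call. = FALSE)
    }
  }
  invisible(design)
}

#' Generate synthetic expression cohorts with planted ground truth
#'
#' Baseline expression of gene g in every sample is `Normal(mu_g, noise_sd)`,
#' with `mu_g` drawn once per gene from `Normal(8, 1)` for absolute-scale
#' cohorts and fixed at 0 for log-ratio cohorts. For every program, samples of
#' each member (cohort, subtype) slot get `+delta` (direction `"up"`) or
#' `-delta` (`"down"`) on the module genes. Under `null_mode` no effects are
#' added.
#'
#' @param design A [synthetic_design()].
#' @param seed Seed; defaults to the design's seed. Identical seeds give
#'   bit-identical cohorts.
#' @return List with `cohorts` (list of [expression_cohort()]) and `truth`
#'   (programs, cross-cohort `partnerships`, per-subtype `dysregulated` table,
#'   `tissue_of_cohort`, and `group_of` sample assignments when programs carry
#'   group tags).
#' @export
generate_cohorts <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed)
  all_genes <- c(design$core_genes, unlist(design$private_genes))
  mu_g <- stats::setNames(rnorm(length(all_genes), mean = 8, sd = 1), all_genes)

  cohorts <- vector("list", design$n_cohorts)
  names(cohorts) <- design$cohort_ids
  group_of <- character()
  for (i in seq_len(design$n_cohorts)) {
    cid <- design$cohort_ids[i]
    genes <- c(design$core_genes, design$private_genes[[i]])
    n <- design$n_samples
    per <- n %/% design$n_subtypes
    labels <- rep(design$subtype_ids, c(rep(per, design$n_subtypes - 1L),
                                        n - per * (design$n_subtypes - 1L)))
    samples <- sprintf("%s.S%03d", cid, seq_len(n))
    names(labels) <- samples
    baseline <- if (design$scales[i] == "absolute") mu_g[genes] else 0
    vals <- matrix(rnorm(length(genes) * n, sd = design$noise_sd), length(genes), n,
                   dimnames = list(genes, samples)) + baseline
    if (!design$null_mode) {
      for (p in design$programs) {
        hit <- p$members$cohort_id == cid
        for (st in p$members$subtype[hit]) {
          cols <- labels == st
          vals[p$genes, cols] <- vals[p$genes, cols] +
            ifelse(p$direction == "up", 1, -1) * design$delta
        }
      }
    }
    cohorts[[i]] <- expression_cohort(cid, vals, labels, design$scales[i])
    for (p in design$programs) {
      if (!is.null(p$group)) {
        sel <- p$members$cohort_id == cid
        for (st in p$members$subtype[sel])
          group_of <- c(group_of, stats::setNames(rep(p$group, sum(labels == st)),
                                                  samples[labels == st]))
      }
    }
  }

  truth <- list(programs = design$programs,
                tissue_of_cohort = design$tissue_of_cohort,
                null_mode = design$null_mode)
  if (design$null_mode) {
    truth$partnerships <- data.frame()
    truth$dysregulated <- data.frame()
  } else {
    truth$partnerships <- program_partnerships(design$programs)
    dys <- lapply(design$programs, function(p)
      data.frame(cohort_id = p$members$cohort_id, subtype = p$members$subtype,
                 set_name = p$name, direction = p$direction,
                 stringsAsFactors = FALSE))
    truth$dysregulated <- do.call(rbind, dys)
  }
  if (length(group_of) > 0L) truth$group_of <- group_of
  list(cohorts = cohorts, truth = truth)
}

# All unordered cross-cohort member pairs of each program.
program_partnerships <- function(programs) {
  rows <- list()
  for (p in programs) {
    m <- p$members
    if (nrow(m) < 2L) next
    for (a in seq_len(nrow(m) - 1L)) {
      for (b in (a + 1L):nrow(m)) {
        if (m$cohort_id[a] == m$cohort_id[b]) next
        rows[[length(rows) + 1L]] <- data.frame(
          program = p$name,
          cohort_a = m$cohort_id[a], subtype_a = m$subtype[a],
          cohort_b = m$cohort_id[b], subtype_b = m$subtype[b],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

#' Generate a gene set collection with the planted modules and random decoys
#'
#' One set per planted module (exact membership) plus `n_decoys` random sets
#' drawn from the shared core universe, so every set is scoreable in every
#' cohort. Decoys may overlap modules; the per-decoy overlap is recorded in
#' the `overlap_with_modules` attribute.
#'
#' @param design A [synthetic_design()].
#' @param n_decoys Number of decoy sets, default 40.
#' @param set_size Genes per decoy set, default the design's module size.
#' @param seed Seed; defaults to the design's seed + 1000 (a fixed fan-out
#'   offset, so cohorts and sets can be regenerated independently).
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(design, n_decoys = 40L, set_size = design$module_size,
                               seed = design$seed + 1000L) {
  stopifnot(inherits(design, "synthetic_design"),
            set_size <= length(design$core_genes))
  set.seed(seed)
  sets <- lapply(design$programs, `[[`, "genes")
  names(sets) <- vapply(design$programs, `[[`, "", "name")
  module_genes <- unique(unlist(sets))
  overlap <- integer()
  if (n_decoys > 0L) {
    for (k in seq_len(n_decoys)) {
      nm <- sprintf("DECOY_%03d", k)
      sets[[nm]] <- sample(design$core_genes, set_size)
      overlap[nm] <- length(intersect(sets[[nm]], module_genes))
    }
  }
  out <- gene_set_collection(sets)
  attr(out, "overlap_with_modules") <- overlap
  out
}

#' Two-group study preset
#'
#' A design whose subtypes belong to one of two cross-tissue program groups:
#' in every cohort, subtype `s1` carries module `GROUP_A` (up) and subtype
#' `s2` carries module `GROUP_B` (up). Pooled pathway profiles should split at
#' the dendrogram root into these two groups.
#'
#' @inheritParams synthetic_design
#' @return A `synthetic_design` with group-tagged programs.
#' @export
two_group_design <- function(n_cohorts = 3L, n_genes = 2000L, n_samples = 60L,
                             module_size = 50L, delta = 1.0, noise_sd = 1.0,
                             seed = 1L) {
  base <- synthetic_design(n_cohorts = n_cohorts, n_genes = n_genes,
                           n_samples = n_samples, n_subtypes = 2L,
                           module_size = module_size, delta = delta,
                           noise_sd = noise_sd, seed = seed,
                           programs = list())
  progs <- list(
    list(name = "GROUP_A", genes = module_genes(base, 1L),
         members = data.frame(cohort_id = base$cohort_ids, subtype = "s1",
                              stringsAsFactors = FALSE),
         direction = "up", group = "G1"),
    list(name = "GROUP_B", genes = module_genes(base, 2L),
         members = data.frame(cohort_id = base$cohort_ids, subtype = "s2",
                              stringsAsFactors = FALSE),
         direction = "up", group = "G2")
  )
  base$programs <- progs
  validate_programs(base)
  base
}

#' Write synthetic inputs to disk in the pipeline's external formats
#'
#' Absolute-scale cohorts are written as GCT, log-ratio cohorts as plain TSV
#' (exercising both dialects); labels as two-column TSV sidecars; gene sets as
#' GMT; ground truth as JSON. Returns a run configuration usable with
#' [run_pipeline()].
#'
#' @param sim Output of [generate_cohorts()].
#' @param collection A [gene_set_collection()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the configuration.
#' @param min_common_genes Gene-overlap floor written into the configuration;
#'   defaults to a quarter of the smallest cohort's universe.
#' @return A run config list (also written to `config.yaml` in `dir`).
#' @export
write_synthetic_inputs <- function(sim, collection, dir, seed = 1L,
                                   min_common_genes = NULL) {
  if (is.null(min_common_genes))
    min_common_genes <- floor(min(vapply(sim$cohorts, function(co) nrow(co$values), 1L)) / 4)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort_cfg <- lapply(sim$cohorts, function(co) {
    ext <- if (co$scale == "absolute") "gct" else "tsv"
    path <- file.path(dir, sprintf("%s.%s", co$cohort_id, ext))
    labels_path <- file.path(dir, sprintf("%s.labels.tsv", co$cohort_id))
    if (ext == "gct") write_expression_gct(co, path, labels_path)
    else write_expression_tsv(co, path, labels_path)
    list(cohort_id = co$cohort_id, path = path, labels = labels_path,
         scale = co$scale,
         tissue = unname(sim$truth$tissue_of_cohort[co$cohort_id]))
  })
  gmt_path <- file.path(dir, "gene_sets.gmt")
  write_gmt(collection, gmt_path)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  config <- list(cohorts = unname(cohort_cfg), gmt = gmt_path, seed = seed,
                 min_common_genes = min_common_genes,
                 ssgsea = list(alpha = 0.25, min_set_size = 5L, input = "centered"),
                 gsea = list(n_perm = 1000L, weight_p = 1, q_threshold = 0.25))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  config
}
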