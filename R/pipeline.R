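#' Run the whole cross-tissue commonality pipeline
#'
#' Executes preprocess -> ssGSEA -> correlation -> phylogeny -> GSEA ->
#' pathway clustering from a single run configuration, writing every tabular
#' output as TSV (plus a Newick tree and a JSON manifest) under `out_dir`.
#' All randomness is governed by `config$seed`, fanned out to fixed per-stage
#' offsets; rerunning with the same config and seed reproduces every output
#' byte for byte.
#'
#' @param config A run configuration list, or the path to a YAML file with the
#'   same structure: `cohorts` (list of entries with `cohort_id`, `path`,
#'   `labels`, `scale`, `tissue`), `gmt`, `seed`, `min_common_genes`, and
#'   optional `ssgsea` (`alpha`, `min_set_size`, `input: centered|raw`) and
#'   `gsea` (`n_perm`, `weight_p`, `q_threshold`) blocks.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results of every stage and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  for (key in c("cohorts", "gmt", "seed"))
    if (is.null(config[[key]]))
      stop(sprintf("config error: missing key '%s'", key), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  cfg <- function(path, default) {
    v <- config
    for (k in path) v <- v[[k]]
    if (is.null(v)) default else v
  }

  # --- load ---------------------------------------------------------------
  cohorts <- lapply(config$cohorts, function(entry) {
    read_expression(entry$path, entry$labels, scale = entry$scale,
                    cohort_id = entry$cohort_id)
  })
  names(cohorts) <- vapply(cohorts, function(x) x$cohort_id, "")
  tissue_of_cohort <- stats::setNames(
    vapply(config$cohorts, function(e) e$tissue %||% e$cohort_id, ""),
    vapply(config$cohorts, function(e) e$cohort_id, ""))
  collection <- read_gmt(config$gmt)
  seed <- as.integer(config$seed)

  # --- preprocess ---------------------------------------------------------
  common <- intersect_genes(cohorts, min_common = cfg("min_common_genes", 5000L))
  cohorts <- cohorts[common$cohorts_included]
  centered <- lapply(cohorts, median_center_genes)
  write_tsv(data.frame(cohort_id = names(cohorts), n_genes = length(common$genes)),
            file.path(out_dir, "common_genes.tsv"))
  write_tsv(common$excluded, file.path(out_dir, "excluded_cohorts.tsv"))
  stages <- c(stages, "preprocess")

  # --- ssgsea ---------------------------------------------------------------
  ssgsea_input <- if (cfg(c("ssgsea", "input"), "centered") == "centered") centered else cohorts
  profiles <- lapply(ssgsea_input, pathway_profile,
                     collection = collection,
                     alpha = cfg(c("ssgsea", "alpha"), 0.25),
                     min_set_size = cfg(c("ssgsea", "min_set_size"), 5L))
  for (cid in names(profiles))
    write_tsv(as_feature_table(profiles[[cid]], "set_name"),
              file.path(out_dir, sprintf("pathway_profile_%s.tsv", cid)))
  stages <- c(stages, "ssgsea")

  # --- correlation ----------------------------------------------------------
  labels <- lapply(cohorts, `[[`, "subtypes")
  sim_tx <- subtype_median_correlation(lapply(centered, `[[`, "values"), labels,
                                       features = common$genes)
  common_sets <- Reduce(intersect, lapply(profiles, rownames))
  sim_pw <- subtype_median_correlation(lapply(profiles, unclass), labels,
                                       features = common_sets)
  write_tsv(as_feature_table(sim_tx$median_rho, "subtype"),
            file.path(out_dir, "subtype_similarity_transcriptional.tsv"))
  write_tsv(as_feature_table(sim_pw$median_rho, "subtype"),
            file.path(out_dir, "subtype_similarity_pathway.tsv"))
  stages <- c(stages, "correlation")

  # --- phylogeny ------------------------------------------------------------
  tree <- subtype_phylogeny(sim_tx)
  write_newick(tree, file.path(out_dir, "subtype_phylogeny.nwk"))
  write_tsv(merge_table(tree), file.path(out_dir, "subtype_phylogeny_merges.tsv"))
  stages <- c(stages, "phylogeny")

  # --- gsea -----------------------------------------------------------------
  gsea_tab <- gsea_all_cohorts(cohorts, collection,
                               n_perm = cfg(c("gsea", "n_perm"), 1000L),
                               weight_p = cfg(c("gsea", "weight_p"), 1),
                               seed = seed)
  q_thr <- cfg(c("gsea", "q_threshold"), 0.25)
  retained <- retain_significant(gsea_tab, q_thr)
  recurrence <- tabulate_recurrence(retained, tissue_of_cohort, q_thr)
  write_tsv(gsea_tab, file.path(out_dir, "gsea_table.tsv"))
  write_tsv(retained, file.path(out_dir, "gsea_retained.tsv"))
  write_tsv(recurrence, file.path(out_dir, "pathway_recurrence.tsv"))
  stages <- c(stages, "gsea")

  # --- pathway clustering ---------------------------------------------------
  pooled <- do.call(cbind, lapply(profiles, function(p) unclass(p)[common_sets, , drop = FALSE]))
  sample_tree <- cluster_columns(pooled)
  groups <- split_two(sample_tree)
  composite <- stats::setNames(
    unlist(lapply(names(labels), function(cid)
      paste(cid, labels[[cid]], sep = "."))),
    unlist(lapply(labels, names)))
  enrichment <- subtype_enrichment(groups, composite)
  write_tsv(data.frame(sample_id = names(groups), group = unname(groups)),
            file.path(out_dir, "pathway_groups.tsv"))
  write_tsv(enrichment, file.path(out_dir, "group_enrichment.tsv"))
  stages <- c(stages, "pathway_clustering")

  # --- manifest -------------------------------------------------------------
  config_path <- file.path(out_dir, "config_used.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package = "pansubtype",
    version = as.character(utils::packageVersion("pansubtype")),
    seed = seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(config_path)),
    cohorts = names(cohorts),
    n_common_genes = length(common$genes),
    n_gene_sets = length(collection)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(common = common, profiles = profiles,
                 similarity_transcriptional = sim_tx, similarity_pathway = sim_pw,
                 tree = tree, gsea = gsea_tab, retained = retained,
                 recurrence = recurrence, groups = groups,
                 group_enrichment = enrichment, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_feature_table <- function(mat, id_col) {
  df <- data.frame(rownames(mat), as.data.frame(unclass(mat), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  df
}
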