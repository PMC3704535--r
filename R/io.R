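#' Read an expression matrix with subtype labels
#'
#' Reads a genes-by-samples expression matrix from a plain tab-separated file
#' (header row of sample ids, first column of gene/probe ids) or from a GCT
#' v1.2 file (`#1.2` line, a dimensions line, then the same layout with an
#' extra Description column). Subtype labels come from a two-column sidecar
#' file (sample id, subtype) or a named character vector.
#'
#' @param path Path to the expression file.
#' @param labels Named character vector (sample id -> subtype) or path to a
#'   two-column tab-separated label file with a header.
#' @param scale Measurement dialect: `"absolute"` (one-color log2 intensity)
#'   or `"log_ratio"` (two-color log2 ratio).
#' @param cohort_id Cohort identifier; defaults to the file name without
#'   extension.
#' @param format `"auto"` (sniff the `#1.2` magic), `"tsv"` or `"gct"`.
#'
#' @return An [expression_cohort()].
#' @export
read_expression <- function(path, labels, scale = c("absolute", "log_ratio"),
                            cohort_id = NULL, format = c("auto", "tsv", "gct")) {
  scale <- match.arg(scale)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "#1.2")) "gct" else "tsv"
  }
  if (is.null(cohort_id))
    cohort_id <- sub("\\.[^.]*$", "", basename(path))
  mat <- if (format == "gct") read_gct_matrix(path) else read_tsv_matrix(path)
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)) && file.exists(labels))
    labels <- read_labels(labels)
  expression_cohort(cohort_id, mat, labels, scale)
}

read_tsv_matrix <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 2L) stop("format error: expression file needs >= 1 sample column", call. = FALSE)
  if (anyDuplicated(hdr[-1L]))
    stop("format error: duplicate sample ids in ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  names(df) <- hdr                 # read.delim uniquifies; keep ids verbatim
  as_numeric_matrix(df[[1L]], df[-1L], path)
}

read_gct_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#1.2"))
    stop("format error: not a GCT v1.2 file: ", path, call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("format error: malformed GCT dimensions line", call. = FALSE)
  hdr <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 3L) stop("format error: GCT needs Name, Description and sample columns", call. = FALSE)
  if (anyDuplicated(hdr[-(1:2)]))
    stop("format error: duplicate sample ids in ", path, call. = FALSE)
  con <- textConnection(lines[-(1:2)])
  on.exit(close(con))
  df <- read.delim(con, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  names(df) <- hdr
  mat <- as_numeric_matrix(df[[1L]], df[-(1:2)], path)
  if (nrow(mat) != dims[1L] || ncol(mat) != dims[2L])
    stop(sprintf("format error: GCT declares %d x %d but contains %d x %d",
                 dims[1L], dims[2L], nrow(mat), ncol(mat)), call. = FALSE)
  mat
}

as_numeric_matrix <- function(row_ids, value_df, path) {
  sample_ids <- colnames(value_df)
  if (anyDuplicated(sample_ids))
    stop("format error: duplicate sample ids in ", path, call. = FALSE)
  vals <- suppressWarnings(vapply(value_df, as.numeric, numeric(nrow(value_df))))
  vals <- matrix(vals, nrow = length(row_ids),
                 dimnames = list(row_ids, sample_ids))
  if (anyNA(vals)) {
    bad <- row_ids[apply(is.na(vals), 1L, any)]
    stop("format error: non-numeric or missing cells in rows: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  vals
}

#' Read a two-column sample-to-subtype label file
#'
#' @param path Tab-separated file with a header and columns sample id, subtype.
#' @return Named character vector (sample id -> subtype label).
#' @export
read_labels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("label error: label file needs two columns", call. = FALSE)
  if (anyDuplicated(df[[1L]])) stop("label error: duplicate sample ids in label file", call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write an expression cohort as TSV (and its labels as a sidecar)
#'
#' @param cohort An [expression_cohort()].
#' @param path Output path for the matrix.
#' @param labels_path Optional output path for the two-column label sidecar.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(cohort, path, labels_path = NULL) {
  df <- data.frame(gene_id = rownames(cohort$values), cohort$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) write_labels(cohort$subtypes, labels_path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
write_expression_gct <- function(cohort, path, labels_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(cohort$values), ncol(cohort$values), sep = "\t")), con)
  df <- data.frame(Name = rownames(cohort$values), Description = "na",
                   cohort$values, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) write_labels(cohort$subtypes, labels_path)
  invisible(path)
}

write_labels <- function(subtypes, path) {
  write.table(data.frame(sample_id = names(subtypes), subtype = unname(subtypes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a line are removed; a line with fewer than three fields is a format
#' error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()]; an empty file yields an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop("format error: GMT line(s) with fewer than 3 fields: line ",
         paste(which(nf < 3L), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), names(sets))
  gene_set_collection(sets, desc)
}

#' Write a gene set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a merge tree to Newick
#'
#' Writes a rooted binary merge tree (a `subtype_tree` from
#' [average_linkage()], or any `hclust`-shaped object) as a Newick string.
#' The branch length of a node is its parent's merge height minus its own
#' height; leaves sit at height zero. Label characters that clash with Newick
#' syntax are replaced by `_`.
#'
#' @param tree An object with `merge`, `height` and `labels` components
#'   (hclust convention), or a single leaf label for the degenerate one-leaf
#'   tree.
#' @param path Optional file to write to.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 6L) {
  if (is.character(tree) && length(tree) == 1L) {
    nwk <- paste0(sanitize_newick_label(tree), ";")
  } else {
    if (any(!is.finite(tree$height)))
      stop("serialization error: non-finite merge heights", call. = FALSE)
    labels <- sanitize_newick_label(tree$labels)
    min_leaf <- function(i) {
      if (i < 0L) return(labels[-i])
      min(min_leaf(tree$merge[i, 1L]), min_leaf(tree$merge[i, 2L]))
    }
    children <- function(i) {
      ch <- tree$merge[i, ]
      ch[order(c(min_leaf(ch[1L]), min_leaf(ch[2L])))]
    }
    node_string <- function(i, parent_h) {
      if (i < 0L) {                       # leaf, height 0
        sprintf("%s:%s", labels[-i], format_bl(parent_h, digits))
      } else {
        h <- tree$height[i]
        ch <- children(i)
        sprintf("(%s,%s):%s",
                node_string(ch[1L], h), node_string(ch[2L], h),
                format_bl(parent_h - h, digits))
      }
    }
    root <- nrow(tree$merge)
    h <- tree$height[root]
    ch <- children(root)
    nwk <- sprintf("(%s,%s);", node_string(ch[1L], h), node_string(ch[2L], h))
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

sanitize_newick_label <- function(x) gsub("[\\s,;:()\\[\\]']", "_", x, perl = TRUE)

format_bl <- function(x, digits) sprintf("%.*g", digits, x)
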