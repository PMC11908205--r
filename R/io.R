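#' Read a tree sequence from tab-separated tables
#'
#' Loads the tabular tree-sequence dialect: `<prefix>.nodes.tsv` with columns
#' `id`, `time`, `is_sample`, `individual`; `<prefix>.edges.tsv` with `left`,
#' `right`, `parent`, `child`; optionally `<prefix>.sites.tsv` (`position`) and
#' `<prefix>.mutations.tsv` (`site`, `node`).  All files are tab-separated with
#' a header row; node ids must be 0..N-1 in row order.
#'
#' @param prefix path prefix for the table files.
#' @param sequence_length total genome length; if `NULL`, the maximum edge
#'   `right` is used.
#' @return A validated `tree_sequence`.
#' @seealso [write_tree_sequence()]
#' @export
read_tree_sequence <- function(prefix, sequence_length = NULL) {
  read_tsv <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  nodes_path <- paste0(prefix, ".nodes.tsv")
  edges_path <- paste0(prefix, ".edges.tsv")
  if (!file.exists(nodes_path)) stop("missing node table: ", nodes_path)
  if (!file.exists(edges_path)) stop("missing edge table: ", edges_path)
  nodes <- read_tsv(nodes_path)
  for (col in c("id", "time", "is_sample")) {
    if (is.null(nodes[[col]])) {
      stop("node table lacks required column '", col, "'")
    }
  }
  if (!identical(as.integer(nodes$id), seq_len(nrow(nodes)) - 1L)) {
    stop("node ids must be 0..N-1 in row order")
  }
  edges <- read_tsv(edges_path)
  for (col in c("left", "right", "parent", "child")) {
    if (is.null(edges[[col]])) {
      stop("edge table lacks required column '", col, "'")
    }
  }
  sites <- mutations <- NULL
  if (file.exists(paste0(prefix, ".sites.tsv"))) {
    sites <- read_tsv(paste0(prefix, ".sites.tsv"))
  }
  if (file.exists(paste0(prefix, ".mutations.tsv"))) {
    mutations <- read_tsv(paste0(prefix, ".mutations.tsv"))
  }
  if (is.null(sequence_length)) {
    if (nrow(edges) == 0L) stop("sequence_length required when no edges")
    sequence_length <- max(edges$right)
  }
  tree_sequence(nodes, edges, sequence_length, sites, mutations)
}

#' Write a tree sequence as tab-separated tables
#'
#' Inverse of [read_tree_sequence()]; positions and times are written with full
#' precision so that a round trip reproduces the tables exactly.
#'
#' @param ts a `tree_sequence`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_tree_sequence <- function(ts, prefix) {
  write_tsv <- function(df, path) {
    utils::write.table(format(df, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  nd <- ts$nodes
  write_tsv(data.frame(id = seq_len(nrow(nd)) - 1L, time = nd$time,
                       is_sample = as.integer(nd$is_sample),
                       individual = ifelse(is.na(nd$individual), -1L,
                                           nd$individual)),
            paste0(prefix, ".nodes.tsv"))
  ed <- ts$edges
  write_tsv(data.frame(left = ed$left, right = ed$right,
                       parent = ed$parent - 1L, child = ed$child - 1L),
            paste0(prefix, ".edges.tsv"))
  if (!is.null(ts$sites)) {
    write_tsv(data.frame(position = ts$sites$position),
              paste0(prefix, ".sites.tsv"))
  }
  if (!is.null(ts$mutations)) {
    write_tsv(data.frame(site = ts$mutations$site - 1L,
                         node = ts$mutations$node - 1L),
              paste0(prefix, ".mutations.tsv"))
  }
  invisible(prefix)
}

#' Read a pedigree from a tab-separated file
#'
#' Columns: `id`, `father`, `mother`, optionally `generation` and
#' `is_proband`.  A father/mother value of 0 (or an id not present in the
#' file) marks an unknown parent; such individuals are founders.
#'
#' @param path file path.
#' @return A `pedigree` object (see [pedigree()]).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("id", "father", "mother")) {
    if (is.null(df[[col]])) stop("pedigree lacks required column '", col, "'")
  }
  pedigree(df$id, df$father, df$mother,
           probands = if (!is.null(df$is_proband)) df$id[df$is_proband == 1]
           else NULL)
}

#' Write a relatedness matrix as TSV plus a JSON sidecar
#'
#' The matrix is written tab-separated with ids as header and first column;
#' the mode and unit are recorded in `<path>.json`.
#'
#' @param m a `relatedness_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_relatedness_matrix <- function(m, path) {
  vals <- as.matrix(m)
  ids <- rownames(vals)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(vals)) - 1L)
  df <- data.frame(id = ids, vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mode = attr(m, "mode"), unit = attr(m, "unit"), n = nrow(vals)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a weight vector (one value per line)
#' @param path file path.
#' @return numeric vector.
#' @export
read_weights <- function(path) {
  scan(path, what = numeric(), quiet = TRUE)
}
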