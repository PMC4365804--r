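## File formats: TSV count matrices (gene ids in the first column, library
## ids in the header), two-column group maps, one-column normalisation
## factors, TSV result tables, Newick dendrograms, and the chain store
## directory.

#' Read a count matrix from a tab-separated file
#'
#' Expects a header of library identifiers, gene identifiers in the first
#' column and integer cells.  Malformed input (ragged rows, non-integer
#' cells, duplicate identifiers) is reported with the offending line.
#'
#' @param path file path.
#' @param filter_zero_rows drop genes whose counts sum to zero (reported
#'   via a message); the sampler refuses such rows otherwise.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, filter_zero_rows = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged input: line %d of '%s' has %d fields, expected %d",
                 which(nf != nf[1])[1], path, nf[nf != nf[1]][1], nf[1]))
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   quote = "")
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier: ",
         gene_ids[duplicated(gene_ids)][1])
  lib_ids <- colnames(df)[-1]
  if (anyDuplicated(lib_ids))
    stop("duplicate library identifier: ", lib_ids[duplicated(lib_ids)][1])
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  bad <- which(is.na(vals) | abs(vals - round(vals)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(paste0("non-integer count '%s' at line %d (gene '%s', ",
                        "library '%s')"),
                 df[bad[1, 1], bad[1, 2] + 1L], bad[1, 1] + 1L,
                 gene_ids[bad[1, 1]], lib_ids[bad[1, 2]]))
  }
  if (filter_zero_rows) {
    zero <- rowSums(vals) == 0
    if (any(zero)) {
      message(sprintf("filtered %d gene(s) with zero count sum", sum(zero)))
      vals <- vals[!zero, , drop = FALSE]
      gene_ids <- gene_ids[!zero]
    }
  }
  count_matrix(vals, gene_ids, lib_ids)
}

#' Write a count matrix as TSV
#' @param x a [count_matrix()].
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", x$library_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a library-to-group map
#'
#' Two tab-separated columns with header: `library_id`, `group`.
#'
#' @param path file path.
#' @param library_ids optional library order to match (e.g. from the count
#'   matrix header); an error names any mismatch.
#' @return a [group_map()].
#' @export
read_group_map <- function(path, library_ids = NULL) {
  df <- read.delim(path, colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("group map needs two columns: library_id, group")
  if (!is.null(library_ids)) {
    i <- match(library_ids, df[[1]])
    if (anyNA(i))
      stop("libraries missing from the group map: ",
           paste(library_ids[is.na(i)], collapse = ", "))
    df <- df[i, ]
  }
  group_map(df[[2]], library_ids = df[[1]])
}

#' Write a group map as TSV
#' @param groups a [group_map()].
#' @param path output path.
#' @export
write_group_map <- function(groups, path) {
  write.table(data.frame(library_id = groups$library_ids,
                         group = groups$group_names[groups$group]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read user normalisation factors
#'
#' A one-column text file (header optional) with one positive factor per
#' library, in the column order of the count matrix.
#'
#' @param path file path.
#' @param x the [count_matrix()] (or library count) the factors belong to.
#' @return [norm_factors()].
#' @export
read_factors <- function(path, x) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  vals <- suppressWarnings(as.numeric(raw))
  if (length(vals) && is.na(vals[1])) vals <- vals[-1]  # header line
  if (anyNA(vals)) stop("non-numeric normalisation factor in ", path)
  apply_user_factors(vals, x)
}

#' Write the per-gene DE table as TSV
#'
#' Columns: `gene_id`, `pi`, `in_de_set`.
#'
#' @param de a `de_result` from [select_threshold()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  write.table(data.frame(gene_id = names(de$pi), pi = de$pi,
                         in_de_set = names(de$pi) %in% de$de_set),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a similarity matrix as TSV (ids in first column and header)
#' @param sim similarity matrix with dimnames.
#' @param path output path.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(id = rownames(sim), sim, check.names = FALSE)
  colnames(df) <- c("id", colnames(sim))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity()]
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_similarity <- function(path) {
  df <- read.delim(path, check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Convert an hclust tree to Newick text
#' @param hc an `stats::hclust` object.
#' @return single Newick string (with trailing semicolon).
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Persist a chain to a store directory
#'
#' Writes `chain.rds` (the `posterior_samples` object), a deterministic
#' `config.json` echo and a plain-text `progress.log` of per-sweep occupied
#' cluster counts.  Identical runs produce byte-identical stores.
#'
#' @param ps a `posterior_samples` object.
#' @param dir store directory (created if needed).
#' @export
write_chain <- function(ps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(ps, file.path(dir, "chain.rds"))
  cfg <- ps$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "nig")],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("%d\t%d", seq_along(ps$occupancy), ps$occupancy),
             file.path(dir, "progress.log"))
  invisible(dir)
}

#' Load a chain store written by [write_chain()]
#' @param dir store directory.
#' @return the `posterior_samples` object.
#' @export
read_chain <- function(dir) {
  f <- file.path(dir, "chain.rds")
  if (!file.exists(f))
    stop("no chain store found at '", dir,
         "'; run the sampler first (countHDP run / run_chain)")
  readRDS(f)
}
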