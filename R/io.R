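# Readers/writers for node features, sequence embeddings and split lists.

#' Read a node feature matrix
#'
#' Two dialects are supported and auto-detected from the first row:
#' a three-column sparse triplet file (`protein  feature_index  value`,
#' 1-based integer feature indices), or a dense table whose header row names
#' the features and whose first column holds protein ids.
#'
#' @param path feature file.
#' @param m feature dimension; required for the triplet dialect when indices
#'   beyond the observed maximum exist, otherwise inferred.
#' @return a `feature_matrix` (sparse).
#' @export
read_features <- function(path, m = NULL) {
  if (!file.exists(path)) stop_gtgo("feature file not found: ", path)
  first <- strsplit(trimws(readLines(path, n = 1)), "[ \t]+")[[1]]
  triplet <- length(first) == 3 &&
    !is.na(suppressWarnings(as.numeric(first[2])))
  if (triplet) {
    df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    ids <- unique(df[[1]])
    j <- as.integer(df[[2]])
    if (any(j < 1)) stop_gtgo("feature indices must be >= 1")
    if (is.null(m)) m <- max(j)
    if (max(j) > m) stop_gtgo("feature index exceeds declared dimension m")
    X <- Matrix::sparseMatrix(i = match(df[[1]], ids), j = j, x = df[[3]],
                              dims = c(length(ids), m))
    rownames(X) <- ids
    new_feature_matrix(X, ids)
  } else {
    df <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    ids <- as.character(df[[1]])
    X <- as(as.matrix(df[, -1, drop = FALSE]), "CsparseMatrix")
    rownames(X) <- ids
    new_feature_matrix(X, ids)
  }
}

#' Write a feature matrix as a sparse triplet TSV
#' @param features a `feature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(is(features, "feature_matrix"))
  trip <- Matrix::summary(as(features$X, "TsparseMatrix"))
  ord <- order(trip$i, trip$j)
  writeLines(sprintf("%s\t%d\t%.8g",
                     features$ids[trip$i[ord]], trip$j[ord], trip$x[ord]),
             path)
  invisible(path)
}

#' Read per-protein sequence embeddings
#'
#' One row per protein: the id followed by the embedding values
#' (whitespace/tab separated). All rows must share one dimension.
#'
#' @param path embedding TSV.
#' @return dense numeric matrix with protein ids as rownames.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop_gtgo("embedding file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  dims <- unique(lengths(parts)) - 1
  if (length(dims) != 1) stop_gtgo("embedding rows have differing dimensions")
  ids <- vapply(parts, `[`, character(1), 1)
  E <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims)))
  if (any(!is.finite(E))) stop_gtgo("non-finite embedding values in ", path)
  rownames(E) <- ids
  E
}

#' Write per-protein sequence embeddings
#' @param E numeric matrix, rownames are protein ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(E, path) {
  stopifnot(is.matrix(E), !is.null(rownames(E)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(E))) {
    writeLines(paste(c(rownames(E)[i], sprintf("%.8g", E[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a split id list (one protein per line, optional tag column)
#' @param path file with one id per line; a second column, when present,
#'   carries STRING/HOMO/NONE subset tags.
#' @return list with `ids` and `tags` (NULL when absent).
#' @export
read_split <- function(path) {
  if (!file.exists(path)) stop_gtgo("split file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(parts, `[`, character(1), 1)
  tags <- NULL
  if (any(lengths(parts) > 1)) {
    tags <- vapply(parts, function(p) if (length(p) > 1) p[2] else "NONE",
                   character(1))
    names(tags) <- ids
  }
  list(ids = ids, tags = tags)
}

#' Write a split id list
#' @param ids character vector of protein ids.
#' @param path output file.
#' @param tags optional named tag vector written as a second column.
#' @return `path`, invisibly.
#' @export
write_split <- function(ids, path, tags = NULL) {
  if (is.null(tags)) {
    writeLines(ids, path)
  } else {
    writeLines(paste(ids, tags[ids], sep = "\t"), path)
  }
  invisible(path)
}

#' Write a PPI network as a STRING-style edge list
#' @param network a `ppi_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(is(network, "ppi_network"))
  trip <- Matrix::summary(as(network$adjacency, "TsparseMatrix"))
  keep <- trip$i < trip$j
  trip <- trip[keep, , drop = FALSE]
  ord <- order(trip$i, trip$j)
  writeLines(sprintf("%s\t%s\t%.8g",
                     network$ids[trip$i[ord]], network$ids[trip$j[ord]],
                     trip$x[ord]),
             path)
  invisible(path)
}

#' Write an annotation table as (protein, term) pairs
#' @param annotations an `annotation_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(is(annotations, "annotation_matrix"))
  nz <- which(annotations$Y == 1, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  writeLines(paste(annotations$ids[nz[, 1]], annotations$terms[nz[, 2]],
                   sep = "\t"),
             path)
  invisible(path)
}
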