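# Data model and IO: PPI networks, node features, GO annotations, splits,
# and prediction matrices, all indexed by a shared ordered protein catalog.

new_ppi_network <- function(adjacency, ids) {
  stopifnot(nrow(adjacency) == length(ids))
  structure(
    list(adjacency = adjacency, ids = ids, n = length(ids)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  ne <- Matrix::nnzero(x$adjacency) / 2
  cat("PPI network:", x$n, "proteins,", ne, "weighted edges\n")
  invisible(x)
}

new_feature_matrix <- function(X, ids) {
  stopifnot(nrow(X) == length(ids))
  structure(list(X = X, ids = ids, m = ncol(X)), class = "feature_matrix")
}

new_annotation_matrix <- function(Y, ids, terms, domain = "MFO") {
  stopifnot(nrow(Y) == length(ids), ncol(Y) == length(terms))
  structure(
    list(Y = Y, ids = ids, terms = terms, domain = domain),
    class = "annotation_matrix"
  )
}

new_dataset_split <- function(train, valid, test, test_tags = NULL) {
  if (anyDuplicated(c(train, valid, test))) {
    stop_gtgo("train/valid/test lists must be pairwise disjoint")
  }
  structure(
    list(train = train, valid = valid, test = test, test_tags = test_tags),
    class = "dataset_split"
  )
}

new_prediction_matrix <- function(S, ids, terms) {
  stopifnot(nrow(S) == length(ids), ncol(S) == length(terms))
  if (any(!is.finite(S)) || any(S < 0) || any(S > 1)) {
    stop_gtgo("prediction scores must be finite and in [0, 1]")
  }
  dimnames(S) <- list(ids, terms)
  structure(list(S = S, ids = ids, terms = terms), class = "prediction_matrix")
}

#' Load a STRING-style weighted edge list as a PPI network
#'
#' Reads a whitespace/tab-delimited edge list (columns: protein a, protein b,
#' then the confidence in the last column, so STRING detailed-links files work
#' unmodified). If any weight exceeds 1 the whole file is assumed to be on the
#' STRING 0-1000 integer scale and all weights are divided by 1000. Duplicate
#' edges (in either orientation) are collapsed keeping the maximum confidence;
#' self-edges are dropped. The protein catalog follows first appearance in the
#' file.
#'
#' @param path edge-list file.
#' @param min_confidence edges with confidence (after scaling) strictly below
#'   this are dropped. Default 0 keeps everything.
#' @return a `ppi_network`: sparse symmetric adjacency with zero diagonal and
#'   entries in (0, 1].
#' @export
load_network <- function(path, min_confidence = 0) {
  if (!file.exists(path)) stop_gtgo("network file not found: ", path)
  stopifnot(min_confidence >= 0, min_confidence < 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop_gtgo("network file is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  a <- character(length(fields))
  b <- character(length(fields))
  w <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stop_gtgo("malformed network row at line ", i, ": expected >= 3 columns")
    }
    wt <- suppressWarnings(as.numeric(f[length(f)]))
    if (is.na(wt)) {
      stop_gtgo("malformed network row at line ", i, ": non-numeric weight")
    }
    if (wt < 0 || wt > 1000) {
      stop_gtgo("weight outside [0, 1000] at line ", i, ": ", wt)
    }
    a[i] <- f[1]
    b[i] <- f[2]
    w[i] <- wt
  }
  if (any(w > 1)) w <- w / 1000
  keep <- a != b & w >= min_confidence & w > 0
  a <- a[keep]
  b <- b[keep]
  w <- w[keep]
  # catalog in first-appearance order over both endpoint columns, row by row
  ids <- unique(as.vector(rbind(
    vapply(fields, `[`, character(1), 1),
    vapply(fields, `[`, character(1), 2)
  )))
  n <- length(ids)
  ia <- match(a, ids)
  ib <- match(b, ids)
  # canonical unordered orientation, then max-collapse duplicates
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  if (length(lo) > 0) {
    key <- paste(lo, hi)
    mx <- tapply(w, key, max)
    kk <- strsplit(names(mx), " ", fixed = TRUE)
    lo <- as.integer(vapply(kk, `[`, character(1), 1))
    hi <- as.integer(vapply(kk, `[`, character(1), 2))
    w <- as.numeric(mx)
  }
  adj <- Matrix::sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = c(w, w),
    dims = c(n, n), dimnames = list(ids, ids)
  )
  new_ppi_network(adj, ids)
}

#' Load a two-column (protein, GO term) annotation table
#'
#' Builds a binary protein-by-term matrix over the distinct proteins and terms
#' encountered, both in first-appearance order. Repeated pairs are idempotent.
#'
#' @param path TSV/whitespace-delimited file with columns protein id, GO term.
#' @param domain ontology domain tag, one of `"MFO"`, `"BPO"`, `"CCO"`.
#' @return an `annotation_matrix`.
#' @export
load_annotations <- function(path, domain = "MFO") {
  if (!file.exists(path)) stop_gtgo("annotation file not found: ", path)
  domain <- match.arg(domain, c("MFO", "BPO", "CCO"))
  if (length(readLines(path, n = 1, warn = FALSE)) == 0) {
    stop_gtgo("annotation file is empty: ", path)
  }
  df <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop_gtgo("cannot parse annotation file: ",
                                  conditionMessage(e))
  )
  if (nrow(df) == 0) stop_gtgo("annotation file is empty: ", path)
  if (ncol(df) < 2) stop_gtgo("annotation file needs two columns")
  prot <- df[[1]]
  term <- df[[2]]
  ids <- unique(prot)
  terms <- unique(term)
  Y <- matrix(0, length(ids), length(terms), dimnames = list(ids, terms))
  Y[cbind(match(prot, ids), match(term, terms))] <- 1
  new_annotation_matrix(Y, ids, terms, domain)
}

#' Align network, features and annotations onto one shared catalog
#'
#' The shared catalog is the union of all protein ids, network order first,
#' then proteins seen only in the feature or annotation tables. Proteins
#' missing from the network become isolated nodes; proteins without features
#' get all-zero feature rows; proteins without annotations get all-zero label
#' rows. Alignment is report-only: counts of padded entries are attached as
#' the `"alignment"` attribute and messaged.
#'
#' @param network a `ppi_network`.
#' @param features a `feature_matrix`.
#' @param annotations an `annotation_matrix`.
#' @param quiet suppress the alignment message.
#' @return list with aligned `network`, `features`, `annotations`, and `ids`.
#' @export
align_datasets <- function(network, features, annotations, quiet = FALSE) {
  stopifnot(is(network, "ppi_network"), is(features, "feature_matrix"),
            is(annotations, "annotation_matrix"))
  ids <- unique(c(network$ids, features$ids, annotations$ids))
  n <- length(ids)
  n_isolated <- sum(!(ids %in% network$ids))
  n_nofeat <- sum(!(ids %in% features$ids))
  n_noann <- sum(!(ids %in% annotations$ids))

  adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n), dimnames = list(ids, ids))
  pos <- match(network$ids, ids)
  adj[pos, pos] <- network$adjacency

  X <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, features$m))
  X[match(features$ids, ids), ] <- features$X
  rownames(X) <- ids

  Y <- matrix(0, n, length(annotations$terms),
              dimnames = list(ids, annotations$terms))
  Y[match(annotations$ids, ids), ] <- annotations$Y

  report <- c(isolated = n_isolated, no_features = n_nofeat,
              no_annotations = n_noann)
  if (!quiet) {
    message(sprintf(
      "aligned %d proteins (%d isolated, %d zero-feature, %d unannotated)",
      n, n_isolated, n_nofeat, n_noann))
  }
  out <- list(
    network = new_ppi_network(adj, ids),
    features = new_feature_matrix(X, ids),
    annotations = new_annotation_matrix(Y, ids, annotations$terms,
                                        annotations$domain),
    ids = ids
  )
  attr(out, "alignment") <- report
  out
}

#' Restrict the training list to proteins present in the PPI network
#'
#' Network-based training uses only labelled proteins that also appear in the
#' interaction network; validation and test lists are left untouched.
#'
#' @param split a `dataset_split`.
#' @param network a `ppi_network`.
#' @return a `dataset_split` with the intersected train list.
#' @export
restrict_training_to_network <- function(split, network) {
  stopifnot(is(split, "dataset_split"), is(network, "ppi_network"))
  train <- split$train[split$train %in% network$ids]
  if (length(train) == 0) {
    stop_gtgo("no training proteins remain after network restriction")
  }
  new_dataset_split(train, split$valid, split$test, split$test_tags)
}

#' Write predictions as a three-column TSV
#'
#' One `protein <TAB> term <TAB> score` row per nonzero score (zeros are
#' omitted and restored on read). The full protein and term catalogs are
#' recorded in commented header lines so an all-zero matrix round-trips.
#' Scores are printed with 8 significant digits.
#'
#' @param pred a `prediction_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(is(pred, "prediction_matrix"))
  S <- pred$S
  if (any(!is.finite(S)) || any(S < 0) || any(S > 1)) {
    stop_gtgo("prediction scores must be finite and in [0, 1]")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#proteins\t", paste(pred$ids, collapse = "\t")), con)
  writeLines(paste0("#terms\t", paste(pred$terms, collapse = "\t")), con)
  nz <- which(S != 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
    writeLines(sprintf("%s\t%s\t%.8g",
                       pred$ids[nz[, 1]], pred$terms[nz[, 2]],
                       S[nz]), con)
  }
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#' @param path prediction TSV.
#' @return a `prediction_matrix`.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop_gtgo("prediction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(tag) {
    ln <- hdr[startsWith(hdr, paste0("#", tag, "\t"))]
    if (length(ln) != 1) stop_gtgo("missing #", tag, " header in ", path)
    strsplit(ln, "\t", fixed = TRUE)[[1]][-1]
  }
  ids <- get_hdr("proteins")
  terms <- get_hdr("terms")
  S <- matrix(0, length(ids), length(terms), dimnames = list(ids, terms))
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) != 3) stop_gtgo("malformed prediction row: ", body[i])
      ri <- match(p[1], ids)
      ci <- match(p[2], terms)
      if (is.na(ri) || is.na(ci)) {
        stop_gtgo("prediction row references unknown protein/term: ", body[i])
      }
      S[ri, ci] <- as.numeric(p[3])
    }
  }
  new_prediction_matrix(S, ids, terms)
}

#' Build a dataset split from id vectors
#' @param train,valid,test disjoint character vectors of protein ids.
#' @param test_tags optional named character vector tagging test proteins as
#'   `"STRING"`, `"HOMO"` or `"NONE"` (names are protein ids).
#' @return a `dataset_split`.
#' @export
dataset_split <- function(train, valid = character(0), test = character(0),
                          test_tags = NULL) {
  new_dataset_split(train, valid, test, test_tags)
}
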