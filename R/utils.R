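# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded generators do not perturb surrounding randomness.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Fan one user-level seed out to independent per-component substreams, so a
# change in one component's draws never shifts another's. Kept below 2^31.
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) + 99991 * as.numeric(k)) %% 2147483629)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Named activation lookup; "identity" is a test hook used to obtain linear
# closed forms.
get_activation <- function(name) {
  switch(name,
    relu = relu,
    identity = identity,
    stop("unknown activation: ", name, call. = FALSE)
  )
}

activation_deriv <- function(name, pre) {
  switch(name,
    relu = (pre > 0) * 1,
    identity = array(1, dim = dim(pre)),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else x
}

stop_gtgo <- function(...) stop(..., call. = FALSE)

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored. Values that parse as numbers are returned numeric, `TRUE`/`FALSE`
#' logical, everything else character.
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_gtgo("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop_gtgo("malformed config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (val %in% c("TRUE", "FALSE", "true", "false")) {
      as.logical(toupper(val))
    } else {
      val
    }
  }
  out
}

#' Write a flat key = value configuration file
#' @param config named list of scalar values.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", format(v, digits = 17, scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
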