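# CAFA-style protein-centric evaluation: Fmax over a threshold grid,
# micro-averaged AUPR over all (protein, term) pairs, and per-subset
# reports (STRING / HOMO / NONE membership supplied, never inferred).

# Coerce (annotation, prediction) inputs onto aligned plain matrices and
# drop proteins with zero true annotations (protein-centric convention:
# their recall denominator would be 0).
eval_align <- function(Y, S) {
  if (is(Y, "annotation_matrix")) Y <- Y$Y
  if (is(S, "prediction_matrix")) S <- S$S
  if (!is.null(rownames(Y)) && !is.null(rownames(S))) {
    common <- intersect(rownames(S), rownames(Y))
    if (length(common) == 0) stop_gtgo("no shared proteins to evaluate")
    Y <- Y[common, , drop = FALSE]
    Sal <- matrix(0, length(common), ncol(Y),
                  dimnames = list(common, colnames(Y)))
    shared_terms <- intersect(colnames(S), colnames(Y))
    if (!is.null(colnames(S)) && length(shared_terms) > 0) {
      Sal[, shared_terms] <- S[common, shared_terms, drop = FALSE]
      S <- Sal
    } else {
      S <- S[common, , drop = FALSE]
    }
  }
  if (!all(dim(Y) == dim(S))) {
    stop_gtgo("annotation and prediction matrices must align")
  }
  keep <- rowSums(Y) > 0
  list(Y = Y[keep, , drop = FALSE], S = S[keep, , drop = FALSE])
}

#' Protein-centric precision and recall at one threshold
#'
#' A term is called predicted for a protein when its score is `>= tau`.
#' Precision averages true-positive fractions over the `N(tau)` proteins
#' with at least one call; recall averages over all evaluated proteins
#' (those with at least one true annotation — others are excluded).
#'
#' @param Y binary annotation matrix (or `annotation_matrix`).
#' @param S score matrix (or `prediction_matrix`), aligned with `Y`.
#' @param tau threshold in \[0, 1\]; at `tau = 0` every term is called.
#' @return list with `pr` (NA when `N(tau)` is 0), `rc`, and `n_pred` =
#'   `N(tau)`.
#' @export
precision_recall_at_threshold <- function(Y, S, tau) {
  al <- eval_align(Y, S)
  Y <- al$Y; S <- al$S
  P <- S >= tau
  npred <- rowSums(P)
  tp <- rowSums(P & (Y == 1))
  npos <- rowSums(Y)
  covered <- npred > 0
  pr <- if (any(covered)) mean(tp[covered] / npred[covered]) else NA_real_
  rc <- mean(tp / npos)
  list(pr = pr, rc = rc, n_pred = sum(covered))
}

#' Fmax: maximum harmonic mean of precision and recall over a threshold grid
#'
#' Scans `tau` over `{0, step, ..., 1}`, computes protein-centric precision
#' and recall at each, and returns the maximum `2 pr rc / (pr + rc)`.
#' Thresholds where precision is undefined (no protein has a call) or where
#' `pr + rc = 0` are skipped; the smallest maximizing threshold is reported.
#'
#' @inheritParams precision_recall_at_threshold
#' @param step grid step (default 0.01).
#' @return list with `fmax`, `tau` (smallest maximizer), and `table`
#'   (per-threshold tau, pr, rc, n_pred, f).
#' @export
fmax <- function(Y, S, step = 0.01) {
  al <- eval_align(Y, S)
  taus <- seq(0, 1, by = step)
  tab <- data.frame(tau = taus, pr = NA_real_, rc = NA_real_,
                    n_pred = NA_integer_, f = NA_real_)
  for (i in seq_along(taus)) {
    r <- precision_recall_at_threshold(al$Y, al$S, taus[i])
    tab$pr[i] <- r$pr
    tab$rc[i] <- r$rc
    tab$n_pred[i] <- r$n_pred
    if (!is.na(r$pr) && (r$pr + r$rc) > 0) {
      tab$f[i] <- 2 * r$pr * r$rc / (r$pr + r$rc)
    }
  }
  if (all(is.na(tab$f))) stop_gtgo("no threshold yields a defined F-measure")
  best <- which.max(tab$f)  # first index attaining the max
  list(fmax = tab$f[best], tau = tab$tau[best], table = tab)
}

#' Micro-averaged area under the precision-recall curve
#'
#' Flattens all (protein, term) pairs, ranks them by score descending, and
#' computes average precision: each positive contributes the precision at
#' its rank, with tied scores handled as one group (every positive in a
#' group receives the precision at the group boundary).
#'
#' @inheritParams precision_recall_at_threshold
#' @return scalar in \[0, 1\].
#' @export
micro_aupr <- function(Y, S) {
  al <- eval_align(Y, S)
  y <- as.vector(al$Y)
  s <- as.vector(al$S)
  npos <- sum(y)
  if (npos == 0) stop_gtgo("no positive pairs to evaluate")
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  grp <- rle(s)
  ends <- cumsum(grp$lengths)
  cum_tp <- cumsum(y)[ends]
  prec_g <- cum_tp / ends
  tp_in_grp <- diff(c(0, cum_tp))
  sum(tp_in_grp * prec_g) / npos
}

#' Full evaluation report with optional subset breakdown
#'
#' Computes overall Fmax and micro-AUPR; when subset tags (STRING / HOMO /
#' NONE membership) are supplied, recomputes both metrics restricted to the
#' proteins of each tag class.
#'
#' @inheritParams precision_recall_at_threshold
#' @param subset_tags optional named character vector (names are protein
#'   ids) tagging each evaluated protein.
#' @return an `evaluation_report`: `fmax`, `tau`, `aupr` (micro),
#'   `n_proteins`, `thresholds` table, and `subsets` (list of sub-reports).
#' @export
evaluate_predictions <- function(Y, S, subset_tags = NULL) {
  al <- eval_align(Y, S)
  fm <- fmax(al$Y, al$S)
  au <- micro_aupr(al$Y, al$S)
  subsets <- NULL
  if (!is.null(subset_tags)) {
    unknown <- setdiff(names(subset_tags), rownames(al$Y))
    # tags may reference proteins filtered out for having no annotations;
    # but tags for proteins never seen at all are an error
    if (is(Y, "annotation_matrix")) {
      unknown <- setdiff(names(subset_tags), Y$ids)
    }
    if (length(unknown) > 0) {
      stop_gtgo("subset tags reference unknown proteins: ",
                paste(unknown, collapse = ", "))
    }
    subsets <- list()
    for (tag in unique(subset_tags)) {
      members <- intersect(names(subset_tags)[subset_tags == tag],
                           rownames(al$Y))
      if (length(members) == 0) next
      Ys <- al$Y[members, , drop = FALSE]
      Ss <- al$S[members, , drop = FALSE]
      fms <- fmax(Ys, Ss)
      subsets[[tag]] <- list(fmax = fms$fmax, tau = fms$tau,
                             aupr = micro_aupr(Ys, Ss),
                             n_proteins = length(members))
    }
  }
  structure(list(fmax = fm$fmax, tau = fm$tau, aupr = au,
                 aupr_flavor = "micro",
                 n_proteins = nrow(al$Y), thresholds = fm$table,
                 subsets = subsets),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Fmax  %.4f (tau* = %.2f)\nAUPR  %.4f (micro)\nproteins  %d\n",
              x$fmax, x$tau, x$aupr, x$n_proteins))
  if (!is.null(x$subsets)) {
    for (tag in names(x$subsets)) {
      s <- x$subsets[[tag]]
      cat(sprintf("  %-6s Fmax %.4f  AUPR %.4f  (n = %d)\n", tag, s$fmax,
                  s$aupr, s$n_proteins))
    }
  }
  invisible(x)
}
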