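# Brute-force oracles and fixture builders shared across the suite.
# The oracles are written from first principles (explicit loops, set
# operations) and stay independent of the package's vectorized paths.

# Protein-centric Fmax recomputed with explicit per-protein loops.
bf_fmax <- function(Y, S, step = 0.01) {
  keep <- rowSums(Y) > 0
  Y <- Y[keep, , drop = FALSE]
  S <- S[keep, , drop = FALSE]
  best <- -Inf
  best_tau <- NA_real_
  for (tau in seq(0, 1, by = step)) {
    prs <- numeric(0)
    rcs <- numeric(0)
    for (i in seq_len(nrow(Y))) {
      pred <- which(S[i, ] >= tau)
      truth <- which(Y[i, ] == 1)
      tp <- length(intersect(pred, truth))
      if (length(pred) > 0) prs <- c(prs, tp / length(pred))
      rcs <- c(rcs, tp / length(truth))
    }
    if (length(prs) == 0) next
    pr <- mean(prs)
    rc <- mean(rcs)
    if (pr + rc == 0) next
    f <- 2 * pr * rc / (pr + rc)
    if (f > best) {
      best <- f
      best_tau <- tau
    }
  }
  list(fmax = best, tau = best_tau)
}

# Micro average precision recomputed with set comparisons per unique score
# (group-level precision for ties).
bf_aupr <- function(Y, S) {
  keep <- rowSums(Y) > 0
  y <- as.vector(Y[keep, , drop = FALSE])
  s <- as.vector(S[keep, , drop = FALSE])
  npos <- sum(y)
  total <- 0
  for (g in sort(unique(s[y == 1]), decreasing = TRUE)) {
    k <- sum(y == 1 & s == g)
    prec <- sum(y == 1 & s >= g) / sum(s >= g)
    total <- total + k * prec
  }
  total / npos
}

# Random multi-label evaluation instance (every protein gets >= 1 positive).
rand_eval_instance <- function(n = 5, M = 6) {
  Y <- matrix(rbinom(n * M, 1, 0.35), n, M)
  empty <- rowSums(Y) == 0
  Y[cbind(which(empty), sample(M, sum(empty), replace = TRUE))] <- 1
  S <- matrix(runif(n * M), n, M)
  list(Y = Y, S = S)
}

# Random attention parameter set.
rand_sga_params <- function(d, scale = 0.5) {
  list(
    WQ = matrix(rnorm(d * d, sd = scale), d, d),
    WK = matrix(rnorm(d * d, sd = scale), d, d),
    WV = matrix(rnorm(d * d, sd = scale), d, d),
    bQ = rnorm(d, sd = 0.1), bK = rnorm(d, sd = 0.1),
    bV = rnorm(d, sd = 0.1)
  )
}

# Random weighted undirected graph as a ppi_network.
rand_network <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A), arr.ind = TRUE)
  on <- runif(nrow(up)) < p
  w <- runif(sum(on), 0.15, 1)
  A[up[on, , drop = FALSE]] <- w
  A <- A + t(A)
  ids <- sprintf("N%03d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  gtgo:::new_ppi_network(methods::as(A, "CsparseMatrix"), ids)
}

# Tiny synthetic dataset + aligned bundle for training tests.
tiny_bundle <- function(cfg = sim_config(n_modules = 3,
                                         proteins_per_module = 20,
                                         emb_dim = 16, m_features = 30,
                                         features_per_module = 8,
                                         n_terms = 12, terms_per_module = 4,
                                         seed = 11),
                        fractions = c(0.7, 0.15, 0.15)) {
  ds <- simulate_dataset(cfg, split_fractions = fractions)
  data <- assemble_dataset(ds$network, ds$features, ds$annotations,
                           ds$seq_embeddings)
  split <- restrict_training_to_network(ds$split, data$network)
  list(ds = ds, data = data, split = split)
}

# Test-set label slice helper.
labels_for <- function(ds, ids) ds$annotations$Y[ids, , drop = FALSE]
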