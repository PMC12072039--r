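# Seeded synthetic benchmark generator. Functional modules are planted
# jointly in the network topology (planted-partition edges), the sparse
# binary node features (module-owned feature blocks), the multi-label
# annotations (module-owned term blocks) and the sequence embeddings
# (module-separated Gaussians), so that every branch of the model has a
# controllable amount of signal.

#' Synthetic benchmark configuration
#'
#' Defaults describe the standard desk-scale fixture: a 4-module
#' planted-partition network of 100 proteins with dense within-module
#' connectivity (p_in = 0.5) against sparse background (p_out = 0.05),
#' module-owned InterPro-like feature blocks with light activation noise,
#' noise-free module-driven labels, and 1024-d Gaussian sequence embeddings
#' whose module centroids sit `emb_separation` apart along orthogonal axes.
#'
#' @param n_modules number of planted functional modules.
#' @param proteins_per_module proteins per module (>= 2).
#' @param p_in,p_out within/between-module edge probabilities.
#' @param weight_low,weight_high edge-confidence range, a subset of (0, 1].
#' @param m_features total feature dimension.
#' @param features_per_module features owned by each module.
#' @param feature_on_prob probability a module member activates an owned
#'   feature.
#' @param feature_noise_prob probability any non-owned cell activates.
#' @param n_terms total GO terms.
#' @param terms_per_module terms owned by each module.
#' @param label_flip_prob per-cell label flip probability (0 = noise-free).
#' @param emb_dim sequence embedding dimension.
#' @param emb_separation distance scale between module centroids: centroid k
#'   is `emb_separation * e_k` so distinct centroids are
#'   `emb_separation * sqrt(2)` apart.
#' @param seed global seed fanned out to per-generator substreams.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_modules = 4, proteins_per_module = 25,
                       p_in = 0.5, p_out = 0.05,
                       weight_low = 0.4, weight_high = 1,
                       m_features = 40, features_per_module = 8,
                       feature_on_prob = 0.8, feature_noise_prob = 0.02,
                       n_terms = 20, terms_per_module = 5,
                       label_flip_prob = 0,
                       emb_dim = 1024, emb_separation = 4,
                       seed = 0) {
  stopifnot(n_modules >= 1, proteins_per_module >= 2,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            weight_low > 0, weight_high <= 1, weight_low <= weight_high,
            feature_on_prob >= 0, feature_on_prob <= 1,
            feature_noise_prob >= 0, feature_noise_prob <= 1,
            label_flip_prob >= 0, label_flip_prob <= 1,
            emb_separation >= 0)
  if (n_modules * terms_per_module > n_terms) {
    stop_gtgo("n_modules * terms_per_module must not exceed n_terms")
  }
  if (p_in < p_out) {
    warning("p_in < p_out: modules will be anti-assortative", call. = FALSE)
  }
  cfg <- list(
    n_modules = n_modules, proteins_per_module = proteins_per_module,
    p_in = p_in, p_out = p_out,
    weight_low = weight_low, weight_high = weight_high,
    m_features = m_features, features_per_module = features_per_module,
    feature_on_prob = feature_on_prob,
    feature_noise_prob = feature_noise_prob,
    n_terms = n_terms, terms_per_module = terms_per_module,
    label_flip_prob = label_flip_prob,
    emb_dim = emb_dim, emb_separation = emb_separation,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

sim_ids <- function(cfg) {
  n <- cfg$n_modules * cfg$proteins_per_module
  sprintf("P%04d", seq_len(n))
}

sim_assignment <- function(cfg) {
  setNames(rep(seq_len(cfg$n_modules), each = cfg$proteins_per_module),
           sim_ids(cfg))
}

#' Simulate a planted-partition weighted PPI network
#'
#' Each unordered protein pair receives an edge with probability `p_in` when
#' both proteins share a module and `p_out` otherwise; edge confidences are
#' uniform on `[weight_low, weight_high]`. Isolated proteins are permitted
#' (they occur in real interactomes).
#'
#' @param cfg a `sim_config`.
#' @return list with `network` (a `ppi_network`) and `assignment` (named
#'   integer vector, protein id to module).
#' @export
simulate_network <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  assignment <- sim_assignment(cfg)
  ids <- names(assignment)
  n <- length(ids)
  with_seed(seed_stream(cfg$seed, 1), {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- assignment[pairs[, 1]] == assignment[pairs[, 2]]
    p <- ifelse(same, cfg$p_in, cfg$p_out)
    has_edge <- runif(nrow(pairs)) < p
    w <- runif(sum(has_edge), cfg$weight_low, cfg$weight_high)
    i <- pairs[has_edge, 1]
    j <- pairs[has_edge, 2]
    adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                                dims = c(n, n), dimnames = list(ids, ids))
    list(network = new_ppi_network(adj, ids), assignment = assignment)
  })
}

#' Simulate module-correlated sparse binary node features
#'
#' Module k owns the k-th block of `features_per_module` consecutive
#' features. An owned cell activates with probability `feature_on_prob` for
#' module members; every other cell activates with probability
#' `feature_noise_prob`.
#'
#' @param assignment named module assignment from [simulate_network()].
#' @param cfg a `sim_config`.
#' @return a binary `feature_matrix`.
#' @export
simulate_features <- function(assignment, cfg) {
  stopifnot(is(cfg, "sim_config"))
  if (cfg$m_features < cfg$n_modules * cfg$features_per_module) {
    stop_gtgo("m_features must be >= n_modules * features_per_module")
  }
  ids <- names(assignment)
  n <- length(ids)
  m <- cfg$m_features
  with_seed(seed_stream(cfg$seed, 2), {
    owner <- rep(NA_integer_, m)
    owned <- seq_len(cfg$n_modules * cfg$features_per_module)
    owner[owned] <- rep(seq_len(cfg$n_modules), each = cfg$features_per_module)
    member <- outer(unname(assignment), owner, `==`)
    member[is.na(member)] <- FALSE
    p <- ifelse(member, cfg$feature_on_prob, cfg$feature_noise_prob)
    X <- matrix(as.numeric(runif(n * m) < p), n, m)
    rownames(X) <- ids
    new_feature_matrix(as(X, "CsparseMatrix"), ids)
  })
}

#' Simulate module-driven multi-label GO annotations
#'
#' Module k's members are positive for its `terms_per_module` owned terms;
#' every (protein, term) cell is then flipped independently with probability
#' `label_flip_prob`; unowned terms stay background-negative apart from
#' flips.
#'
#' @param assignment named module assignment.
#' @param cfg a `sim_config`.
#' @return an `annotation_matrix` with terms `GO:SYN0001`, ...
#' @export
simulate_annotations <- function(assignment, cfg) {
  stopifnot(is(cfg, "sim_config"))
  ids <- names(assignment)
  n <- length(ids)
  M <- cfg$n_terms
  terms <- sprintf("GO:SYN%04d", seq_len(M))
  with_seed(seed_stream(cfg$seed, 3), {
    owner <- rep(NA_integer_, M)
    owned <- seq_len(cfg$n_modules * cfg$terms_per_module)
    owner[owned] <- rep(seq_len(cfg$n_modules), each = cfg$terms_per_module)
    base <- outer(unname(assignment), owner, `==`)
    base[is.na(base)] <- FALSE
    flips <- matrix(runif(n * M) < cfg$label_flip_prob, n, M)
    Y <- (base != flips) * 1
    dimnames(Y) <- list(ids, terms)
    new_annotation_matrix(Y, ids, terms, "MFO")
  })
}

#' Simulate module-separated Gaussian sequence embeddings
#'
#' Stands in for precomputed protein language model vectors: a protein in
#' module k is drawn from `Normal(mu_k, I)` with `mu_k = emb_separation *
#' e_k` on the first `n_modules` coordinate axes, so centroids of distinct
#' modules are `emb_separation * sqrt(2)` apart.
#'
#' @param assignment named module assignment.
#' @param cfg a `sim_config`.
#' @return dense numeric matrix (proteins by `emb_dim`) with id rownames.
#' @export
simulate_sequence_embeddings <- function(assignment, cfg) {
  stopifnot(is(cfg, "sim_config"))
  if (cfg$emb_dim < cfg$n_modules) {
    stop_gtgo("emb_dim must be >= n_modules for orthogonal centroids")
  }
  ids <- names(assignment)
  n <- length(ids)
  with_seed(seed_stream(cfg$seed, 4), {
    E <- matrix(rnorm(n * cfg$emb_dim), n, cfg$emb_dim)
    E[cbind(seq_len(n), unname(assignment))] <-
      E[cbind(seq_len(n), unname(assignment))] + cfg$emb_separation
    rownames(E) <- ids
    E
  })
}

#' Stratified train/valid/test split
#'
#' When a module assignment is supplied the split is stratified by module
#' (fractions honoured to +/- 1 protein per stratum); otherwise proteins are
#' shuffled as one stratum. Deterministic per seed.
#'
#' @param ids protein catalog (character vector).
#' @param fractions numeric length-3 vector (train, valid, test) summing
#'   to 1.
#' @param seed integer seed.
#' @param assignment optional named module assignment for stratification.
#' @return a `dataset_split`.
#' @export
make_split <- function(ids, fractions = c(0.6, 0.2, 0.2), seed = 0,
                       assignment = NULL) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  strata <- if (is.null(assignment)) {
    list(ids)
  } else {
    split(ids, unname(assignment[ids]))
  }
  train <- valid <- test <- character(0)
  with_seed(seed_stream(seed, 5), {
    for (s in strata) {
      s <- sample(s)
      n <- length(s)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      n_va <- min(n_va, n - n_tr)
      train <- c(train, s[seq_len(n_tr)])
      if (n_va > 0) valid <- c(valid, s[n_tr + seq_len(n_va)])
      if (n - n_tr - n_va > 0) test <- c(test, s[(n_tr + n_va + 1):n])
    }
  })
  new_dataset_split(train, valid, test)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running every generator off one `sim_config`, plus a
#' stratified split. Every component draws from an independent substream of
#' `cfg$seed`, so repeated calls are bitwise identical.
#'
#' @param cfg a `sim_config`.
#' @param split_fractions train/valid/test fractions for [make_split()].
#' @return list with `network`, `features`, `annotations`, `seq_embeddings`,
#'   `assignment`, `split`, and the echoed `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(),
                             split_fractions = c(0.6, 0.2, 0.2)) {
  net <- simulate_network(cfg)
  feats <- simulate_features(net$assignment, cfg)
  ann <- simulate_annotations(net$assignment, cfg)
  emb <- simulate_sequence_embeddings(net$assignment, cfg)
  split <- make_split(net$network$ids, split_fractions, seed = cfg$seed,
                      assignment = net$assignment)
  list(network = net$network, features = feats, annotations = ann,
       seq_embeddings = emb, assignment = net$assignment, split = split,
       config = cfg)
}
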