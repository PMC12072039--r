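test_that("embed_nodes applies the affine map and nonlinearity", {
  d <- 3
  W0 <- diag(3)
  b0 <- c(-1, 0, 1)
  X <- matrix(0, 2, 3)
  H <- embed_nodes(X, W0, b0)
  expect_equal(H, matrix(rep(c(0, 0, 1), each = 2), 2, 3))

  # identity hook, X = I, W0 = I, b = 0
  expect_equal(embed_nodes(diag(3), diag(3), rep(0, 3),
                           activation = "identity"), diag(3))

  # random case vs naive triple loop
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  W0 <- matrix(rnorm(9), 3, 3)
  b0 <- rnorm(3)
  ref <- matrix(0, 4, 3)
  for (i in 1:4) for (j in 1:3) {
    acc <- b0[j]
    for (k in 1:3) acc <- acc + X[i, k] * W0[k, j]
    ref[i, j] <- max(0, acc)
  }
  expect_equal(embed_nodes(X, W0, b0), ref, tolerance = 1e-12)

  expect_error(embed_nodes(matrix(0, 2, 4), W0, b0), "dimension")
})

test_that("frobenius_normalize yields unit norm and matches a loop computation", {
  expect_equal(frobenius_normalize(2 * diag(2)), diag(2) / sqrt(2))
  set.seed(2)
  M <- matrix(rnorm(20), 5, 4)
  rss <- 0
  for (v in as.vector(M)) rss <- rss + v^2
  expect_equal(frobenius_normalize(M), M / sqrt(rss), tolerance = 1e-12)
  expect_equal(sqrt(sum(frobenius_normalize(M)^2)), 1, tolerance = 1e-12)
  expect_error(frobenius_normalize(matrix(0, 2, 2)), "zero")
})

test_that("sga_linear handles the closed-form corner cases", {
  set.seed(3)
  d <- 4
  params <- rand_sga_params(d)
  # N = 1: numerator and normalizer cancel, leaving V + H0
  H1 <- matrix(rnorm(d), 1, d)
  V1 <- H1 %*% params$WV + rep(1, 1) %o% params$bV
  expect_equal(sga_linear(H1, params), V1 + H1, tolerance = 1e-12)

  # antisymmetric K rows (column sums 0) force D = I
  h <- rnorm(d)
  H0 <- rbind(h, -h)
  params0 <- rand_sga_params(d)
  params0$bK <- rep(0, d)  # keeps K = H0 WK antisymmetric
  K <- H0 %*% params0$WK
  expect_equal(colSums(K), rep(0, d), tolerance = 1e-12)
  Q <- sweep(H0 %*% params0$WQ, 2, params0$bQ, `+`)
  V <- sweep(H0 %*% params0$WV, 2, params0$bV, `+`)
  Qn <- Q / sqrt(sum(Q^2))
  Kn <- K / sqrt(sum(K^2))
  manual <- V + (Qn %*% (t(Kn) %*% V)) / 2 + H0
  expect_equal(sga_linear(H0, params0), manual, tolerance = 1e-12)
})

test_that("sga_linear agrees with the dense oracle and is permutation-equivariant", {
  set.seed(4)
  worst <- 0
  for (i in 1:100) {
    n <- sample(3:64, 1)
    d <- sample(2:16, 1)
    H0 <- matrix(rnorm(n * d), n, d)
    params <- rand_sga_params(d)
    a <- sga_linear(H0, params)
    b <- sga_dense_oracle(H0, params)
    worst <- max(worst, max(abs(a - b)))
  }
  expect_lt(worst, 1e-5)

  # permuting node order permutes output rows
  n <- 12; d <- 5
  H0 <- matrix(rnorm(n * d), n, d)
  params <- rand_sga_params(d)
  perm <- sample(n)
  expect_equal(sga_linear(H0[perm, ], params), sga_linear(H0, params)[perm, ],
               tolerance = 1e-10)

  # the normalizer equals 1 + mean attention score per row (dense route)
  Q <- sweep(H0 %*% params$WQ, 2, params$bQ, `+`)
  K <- sweep(H0 %*% params$WK, 2, params$bK, `+`)
  Qn <- frobenius_normalize(Q); Kn <- frobenius_normalize(K)
  P <- Qn %*% t(Kn) / n
  s <- colSums(Kn)
  expect_equal(1 + as.vector(Qn %*% s) / n, unname(1 + rowSums(P)),
               tolerance = 1e-12)
})

test_that("transformer_encoder composes attention, layer norm and MLP", {
  set.seed(5)
  d <- 4
  H0 <- matrix(rnorm(20), 5, d)
  params <- c(rand_sga_params(d), list(
    ln_scale = rep(1, d), ln_shift = rep(0, d),
    Wm1 = diag(d), bm1 = rep(0, d), Wm2 = diag(d), bm2 = rep(0, d)))

  # identity MLP hook reduces the encoder to LN(SGA(H0))
  expect_equal(
    transformer_encoder(H0, params, activation = "identity"),
    layer_norm(sga_linear(H0, params), params$ln_scale, params$ln_shift),
    tolerance = 1e-12)

  # a constant row layer-normalizes to the shift vector
  const <- matrix(3, 2, d)
  expect_equal(layer_norm(const, rep(1, d), rep(0, d)), matrix(0, 2, d))
  expect_equal(layer_norm(const, rep(1, d), rep(2, d)), matrix(2, 2, d))

  # random parameters match the stage-by-stage composition
  params$Wm1 <- matrix(rnorm(d * d), d, d)
  params$Wm2 <- matrix(rnorm(d * d), d, d)
  params$bm1 <- rnorm(d); params$bm2 <- rnorm(d)
  params$ln_scale <- rnorm(d); params$ln_shift <- rnorm(d)
  L <- layer_norm(sga_linear(H0, params), params$ln_scale, params$ln_shift)
  M1 <- pmax(sweep(L %*% params$Wm1, 2, params$bm1, `+`), 0)
  ref <- sweep(M1 %*% params$Wm2, 2, params$bm2, `+`)
  expect_equal(transformer_encoder(H0, params), ref, tolerance = 1e-12)

  # outer-residual reading adds H0 before the norm
  L2 <- layer_norm(sga_linear(H0, params) + H0, params$ln_scale,
                   params$ln_shift)
  M2 <- pmax(sweep(L2 %*% params$Wm1, 2, params$bm1, `+`), 0)
  ref2 <- sweep(M2 %*% params$Wm2, 2, params$bm2, `+`)
  expect_equal(transformer_encoder(H0, params, outer_residual = TRUE), ref2,
               tolerance = 1e-12)
})

test_that("normalize_adjacency matches closed forms and a loop computation", {
  # edgeless network -> identity
  empty <- gtgo:::new_ppi_network(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(3, 3)), c("a", "b", "c"))
  expect_equal(as.matrix(normalize_adjacency(empty)), diag(3),
               ignore_attr = TRUE)

  # two nodes, unit weight: all entries 0.5
  two <- gtgo:::new_ppi_network(
    Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 1)),
    c("a", "b"))
  expect_equal(as.matrix(normalize_adjacency(two)),
               matrix(0.5, 2, 2), ignore_attr = TRUE)

  # 3-node path, weights 0.5/0.5, vs explicit loop
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5
  A[2, 3] <- A[3, 2] <- 0.5
  path <- gtgo:::new_ppi_network(methods::as(A, "CsparseMatrix"),
                                 c("a", "b", "c"))
  At <- A + diag(3)
  dg <- rowSums(At)
  ref <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) ref[i, j] <- At[i, j] / sqrt(dg[i] * dg[j])
  expect_equal(as.matrix(normalize_adjacency(path)), ref,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("gcn_layer keeps the residual outside the nonlinearity", {
  set.seed(6)
  H <- abs(matrix(rnorm(12), 4, 3))
  eye <- normalize_adjacency(gtgo:::new_ppi_network(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(4, 4)), sprintf("n%d", 1:4)))
  # edgeless graph, W = I, H >= 0: doubling
  expect_equal(gcn_layer(H, eye, diag(3)), 2 * H, ignore_attr = TRUE)
  # W = 0: residual only
  expect_equal(gcn_layer(H, eye, matrix(0, 3, 3)), H, ignore_attr = TRUE)
})

test_that("gcn matrix form equals the nodewise oracle and is equivariant", {
  set.seed(7)
  net <- rand_network(6, p = 0.5)
  H <- matrix(rnorm(6 * 4), 6, 4)
  W <- matrix(rnorm(16), 4, 4)
  A_hat <- normalize_adjacency(net)
  expect_equal(gcn_layer(H, A_hat, W), gcn_nodewise_oracle(H, net, W),
               tolerance = 1e-6, ignore_attr = TRUE)

  # single isolated node
  iso <- gtgo:::new_ppi_network(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(1, 1)), "solo")
  h <- matrix(rnorm(4), 1, 4)
  expect_equal(gcn_nodewise_oracle(h, iso, W),
               h + pmax(h %*% W, 0), tolerance = 1e-12)

  # node relabeling permutes rows
  perm <- sample(6)
  A <- as.matrix(net$adjacency)[perm, perm]
  netp <- gtgo:::new_ppi_network(methods::as(A, "CsparseMatrix"),
                                 net$ids[perm])
  expect_equal(gcn_layer(H[perm, ], normalize_adjacency(netp), W),
               gcn_layer(H, A_hat, W)[perm, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("gcn_forward composes layers; ppi_embedding stacks the two blocks", {
  set.seed(8)
  net <- rand_network(5, p = 0.5)
  A_hat <- normalize_adjacency(net)
  H0 <- matrix(rnorm(15), 5, 3)
  W1 <- matrix(rnorm(9), 3, 3)
  W2 <- matrix(rnorm(9), 3, 3)
  # composition is definitional
  expect_equal(gcn_forward(H0, A_hat, list(W1, W2)),
               gcn_layer(gcn_layer(H0, A_hat, W1), A_hat, W2))
  # both W = 0: identity
  z <- matrix(0, 3, 3)
  expect_equal(gcn_forward(H0, A_hat, list(z, z)), H0)

  HT <- matrix(rnorm(15), 5, 3)
  HG <- matrix(rnorm(15), 5, 3)
  emb <- ppi_embedding(HG, HT)
  expect_equal(dim(emb), c(5, 6))
  expect_equal(emb[, 1:3], HG)
  expect_equal(emb[, 4:6], HT)
  expect_equal(ppi_embedding(HG, matrix(0, 5, 3))[, 4:6], matrix(0, 5, 3))
  expect_error(ppi_embedding(HG, HT[1:4, ]), "row count")
})

test_that("the full PPI branch is permutation-equivariant", {
  set.seed(9)
  bundle <- tiny_bundle()
  data <- bundle$data
  tc <- training_config(hidden_d = 8, dropout = 0, seed = 1)
  model <- init_model(ncol(data$X), ncol(data$Hseq), data$terms, tc)
  H <- ppi_branch_embedding(model, data)

  perm <- sample(length(data$ids))
  A <- as.matrix(data$network$adjacency)[perm, perm]
  netp <- gtgo:::new_ppi_network(methods::as(A, "CsparseMatrix"),
                                 data$ids[perm])
  featp <- gtgo:::new_feature_matrix(data$X[perm, ], data$ids[perm])
  annp <- gtgo:::new_annotation_matrix(data$Y[perm, ], data$ids[perm],
                                       data$terms)
  datap <- assemble_dataset(netp, featp, annp,
                            data$Hseq[perm, ])
  Hp <- ppi_branch_embedding(model, datap)
  expect_equal(unname(Hp), unname(H[perm, ]), tolerance = 1e-10)
})
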