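# The PPI branch: node embedding, softmax-free linear attention (never
# materialising the N x N attention matrix), a per-row layer-normalised MLP
# encoder, and a two-layer edge-weighted residual GCN. Each linear-algebra
# shortcut has a brute-force oracle twin used in the test suite.

#' Embed initial node features into the hidden space
#'
#' `H0 = sigma(X W0 + b0)` with `b0` broadcast across rows.
#'
#' @param X node feature matrix (N x m), dense, sparse, or a
#'   `feature_matrix`.
#' @param W0 m x d weight matrix.
#' @param b0 length-d bias.
#' @param activation `"relu"` (default) or `"identity"` (test hook).
#' @return dense N x d matrix.
#' @export
embed_nodes <- function(X, W0, b0, activation = "relu") {
  if (is(X, "feature_matrix")) X <- X$X
  if (ncol(X) != nrow(W0)) {
    stop_gtgo("feature dimension ", ncol(X), " does not match W0 rows ",
              nrow(W0))
  }
  act <- get_activation(activation)
  pre <- sweep(as_dense(X %*% W0), 2, b0, `+`)
  act(pre)
}

#' Normalize a matrix by its Frobenius norm
#'
#' @param M real matrix with positive Frobenius norm.
#' @return `M / ||M||_F`, which has unit Frobenius norm.
#' @export
frobenius_normalize <- function(M) {
  r <- sqrt(sum(M^2))
  if (!is.finite(r) || r == 0) {
    stop_gtgo("cannot Frobenius-normalize a zero (or non-finite) matrix")
  }
  M / r
}

sga_qkv <- function(H0, params) {
  list(
    Q = sweep(H0 %*% params$WQ, 2, params$bQ, `+`),
    K = sweep(H0 %*% params$WK, 2, params$bK, `+`),
    V = sweep(H0 %*% params$WV, 2, params$bV, `+`)
  )
}

#' Linear-time global attention over node embeddings
#'
#' Softmax-free attention with a residual connection:
#' `Q, K, V` are linear maps of `H0`; `Q` and `K` are Frobenius-normalized;
#' `D = diag(1_N + (1/N) Qn (Kn' 1_N))`; the output is
#' `D^{-1} (V + (1/N) Qn (Kn' V)) + H0`. The products are associated as
#' `Qn (Kn' V)` so only N x d and d x d intermediates exist — the N x N
#' attention matrix is never formed, giving O(N d^2) time and O(N d) memory.
#'
#' @param H0 dense N x d input embedding.
#' @param params list with `WQ`, `WK`, `WV` (d x d) and `bQ`, `bK`, `bV`
#'   (length d).
#' @param eps_d degeneracy floor: any `|D_ii|` below this aborts rather than
#'   silently clamping.
#' @return dense N x d matrix.
#' @export
sga_linear <- function(H0, params, eps_d = 1e-6) {
  n <- nrow(H0)
  qkv <- sga_qkv(H0, params)
  Qn <- frobenius_normalize(qkv$Q)
  Kn <- frobenius_normalize(qkv$K)
  s <- colSums(Kn)                       # Kn' 1_N, length d
  d_diag <- 1 + as.vector(Qn %*% s) / n  # diagonal of D
  if (any(abs(d_diag) < eps_d)) {
    stop_gtgo("degenerate attention normalizer: |D_ii| < ", eps_d)
  }
  C <- crossprod(Kn, qkv$V)              # Kn' V, d x d
  Z <- qkv$V + (Qn %*% C) / n
  Z / d_diag + H0
}

#' Dense reference implementation of the linear attention
#'
#' Materializes the full N x N score matrix `P = (1/N) Qn Kn'` and computes
#' `D` from its row sums; algebraically identical to [sga_linear()]. Guarded
#' to N <= 2048; exists as the independent cross-check.
#'
#' @inheritParams sga_linear
#' @return dense N x d matrix.
#' @export
sga_dense_oracle <- function(H0, params, eps_d = 1e-6) {
  n <- nrow(H0)
  if (n > 2048) stop_gtgo("dense attention oracle is guarded to N <= 2048")
  qkv <- sga_qkv(H0, params)
  Qn <- frobenius_normalize(qkv$Q)
  Kn <- frobenius_normalize(qkv$K)
  P <- (Qn %*% t(Kn)) / n                # the explicit N x N score matrix
  d_diag <- 1 + rowSums(P)
  if (any(abs(d_diag) < eps_d)) {
    stop_gtgo("degenerate attention normalizer: |D_ii| < ", eps_d)
  }
  (qkv$V + P %*% qkv$V) / d_diag + H0
}

#' Per-row layer normalization
#'
#' Each row is centred, scaled by `1/sqrt(var + eps)` (population variance),
#' then affinely transformed by the learned `scale` and `shift`. A constant
#' row maps to `shift`.
#'
#' @param M dense N x d matrix.
#' @param scale,shift length-d learned parameters.
#' @param eps variance floor (default 1e-5).
#' @return dense N x d matrix.
#' @export
layer_norm <- function(M, scale, shift, eps = 1e-5) {
  mu <- rowMeans(M)
  xc <- M - mu
  v <- rowMeans(xc^2)
  xhat <- xc / sqrt(v + eps)
  sweep(sweep(xhat, 2, scale, `*`), 2, shift, `+`)
}

#' Linear-attention transformer encoder
#'
#' `H_trans = MLP(LN(SGA(H0)))`: the attention output (which already carries
#' the `+H0` residual) is layer-normalized and passed through a two-layer
#' d -> d MLP. Setting `outer_residual = TRUE` switches to the alternative
#' reading `MLP(LN(SGA(H0) + H0))` with a second residual into the norm.
#'
#' @param H0 dense N x d input embedding.
#' @param params list with the attention parameters of [sga_linear()] plus
#'   `ln_scale`, `ln_shift` (length d), `Wm1`, `Wm2` (d x d), `bm1`, `bm2`
#'   (length d).
#' @param activation MLP nonlinearity, `"relu"` or `"identity"`.
#' @param outer_residual add `H0` again before the layer norm.
#' @param eps_d passed to [sga_linear()].
#' @return dense N x d matrix.
#' @export
transformer_encoder <- function(H0, params, activation = "relu",
                                outer_residual = FALSE, eps_d = 1e-6) {
  act <- get_activation(activation)
  S <- sga_linear(H0, params, eps_d = eps_d)
  if (outer_residual) S <- S + H0
  L <- layer_norm(S, params$ln_scale, params$ln_shift)
  M1 <- act(sweep(L %*% params$Wm1, 2, params$bm1, `+`))
  sweep(M1 %*% params$Wm2, 2, params$bm2, `+`)
}

#' Symmetric normalization of a weighted adjacency with self-loops
#'
#' `A~ = A + I`, `D~_ii = sum_j A~_ij` (weighted degree including the unit
#' self-loop), and `A^ = D~^{-1/2} A~ D~^{-1/2}`. An isolated node gets
#' `A^_ii = 1`.
#'
#' @param network a `ppi_network`, or a symmetric (sparse or dense)
#'   adjacency matrix with zero diagonal.
#' @return sparse symmetric nonnegative matrix with strictly positive
#'   diagonal.
#' @export
normalize_adjacency <- function(network) {
  A <- if (is(network, "ppi_network")) network$adjacency else network
  A <- as(A, "CsparseMatrix")
  n <- nrow(A)
  At <- A + Matrix::Diagonal(n)
  dg <- Matrix::rowSums(At)
  dhalf <- Matrix::Diagonal(n, 1 / sqrt(dg))
  dhalf %*% At %*% dhalf
}

#' One edge-weighted residual graph convolution layer
#'
#' `H + sigma(A^ H W)`: the residual is added outside the nonlinearity, so a
#' zero weight matrix leaves the embedding unchanged (under ReLU).
#'
#' @param H dense N x d embedding.
#' @param A_hat normalized adjacency from [normalize_adjacency()].
#' @param W d x d weight matrix (no bias).
#' @param activation `"relu"` or `"identity"`.
#' @return dense N x d matrix.
#' @export
gcn_layer <- function(H, A_hat, W, activation = "relu") {
  if (ncol(H) != nrow(W)) stop_gtgo("H columns must match W rows")
  if (nrow(A_hat) != nrow(H)) stop_gtgo("A_hat and H disagree on N")
  act <- get_activation(activation)
  H + act(as_dense(A_hat %*% H %*% W))
}

#' Node-perspective reference of the graph convolution layer
#'
#' Computes, for every node i, `h_i + sigma(sum_{j in N(i) + {i}} w_ij /
#' sqrt(deg(i) deg(j)) W' h_j)` with an explicit loop over neighbours,
#' weighted degrees including the unit self-loop (`w_ii = 1`). Must agree
#' with the matrix form [gcn_layer()] composed with
#' [normalize_adjacency()]; guarded to N <= 512.
#'
#' @param H dense N x d embedding.
#' @param network a `ppi_network` (raw adjacency, no self-loops).
#' @param W d x d weight matrix.
#' @param activation `"relu"` or `"identity"`.
#' @return dense N x d matrix.
#' @export
gcn_nodewise_oracle <- function(H, network, W, activation = "relu") {
  A <- as.matrix(if (is(network, "ppi_network")) network$adjacency
                 else network)
  n <- nrow(A)
  if (n > 512) stop_gtgo("nodewise GCN oracle is guarded to N <= 512")
  act <- get_activation(activation)
  deg <- rowSums(A) + 1  # weighted degree including the self-loop
  out <- H
  Wt <- t(W)
  for (i in seq_len(n)) {
    nbrs <- which(A[i, ] != 0)
    acc <- numeric(ncol(H))
    for (j in c(nbrs, i)) {
      w_ij <- if (j == i) 1 else A[i, j]
      acc <- acc + (w_ij / sqrt(deg[i] * deg[j])) * as.vector(Wt %*% H[j, ])
    }
    out[i, ] <- H[i, ] + act(matrix(acc, 1))
  }
  out
}

#' Two-layer residual GCN forward pass
#'
#' Applies [gcn_layer()] successively with each matrix in `weights`
#' (two layers by default, matching the model configuration; other depths
#' are accepted and logged).
#'
#' @param H0 dense N x d input embedding.
#' @param A_hat normalized adjacency.
#' @param weights list of d x d weight matrices.
#' @param activation `"relu"` or `"identity"`.
#' @return dense N x d matrix.
#' @export
gcn_forward <- function(H0, A_hat, weights, activation = "relu") {
  if (length(weights) != 2) {
    message("GCN depth ", length(weights), " (default is 2)")
  }
  H <- H0
  for (W in weights) H <- gcn_layer(H, A_hat, W, activation)
  H
}

#' Concatenate the two PPI-branch outputs
#'
#' Column-binds the GCN block (first) and the transformer block (second)
#' into the N x 2d PPI embedding.
#'
#' @param H_gcn dense N x d GCN output.
#' @param H_trans dense N x d encoder output.
#' @return dense N x 2d matrix.
#' @export
ppi_embedding <- function(H_gcn, H_trans) {
  if (nrow(H_gcn) != nrow(H_trans)) {
    stop_gtgo("GCN and transformer outputs disagree on row count")
  }
  cbind(H_gcn, H_trans)
}
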