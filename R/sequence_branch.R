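# Sequence branch: protein language model output (consumed precomputed,
# either residue-level matrices or protein-level vectors) mapped into the
# model's hidden space by a single-layer MLP.

#' Pool residue-level embeddings into one protein vector
#'
#' Residue-level language-model output arrives as a d x n matrix (one column
#' per residue); the protein-level vector is the arithmetic mean over the
#' residue axis.
#'
#' @param residue_matrix numeric matrix, embedding dimension by residues
#'   (n >= 1).
#' @return numeric vector of length `nrow(residue_matrix)`.
#' @export
pool_residue_embeddings <- function(residue_matrix) {
  if (!is.matrix(residue_matrix) || ncol(residue_matrix) < 1) {
    stop_gtgo("residue matrix must have at least one residue column")
  }
  rowMeans(residue_matrix)
}

#' Map pooled sequence embeddings into the hidden space
#'
#' `emb = f(W h + b)` for a single protein vector `h`, applied row-wise for
#' a batch matrix (proteins in rows).
#'
#' @param h_seq numeric vector of length `k`, or an N x k matrix.
#' @param W d x k weight matrix.
#' @param b length-d bias.
#' @param activation `"relu"` or `"identity"`.
#' @return length-d vector, or an N x d matrix for batch input.
#' @export
sequence_embedding <- function(h_seq, W, b, activation = "relu") {
  act <- get_activation(activation)
  if (is.matrix(h_seq)) {
    if (ncol(h_seq) != ncol(W)) {
      stop_gtgo("embedding dimension ", ncol(h_seq),
                " does not match W columns ", ncol(W))
    }
    act(sweep(h_seq %*% t(W), 2, b, `+`))
  } else {
    if (length(h_seq) != ncol(W)) {
      stop_gtgo("embedding dimension ", length(h_seq),
                " does not match W columns ", ncol(W))
    }
    act(as.vector(W %*% h_seq) + b)
  }
}
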