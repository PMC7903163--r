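#' Khatri-Rao (columnwise Kronecker) product
#'
#' For `A` (I x R) and `B` (J x R), returns the (I*J) x R matrix whose r-th
#' column is `kronecker(A[, r], B[, r])` (index of `A` varies slowest).
#'
#' @param A,B numeric matrices with the same number of columns.
#' @return numeric matrix of dimension `(nrow(A) * nrow(B)) x ncol(A)`.
#' @keywords internal
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (r in seq_len(ncol(A))) {
    out[, r] <- as.vector(outer(B[, r], A[, r]))
  }
  out
}

#' Mode-n unfolding of a third-order array
#'
#' Mode-1 unfolding maps `X[i, j, k]` to row `i`, column `j + (k-1)*dim(X)[2]`
#' (the convention under which `unfold1(X) = S %*% t(khatri_rao(M, G))` for a
#' polyadic model with factors `S`, `G`, `M`).
#'
#' @param X three-way numeric array.
#' @keywords internal
unfold1 <- function(X) {
  d <- dim(X)
  matrix(X, d[1L], d[2L] * d[3L])
}

#' @rdname unfold1
#' @keywords internal
unfold2 <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
}

#' @rdname unfold1
#' @keywords internal
unfold3 <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
}

#' Compose a third-order tensor from polyadic factors
#'
#' Returns `sum_r S[, r] o G[, r] o M[, r]` as an Is x Ig x Im array.
#'
#' @param S,G,M factor matrices with a common number of columns.
#' @keywords internal
cpd_compose <- function(S, G, M) {
  Is <- nrow(S); Ig <- nrow(G); Im <- nrow(M)
  X1 <- S %*% t(khatri_rao(M, G))
  array(X1, c(Is, Ig, Im))
}

#' Greedy-matched factor congruence between two polyadic solutions
#'
#' For each pair of components the score is the product over modes of the
#' absolute cosine between the corresponding factor columns; components are
#' matched greedily (best pair first) and the mean matched score is returned.
#' A value of 1 means the two solutions coincide up to the intrinsic
#' scaling/permutation/sign ambiguities of the decomposition.
#'
#' @param fac1,fac2 lists of factor matrices (same lengths and dimensions).
#' @return list with `score` (mean matched congruence), `perm` (matching of
#'   `fac2` components onto `fac1` components) and `pair_scores`.
#' @export
factor_congruence <- function(fac1, fac2) {
  stopifnot(length(fac1) == length(fac2))
  R1 <- ncol(fac1[[1L]]); R2 <- ncol(fac2[[1L]])
  C <- matrix(1, R1, R2)
  for (m in seq_along(fac1)) {
    A <- fac1[[m]]; B <- fac2[[m]]
    An <- sweep(A, 2, pmax(sqrt(colSums(A^2)), .Machine$double.eps), "/")
    Bn <- sweep(B, 2, pmax(sqrt(colSums(B^2)), .Machine$double.eps), "/")
    C <- C * abs(crossprod(An, Bn))
  }
  nmatch <- min(R1, R2)
  perm <- integer(R1); perm[] <- NA_integer_
  scores <- numeric(nmatch)
  Cw <- C
  for (i in seq_len(nmatch)) {
    idx <- arrayInd(which.max(Cw), dim(Cw))
    scores[i] <- Cw[idx[1L], idx[2L]]
    perm[idx[1L]] <- idx[2L]
    Cw[idx[1L], ] <- -Inf
    Cw[, idx[2L]] <- -Inf
  }
  list(score = mean(scores), perm = perm, pair_scores = C)
}

norm2 <- function(x) sqrt(sum(x^2))

#' Column-wise z-scoring
#' @keywords internal
zscore_cols <- function(Y) {
  Y <- sweep(Y, 2, colMeans(Y), "-")
  s <- apply(Y, 2, stats::sd)
  s[s < .Machine$double.eps] <- 1
  sweep(Y, 2, s, "/")
}
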