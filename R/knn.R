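#' Gaussian interaction-profile similarity between diseases
#'
#' Computes the Gaussian Interaction Profile (GIP) kernel on disease columns
#' of the binary adjacency matrix: similarity between diseases p and q is
#' \eqn{\exp(-\gamma \|IP(d_p) - IP(d_q)\|^2)} where IP(d) is disease d's
#' binary lncRNA-association profile and the bandwidth is normalized by the
#' mean squared profile norm, \eqn{\gamma = 1 / (\frac{1}{n_d}\sum_q
#' \|IP(d_q)\|^2)}.
#'
#' @param A Binary adjacency matrix, lncRNAs x diseases (at least 2 diseases).
#' @return A list of class `gip_similarity`: `S` (symmetric n_d x n_d matrix
#'   with unit diagonal, entries in (0, 1]) and the bandwidth `gamma`.
#' @export
gip_similarity <- function(A) {
  stopifnot(is.matrix(A), ncol(A) >= 2)
  norms2 <- colSums(A^2)
  if (sum(norms2) == 0) stop_fatal("adjacency matrix is all-zero; GIP bandwidth undefined")
  gamma <- 1 / mean(norms2)
  # ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y
  G <- crossprod(A)
  d2 <- outer(norms2, norms2, "+") - 2 * G
  d2[d2 < 0] <- 0  # clip numerical noise
  S <- exp(-gamma * d2)
  dimnames(S) <- list(colnames(A), colnames(A))
  structure(list(S = S, gamma = gamma), class = "gip_similarity")
}

#' KNN prediction from similar diseases' interaction profiles
#'
#' The similarity-based comparator: for a disease, find its `n_neighbors`
#' most similar diseases under the GIP kernel (self excluded, ties broken by
#' ascending disease index) and score every lncRNA by the mean of the
#' neighbors' binary profiles — the fraction of neighbor diseases associated
#' with that lncRNA.
#'
#' @param A Binary adjacency matrix (training associations only).
#' @param S A `gip_similarity` object or a plain similarity matrix.
#' @param disease_idx Disease to predict for (1-based index).
#' @param n_neighbors Number of neighbors (default 40; must be < n_d).
#' @param weighted If `TRUE`, use a similarity-weighted mean instead of the
#'   unweighted average profile.
#' @return Numeric vector of scores in [0, 1], one per lncRNA.
#' @export
knn_predict <- function(A, S, disease_idx, n_neighbors = 40, weighted = FALSE) {
  if (inherits(S, "gip_similarity")) S <- S$S
  n_d <- ncol(A)
  stopifnot(nrow(S) == n_d, ncol(S) == n_d)
  if (n_neighbors >= n_d) {
    stop_fatal("n_neighbors (%d) must be smaller than the number of diseases (%d)",
               n_neighbors, n_d)
  }
  sims <- S[disease_idx, ]
  others <- setdiff(seq_len(n_d), disease_idx)
  # order(): decreasing similarity, ascending index on ties
  nb <- others[order(-sims[others], others)][seq_len(n_neighbors)]
  if (weighted) {
    w <- sims[nb]
    drop(A[, nb, drop = FALSE] %*% (w / sum(w)))
  } else {
    rowMeans(A[, nb, drop = FALSE])
  }
}
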