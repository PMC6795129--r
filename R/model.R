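#' Model and training configuration
#'
#' Collects every tunable of the NNMF/NNLDA scorers with the reference
#' defaults: 32-dimensional latent factors, a three-layer deep part of widths
#' 32, 16 and 8, L2 rate 0.01 on latent factors and all fully-connected
#' weights, Adam with learning rate 0.01, 100 epochs, batch size 1024, and
#' four sampled negatives per training positive.
#'
#' @param latent_dim Latent factor dimension k (default 32).
#' @param layer_sizes Widths of the deep part's ReLU layers (default
#'   `c(32, 16, 8)`); used by NNLDA only.
#' @param l2_rate L2 regularization rate (default 0.01), applied to the
#'   embedding rows referenced by each batch and to all fully-connected
#'   weight matrices (biases are not regularized).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param epochs Training epochs (default 100; no early stopping).
#' @param batch_size Mini-batch size (default 1024; the last batch of an epoch
#'   may be smaller).
#' @param neg_ratio Training negatives sampled per positive (default 4).
#' @param seed Integer seed controlling initialization, negative sampling and
#'   batch shuffling.
#' @param shared_embeddings If `TRUE` (default) the NNLDA matrix-factorization
#'   part and deep part read the same embedding tables (one lookup per
#'   entity); `FALSE` gives the deep part its own tables.
#' @param l2_all_rows If `TRUE`, the L2 penalty covers every embedding row at
#'   every step instead of only the rows in the current batch.
#' @param resample_per_epoch If `TRUE`, training negatives are redrawn each
#'   epoch; default `FALSE` draws them once per fit.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment constants (conventional
#'   defaults 0.9, 0.999, 1e-8).
#' @return A list of class `nnlda_config`.
#' @export
nnlda_config <- function(latent_dim = 32, layer_sizes = c(32, 16, 8),
                         l2_rate = 0.01, learning_rate = 0.01, epochs = 100,
                         batch_size = 1024, neg_ratio = 4, seed = 1,
                         shared_embeddings = TRUE, l2_all_rows = FALSE,
                         resample_per_epoch = FALSE,
                         adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(is_count(latent_dim), length(layer_sizes) >= 1,
            all(layer_sizes == floor(layer_sizes)), all(layer_sizes > 0),
            l2_rate >= 0, learning_rate > 0, is_count(epochs, min = 0),
            is_count(batch_size), is_count(neg_ratio, min = 0),
            is_count(seed, min = 0))
  structure(
    list(latent_dim = as.integer(latent_dim),
         layer_sizes = as.integer(layer_sizes),
         l2_rate = l2_rate, learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         neg_ratio = as.integer(neg_ratio), seed = as.integer(seed),
         shared_embeddings = isTRUE(shared_embeddings),
         l2_all_rows = isTRUE(l2_all_rows),
         resample_per_epoch = isTRUE(resample_per_epoch),
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2, adam_eps = adam_eps),
    class = "nnlda_config"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Dot-product association score
#'
#' The classical matrix-factorization scorer: the predicted affinity of an
#' lncRNA and a disease is the dot product of their latent factors.
#'
#' @param L_i,D_j Latent factor vectors of equal length k.
#' @return The scalar dot product.
#' @export
mf_score <- function(L_i, D_j) {
  if (length(L_i) != length(D_j)) {
    stop_fatal("latent factor length mismatch: %d vs %d", length(L_i), length(D_j))
  }
  sum(L_i * D_j)
}

#' Squared-error matrix factorization loss
#'
#' The Frobenius reconstruction loss of classical matrix factorization,
#' \eqn{\|A - L D^\top\|_F^2}. Kept as a reference quantity: the neural models
#' train on cross-entropy over sampled pairs instead, precisely because this
#' global loss requires touching every (lncRNA, disease) cell.
#'
#' @param A Binary adjacency matrix (n_l x n_d).
#' @param L lncRNA embedding matrix (n_l x k).
#' @param D Disease embedding matrix (n_d x k).
#' @return The scalar loss.
#' @export
mf_square_loss <- function(A, L, D) {
  stopifnot(nrow(A) == nrow(L), ncol(A) == nrow(D), ncol(L) == ncol(D))
  sum((A - L %*% t(D))^2)
}

# Initialize model parameters. Embeddings and dense weights are drawn from
# N(0, 0.01^2); biases start at zero. Shape consistency of the deep chain is
# enforced here, so a malformed configuration fails at construction rather
# than at forward time. Parameters live in a flat named list `theta` (L, D,
# optionally L_deep/D_deep, W1/b1, ..., out_w, out_b) so that optimizer state
# and gradients can mirror its structure.
init_params <- function(n_l, n_d, config, model_kind = c("nnlda", "nnmf"),
                        init_sd = 0.01) {
  model_kind <- match.arg(model_kind)
  k <- config$latent_dim
  theta <- list(
    L = matrix(stats::rnorm(n_l * k, 0, init_sd), n_l, k),
    D = matrix(stats::rnorm(n_d * k, 0, init_sd), n_d, k)
  )
  layer_sizes <- integer(0)
  if (model_kind == "nnlda") {
    layer_sizes <- config$layer_sizes
    if (!config$shared_embeddings) {
      theta$L_deep <- matrix(stats::rnorm(n_l * k, 0, init_sd), n_l, k)
      theta$D_deep <- matrix(stats::rnorm(n_d * k, 0, init_sd), n_d, k)
    }
    # Dense layers use Glorot-uniform initialization (the framework default
    # for fully-connected layers); tiny dense inits leave the fused model's
    # output layer unable to pick up the MF features within the training
    # budget.
    glorot <- function(n_out, n_in) {
      lim <- sqrt(6 / (n_in + n_out))
      matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
    }
    in_dim <- 2L * k
    for (l in seq_along(layer_sizes)) {
      out_dim <- layer_sizes[l]
      theta[[paste0("W", l)]] <- glorot(out_dim, in_dim)
      theta[[paste0("b", l)]] <- numeric(out_dim)
      in_dim <- out_dim
    }
    theta$out_w <- drop(glorot(1L, k + in_dim))
    theta$out_b <- 0
  }
  params <- structure(
    list(model_kind = model_kind, k = k, layer_sizes = layer_sizes,
         shared_embeddings = config$shared_embeddings, n_l = n_l, n_d = n_d,
         theta = theta),
    class = "nnlda_params"
  )
  validate_params(params)
  params
}

validate_params <- function(params) {
  th <- params$theta
  k <- params$k
  stopifnot(ncol(th$L) == k, ncol(th$D) == k)
  if (params$model_kind == "nnlda") {
    in_dim <- 2L * k
    for (l in seq_along(params$layer_sizes)) {
      W <- th[[paste0("W", l)]]
      if (is.null(W) || ncol(W) != in_dim || nrow(W) != params$layer_sizes[l]) {
        stop_fatal("deep layer %d has shape %sx%s; expected %dx%d", l,
                   nrow(W) %||% NA, ncol(W) %||% NA, params$layer_sizes[l], in_dim)
      }
      if (length(th[[paste0("b", l)]]) != params$layer_sizes[l]) {
        stop_fatal("deep layer %d bias length mismatch", l)
      }
      in_dim <- params$layer_sizes[l]
    }
    if (length(th$out_w) != k + in_dim) {
      stop_fatal("output layer expects a %d-vector (k + last layer width), got %d",
                 k + in_dim, length(th$out_w))
    }
  }
  if (!all(vapply(th, function(x) all(is.finite(x)), logical(1)))) {
    stop_fatal("non-finite model parameters")
  }
  invisible(params)
}

check_pairs <- function(params, pairs) {
  pairs <- rbind(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2) stop_fatal("pairs must have two columns (lncrna, disease)")
  if (any(pairs[, 1] < 1 | pairs[, 1] > params$n_l) ||
      any(pairs[, 2] < 1 | pairs[, 2] > params$n_d)) {
    stop_fatal("pair index out of range for a %d x %d model", params$n_l, params$n_d)
  }
  pairs
}

#' NNMF forward pass
#'
#' Scores (lncRNA, disease) pairs with the neural matrix-factorization model:
#' the sigmoid of the dot product of the pair's latent factors, giving an
#' association probability in (0, 1).
#'
#' @param params An `nnlda_params` object (or a fitted [nnlda()] model) with
#'   `model_kind = "nnmf"`.
#' @param pairs Integer matrix with columns (lncrna_idx, disease_idx).
#' @return Numeric vector of probabilities.
#' @export
nnmf_forward <- function(params, pairs) {
  if (inherits(params, "nnlda")) params <- params$params
  stopifnot(params$model_kind == "nnmf")
  pairs <- check_pairs(params, pairs)
  P <- params$theta$L[pairs[, 1], , drop = FALSE]
  Q <- params$theta$D[pairs[, 2], , drop = FALSE]
  sigmoid(rowSums(P * Q))
}

# Full NNLDA forward with cached intermediates for backprop.
nnlda_forward_cache <- function(params, pairs) {
  th <- params$theta
  k <- params$k
  i <- pairs[, 1]; j <- pairs[, 2]
  P <- th$L[i, , drop = FALSE]
  Q <- th$D[j, , drop = FALSE]
  Pd <- if (params$shared_embeddings) P else th$L_deep[i, , drop = FALSE]
  Qd <- if (params$shared_embeddings) Q else th$D_deep[j, , drop = FALSE]
  n_layers <- length(params$layer_sizes)
  X <- vector("list", n_layers + 1)
  Z <- vector("list", n_layers)
  X[[1]] <- cbind(Pd, Qd)
  for (l in seq_len(n_layers)) {
    Z[[l]] <- sweep(X[[l]] %*% t(th[[paste0("W", l)]]), 2, th[[paste0("b", l)]], "+")
    X[[l + 1]] <- pmax(Z[[l]], 0)
  }
  mf <- P * Q
  concat <- cbind(mf, X[[n_layers + 1]])
  logits <- drop(concat %*% th$out_w) + th$out_b
  list(P = P, Q = Q, Pd = Pd, Qd = Qd, X = X, Z = Z, concat = concat,
       logits = logits, prob = sigmoid(logits))
}

#' NNLDA forward pass
#'
#' Scores pairs with the fused model. The matrix-factorization part is the
#' element-wise product of the pair's latent factors (a k-vector, not its
#' sum); the deep part passes the concatenated latent factors through the
#' configured stack of ReLU fully-connected layers. Both results are
#' concatenated and fed to a final one-unit layer with sigmoid activation.
#'
#' @inheritParams nnmf_forward
#' @return Numeric vector of association probabilities in (0, 1).
#' @export
nnlda_forward <- function(params, pairs) {
  if (inherits(params, "nnlda")) params <- params$params
  stopifnot(params$model_kind == "nnlda")
  pairs <- check_pairs(params, pairs)
  nnlda_forward_cache(params, pairs)$prob
}

model_forward <- function(params, pairs) {
  if (params$model_kind == "nnmf") nnmf_forward(params, pairs)
  else nnlda_forward(params, pairs)
}

# L2 penalty. The embedding term lives INSIDE the per-example mean: each
# example contributes l2_rate * (||L_i||^2 + ||D_j||^2) and the batch is
# averaged, so a row's regularization pressure is proportional to how often
# the data touches it — the standard embedding regularization of
# implicit-feedback factorization models. (A flat penalty on whole tables
# would out-pull the sparse data gradient at any realistic batch size and
# collapse the embeddings.) Dense weight matrices, which every example
# touches, carry the full l2_rate * sum(W^2); biases are not regularized.
l2_penalty <- function(params, l2_rate, lncrna_rows = NULL, disease_rows = NULL,
                       all_rows = FALSE) {
  if (l2_rate == 0) return(0)
  th <- params$theta
  emb <- 0
  if (all_rows) {
    emb <- sum(th$L^2) + sum(th$D^2)
    if (!is.null(th$L_deep)) emb <- emb + sum(th$L_deep^2) + sum(th$D_deep^2)
  } else if (!is.null(lncrna_rows)) {
    B <- length(lncrna_rows)
    emb <- (sum(th$L[lncrna_rows, , drop = FALSE]^2) +
              sum(th$D[disease_rows, , drop = FALSE]^2)) / B
    if (!is.null(th$L_deep)) {
      emb <- emb + (sum(th$L_deep[lncrna_rows, , drop = FALSE]^2) +
                      sum(th$D_deep[disease_rows, , drop = FALSE]^2)) / B
    }
  }
  dense <- 0
  for (l in seq_along(params$layer_sizes)) {
    dense <- dense + sum(th[[paste0("W", l)]]^2)
  }
  if (!is.null(th$out_w)) dense <- dense + sum(th$out_w^2)
  l2_rate * (emb + dense)
}

#' Binary cross-entropy loss with L2 regularization
#'
#' Mean binary cross-entropy over a batch,
#' \eqn{-\frac{1}{B}\sum_i [y_i \ln p_i + (1-y_i)\ln(1-p_i)]}, plus an L2
#' penalty: each example adds `l2_rate` times the squared norms of the
#' embedding rows it references (so the embedding term sits inside the batch
#' mean), and all fully-connected weight matrices add `l2_rate` times their
#' summed squares once per batch. When `logits` is supplied
#' the cross-entropy is computed in the numerically stable logit form
#' \eqn{\max(z,0) - zy + \ln(1+e^{-|z|})}, which stays finite for arbitrarily
#' extreme scores.
#'
#' @param prob Predicted probabilities in (0, 1); ignored if `logits` given.
#' @param labels 0/1 vector of the same length.
#' @param params Optional `nnlda_params` for the L2 term.
#' @param l2_rate L2 rate (default 0: pure cross-entropy).
#' @param lncrna_rows,disease_rows Embedding rows referenced by the batch.
#' @param logits Optional raw scores; preferred for numerical stability.
#' @return Scalar loss (finite whenever labels and inputs are finite).
#' @export
bce_l2_loss <- function(prob, labels, params = NULL, l2_rate = 0,
                        lncrna_rows = NULL, disease_rows = NULL, logits = NULL) {
  if (!is.null(logits)) {
    stopifnot(length(logits) == length(labels))
    bce <- mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
  } else {
    stopifnot(length(prob) == length(labels))
    p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
    bce <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  }
  pen <- if (is.null(params) || l2_rate == 0) 0 else {
    l2_penalty(params, l2_rate, lncrna_rows, disease_rows)
  }
  bce + pen
}
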