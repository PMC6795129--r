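# Training: mini-batch Adam on the cross-entropy + L2 objective.
# Gradients are derived analytically and verified against central finite
# differences in the test suite.

# Scatter per-example embedding gradients (B x k) into a full table gradient.
scatter_rows <- function(d, idx, n) {
  g <- matrix(0, n, ncol(d))
  agg <- rowsum(d, idx)
  g[as.integer(rownames(agg)), ] <- agg
  g
}

# Per-example embedding L2 gradient (2*l2/B per occurrence), or classic
# whole-table weight decay when all_rows is set.
add_l2_rows <- function(g, M, rows, l2_rate, all_rows) {
  if (l2_rate == 0) return(g)
  if (all_rows) return(g + 2 * l2_rate * M)
  B <- length(rows)
  agg <- rowsum((2 * l2_rate / B) * M[rows, , drop = FALSE], rows)
  u <- as.integer(rownames(agg))
  g[u, ] <- g[u, , drop = FALSE] + agg
  g
}

# Loss and analytic gradients for one mini-batch. Returns list(loss, grads)
# where grads mirrors params$theta (names and shapes).
grad_batch <- function(params, i, j, y, l2_rate = 0, l2_all_rows = FALSE) {
  th <- params$theta
  B <- length(y)
  k <- params$k
  if (params$model_kind == "nnmf") {
    P <- th$L[i, , drop = FALSE]
    Q <- th$D[j, , drop = FALSE]
    z <- rowSums(P * Q)
    loss <- bce_l2_loss(labels = y, logits = z) +
      l2_penalty(params, l2_rate, i, j, all_rows = l2_all_rows)
    dz <- (sigmoid(z) - y) / B
    gL <- add_l2_rows(scatter_rows(dz * Q, i, params$n_l), th$L, i, l2_rate, l2_all_rows)
    gD <- add_l2_rows(scatter_rows(dz * P, j, params$n_d), th$D, j, l2_rate, l2_all_rows)
    return(list(loss = loss, grads = list(L = gL, D = gD)))
  }
  cache <- nnlda_forward_cache(params, cbind(i, j))
  loss <- bce_l2_loss(labels = y, logits = cache$logits) +
    l2_penalty(params, l2_rate, i, j, all_rows = l2_all_rows)
  dz <- (cache$prob - y) / B
  grads <- list()
  grads$out_w <- drop(crossprod(cache$concat, dz)) + 2 * l2_rate * th$out_w
  grads$out_b <- sum(dz)
  dcat <- outer(dz, th$out_w)
  dmf <- dcat[, seq_len(k), drop = FALSE]
  dX <- dcat[, -seq_len(k), drop = FALSE]
  dP <- dmf * cache$Q
  dQ <- dmf * cache$P
  for (l in rev(seq_along(params$layer_sizes))) {
    dZ <- dX * (cache$Z[[l]] > 0)
    grads[[paste0("W", l)]] <- crossprod(dZ, cache$X[[l]]) +
      2 * l2_rate * th[[paste0("W", l)]]
    grads[[paste0("b", l)]] <- colSums(dZ)
    dX <- dZ %*% th[[paste0("W", l)]]
  }
  dPd <- dX[, seq_len(k), drop = FALSE]
  dQd <- dX[, k + seq_len(k), drop = FALSE]
  if (params$shared_embeddings) {
    grads$L <- add_l2_rows(scatter_rows(dP + dPd, i, params$n_l), th$L, i,
                           l2_rate, l2_all_rows)
    grads$D <- add_l2_rows(scatter_rows(dQ + dQd, j, params$n_d), th$D, j,
                           l2_rate, l2_all_rows)
  } else {
    grads$L <- add_l2_rows(scatter_rows(dP, i, params$n_l), th$L, i, l2_rate, l2_all_rows)
    grads$D <- add_l2_rows(scatter_rows(dQ, j, params$n_d), th$D, j, l2_rate, l2_all_rows)
    grads$L_deep <- add_l2_rows(scatter_rows(dPd, i, params$n_l), th$L_deep, i,
                                l2_rate, l2_all_rows)
    grads$D_deep <- add_l2_rows(scatter_rows(dQd, j, params$n_d), th$D_deep, j,
                                l2_rate, l2_all_rows)
  }
  list(loss = loss, grads = grads)
}

train_model <- function(train_positives, n_l, n_d, config, model_kind) {
  params <- with_seed(derive_seed(config$seed, 11),
                      init_params(n_l, n_d, config, model_kind))
  examples <- sample_train_negatives(train_positives, n_l, config$neg_ratio,
                                     derive_seed(config$seed, 12))
  n_ex <- nrow(examples)
  # Full-pass training cross-entropy at a parameter state, evaluated
  # identically at initialization and after the last update. This is the
  # loss function proper; the L2 penalty is a regularizer whose value GROWS
  # as embeddings are learned, so it is reported within the per-epoch
  # objective trajectory but excluded from the before/after comparison.
  full_loss <- function() {
    pr <- model_forward(params, cbind(examples$lncrna, examples$disease))
    bce_l2_loss(pr, examples$label)
  }
  initial_loss <- full_loss()
  # Adam state mirrors theta
  m <- lapply(params$theta, function(x) x * 0)
  v <- m
  t_step <- 0
  b1 <- config$adam_beta1; b2 <- config$adam_beta2; eps <- config$adam_eps
  lr <- config$learning_rate
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    if (config$resample_per_epoch && epoch > 1) {
      examples <- sample_train_negatives(train_positives, n_l, config$neg_ratio,
                                         derive_seed(config$seed, 12, epoch))
    }
    ord <- with_seed(derive_seed(config$seed, 13, epoch), sample.int(n_ex))
    loss_sum <- 0
    starts <- seq(1, n_ex, by = config$batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, n_ex)]
      g <- grad_batch(params, examples$lncrna[idx], examples$disease[idx],
                      examples$label[idx], config$l2_rate, config$l2_all_rows)
      if (!is.finite(g$loss)) {
        stop_fatal("non-finite loss at epoch %d, batch %d", epoch, bi)
      }
      t_step <- t_step + 1
      for (nm in names(g$grads)) {
        gr <- g$grads[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr * gr
        mhat <- m[[nm]] / (1 - b1^t_step)
        vhat <- v[[nm]] / (1 - b2^t_step)
        params$theta[[nm]] <- params$theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      loss_sum <- loss_sum + g$loss * length(idx)
    }
    losses[epoch] <- loss_sum / n_ex
  }
  list(params = params, loss = losses, initial_loss = initial_loss,
       final_loss = full_loss(), n_examples = n_ex)
}

#' Fit a neural lncRNA-disease association model
#'
#' Trains either the fused NNLDA model (element-wise-product matrix
#' factorization part concatenated with a ReLU multilayer part, joint
#' training) or the plain neural matrix factorization model NNMF (sigmoid of
#' the embedding dot product) on the known associations of a dataset.
#' Training minimizes mean binary cross-entropy plus L2 regularization by
#' mini-batch Adam, with `neg_ratio` sampled negatives per known association.
#' The fit is deterministic given `config$seed`.
#'
#' @param dataset An `association_dataset` from [build_dataset()] or
#'   [simulate_associations()].
#' @param model `"nnlda"` (default) or `"nnmf"`.
#' @param config An [nnlda_config()]; its defaults are the reference
#'   hyperparameters.
#' @param train_positives Optional integer pair matrix to train on instead of
#'   the dataset's full positive set (used by cross-validation to hold folds
#'   out). Every entity keeps its embedding row even if it has no training
#'   positive.
#' @return An object of class `nnlda`: the fitted parameters (`params`), the
#'   per-epoch mean of the optimized objective (`loss`), the full-pass
#'   training cross-entropy at initialization and at the final parameters
#'   (`initial_loss`, `final_loss`), the configuration, model kind, entity
#'   name tables, and the call. Use [predict.nnlda()] to score pairs or rank
#'   lncRNAs for a disease.
#' @examples
#' sim <- simulate_associations(synthetic_spec(n_l = 60, n_d = 12,
#'   density_target = 0.05, seed = 7))
#' fit <- nnlda(sim$dataset, "nnmf", nnlda_config(latent_dim = 8, epochs = 5))
#' fit
#' head(predict(fit, disease = sim$dataset$disease[1], top = 3))
#' @export
nnlda <- function(dataset, model = c("nnlda", "nnmf"), config = nnlda_config(),
                  train_positives = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "association_dataset"),
            inherits(config, "nnlda_config"))
  if (is.null(train_positives)) train_positives <- dataset$positives
  fit <- train_model(train_positives, dataset$n_l, dataset$n_d, config, model)
  structure(
    list(call = match.call(), model = model, config = config,
         params = fit$params, loss = fit$loss, initial_loss = fit$initial_loss,
         final_loss = fit$final_loss, n_examples = fit$n_examples,
         lncrna = dataset$lncrna, disease = dataset$disease),
    class = "nnlda"
  )
}

#' @export
print.nnlda <- function(x, ...) {
  cat(sprintf("%s model: %d lncRNAs x %d diseases, k = %d",
              toupper(x$model), x$params$n_l, x$params$n_d, x$params$k))
  if (x$model == "nnlda") {
    cat(sprintf(", deep layers [%s]", paste(x$params$layer_sizes, collapse = ", ")))
  }
  cat("\n")
  if (length(x$loss)) {
    cat(sprintf("Trained %d epochs on %d examples; cross-entropy %.4f -> %.4f\n",
                length(x$loss), x$n_examples, x$initial_loss, x$final_loss))
  } else {
    cat("Untrained (0 epochs): parameters at initialization\n")
  }
  invisible(x)
}

#' @export
summary.nnlda <- function(object, ...) {
  s <- list(model = object$model, config = object$config,
            n_l = object$params$n_l, n_d = object$params$n_d,
            loss = object$loss, initial_loss = object$initial_loss,
            n_examples = object$n_examples)
  class(s) <- "summary.nnlda"
  s
}

#' @export
print.summary.nnlda <- function(x, ...) {
  cat(sprintf("%s fit on %d lncRNAs x %d diseases (%d training examples)\n",
              toupper(x$model), x$n_l, x$n_d, x$n_examples))
  cat(sprintf("k = %d, lr = %g, l2 = %g, batch = %d, neg_ratio = %d, seed = %d\n",
              x$config$latent_dim, x$config$learning_rate, x$config$l2_rate,
              x$config$batch_size, x$config$neg_ratio, x$config$seed))
  if (length(x$loss)) {
    q <- stats::quantile(x$loss, c(0, .5, 1))
    cat(sprintf("Objective per epoch: first %.4f, median %.4f, last %.4f\n",
                x$loss[1], q[2], x$loss[length(x$loss)]))
    cat(sprintf("Training cross-entropy: %.4f at init, %.4f final\n",
                x$initial_loss, x$final_loss))
  }
  invisible(x)
}

#' Extract embedding tables
#'
#' @param object A fitted `nnlda` model.
#' @param ... Unused.
#' @return List with matrices `L` (lncRNA embeddings) and `D` (disease
#'   embeddings), rows named by entity.
#' @export
coef.nnlda <- function(object, ...) {
  L <- object$params$theta$L
  D <- object$params$theta$D
  rownames(L) <- object$lncrna
  rownames(D) <- object$disease
  list(L = L, D = D)
}

#' Plot the training loss trajectory
#'
#' @param x A fitted `nnlda` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nnlda <- function(x, ...) {
  if (!length(x$loss)) stop_fatal("no loss trajectory: model trained 0 epochs")
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "mean training loss",
                 main = toupper(x$model), ...)
  invisible(x)
}

resolve_entity <- function(x, names_vec, what) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
  } else {
    idx <- match(x, names_vec)
  }
  if (any(is.na(idx)) || any(idx < 1) || any(idx > length(names_vec))) {
    stop_fatal("unknown %s: %s", what,
               paste(utils::head(x[is.na(idx) | idx < 1 | idx > length(names_vec)], 3),
                     collapse = ", "))
  }
  idx
}

#' Predict association probabilities
#'
#' Two modes: score explicit (lncRNA, disease) pairs given in `newdata`, or
#' rank every lncRNA (or the top `top`) for one `disease`.
#'
#' @param object A fitted `nnlda` model.
#' @param newdata Data frame with columns `lncrna` and `disease` (names or
#'   1-based indices).
#' @param disease A single disease (name or index) to rank lncRNAs for.
#' @param top Keep only the `top` highest-scoring lncRNAs (default all).
#' @param ... Unused.
#' @return For `newdata`: a numeric vector of probabilities. For `disease`: a
#'   data frame `disease, lncrna, score, rank` in descending score order.
#' @export
predict.nnlda <- function(object, newdata = NULL, disease = NULL, top = NULL, ...) {
  if (is.null(newdata) == is.null(disease)) {
    stop_fatal("supply exactly one of `newdata` or `disease`")
  }
  if (!is.null(newdata)) {
    i <- resolve_entity(newdata$lncrna, object$lncrna, "lncRNA")
    j <- resolve_entity(newdata$disease, object$disease, "disease")
    return(model_forward(object$params, cbind(i, j)))
  }
  j <- resolve_entity(disease, object$disease, "disease")
  stopifnot(length(j) == 1)
  i <- seq_along(object$lncrna)
  p <- model_forward(object$params, cbind(i, j))
  ord <- order(-p, i)
  out <- data.frame(disease = object$disease[j],
                    lncrna = object$lncrna[i[ord]],
                    score = p[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
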