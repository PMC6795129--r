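# Fixtures and independent brute-force oracles. The oracles deliberately use
# scalar loops and naive formulas, sharing no code path with the package
# internals they check.

# random unique index pairs, always covering every index on both sides
random_positives <- function(n_l, n_d, m, seed) {
  set.seed(seed)
  stopifnot(m >= max(n_l, n_d))
  base <- cbind(sample.int(n_l), sample(n_d, n_l, replace = TRUE))
  base[seq_len(n_d), 2] <- sample.int(n_d)
  all_pairs <- expand.grid(l = seq_len(n_l), d = seq_len(n_d))
  key <- paste(base[, 1], base[, 2])
  rest <- all_pairs[!paste(all_pairs$l, all_pairs$d) %in% key, ]
  extra <- rest[sample.int(nrow(rest), m - nrow(base)), ]
  pos <- rbind(base, as.matrix(unname(extra)))
  dimnames(pos) <- list(NULL, c("lncrna", "disease"))
  pos[!duplicated(pos), , drop = FALSE]
}

dataset_from_positives <- function(positives, n_l, n_d) {
  structure(
    list(lncrna = sprintf("L%04d", seq_len(n_l)),
         disease = sprintf("D%03d", seq_len(n_d)),
         n_l = n_l, n_d = n_d,
         positives = positives),
    class = "association_dataset"
  )
}

random_params <- function(n_l, n_d, k, layers, seed, model = "nnlda",
                          shared = TRUE, scale = 20) {
  cfg <- nnlda_config(latent_dim = k, layer_sizes = layers,
                      shared_embeddings = shared, seed = seed)
  p <- nnlda:::with_seed(seed, nnlda:::init_params(n_l, n_d, cfg, model))
  # scale up from the tiny init so forward values are non-trivial
  p$theta <- lapply(p$theta, function(x) x * scale)
  p
}

oracle_mf_score <- function(a, b) {
  s <- 0
  for (n in seq_along(a)) s <- s + a[n] * b[n]
  s
}

oracle_square_loss <- function(A, L, D) {
  s <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      ahat <- oracle_mf_score(L[i, ], D[j, ])
      s <- s + (A[i, j] - ahat)^2
    }
  }
  s
}

oracle_nnmf <- function(params, pairs) {
  th <- params$theta
  vapply(seq_len(nrow(pairs)), function(r) {
    z <- oracle_mf_score(th$L[pairs[r, 1], ], th$D[pairs[r, 2], ])
    1 / (1 + exp(-z))
  }, numeric(1))
}

# scalar-by-scalar NNLDA forward: explicit unit loops, no matrix arithmetic
oracle_nnlda <- function(params, pairs) {
  th <- params$theta
  k <- params$k
  vapply(seq_len(nrow(pairs)), function(r) {
    Li <- th$L[pairs[r, 1], ]
    Dj <- th$D[pairs[r, 2], ]
    Ld <- if (params$shared_embeddings) Li else th$L_deep[pairs[r, 1], ]
    Dd <- if (params$shared_embeddings) Dj else th$D_deep[pairs[r, 2], ]
    x <- c(Ld, Dd)
    for (l in seq_along(params$layer_sizes)) {
      W <- th[[paste0("W", l)]]
      bb <- th[[paste0("b", l)]]
      nxt <- numeric(nrow(W))
      for (u in seq_len(nrow(W))) {
        acc <- bb[u]
        for (w in seq_len(ncol(W))) acc <- acc + W[u, w] * x[w]
        nxt[u] <- max(acc, 0)
      }
      x <- nxt
    }
    feats <- c(Li * Dj, x)
    z <- th$out_b
    for (w in seq_along(feats)) z <- z + th$out_w[w] * feats[w]
    1 / (1 + exp(-z))
  }, numeric(1))
}

# term-by-term cross-entropy + L2, matching the package's per-example
# embedding penalty and per-batch dense penalty
oracle_bce_l2 <- function(prob, labels, params = NULL, l2_rate = 0,
                          lrows = NULL, drows = NULL) {
  s <- 0
  for (i in seq_along(prob)) {
    s <- s - (labels[i] * log(prob[i]) + (1 - labels[i]) * log(1 - prob[i]))
  }
  s <- s / length(prob)
  if (!is.null(params) && l2_rate > 0) {
    th <- params$theta
    emb <- 0
    for (i in seq_along(lrows)) {
      emb <- emb + sum(th$L[lrows[i], ]^2) + sum(th$D[drows[i], ]^2)
      if (!is.null(th$L_deep)) {
        emb <- emb + sum(th$L_deep[lrows[i], ]^2) + sum(th$D_deep[drows[i], ]^2)
      }
    }
    dense <- 0
    for (l in seq_along(params$layer_sizes)) dense <- dense + sum(th[[paste0("W", l)]]^2)
    if (!is.null(th$out_w)) dense <- dense + sum(th$out_w^2)
    s <- s + l2_rate * (emb / length(lrows) + dense)
  }
  s
}

oracle_gip <- function(A) {
  n_d <- ncol(A)
  gamma <- 1 / (sum(colSums(A^2)) / n_d)
  S <- matrix(0, n_d, n_d)
  for (p in seq_len(n_d)) {
    for (q in seq_len(n_d)) {
      S[p, q] <- exp(-gamma * sum((A[, p] - A[, q])^2))
    }
  }
  list(S = S, gamma = gamma)
}

oracle_knn <- function(A, S, j, n_neighbors) {
  sims <- S[j, ]
  cand <- setdiff(seq_len(ncol(A)), j)
  # selection sort with explicit tie-break on index
  nb <- integer(0)
  while (length(nb) < n_neighbors) {
    best <- cand[1]
    for (c in cand) if (sims[c] > sims[best]) best <- c
    nb <- c(nb, best)
    cand <- setdiff(cand, best)
  }
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) out[i] <- mean(A[i, nb])
  out
}

# rank by counting candidates at or above the positive's score
oracle_rank <- function(scores) {
  pos <- scores[1]
  1L + sum(scores[-1] >= pos)
}

# central finite-difference gradient of the batch loss wrt every leaf
fd_grads <- function(params, i, j, y, l2_rate, h = 1e-6) {
  loss_at <- function(p) {
    prob <- if (p$model_kind == "nnmf") nnmf_forward(p, cbind(i, j)) else nnlda_forward(p, cbind(i, j))
    bce_l2_loss(prob, y) + nnlda:::l2_penalty(p, l2_rate, i, j)
  }
  out <- list()
  for (nm in names(params$theta)) {
    g <- params$theta[[nm]] * 0
    for (e in seq_along(g)) {
      up <- params; up$theta[[nm]][e] <- up$theta[[nm]][e] + h
      dn <- params; dn$theta[[nm]][e] <- dn$theta[[nm]][e] - h
      g[e] <- (loss_at(up) - loss_at(dn)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
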