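#' Partition known associations into cross-validation folds
#'
#' Seeded uniform shuffle of the positive pairs followed by round-robin
#' assignment, so the fold test sets partition the positives with sizes
#' differing by at most one.
#'
#' @param positives Integer pair matrix of all known associations.
#' @param n_folds Number of folds (default 10).
#' @param rng_seed Integer seed.
#' @return List of `n_folds` fold splits, each a list with `fold_id`,
#'   `train_positives` and `test_positives` (pair matrices).
#' @export
make_folds <- function(positives, n_folds = 10, rng_seed) {
  stopifnot(is.matrix(positives), ncol(positives) == 2)
  if (n_folds < 2) stop_fatal("n_folds must be at least 2")
  m <- nrow(positives)
  if (m < n_folds) stop_fatal("%d positives cannot fill %d folds", m, n_folds)
  ord <- with_seed(rng_seed, sample.int(m))
  fold_of <- integer(m)
  fold_of[ord] <- rep_len(seq_len(n_folds), m)
  lapply(seq_len(n_folds), function(f) {
    list(fold_id = f,
         train_positives = positives[fold_of != f, , drop = FALSE],
         test_positives = positives[fold_of == f, , drop = FALSE])
  })
}

#' Rank a candidate set by model score
#'
#' Sorts the 1 + n_neg candidates by descending score and locates the held-out
#' positive. Ties involving the positive are resolved pessimistically: the
#' positive is placed after every negative with an equal score, so the
#' reported rank is deterministic and never flatters the model.
#'
#' @param scores Numeric vector of scores, aligned with
#'   `c(candidate_set$positive_lncrna, candidate_set$negative_lncrnas)`.
#' @param candidate_set A `candidate_set` from [sample_eval_candidates()].
#' @return A list of class `ranked_list`: the candidate set,
#'   `ordered_candidates` (lncRNA indices by descending score), and
#'   `positive_rank` (1-based).
#' @export
rank_candidates <- function(scores, candidate_set) {
  stopifnot(inherits(candidate_set, "candidate_set"))
  candidates <- c(candidate_set$positive_lncrna, candidate_set$negative_lncrnas)
  if (length(scores) != length(candidates)) {
    stop_fatal("need one score per candidate: got %d scores for %d candidates",
               length(scores), length(candidates))
  }
  if (any(!is.finite(scores))) stop_fatal("non-finite candidate score")
  is_pos <- c(1L, rep(0L, length(candidates) - 1L))
  ord <- order(-scores, is_pos, candidates)
  positive_rank <- 1L + sum(scores[-1] >= scores[1])
  structure(
    list(candidate_set = candidate_set,
         ordered_candidates = candidates[ord],
         positive_rank = positive_rank),
    class = "ranked_list"
  )
}

#' Hit Ratio at k
#'
#' HR(k) is the fraction of ranked candidate lists whose held-out positive
#' appears within the top k — the probability that a true association is
#' recovered among the first k suggestions. Under the 1-positive +
#' 99-negative protocol HR(100) is 1 by construction and a random scorer
#' gives HR(k) = k/100 in expectation.
#'
#' @param ranked_lists List of `ranked_list` objects.
#' @param cutoffs Integer cutoffs (default 1:10).
#' @return A list of class `hr_curve` with `cutoffs`, `hr` (non-decreasing,
#'   in [0, 1]) and `n_lists`.
#' @export
hit_ratio <- function(ranked_lists, cutoffs = 1:10) {
  if (length(ranked_lists) == 0) stop_fatal("no ranked lists")
  if (any(cutoffs < 1 | cutoffs > 100)) stop_fatal("cutoffs must lie in [1, 100]")
  ranks <- vapply(ranked_lists, function(r) as.numeric(r$positive_rank), numeric(1))
  hr <- vapply(cutoffs, function(k) mean(ranks <= k), numeric(1))
  structure(list(cutoffs = as.integer(cutoffs), hr = hr,
                 n_lists = length(ranks)),
            class = "hr_curve")
}

#' @export
print.hr_curve <- function(x, ...) {
  cat(sprintf("Hit Ratio over %d candidate lists:\n", x$n_lists))
  print(stats::setNames(round(x$hr, 4), paste0("HR@", x$cutoffs)))
  invisible(x)
}

# Build one fold's scorer: a function(pairs) -> scores. `method` is a model
# name or a user function(dataset, train_positives, config, seed) returning
# such a scorer.
fold_scorer <- function(method, dataset, train_positives, config, seed,
                        n_neighbors = 40) {
  if (is.function(method)) return(method(dataset, train_positives, config, seed))
  switch(method,
    nnlda = ,
    nnmf = {
      cfg <- config
      cfg$seed <- seed
      fit <- nnlda(dataset, method, cfg, train_positives = train_positives)
      function(pairs) model_forward(fit$params, pairs)
    },
    knn = {
      A <- to_matrix(dataset, train_positives)
      S <- gip_similarity(A)
      cache <- new.env(parent = emptyenv())
      function(pairs) {
        out <- numeric(nrow(pairs))
        for (j in unique(pairs[, 2])) {
          key <- as.character(j)
          if (is.null(cache[[key]])) {
            cache[[key]] <- knn_predict(A, S, j, n_neighbors = n_neighbors)
          }
          sel <- pairs[, 2] == j
          out[sel] <- cache[[key]][pairs[sel, 1]]
        }
        out
      }
    },
    random = {
      M <- with_seed(seed, matrix(stats::runif(dataset$n_l * dataset$n_d),
                                  dataset$n_l, dataset$n_d))
      function(pairs) M[pairs]
    },
    stop_fatal("unknown method '%s'", method)
  )
}

#' Cross-validated Hit-Ratio evaluation
#'
#' Runs the full evaluation protocol: the known associations are split into
#' `n_folds` folds; for each fold a scorer is fit on the training positives
#' only (model training, or the GIP similarity for KNN, never sees held-out
#' pairs); every held-out positive is ranked against 99 sampled negatives
#' screened against all known associations; and Hit Ratios are pooled over
#' every candidate list (micro-average), with per-fold curves retained.
#' Folds and candidate sets depend only on `rng_seed`, so different methods
#' evaluated with the same seed see identical splits and candidates.
#'
#' @param dataset An `association_dataset`.
#' @param method `"nnlda"`, `"nnmf"`, `"knn"`, `"random"` (a seeded uniform
#'   scorer, useful for protocol calibration), or a function
#'   `(dataset, train_positives, config, seed)` returning a scorer
#'   `function(pairs) -> scores`.
#' @param config An [nnlda_config()] (model hyperparameters).
#' @param cutoffs Hit-Ratio cutoffs (default 1:10).
#' @param rng_seed Seed governing folds, candidate sets, and per-fold model
#'   seeds. Defaults to `config$seed`.
#' @param n_folds Number of folds (default 10).
#' @param n_neg Negatives per candidate list (default 99).
#' @param n_neighbors KNN neighborhood size (default 40).
#' @return An object of class `nnlda_cv`: pooled `hr` curve, `per_fold`
#'   curves, all positive ranks, and the run's settings.
#' @export
run_cv <- function(dataset, method = "nnlda", config = nnlda_config(),
                   cutoffs = 1:10, rng_seed = config$seed, n_folds = 10,
                   n_neg = 99, n_neighbors = 40) {
  stopifnot(inherits(dataset, "association_dataset"))
  folds <- make_folds(dataset$positives, n_folds, derive_seed(rng_seed, 1))
  cand_seed <- derive_seed(rng_seed, 4)
  all_lists <- list()
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    scorer <- fold_scorer(method, dataset, folds[[f]]$train_positives, config,
                          derive_seed(rng_seed, 2, f), n_neighbors)
    test <- folds[[f]]$test_positives
    fold_lists <- vector("list", nrow(test))
    for (r in seq_len(nrow(test))) {
      cs <- sample_eval_candidates(test[r, ], dataset$positives, dataset$n_l,
                                   n_neg = n_neg, rng_seed = cand_seed)
      cand <- c(cs$positive_lncrna, cs$negative_lncrnas)
      fold_lists[[r]] <- rank_candidates(scorer(cbind(cand, cs$disease)), cs)
    }
    per_fold[[f]] <- hit_ratio(fold_lists, cutoffs)
    all_lists <- c(all_lists, fold_lists)
  }
  structure(
    list(method = if (is.function(method)) "custom" else method,
         hr = hit_ratio(all_lists, cutoffs),
         per_fold = per_fold,
         ranks = vapply(all_lists, function(r) r$positive_rank, integer(1)),
         n_folds = n_folds, cutoffs = as.integer(cutoffs),
         config = config, rng_seed = rng_seed),
    class = "nnlda_cv"
  )
}

#' @export
print.nnlda_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, method = %s (%d test lists)\n",
              x$n_folds, x$method, x$hr$n_lists))
  print(x$hr)
  invisible(x)
}

#' Hyperparameter sweeps over latent dimension or deep-layer depth
#'
#' Re-runs the full cross-validated evaluation for each setting of one
#' hyperparameter, with folds, candidate sets and seeds shared across
#' settings. The two reference sweeps are the latent dimension over
#' {8, 16, 32, 64, 128} and the deep-part depth over the four shapes (32),
#' (32, 16), (32, 16, 8) and (32, 16, 8, 4).
#'
#' @param dataset An `association_dataset`.
#' @param method `"nnlda"` or `"nnmf"` (`"nnmf"` not valid for the layer
#'   sweep, which varies the deep part).
#' @param sweep `"latent_dim"` or `"layers"`.
#' @param values Settings to sweep; defaults to the reference grids above.
#' @param config Base configuration; the swept field is overridden.
#' @param rng_seed Shared evaluation seed (default `config$seed`).
#' @param cutoffs Hit-Ratio cutoffs; HR at 10 is tabulated.
#' @param ... Passed to [run_cv()].
#' @return Data frame with columns `setting` (character) and `hr10`, one row
#'   per setting; the full `nnlda_cv` objects are attached as attribute
#'   `"runs"`.
#' @export
parameter_sweep <- function(dataset, method = "nnlda",
                            sweep = c("latent_dim", "layers"), values = NULL,
                            config = nnlda_config(), rng_seed = config$seed,
                            cutoffs = 1:10, ...) {
  sweep <- match.arg(sweep)
  if (is.null(values)) {
    values <- if (sweep == "latent_dim") list(8, 16, 32, 64, 128)
    else list(c(32), c(32, 16), c(32, 16, 8), c(32, 16, 8, 4))
  }
  if (!is.list(values)) values <- as.list(values)
  if (sweep == "layers" && method != "nnlda") {
    stop_fatal("the layer sweep varies the deep part; method must be 'nnlda'")
  }
  runs <- lapply(values, function(v) {
    cfg <- config
    if (sweep == "latent_dim") cfg$latent_dim <- as.integer(v)
    else cfg$layer_sizes <- as.integer(v)
    run_cv(dataset, method, cfg, cutoffs = cutoffs, rng_seed = rng_seed, ...)
  })
  hr10 <- vapply(runs, function(r) {
    pos <- match(10L, r$cutoffs)
    if (is.na(pos)) pos <- length(r$cutoffs)  # largest cutoff if 10 absent
    r$hr$hr[pos]
  }, numeric(1))
  out <- data.frame(
    setting = vapply(values, function(v) paste(v, collapse = "-"), character(1)),
    hr10 = hr10, stringsAsFactors = FALSE
  )
  attr(out, "runs") <- runs
  out
}
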