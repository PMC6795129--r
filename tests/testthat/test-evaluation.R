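test_that("folds partition the positives with sizes differing by at most one", {
  pos <- random_positives(40, 10, 100, seed = 51)
  folds <- make_folds(pos, 10, rng_seed = 1)
  expect_equal(sort(vapply(folds, function(f) nrow(f$test_positives), integer(1))),
               rep(10L, 10))

  pos101 <- random_positives(40, 10, 101, seed = 52)
  sizes <- vapply(make_folds(pos101, 10, rng_seed = 1),
                  function(f) nrow(f$test_positives), integer(1))
  expect_equal(sort(sizes, decreasing = TRUE), c(11L, rep(10L, 9)))

  # exhaustive partition check on 1,000 positives
  big <- random_positives(100, 20, 1000, seed = 53)
  fb <- make_folds(big, 10, rng_seed = 9)
  all_test <- do.call(rbind, lapply(fb, `[[`, "test_positives"))
  expect_setequal(paste(all_test[, 1], all_test[, 2]), paste(big[, 1], big[, 2]))
  for (f in fb) {
    expect_equal(nrow(f$train_positives) + nrow(f$test_positives), nrow(big))
    expect_length(intersect(paste(f$train_positives[, 1], f$train_positives[, 2]),
                            paste(f$test_positives[, 1], f$test_positives[, 2])), 0)
  }
  # deterministic given the seed
  expect_identical(fb, make_folds(big, 10, rng_seed = 9))
  expect_error(make_folds(pos, 1, rng_seed = 1), "at least 2")
})

test_that("rank_candidates sorts descending with the pessimistic tie rule", {
  cs <- structure(list(disease = 1L, positive_lncrna = 5L,
                       negative_lncrnas = as.integer(6:104)),
                  class = "candidate_set")
  s <- c(1, runif(99))
  rl <- rank_candidates(s, cs)
  expect_equal(rl$positive_rank, 1L)
  expect_equal(rl$ordered_candidates[1], 5L)

  # all scores tied: positive goes last
  rl_tie <- rank_candidates(rep(0.5, 100), cs)
  expect_equal(rl_tie$positive_rank, 100L)
  expect_setequal(rl_tie$ordered_candidates, c(5L, 6:104))

  # random scores agree with the counting oracle
  set.seed(55)
  for (r in 1:50) {
    s <- sample(round(runif(100), 2))  # coarse grid forces some ties
    expect_equal(rank_candidates(s, cs)$positive_rank, oracle_rank(s))
  }
  expect_error(rank_candidates(c(NA, runif(99)), cs), "non-finite")
})

test_that("hit_ratio counts top-k membership and is monotone", {
  mk <- function(rank) {
    structure(list(candidate_set = NULL, ordered_candidates = NULL,
                   positive_rank = rank), class = "ranked_list")
  }
  all_first <- hit_ratio(lapply(rep(1, 5), mk), cutoffs = c(1, 5, 10))
  expect_equal(all_first$hr, rep(1, 3))
  spread <- hit_ratio(lapply(c(1, 50, 100), mk), cutoffs = 10)
  expect_equal(spread$hr, 1 / 3)
  expect_error(hit_ratio(lapply(1:3, mk), cutoffs = 101), "\\[1, 100\\]")

  # binomial calibration: 1,000 uniform ranks
  set.seed(56)
  ranks <- sample(100, 1000, replace = TRUE)
  hr10 <- hit_ratio(lapply(ranks, mk), cutoffs = 1:10)
  expect_false(is.unsorted(hr10$hr))
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_lt(abs(hr10$hr[10] - 0.10), 3 * se)
})

small_cv_dataset <- function(seed = 61) {
  sim <- simulate_associations(synthetic_spec(n_l = 150, n_d = 12, k_true = 2,
                                              density_target = 0.12,
                                              degree_skew = 0, seed = seed))
  sim$dataset
}

test_that("run_cv with an oracle scorer attains HR(1) = 1", {
  ds <- small_cv_dataset()
  truth <- to_matrix(ds)
  oracle_method <- function(dataset, train_positives, config, seed) {
    function(pairs) truth[pairs]
  }
  cv <- run_cv(ds, oracle_method, nnlda_config(seed = 1), cutoffs = c(1, 10),
               rng_seed = 1, n_neg = 20)
  expect_equal(cv$hr$hr[1], 1)
})

test_that("run_cv with a random scorer sits at the k/100 baseline and HR(100)=1", {
  sim <- simulate_associations(synthetic_spec(n_l = 400, n_d = 15, k_true = 2,
                                              density_target = 0.08,
                                              degree_skew = 0, seed = 62))
  ds <- sim$dataset
  cv <- run_cv(ds, "random", nnlda_config(seed = 1), cutoffs = c(10, 100),
               rng_seed = 2)
  n <- cv$hr$n_lists
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(cv$hr$hr[1] - 0.10), 3 * se)
  expect_equal(cv$hr$hr[2], 1)
  expect_false(is.unsorted(cv$hr$hr))
})

test_that("run_cv is deterministic and shares folds/candidates across methods", {
  ds <- small_cv_dataset(63)
  a <- run_cv(ds, "random", nnlda_config(seed = 1), rng_seed = 7, n_neg = 20)
  b <- run_cv(ds, "random", nnlda_config(seed = 1), rng_seed = 7, n_neg = 20)
  expect_identical(a$ranks, b$ranks)
  expect_identical(a$hr, b$hr)
  # folds and candidate draws depend only on the evaluation seed
  f1 <- make_folds(ds$positives, 10, nnlda:::derive_seed(7, 1))
  f2 <- make_folds(ds$positives, 10, nnlda:::derive_seed(7, 1))
  expect_identical(f1, f2)
  cs1 <- sample_eval_candidates(ds$positives[1, ], ds$positives, ds$n_l,
                                n_neg = 20, rng_seed = nnlda:::derive_seed(7, 4))
  cs2 <- sample_eval_candidates(ds$positives[1, ], ds$positives, ds$n_l,
                                n_neg = 20, rng_seed = nnlda:::derive_seed(7, 4))
  expect_identical(cs1, cs2)
})

test_that("parameter sweeps share evaluation seeds and tabulate HR@10", {
  ds <- small_cv_dataset(64)
  cfg <- nnlda_config(latent_dim = 4, epochs = 3, batch_size = 256, seed = 5)
  # single-setting sweep equals a plain run
  one <- parameter_sweep(ds, "nnmf", "latent_dim", values = list(4),
                         config = cfg, rng_seed = 5, n_folds = 3, n_neg = 20)
  plain <- run_cv(ds, "nnmf", cfg, rng_seed = 5, n_folds = 3, n_neg = 20)
  expect_equal(one$hr10, plain$hr$hr[10])

  two <- parameter_sweep(ds, "nnlda", "layers",
                         values = list(c(8), c(8, 4)),
                         config = cfg, rng_seed = 5, n_folds = 3, n_neg = 20)
  expect_equal(nrow(two), 2)
  expect_equal(two$setting, c("8", "8-4"))
  expect_error(parameter_sweep(ds, "nnmf", "layers"), "deep part")
})
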