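#' Sample training negatives for known associations
#'
#' True non-associations are unobserved, so training negatives are presumed:
#' for every known (lncRNA, disease) training pair, `ratio` lncRNAs that are
#' not associated with that disease in the training positives are drawn
#' uniformly without replacement and labelled 0. Negatives are checked only
#' against the training positives — test-fold pairs are hidden at train time,
#' so an occasional collision with a held-out positive is accepted rather than
#' leaking fold information.
#'
#' @param train_positives Integer matrix of training pairs (columns lncrna,
#'   disease; 1-based indices).
#' @param n_l Number of lncRNAs in the universe.
#' @param ratio Negatives per positive (default 4).
#' @param rng_seed Integer seed; the full sample is a deterministic function
#'   of it.
#' @return Data frame with columns `lncrna`, `disease`, `label` (1 for every
#'   training positive, 0 for sampled negatives; `ratio` negatives per
#'   positive).
#' @export
sample_train_negatives <- function(train_positives, n_l, ratio = 4, rng_seed) {
  stopifnot(is.matrix(train_positives), ncol(train_positives) == 2,
            is_count(n_l), is_count(ratio, min = 0), is_count(rng_seed, min = 0))
  pos <- data.frame(lncrna = as.integer(train_positives[, 1]),
                    disease = as.integer(train_positives[, 2]),
                    label = 1L)
  if (ratio == 0) return(pos)
  by_disease <- split(pos$lncrna, pos$disease)
  deg <- lengths(by_disease)
  over <- deg > n_l - ratio
  if (any(over)) {
    stop_fatal("disease index %s has %d associated lncRNAs; cannot draw %d negatives from %d lncRNAs",
               names(by_disease)[over][1], deg[over][1], ratio, n_l)
  }
  neg <- with_seed(rng_seed, {
    # iterate in positive order so the draw stream is reproducible
    out <- vector("list", nrow(pos))
    for (r in seq_len(nrow(pos))) {
      d <- pos$disease[r]
      excluded <- by_disease[[as.character(d)]]
      candidates <- setdiff(seq_len(n_l), excluded)
      out[[r]] <- data.frame(
        lncrna = candidates[sample.int(length(candidates), ratio)],
        disease = d, label = 0L
      )
    }
    do.call(rbind, out)
  })
  rbind(pos, neg)
}

#' Build the 100-candidate evaluation set for one held-out positive
#'
#' Implements the 99-negative ranking protocol: for a held-out test pair, 99
#' lncRNAs with no known association to the disease are drawn uniformly
#' without replacement; the model then ranks the test lncRNA among them.
#' Negatives are screened against ALL known positives (training and test),
#' so a true association is never scored as a presumed negative.
#'
#' @param test_pair Length-2 integer vector `(lncrna_idx, disease_idx)`.
#' @param all_positives Integer pair matrix of every known association.
#' @param n_l Number of lncRNAs in the universe.
#' @param n_neg Number of negatives (default 99).
#' @param rng_seed Integer seed. The draw is deterministic in `rng_seed` and
#'   `test_pair` jointly, so the same pair gets the same candidates whichever
#'   model is being evaluated.
#' @return A list of class `candidate_set`: `disease`, `positive_lncrna`,
#'   `negative_lncrnas` (length `n_neg`, distinct, excluding the positive and
#'   every known partner of the disease).
#' @export
sample_eval_candidates <- function(test_pair, all_positives, n_l, n_neg = 99,
                                   rng_seed) {
  stopifnot(length(test_pair) == 2, is_count(n_l), is_count(n_neg),
            is_count(rng_seed, min = 0))
  i <- as.integer(test_pair[1]); j <- as.integer(test_pair[2])
  known <- all_positives[all_positives[, 2] == j, 1]
  candidates <- setdiff(seq_len(n_l), union(known, i))
  if (length(candidates) < n_neg) {
    stop_fatal("disease %d: only %d candidate negatives available, %d required",
               j, length(candidates), n_neg)
  }
  negs <- with_seed(derive_seed(rng_seed, i, j), {
    candidates[sample.int(length(candidates), n_neg)]
  })
  structure(
    list(disease = j, positive_lncrna = i, negative_lncrnas = negs),
    class = "candidate_set"
  )
}
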