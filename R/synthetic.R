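#' Specification for a synthetic association dataset
#'
#' Describes a sparse binary bipartite dataset with planted structure:
#' low-dimensional latent factors drive association scores, per-entity
#' lognormal propensities produce heavy-tailed degree distributions, and an
#' optional nonlinear component makes part of the signal invisible to a pure
#' dot-product scorer. Defaults emulate the scale regime of curated
#' lncRNA-disease data (a few-percent-dense matrix with skewed disease
#' degrees) at a desk-scale size.
#'
#' @param n_l,n_d Numbers of lncRNAs and diseases (defaults 500 and 60).
#' @param k_true Planted latent dimension (default 4).
#' @param density_target Fraction of (lncRNA, disease) cells that are
#'   associations (default 0.02).
#' @param nonlinear_weight Mixing weight in [0, 1] of the nonlinear signal
#'   component (default 0: purely bilinear).
#' @param degree_skew Standard deviation of the per-entity lognormal
#'   propensity on the log scale (default 0.5); 0 gives homogeneous degrees.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param bernoulli If `TRUE`, sample associations independently with
#'   score-dependent probabilities (approximate density) instead of
#'   thresholding scores at the exact target count.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_l = 500, n_d = 60, k_true = 4,
                           density_target = 0.02, nonlinear_weight = 0,
                           degree_skew = 0.5, seed = 1, bernoulli = FALSE) {
  stopifnot(is_count(n_l, 2), is_count(n_d, 2), is_count(k_true),
            density_target > 0, density_target < 1,
            nonlinear_weight >= 0, nonlinear_weight <= 1, degree_skew >= 0,
            is_count(seed, min = 0))
  structure(
    list(n_l = as.integer(n_l), n_d = as.integer(n_d),
         k_true = as.integer(k_true), density_target = density_target,
         nonlinear_weight = nonlinear_weight, degree_skew = degree_skew,
         seed = as.integer(seed), bernoulli = isTRUE(bernoulli)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic association dataset with planted structure
#'
#' Latent vectors \eqn{u_i, v_j} are standard normal draws of dimension
#' `k_true`, scaled by per-entity lognormal propensities (heavy-tailed
#' degrees). The planted score is a mixture of a bilinear term and a fixed
#' nonlinear interaction:
#' \deqn{s_{ij} = (1-w)\,\tilde{b}_{ij} + w\,\tilde{g}_{ij},}
#' where \eqn{b_{ij} = u_i \cdot v_j}, and the nonlinear component is the
#' Euclidean norm of the element-wise maximum of the unscaled latent draws,
#' \eqn{g_{ij} = \|\max(z_i, z_j)\|_2}, double-centered to strip row and
#' column main effects; both components are z-scored over all cells before
#' mixing so `nonlinear_weight` is comparable across scales.
#' With `w = 0` the optimal scorer is a rank-`k_true` factorization; with
#' `w = 1` the signal carries no bilinear structure at the planted dimension.
#' Associations are the top `round(density_target * n_l * n_d)` cells of s
#' (deterministic thresholding pins the density exactly); entities left with
#' no association are dropped, with a message, so every indexed entity
#' appears in at least one positive pair.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `dataset` (an `association_dataset`), `truth` (the planted
#'   score matrix over the retained entities, for oracle checks), and `spec`.
#' @export
simulate_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    k <- spec$k_true
    a <- if (spec$degree_skew > 0) stats::rlnorm(spec$n_l, 0, spec$degree_skew) else rep(1, spec$n_l)
    b <- if (spec$degree_skew > 0) stats::rlnorm(spec$n_d, 0, spec$degree_skew) else rep(1, spec$n_d)
    Z_l <- matrix(stats::rnorm(spec$n_l * k), spec$n_l, k)
    Z_d <- matrix(stats::rnorm(spec$n_d * k), spec$n_d, k)
    U <- a * Z_l
    V <- b * Z_d
    bilinear <- U %*% t(V)
    s <- if (spec$nonlinear_weight > 0) {
      # Nonlinear component: g_ij = || pmax(z_i, z_j) ||_2, the norm of the
      # element-wise maximum of the UNSCALED latent vectors — an interaction
      # a dot-product model of dimension k cannot represent. It is computed
      # on the unscaled vectors and double-centered (row/column main effects
      # removed) so that it is a pure interaction: propensity scale or norm
      # main effects would be partly visible to a bilinear scorer and would
      # concentrate degrees onto a handful of entities.
      g <- matrix(0, spec$n_l, spec$n_d)
      for (j in seq_len(spec$n_d)) {
        Zj <- matrix(Z_d[j, ], spec$n_l, k, byrow = TRUE)
        g[, j] <- sqrt(rowSums(pmax(Z_l, Zj)^2))
      }
      g <- g - outer(rowMeans(g), colMeans(g), "+") + mean(g)
      zs <- function(M) (M - mean(M)) / stats::sd(M)
      (1 - spec$nonlinear_weight) * zs(bilinear) + spec$nonlinear_weight * zs(g)
    } else {
      bilinear
    }
    m <- round(spec$density_target * spec$n_l * spec$n_d)
    if (m < 1) stop_fatal("density_target %.4g yields zero associations on %dx%d; increase it",
                          spec$density_target, spec$n_l, spec$n_d)
    A <- matrix(0, spec$n_l, spec$n_d)
    if (spec$bernoulli) {
      tau <- 0.3 * stats::sd(s)
      q <- stats::quantile(s, 1 - spec$density_target)
      A[] <- as.numeric(stats::runif(length(s)) < stats::plogis((s - q) / tau))
    } else {
      A[order(s, decreasing = TRUE)[seq_len(m)]] <- 1
    }
    keep_l <- rowSums(A) > 0
    keep_d <- colSums(A) > 0
    if (!all(keep_l) || !all(keep_d)) {
      msg("dropping ", sum(!keep_l), " lncRNA(s) and ", sum(!keep_d),
          " disease(s) with no sampled association")
    }
    A <- A[keep_l, keep_d, drop = FALSE]
    if (nrow(A) < 2 || ncol(A) < 2) {
      stop_fatal("density_target %.4g leaves fewer than 2 connected entities per side; increase it",
                 spec$density_target)
    }
    lnc_names <- sprintf("L%05d", seq_len(spec$n_l))[keep_l]
    dis_names <- sprintf("D%04d", seq_len(spec$n_d))[keep_d]
    pos <- which(A == 1, arr.ind = TRUE)
    dataset <- structure(
      list(lncrna = lnc_names, disease = dis_names,
           n_l = nrow(A), n_d = ncol(A),
           positives = cbind(lncrna = as.integer(pos[, 1]),
                             disease = as.integer(pos[, 2]))),
      class = "association_dataset"
    )
    truth <- s[keep_l, keep_d, drop = FALSE]
    dimnames(truth) <- list(lnc_names, dis_names)
    list(dataset = dataset, truth = truth, spec = spec)
  })
}
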