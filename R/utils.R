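# Internal helpers: scoped RNG, seed derivation, logging.

# Evaluate `expr` under set.seed(seed) and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and integer tags, kept inside the
# 32-bit signed range R's set.seed() accepts. Uses a small multiplicative
# hash; collisions are harmless (streams only need to be decoupled, not
# cryptographic).
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    h <- (h * 69069 + as.double(t) + 1) %% 2147483647
  }
  as.integer(h)
}

msg <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fatal <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x) && x >= min
}
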