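# Internal helpers shared across modules.

# Population (MLE, divisor n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded internals never perturb user-level
#' reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic integer stream mixer: folds a master seed and any number of
# integer coordinates into one seed in [1, 2^31 - 2]. Multiplier kept small
# enough that every product stays below 2^53, so the arithmetic is exact in
# doubles. Used to derive independent per-pixel substreams so imputation
# results do not depend on pixel traversal order.
substream_seed <- function(master, ...) {
  ks <- c(master, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + (k %% 2147483563) + 1) %% 2147483563
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, before_pct, after_pct, level = "INFO") {
  message(sprintf("[%s] stage=%s missing_before=%.2f%% missing_after=%.2f%%",
                  level, stage, before_pct, after_pct))
}
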