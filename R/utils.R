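# internal helpers shared across modules

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive reproducible per-stage RNG seeds from one root seed
#'
#' All randomness in a run flows from a single root seed; each named stage
#' gets its own substream seed so stages stay reproducible independently of
#' how many random draws earlier stages consumed.
#'
#' @param seed integer root seed.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds, all below 2^31.
#' @keywords internal
stage_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

# run expr with a temporary seed (NULL = leave RNG alone), restoring state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

stop_cfg <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
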