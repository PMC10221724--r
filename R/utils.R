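# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's). Only used on
# nonnegative quantities (edge counts, grid indices).
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream: the global .Random.seed is saved and restored.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Named substream seeds derived from one root seed, so that e.g. cohort
# simulation and permutation resampling never share a stream. Kept < 2^31.
sub_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  cp <- utf8ToInt(stream)
  h <- sum(cp * seq_along(cp))
  as.integer(((as.double(seed) %% 65011) * 33013 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
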