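# Internal helpers: deterministic seed substreams, scoped RNG, selector matching.

# Lehmer-style mixing of a base seed with integer indices. Keeps every value
# strictly inside [1, 2^31 - 2] so it is always a valid set.seed() input.
# Derived streams make any subset of trials reproducible on its own.
substream_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  for (idx in c(...)) {
    s <- (s * 48271) %% m
    s <- (s + abs(as.numeric(idx)) + 1) %% m
    s <- (s * 48271) %% m
    if (s == 0) s <- 1
  }
  as.integer(s)
}

# Evaluate expr under a local RNG state; the caller's stream is untouched.
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

# TRUE if a trial condition (named list/character) matches a selector.
# An empty selector matches everything.
matches_selector <- function(condition, selector) {
  if (length(selector) == 0L) return(TRUE)
  for (f in names(selector)) {
    if (is.null(condition[[f]]) || !(condition[[f]] %in% selector[[f]])) {
      return(FALSE)
    }
  }
  TRUE
}

# Subset a list of trials by selector (and optionally by participant).
filter_trials <- function(trials, selector = list(), participant = NULL) {
  keep <- vapply(trials, function(tr) {
    ok <- matches_selector(tr$condition, selector)
    if (!is.null(participant)) ok <- ok && identical(tr$participant_id, participant)
    ok
  }, logical(1))
  trials[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
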