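# Internal helpers shared across modules.

# Signal a classed error so callers/tests can distinguish failure modes.
.dsStop <- function(msg, class = "disperset_error", call. = FALSE) {
  stop(structure(
    class = c(class, "disperset_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Deterministic per-task seed derived from one top-level seed.  Keeps every
# scenario independently reproducible; always < 2^31.
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

.checkProbVector <- function(p, name = "probs", allowZero = TRUE, tol = 1e-8) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p))
    .dsStop(sprintf("'%s' must be a numeric probability vector without NAs", name))
  if (any(p < 0) || (!allowZero && any(p <= 0)))
    .dsStop(sprintf("'%s' has entries outside the allowed range", name))
  if (abs(sum(p) - 1) > tol)
    .dsStop(sprintf("'%s' must sum to 1 (observed sum %.10g)", name, sum(p)))
  p / sum(p)
}

.checkCounts <- function(counts, name = "counts") {
  if (!is.numeric(counts) || length(counts) < 1L || anyNA(counts))
    .dsStop(sprintf("'%s' must be a numeric vector without NAs", name))
  if (any(counts < 0) || any(counts != round(counts)))
    .dsStop(sprintf("'%s' must contain non-negative integers", name))
  as.integer(round(counts))
}

# Ordered default labels for variability levels.
.levelLabels <- function(m) {
  if (m <= 4L) c("low", "medium", "high", "very_high")[seq_len(m)]
  else paste0("level", seq_len(m))
}

# Closed-below / open-above interval rule: value <= boundary stays in the
# lower level, so level = 1 + #{b : b < value}.
.applyBoundaries <- function(values, boundaries) {
  if (length(boundaries) == 0L) {
    lev <- rep(1L, length(values))
  } else {
    lev <- findInterval(values, boundaries, left.open = TRUE) + 1L
  }
  names(lev) <- names(values)
  lev
}
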