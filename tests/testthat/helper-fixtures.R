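# Shared fixtures built in code at test time.

# Small deterministic expression matrix with named genes/samples.
makeMatrix <- function(nGenes = 20, nSamples = 6, seed = 42, mean = 8, sd = 2) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples, mean, sd), nGenes, nSamples,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("s%02d", seq_len(nSamples))))
}

# A VariabilityProfile directly from a value vector.
makeProfile <- function(values, statistic = "sd", group = "all") {
  if (is.null(names(values)))
    names(values) <- sprintf("g%04d", seq_along(values))
  methods::new("VariabilityProfile", statistic = statistic,
               values = values, group = group)
}

# A CategoryScheme with given boundaries and assignments derived from values.
makeScheme <- function(values, boundaries, statistic = "sd", group = "all",
                       mode = "mixture") {
  if (is.null(names(values)))
    names(values) <- sprintf("g%04d", seq_along(values))
  m <- length(boundaries) + 1L
  lev <- findInterval(values, boundaries, left.open = TRUE) + 1L
  names(lev) <- names(values)
  methods::new("CategoryScheme", mode = mode, statistic = statistic,
               nLevels = as.integer(m), boundaries = as.numeric(boundaries),
               levelNames = c("low", "medium", "high", "very_high")[seq_len(m)],
               assignments = stats::setNames(list(lev), group))
}

# Write a GMT file from a named list of gene vectors.
writeGmtLines <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}

# Independent naive multinomial exact p-value: direct factorial formula over
# an expand.grid enumeration (no log-space, no shared code with the package).
naiveExactP <- function(obs, p) {
  n <- sum(obs); m <- length(obs)
  grid <- as.matrix(expand.grid(rep(list(0:n), m)))
  grid <- grid[rowSums(grid) == n, , drop = FALSE]
  prob1 <- function(o) factorial(n) / prod(factorial(o)) * prod(p^o)
  probs <- apply(grid, 1, prob1)
  sum(probs[probs <= prob1(obs) * (1 + 1e-9)])
}
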