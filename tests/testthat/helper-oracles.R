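# Independent oracles used across test files. Each is a deliberately naive
# reimplementation (loops, explicit formulas) kept separate from the
# package's code paths.

# BH step-up: sort ascending, multiply by m/rank, cumulative minimum from
# the largest rank, cap at 1, return in input order
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# naive linear scan for strict sign-product switch points
scanOracle <- function(v) {
  idx <- integer(0)
  for (i in seq_len(length(v) - 1)) {
    if (v[i] * v[i + 1] < 0) idx <- c(idx, i)
  }
  idx
}

# exact hypergeometric upper tail from binomial coefficients (log scale)
hyperTailOracle <- function(count, K, N, n) {
  xs <- count:min(n, K)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# small dense expression fixture written as CSV; returns the path
writeCsvFixture <- function(m, path = tempfile(fileext = ".csv")) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# quiet wrappers: retention counts are messaged, tests don't care
quietFit <- function(...) suppressMessages(fitTrajectories(...))
quietRun <- function(...) suppressMessages(runCascade(...))
quietMS <- function(...) suppressMessages(analyzeMultiSample(...))
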