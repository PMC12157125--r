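## Shared fixtures and independent oracles. The oracles deliberately use
## naive enumeration so they stay independent of the vectorised paths
## they check.

randomDataset <- function(n, censorProb = 0.3, seed = 1, withTies = FALSE) {
  set.seed(seed)
  time <- if (withTies) sample(1:4, n, replace = TRUE) else rexp(n)
  survivalDataset(time = time,
                  event = rbinom(n, 1, 1 - censorProb))
}

## Eq.-style partial likelihood by direct enumeration: product over events
## of exp(f_i) / sum_{j in R(T*_i)} exp(f_j), inclusive risk sets.
bruteForcePartialNll <- function(time, event, f) {
  n <- length(time)
  total <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1) {
      denom <- sum(exp(f[time >= time[i]]))
      total <- total + log(exp(f[i]) / denom)
    }
  }
  -total / n
}

## O(n^2) pair enumeration of the concordance index.
bruteForceCIndex <- function(time, event, f, tieW = 0.5) {
  conc <- 0
  npairs <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] > time[j] && event[j] == 1) {
      npairs <- npairs + 1
      if (f[i] < f[j]) conc <- conc + 1
      else if (f[i] == f[j]) conc <- conc + tieW
    }
  }
  conc / npairs
}

## Pairwise AUC by enumeration, ties counted 0.5.
bruteForceAuc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

## Central finite differences of a scalar function of a vector.
numericGrad <- function(fn, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    up <- x; up[i] <- up[i] + eps
    dn <- x; dn[i] <- dn[i] - eps
    g[i] <- (fn(up) - fn(dn)) / (2 * eps)
  }
  g
}
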