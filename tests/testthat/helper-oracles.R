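# Independent reference implementations used as oracles throughout the
# suite: deliberately naive (per-element loops, direct formulas) so they
# share no code with the package's vectorized / compiled paths.

naiveDistance <- function(x, i, j, idx) {
  s <- 0
  for (d in idx) s <- s + (x[i, d] - x[j, d])^2
  sqrt(s)
}

naiveWeightedPrediction <- function(acts, dists) {
  w <- exp(-dists) / sum(exp(-dists))
  sum(w * acts)
}

# Double-loop leave-one-out kNN with exp(-r) weighting; ties at the k-th
# neighbour broken by ascending compound index.
naiveLoo <- function(x, act, idx, k) {
  n <- nrow(x)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    pool <- setdiff(seq_len(n), i)
    d <- vapply(pool, function(j) naiveDistance(x, i, j, idx), numeric(1))
    ord <- order(d, pool)[seq_len(k)]
    pred[i] <- naiveWeightedPrediction(act[pool[ord]], d[ord])
  }
  pred
}

naiveQ2 <- function(actual, predicted)
  1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)

# Random dataset factory for property-style loops.
randomQsar <- function(n, p, seed, scaled = TRUE) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p,
              dimnames = list(paste0("c", seq_len(n)),
                              paste0("d", seq_len(p))))
  QsarSet(x, activity = rnorm(n), scaled = scaled)
}

writeTempQsar <- function(ds, ...) {
  path <- tempfile(fileext = ".csv")
  writeQsarCsv(ds, path, ...)
  path
}
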