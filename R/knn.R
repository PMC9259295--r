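#' Euclidean distance between two compounds in a descriptor subspace
#'
#' Computes sqrt(sum over the subset's descriptors of (D_i - D_j)^2), i.e.
#' the Euclidean distance restricted to the active descriptor subset.
#' Distances are meaningful when the dataset has been range-scaled (or the
#' user has deliberately supplied pre-normalized descriptors).
#'
#' @param ds a [QsarSet-class].
#' @param i,j compound indices (i == j allowed, giving 0).
#' @param subset a [DescriptorSubset-class].
#' @return A non-negative number, symmetric in (i, j).
#' @export
pairwiseDistance <- function(ds, i, j, subset) {
  x <- descriptorMatrix(ds)
  idx <- subset@indices
  if (max(idx) > ncol(x)) stop("subset index out of range: ", max(idx))
  sqrt(sum((x[i, idx] - x[j, idx])^2))
}

#' k nearest neighbours of a compound in a descriptor subspace
#'
#' The target compound is always excluded from its own neighbour pool;
#' additional compounds may be excluded explicitly. Ties at equal distance
#' are broken by ascending compound index, so results are deterministic
#' across runs and platforms.
#'
#' @param ds a [QsarSet-class].
#' @param target compound index whose neighbours are sought.
#' @param subset a [DescriptorSubset-class].
#' @param k number of neighbours.
#' @param excluded integer vector of additional compound indices to exclude.
#' @return data.frame with columns `index` and `distance`, exactly `k` rows,
#'   sorted by ascending distance.
#' @export
nearestNeighbors <- function(ds, target, subset, k, excluded = integer(0)) {
  x <- descriptorMatrix(ds)
  idx <- subset@indices
  if (max(idx) > ncol(x)) stop("subset index out of range: ", max(idx))
  pool <- setdiff(seq_len(nrow(x)), union(as.integer(excluded), target))
  if (k > length(pool))
    stop(sprintf("k = %d exceeds the available neighbour pool (%d)",
                 k, length(pool)))
  d <- sqrt(colSums((t(x[pool, idx, drop = FALSE]) - x[target, idx])^2))
  ord <- order(d, pool)[seq_len(k)]
  data.frame(index = pool[ord], distance = unname(d[ord]))
}

#' Exponentially distance-weighted neighbour prediction
#'
#' Predicts an activity as the weighted mean of the neighbours' activities
#' with weights w_i = exp(-r_i) / sum_j exp(-r_j): the nearer a neighbour,
#' the greater its weight. Weights are normalized to sum to 1, so the
#' prediction always lies within the range of the neighbour activities.
#' Zero distances (exact duplicates) are unproblematic: exp(0) = 1 is
#' finite, so a duplicate receives the maximal weight without dominating
#' unless it is the only neighbour.
#'
#' @param neighborActivities numeric vector of neighbour activities.
#' @param neighborDistances numeric vector of non-negative distances, same
#'   length.
#' @return The weighted mean activity.
#' @examples
#' weightedPrediction(c(2, 4), c(1, 1))   # equal weights -> 3
#' @export
weightedPrediction <- function(neighborActivities, neighborDistances) {
  if (length(neighborActivities) < 1L) stop("at least one neighbour is required")
  if (length(neighborActivities) != length(neighborDistances))
    stop("activities and distances must have equal length")
  if (any(neighborDistances < 0)) stop("distances must be non-negative")
  # shift by the minimum distance: cancels in the normalized weights but
  # avoids underflow of exp(-r) for large r
  w <- exp(-(neighborDistances - min(neighborDistances)))
  sum(w * neighborActivities) / sum(w)
}

#' Leave-one-out cross-validated q-squared
#'
#' q2 = 1 - sum((m - mhat)^2) / sum((m - mean(m))^2), with the mean taken
#' over the actual activities of the full set (the standard LOO-q-squared
#' convention). q2 is at most 1; 1 means perfect LOO prediction, 0 means no
#' better than predicting the mean, and negative values mean worse than the
#' mean.
#'
#' @param actual,predicted numeric vectors of equal length >= 2.
#' @return A number <= 1.
#' @section Errors: all `actual` values identical (zero denominator) signals
#'   an uninformative activity vector; the annealing search maps this to an
#'   invalid (-Inf) subset score.
#' @examples
#' qSquared(1:4, c(1.1, 1.9, 3.2, 3.8))   # 1 - 0.10/5 = 0.98
#' @export
qSquared <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 2L)
    stop("actual and predicted must have equal length >= 2")
  ssTot <- sum((actual - mean(actual))^2)
  if (ssTot == 0)
    stop("all actual values are identical: q-squared is undefined")
  1 - sum((actual - predicted)^2) / ssTot
}

# Row-wise neighbour ordering of a full distance matrix, self excluded
# (diagonal set to Inf), via one grouped radix sort of the flattened
# matrix. Radix sort is stable, so ties are broken by ascending compound
# index. Returns list(index, distance), both n x kMax matrices with
# columns sorted by ascending distance.
.neighborTables <- function(D, kMax) {
  n <- nrow(D)
  diag(D) <- Inf
  v <- as.vector(t(D))                       # row i occupies block i
  o <- order(rep.int(seq_len(n), rep.int(n, n)), v, method = "radix")
  base <- (seq_len(n) - 1L) * n
  posMat <- matrix(o[outer(base, seq_len(kMax), "+")], n, kMax)
  list(index = posMat - base, distance = matrix(v[posMat], n, kMax))
}

# Predictions for one k given precomputed neighbour tables (vectorized).
# Columns are sorted by distance, so column 1 holds the row-wise minimum
# used to stabilize exp(-r) against underflow.
.predictFromTables <- function(tables, act, k) {
  idx <- tables$index[, seq_len(k), drop = FALSE]
  d <- tables$distance[, seq_len(k), drop = FALSE]
  w <- exp(-(d - d[, 1L]))
  rowSums(w * matrix(act[idx], nrow(idx), k)) / rowSums(w)
}

# Fast k-sweep on a precomputed (already subset) descriptor matrix: the
# annealing hot path, delegated to compiled code. Zero activity variance
# maps to a -Inf score.
.sweepQ2 <- function(xsub, act, kMax) {
  .sweepQ2Cpp(xsub, act, as.integer(min(kMax, nrow(xsub) - 1L)))
}

#' Leave-one-out prediction in a descriptor subspace
#'
#' Each compound in turn is held out, its k nearest neighbours among the
#' remaining compounds are found in the subset's descriptor space, and its
#' activity is predicted as their exponentially distance-weighted mean
#' ([weightedPrediction()]). The procedure is repeated until every compound
#' has been held out once, and the predictions are scored with
#' [qSquared()].
#'
#' @param ds a [QsarSet-class].
#' @param subset a [DescriptorSubset-class].
#' @param k neighbourhood size, 1 <= k <= nCompounds - 1.
#' @return A [LooResult-class].
#' @export
looPredict <- function(ds, subset, k) {
  x <- descriptorMatrix(ds)
  idx <- subset@indices
  if (max(idx) > ncol(x)) stop("subset index out of range: ", max(idx))
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L)
    stop(sprintf("k must satisfy 1 <= k <= %d, got %d", n - 1L, k))
  D <- as.matrix(stats::dist(x[, idx, drop = FALSE]))
  tables <- .neighborTables(D, k)
  act <- unname(activity(ds))
  pred <- .predictFromTables(tables, act, k)
  names(pred) <- compoundIds(ds)
  q2 <- if (sum((act - mean(act))^2) == 0) {
    warning("activity is constant: q-squared is undefined (stored as NA)",
            call. = FALSE)
    NA_real_
  } else qSquared(act, pred)
  methods::new("LooResult", predictions = pred,
               residuals = stats::setNames(act, compoundIds(ds)) - pred,
               q2 = q2, k = k, subset = subset)
}

setMethod("show", "LooResult", function(object) {
  cat(sprintf("LooResult: %d compounds, k = %d, subset size %d, q2 = %.6g\n",
              length(object@predictions), object@k,
              length(object@subset@indices), object@q2))
})

#' Sweep the neighbourhood size k and keep the best q-squared
#'
#' Evaluates [looPredict()] for k = 1, ..., kMax and returns the k with the
#' maximal q-squared; ties are broken towards the smaller (more
#' parsimonious) k. Small k (1 to 5) is where distance-weighted kNN
#' typically performs best, hence the default. kMax is clamped to
#' nCompounds - 1 with a message when it exceeds the pool.
#'
#' @param ds a [QsarSet-class].
#' @param subset a [DescriptorSubset-class].
#' @param kMax upper end of the sweep (default 5).
#' @return A list with elements `k` (the winning k), `result` (the
#'   [LooResult-class] at that k) and `table` (data.frame of all (k, q2)
#'   pairs evaluated).
#' @export
sweepK <- function(ds, subset, kMax = 5L) {
  n <- nCompounds(ds)
  kMax <- as.integer(kMax)
  if (kMax < 1L) stop("kMax must be >= 1")
  if (kMax > n - 1L) {
    message(sprintf("kMax clamped from %d to %d (only %d compounds)",
                    kMax, n - 1L, n))
    kMax <- n - 1L
  }
  x <- descriptorMatrix(ds)
  idx <- subset@indices
  if (max(idx) > ncol(x)) stop("subset index out of range: ", max(idx))
  D <- as.matrix(stats::dist(x[, idx, drop = FALSE]))
  tables <- .neighborTables(D, kMax)
  act <- unname(activity(ds))
  q2s <- vapply(seq_len(kMax), function(k)
    qSquared(act, .predictFromTables(tables, act, k)), numeric(1))
  bestK <- which.max(q2s)   # which.max takes the first maximum: smaller k wins ties
  pred <- stats::setNames(.predictFromTables(tables, act, bestK),
                          compoundIds(ds))
  res <- methods::new("LooResult", predictions = pred,
                      residuals = stats::setNames(act, compoundIds(ds)) - pred,
                      q2 = q2s[bestK], k = as.integer(bestK), subset = subset)
  list(k = as.integer(bestK), result = res,
       table = data.frame(k = seq_len(kMax), q2 = q2s))
}

#' Predict activities of new compounds with a fitted model
#'
#' New compounds are scored against all reference compounds (no hold-out):
#' scaling is replayed via the model's stored parameters, the model's k
#' nearest reference compounds are found in the model's descriptor subspace,
#' and the exponentially distance-weighted mean of their activities is
#' returned.
#'
#' @param object a [KnnModel-class].
#' @param newdata an unscaled [QsarSet-class] sharing the reference's
#'   descriptor names and order, or a plain numeric matrix (compounds in
#'   rows, named descriptor columns; may have zero rows).
#' @param ... ignored.
#' @return Named numeric vector of predictions, one per new compound.
#' @export
setMethod("predict", "KnnModel", function(object, newdata, ...) {
  refNames <- descriptorNames(object@reference)
  if (methods::is(newdata, "QsarSet")) {
    newNames <- descriptorNames(newdata)
    newMat <- descriptorMatrix(newdata)
    ids <- compoundIds(newdata)
  } else {
    newMat <- as.matrix(newdata)
    newNames <- colnames(newMat)
    ids <- rownames(newMat)
  }
  if (!identical(newNames, refNames))
    stop("descriptor names/order of the new data do not match the model reference")
  if (!is.null(object@scaling))
    newMat <- .replayScaling(newMat, object@scaling)
  idx <- object@subset@indices
  ref <- descriptorMatrix(object@reference)[, idx, drop = FALSE]
  new <- newMat[, idx, drop = FALSE]
  act <- unname(activity(object@reference))
  k <- object@k
  refIdx <- seq_len(nrow(ref))
  pred <- vapply(seq_len(nrow(new)), function(i) {
    d <- sqrt(colSums((t(ref) - new[i, ])^2))
    ord <- order(d, refIdx)[seq_len(k)]
    weightedPrediction(act[ord], d[ord])
  }, numeric(1))
  stats::setNames(pred, ids)
})

setMethod("show", "KnnModel", function(object) {
  cat(sprintf("KnnModel: k = %d, subset size %d, LOO q2 = %.6g\n",
              object@k, length(object@subset@indices), object@q2))
  cat(sprintf("reference: %d compounds x %d descriptors; subset: %s\n",
              nCompounds(object@reference), nDescriptors(object@reference),
              paste(subsetNames(object@subset, object@reference),
                    collapse = ", ")))
})
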