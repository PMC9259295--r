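#' Construct an annealing configuration
#'
#' Defaults implement the minimal standard simulated-annealing machinery:
#' single-swap proposals, geometric cooling, and a fixed step budget. The
#' temperature scale is that of q-squared differences, since acceptance is
#' exp((q2_new - q2_current)/T).
#'
#' @param n descriptor-subset size.
#' @param steps total number of proposals (default 2000).
#' @param tInitial,tFinal start and end temperatures (defaults 0.05 and
#'   1e-4: the search starts permissive on the q-squared scale and ends
#'   essentially greedy).
#' @param cooling per-step multiplicative factor in (0, 1), or NA (default)
#'   to derive it so that tInitial decays to tFinal over `steps`.
#' @param swapSize descriptors exchanged per proposal (default 1).
#' @param kMax upper end of the k sweep used when scoring (default 5).
#' @param seed RNG seed for the trajectory (NA = use current RNG stream).
#' @return A validated [AnnealConfig-class].
#' @export
annealConfig <- function(n, steps = 2000L, tInitial = 0.05, tFinal = 1e-4,
                         cooling = NA_real_, swapSize = 1L, kMax = 5L,
                         seed = NA_integer_) {
  methods::new("AnnealConfig", n = as.integer(n), steps = as.integer(steps),
               tInitial = as.numeric(tInitial), tFinal = as.numeric(tFinal),
               cooling = as.numeric(cooling), swapSize = as.integer(swapSize),
               kMax = as.integer(kMax), seed = as.integer(seed))
}

#' Draw a uniformly random descriptor subset
#'
#' Draws a duplicate-free subset of `n` of the `nDescriptors` columns,
#' uniformly over all such subsets, from R's global RNG stream (seed with
#' `set.seed()` for determinism).
#'
#' @param nDescriptors total number of descriptor columns.
#' @param n subset size, 1 <= n <= nDescriptors.
#' @return A [DescriptorSubset-class].
#' @export
randomSubset <- function(nDescriptors, n) {
  nDescriptors <- as.integer(nDescriptors)
  n <- as.integer(n)
  if (n < 1L || n > nDescriptors)
    stop(sprintf("subset size must satisfy 1 <= n <= %d, got %d",
                 nDescriptors, n))
  methods::new("DescriptorSubset",
               indices = sort(sample.int(nDescriptors, n)))
}

#' Propose a neighbouring subset by swapping members
#'
#' Removes `swapSize` members (uniformly) and adds `swapSize` non-members
#' (uniformly), producing a subset of identical size differing from the
#' input in exactly `swapSize` elements. Uses R's global RNG stream.
#'
#' @param subset a [DescriptorSubset-class].
#' @param nDescriptors total number of descriptor columns.
#' @param swapSize number of members exchanged (default 1).
#' @return A [DescriptorSubset-class].
#' @export
proposeSwap <- function(subset, nDescriptors, swapSize = 1L) {
  methods::new("DescriptorSubset",
               indices = .swapIdx(subset@indices, as.integer(nDescriptors),
                                  as.integer(swapSize)))
}

# Plain-vector swap move used inside the annealing loop (no S4 overhead).
.swapIdx <- function(cur, nDesc, swapSize) {
  outPool <- setdiff(seq_len(nDesc), cur)
  if (length(outPool) == 0L)
    stop("no legal move: the subset already contains every descriptor")
  if (swapSize > min(length(cur), length(outPool)))
    stop("swapSize exceeds the number of exchangeable descriptors")
  drop <- cur[sample.int(length(cur), swapSize)]
  add <- outPool[sample.int(length(outPool), swapSize)]
  sort(c(setdiff(cur, drop), add))
}

#' Score a subset by its best k-sweep q-squared
#'
#' Runs [sweepK()] and returns the winning (q2, k) pair. A dataset whose
#' activity has zero variance makes q-squared undefined; that is mapped to a
#' -Inf score so the annealing search can never accept it as best.
#'
#' @param ds a [QsarSet-class].
#' @param subset a [DescriptorSubset-class].
#' @param kMax upper end of the k sweep.
#' @return list(q2 = best q-squared, k = winning k).
#' @export
scoreSubset <- function(ds, subset, kMax = 5L) {
  x <- descriptorMatrix(ds)
  idx <- subset@indices
  if (max(idx) > ncol(x)) stop("subset index out of range: ", max(idx))
  .sweepQ2(x[, idx, drop = FALSE], unname(activity(ds)), kMax)
}

# Metropolis acceptance for a maximization move: always accept
# improvements, accept worsenings with probability exp(delta / temperature).
# Draws one uniform variate from the global RNG stream for worsening moves.
.metropolisAccept <- function(delta, temperature) {
  if (delta >= 0) return(TRUE)
  stats::runif(1) < exp(delta / temperature)
}

#' Metropolis acceptance rule
#'
#' Accepts an improving move (`delta >= 0`) always, and a worsening move
#' with probability exp(delta / temperature). Exposed so the acceptance
#' behaviour can be audited empirically.
#'
#' @param delta proposed score minus current score (q-squared scale).
#' @param temperature current temperature (> 0).
#' @return logical.
#' @export
metropolisAccept <- function(delta, temperature) {
  stopifnot(temperature > 0)
  .metropolisAccept(delta, temperature)
}

# Run a block of code with a locally seeded RNG, restoring the caller's
# stream afterwards. seed = NA uses the current stream untouched.
.withLocalSeed <- function(seed, expr) {
  if (is.na(seed)) return(force(expr))
  hasOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasOld) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hasOld) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulated-annealing search for the best descriptor subset
#'
#' Metropolis simulated annealing over fixed-size descriptor subsets with
#' the k-sweep leave-one-out q-squared as the objective: starting from a
#' uniformly random subset, single-swap (or `swapSize`-swap) proposals are
#' accepted whenever they do not decrease q-squared and otherwise with
#' probability exp((q2_new - q2_current)/T), while the temperature T cools
#' geometrically from `tInitial` to `tFinal` over the step budget. The
#' best-ever subset (with its sweep-selected k) is returned as a fitted
#' model. Fully reproducible from `config@seed`.
#'
#' @param ds a [QsarSet-class]; distances are computed on its descriptor
#'   values as-is, so range-scale first unless descriptors are already
#'   commensurate.
#' @param config an [AnnealConfig-class].
#' @param trajectory logical; record (step, q2, accepted) per proposal.
#' @param scaling optional [ScalingParams-class] stored in the returned
#'   model so it can score unscaled external compounds.
#' @return list(model = [KnnModel-class], state = [AnnealState-class]).
#' @export
anneal <- function(ds, config, trajectory = FALSE, scaling = NULL) {
  methods::validObject(config)
  nDesc <- nDescriptors(ds)
  if (config@n > nDesc)
    stop(sprintf("subset size n = %d exceeds the %d available descriptors",
                 config@n, nDesc))
  if (stats::var(activity(ds)) == 0)
    stop("activity has zero variance: no subset can yield a defined q-squared")
  x <- descriptorMatrix(ds)
  act <- unname(activity(ds))
  kMax <- config@kMax
  .withLocalSeed(config@seed, {
    cur <- sort(sample.int(nDesc, config@n))
    curScore <- .sweepQ2(x[, cur, drop = FALSE], act, kMax)
    initialQ2 <- curScore$q2
    best <- cur; bestScore <- curScore
    temp <- config@tInitial
    factor <- if (is.na(config@cooling)) {
      if (config@steps > 1L)
        (config@tFinal / config@tInitial)^(1 / (config@steps - 1L)) else 1
    } else config@cooling
    canMove <- config@n < nDesc
    traj <- if (trajectory)
      list(step = integer(config@steps), q2 = numeric(config@steps),
           accepted = logical(config@steps)) else NULL
    step <- 0L
    while (step < config@steps && canMove) {
      step <- step + 1L
      prop <- .swapIdx(cur, nDesc, config@swapSize)
      propScore <- .sweepQ2(x[, prop, drop = FALSE], act, kMax)
      accepted <- .metropolisAccept(propScore$q2 - curScore$q2, temp)
      if (accepted) {
        cur <- prop; curScore <- propScore
        if (propScore$q2 > bestScore$q2) {
          best <- prop; bestScore <- propScore
        }
      }
      if (trajectory) {
        traj$step[step] <- step
        traj$q2[step] <- propScore$q2
        traj$accepted[step] <- accepted
      }
      temp <- temp * factor
    }
    trajDf <- if (trajectory)
      data.frame(step = c(0L, traj$step[seq_len(step)]),
                 q2 = c(initialQ2, traj$q2[seq_len(step)]),
                 accepted = c(TRUE, traj$accepted[seq_len(step)]))
    else data.frame(step = integer(0), q2 = numeric(0), accepted = logical(0))
    bestSub <- methods::new("DescriptorSubset", indices = best)
    state <- methods::new("AnnealState",
                          currentSubset = methods::new("DescriptorSubset",
                                                       indices = cur),
                          bestSubset = bestSub, currentQ2 = curScore$q2,
                          bestQ2 = bestScore$q2,
                          bestK = as.integer(bestScore$k),
                          temperature = temp, step = step, trajectory = trajDf)
    model <- methods::new("KnnModel", subset = bestSub,
                          k = as.integer(bestScore$k), reference = ds,
                          scaling = scaling, q2 = bestScore$q2)
    list(model = model, state = state)
  })
}

setMethod("show", "AnnealState", function(object) {
  cat(sprintf(
    "AnnealState: step %d, T = %.3g, current q2 = %.6g, best q2 = %.6g (k = %d)\n",
    object@step, object@temperature, object@currentQ2, object@bestQ2,
    object@bestK))
})

#' Exhaustive search over all size-n subsets
#'
#' Scores every size-n descriptor subset in lexicographic order and returns
#' the maximum; ties are broken towards the lexicographically first subset.
#' Intended as a tractable gold standard for small instances (the
#' combination count is capped).
#'
#' @param ds a [QsarSet-class].
#' @param n subset size.
#' @param kMax upper end of the k sweep.
#' @param cap maximum allowed number of combinations (default 100000).
#' @return list(subset = [DescriptorSubset-class], q2, k, evaluated =
#'   number of subsets scored).
#' @export
exhaustiveSearch <- function(ds, n, kMax = 5L, cap = 100000) {
  nDesc <- nDescriptors(ds)
  nComb <- choose(nDesc, n)
  if (nComb > cap)
    stop(sprintf("C(%d, %d) = %.0f exceeds the cap of %g", nDesc, n, nComb, cap))
  combos <- utils::combn(nDesc, n)
  x <- descriptorMatrix(ds)
  act <- unname(activity(ds))
  bestQ2 <- -Inf; bestIdx <- NULL; bestK <- NA_integer_
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    sc <- .sweepQ2(x[, idx, drop = FALSE], act, kMax)
    if (sc$q2 > bestQ2) {
      bestQ2 <- sc$q2
      bestIdx <- methods::new("DescriptorSubset", indices = as.integer(idx))
      bestK <- sc$k
    }
  }
  list(subset = bestIdx, q2 = bestQ2, k = bestK, evaluated = ncol(combos))
}

# Stable integer seed for ensemble member (n, restart) under a base seed;
# kept well below 2^31.
.deriveSeed <- function(baseSeed, n, restart) {
  as.integer((as.double(baseSeed) * 100003 + as.double(n) * 7919 +
                as.double(restart) * 104729) %% 2147483629)
}

#' Multi-n, multi-restart annealing ensemble
#'
#' For each subset size in `nValues` and each of `restarts` independent
#' restarts, runs [anneal()] with a deterministically derived seed (a stable
#' hash of the base seed, n and the restart index, so adding restarts never
#' perturbs earlier members). Sizes exceeding the number of descriptors are
#' skipped with a warning. The default grid (10, 20, 30, 40, 50 informative
#' dimensions, 10 restarts each) reflects common practice for this family
#' of models: many models per subset size, over a range of sizes.
#'
#' @param ds a [QsarSet-class].
#' @param nValues integer vector of subset sizes; NULL for the default grid
#'   c(10, 20, 30, 40, 50) intersected with the valid range.
#' @param restarts independent annealing restarts per n (default 10).
#' @param baseConfig an [AnnealConfig-class] providing steps, temperatures,
#'   swapSize and kMax (its `n` and `seed` are overridden per member).
#' @param baseSeed integer base seed for the derived per-member seeds.
#' @param scaling optional [ScalingParams-class] forwarded to each model.
#' @return An [EnsembleResult-class].
#' @export
runEnsemble <- function(ds, nValues = NULL, restarts = 10L,
                        baseConfig = annealConfig(n = 1L), baseSeed = 1L,
                        scaling = NULL) {
  nDesc <- nDescriptors(ds)
  if (is.null(nValues)) nValues <- c(10L, 20L, 30L, 40L, 50L)
  nValues <- as.integer(nValues)
  bad <- nValues > nDesc | nValues < 1L
  if (any(bad)) {
    warning("skipping subset size(s) out of range: ",
            paste(nValues[bad], collapse = ", "), call. = FALSE)
    nValues <- nValues[!bad]
  }
  if (length(nValues) == 0L) stop("no valid subset sizes to run")
  restarts <- as.integer(restarts)
  stopifnot(restarts >= 1L)
  models <- list()
  rows <- list()
  for (n in nValues) {
    for (r in seq_len(restarts) - 1L) {
      seed <- .deriveSeed(baseSeed, n, r)
      cfg <- annealConfig(n = n, steps = baseConfig@steps,
                          tInitial = baseConfig@tInitial,
                          tFinal = baseConfig@tFinal,
                          cooling = baseConfig@cooling,
                          swapSize = min(baseConfig@swapSize, n),
                          kMax = baseConfig@kMax, seed = seed)
      fit <- anneal(ds, cfg, scaling = scaling)
      models[[length(models) + 1L]] <- fit$model
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, restart = r, seed = seed, best_q2 = fit$model@q2,
        best_k = fit$model@k,
        subset = paste(subsetNames(fit$model@subset, ds), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  bestRow <- which.max(summary$best_q2)
  methods::new("EnsembleResult", models = models, summary = summary,
               overallBest = models[[bestRow]])
}

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: %d models over n = {%s}\n",
              length(object@models),
              paste(unique(object@summary$n), collapse = ", ")))
  cat("overall best: ")
  methods::show(object@overallBest)
})
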