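#' @import methods
#' @useDynLib ccknn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats dist rnorm runif sd var setNames predict
#' @importFrom utils combn read.csv write.csv
NULL

#' QsarSet: a compound-by-descriptor table with activities
#'
#' The central data container. A `QsarSet` extends
#' [SummarizedExperiment::SummarizedExperiment] with descriptors stored as the
#' `"descriptors"` assay (descriptors in rows, compounds in columns, following
#' the features-by-samples convention) and the continuous activity of each
#' compound in `colData(x)$activity`. Whether range scaling has been applied
#' is recorded in `metadata(x)$scaled`.
#'
#' Invariants enforced by the validity method: at least 3 compounds
#' (leave-one-out with k >= 1 needs two training compounds after removal),
#' unique compound identifiers, unique descriptor names, and no non-finite
#' entries in descriptors or activity.
#'
#' @seealso [QsarSet()] for construction, [descriptorMatrix()], [activity()],
#'   [rangeScale()]
#' @export
setClass("QsarSet", contains = "SummarizedExperiment")

#' Per-descriptor range-scaling parameters
#'
#' Records the minimum and maximum of every descriptor column on the training
#' data, so the affine map x -> (x - min)/(max - min) can be replayed on new
#' compounds. Constant columns (max == min) are flagged; they map to zero.
#'
#' @slot names character, descriptor names in canonical column order.
#' @slot min,max numeric, per-descriptor extrema in original units.
#' @slot constant logical, TRUE where max == min.
#' @seealso [rangeScale()], [applyScaling()]
#' @export
setClass("ScalingParams",
  representation(names = "character", min = "numeric", max = "numeric",
                 constant = "logical"))

setValidity("ScalingParams", function(object) {
  n <- length(object@names)
  if (length(object@min) != n || length(object@max) != n ||
      length(object@constant) != n)
    return("names, min, max and constant must have equal length")
  if (any(!is.finite(object@min)) || any(!is.finite(object@max)))
    return("non-finite scaling bounds")
  if (any(object@max < object@min))
    return("max must be >= min for every descriptor")
  if (any(object@constant != (object@max == object@min)))
    return("constant flag inconsistent with min/max")
  TRUE
})

#' A descriptor subset (hypothetical descriptor pharmacophore)
#'
#' An ordered, duplicate-free set of 1-based descriptor column indices that
#' defines the active distance space for kNN. In the QSAR literature a
#' candidate subset of this kind is called a hypothetical descriptor
#' pharmacophore (HDP).
#'
#' @slot indices strictly increasing positive integers.
#' @seealso [descriptorSubset()]
#' @export
setClass("DescriptorSubset", representation(indices = "integer"))

setValidity("DescriptorSubset", function(object) {
  idx <- object@indices
  if (length(idx) < 1L) return("subset must contain at least one descriptor")
  if (anyNA(idx) || any(idx < 1L)) return("indices must be positive integers")
  if (is.unsorted(idx, strictly = TRUE)) return("indices must be strictly increasing")
  TRUE
})

setClassUnion("ScalingParamsOrNULL", c("ScalingParams", "NULL"))

#' A fitted distance-weighted kNN model
#'
#' Bundles everything needed to score new compounds: the selected descriptor
#' subset, the neighbourhood size k, the (scaled) reference dataset whose
#' compounds act as neighbours, the scaling parameters to replay on new data
#' (NULL when scaling was disabled), and the leave-one-out q-squared achieved
#' on the reference set.
#'
#' @slot subset [DescriptorSubset-class].
#' @slot k integer neighbourhood size, 1 <= k <= nCompounds - 1.
#' @slot reference [QsarSet-class] used as the neighbour pool.
#' @slot scaling [ScalingParams-class] or NULL.
#' @slot q2 numeric, the LOO q-squared on the reference set.
#' @seealso [predict,KnnModel-method], [saveKnnModel()], [readKnnModel()]
#' @export
setClass("KnnModel",
  representation(subset = "DescriptorSubset", k = "integer",
                 reference = "QsarSet", scaling = "ScalingParamsOrNULL",
                 q2 = "numeric"))

setValidity("KnnModel", function(object) {
  n <- ncol(object@reference)
  if (length(object@k) != 1L || object@k < 1L || object@k > n - 1L)
    return("k must satisfy 1 <= k <= nCompounds - 1")
  if (max(object@subset@indices) > nrow(object@reference))
    return("subset indices exceed the number of descriptors in the reference")
  if (length(object@q2) != 1L) return("q2 must be a single value")
  TRUE
})

#' Leave-one-out cross-validation result
#'
#' Holds the per-compound LOO predictions and residuals for one
#' (subset, k) pair, together with the q-squared score. The invariant
#' `residuals == actual - predictions` lets the actual activities and the
#' q-squared be recomputed from the stored vectors.
#'
#' @slot predictions named numeric, one finite prediction per compound.
#' @slot residuals named numeric, actual minus predicted.
#' @slot q2 numeric, 1 - SS_res/SS_tot.
#' @slot k integer.
#' @slot subset [DescriptorSubset-class].
#' @seealso [looPredict()], [sweepK()]
#' @export
setClass("LooResult",
  representation(predictions = "numeric", residuals = "numeric",
                 q2 = "numeric", k = "integer", subset = "DescriptorSubset"))

setValidity("LooResult", function(object) {
  if (length(object@predictions) != length(object@residuals))
    return("predictions and residuals must have equal length")
  if (any(!is.finite(object@predictions)))
    return("predictions must be finite")
  TRUE
})

#' Simulated-annealing configuration
#'
#' Parameters of one annealing trajectory. Temperatures are dimensionless and
#' live on the q-squared scale, since acceptance probabilities are
#' exp((q2_new - q2_current)/T). Cooling is geometric: when `cooling` is NA
#' the per-step factor is derived so the temperature falls from `tInitial` to
#' `tFinal` over `steps` proposals.
#'
#' @slot n integer, descriptor-subset size.
#' @slot steps integer, total number of proposals.
#' @slot tInitial,tFinal numeric, start and end temperatures.
#' @slot cooling numeric, multiplicative factor per step, or NA to derive.
#' @slot swapSize integer, descriptors exchanged per proposal.
#' @slot kMax integer, upper end of the k sweep.
#' @slot seed integer RNG seed (NA = use the current RNG stream).
#' @seealso [annealConfig()], [anneal()]
#' @export
setClass("AnnealConfig",
  representation(n = "integer", steps = "integer", tInitial = "numeric",
                 tFinal = "numeric", cooling = "numeric", swapSize = "integer",
                 kMax = "integer", seed = "integer"))

setValidity("AnnealConfig", function(object) {
  if (object@n < 1L) return("n must be >= 1")
  if (object@steps < 1L) return("steps must be >= 1")
  if (!(object@tFinal > 0 && object@tFinal <= object@tInitial))
    return("temperatures must satisfy 0 < tFinal <= tInitial")
  if (!is.na(object@cooling) && !(object@cooling > 0 && object@cooling < 1))
    return("geometric cooling factor must lie in (0, 1)")
  if (object@swapSize < 1L || object@swapSize > object@n)
    return("swapSize must satisfy 1 <= swapSize <= n")
  if (object@kMax < 1L) return("kMax must be >= 1")
  TRUE
})

#' State of one annealing trajectory
#'
#' Records the current and best-so-far subsets and scores, the temperature
#' and step counter at termination, and (optionally) the full trajectory of
#' evaluated q-squared values with acceptance flags. `bestQ2` is the maximum
#' of all q-squared values evaluated along the trajectory; the current score
#' may be worse than the best, since annealing accepts worsening moves.
#'
#' @slot currentSubset,bestSubset [DescriptorSubset-class].
#' @slot currentQ2,bestQ2 numeric.
#' @slot bestK integer, the sweep-selected k at the best subset.
#' @slot temperature numeric, temperature after the final step.
#' @slot step integer, number of proposals performed.
#' @slot trajectory data.frame with columns step, q2, accepted; step 0 is
#'   the evaluation of the initial subset (zero rows when trajectory
#'   recording is off).
#' @export
setClass("AnnealState",
  representation(currentSubset = "DescriptorSubset",
                 bestSubset = "DescriptorSubset",
                 currentQ2 = "numeric", bestQ2 = "numeric", bestK = "integer",
                 temperature = "numeric", step = "integer",
                 trajectory = "data.frame"))

#' Result of a multi-n, multi-restart annealing ensemble
#'
#' @slot models list of [KnnModel-class], one per (n, restart) pair.
#' @slot summary data.frame with columns n, restart, seed, best_q2, best_k,
#'   subset (semicolon-joined descriptor names).
#' @slot overallBest [KnnModel-class], the model with the maximal q-squared.
#' @seealso [runEnsemble()]
#' @export
setClass("EnsembleResult",
  representation(models = "list", summary = "data.frame",
                 overallBest = "KnnModel"))

setValidity("EnsembleResult", function(object) {
  if (nrow(object@summary) != length(object@models))
    return("summary rows must match the number of models")
  q2s <- vapply(object@models, function(m) m@q2, numeric(1))
  if (length(q2s) && abs(object@overallBest@q2 - max(q2s)) > 1e-12)
    return("overallBest q2 must equal the maximum over models")
  TRUE
})

#' Ground truth of a synthetic QSAR dataset
#'
#' @slot informative [DescriptorSubset-class], the columns that determine
#'   activity.
#' @slot form character, "linear" or "cluster".
#' @slot coefficients numeric, linear weights (length 0 for cluster form).
#' @slot centers matrix, cluster centres in informative space (0 rows for
#'   linear form).
#' @slot noiseSd numeric, realized noise standard deviation (activity units).
#' @slot noiseless numeric, the activity vector before noise.
#' @seealso [simulateQsar()]
#' @export
setClass("SyntheticTruth",
  representation(informative = "DescriptorSubset", form = "character",
                 coefficients = "numeric", centers = "matrix",
                 noiseSd = "numeric", noiseless = "numeric"))
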