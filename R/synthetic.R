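#' Generate a synthetic QSAR benchmark with known ground truth
#'
#' Emulates a QSAR descriptor table: a small set of informative descriptors
#' determines activity through a stated functional form plus Gaussian noise,
#' surrounded by many irrelevant descriptors, with columns on heterogeneous
#' scales so range scaling matters. Descriptor columns are drawn uniformly:
#' column j is Uniform(0, s_j) with the scales s_j log-spaced from 1 up to
#' `scaleSpread`, so actual ranges differ by up to that factor. Activity is
#' computed from the *unit-scale* latent values (the column divided by its
#' scale), so every informative column carries comparable signal regardless
#' of its raw scale — exactly the situation range scaling is meant to fix.
#'
#' Functional forms:
#' \describe{
#'   \item{linear}{activity = sum over informative columns of c_j * u_j,
#'     with weights c_j drawn uniformly from `coefRange` (sign random).}
#'   \item{cluster}{compounds are drawn around a few centres in informative
#'     space and activity is the centre's value: local structure that
#'     nearest-neighbour prediction exploits, where a global linear model
#'     would not.}
#' }
#' Gaussian noise with standard deviation `noiseSd` times the SD of the
#' noiseless activity is then added.
#'
#' @param nCompounds number of compounds (rows), >= 3.
#' @param nInformative number of activity-determining descriptors, >= 1.
#' @param nNoise number of irrelevant descriptors, >= 0.
#' @param form "linear" or "cluster".
#' @param coefRange interval for the magnitude of linear weights.
#' @param noiseSd noise SD as a fraction of the noiseless activity SD.
#' @param scaleSpread max ratio between descriptor column scales (>= 1).
#' @param nClusters number of centres for the cluster form.
#' @param seed integer seed; the generator is deterministic per seed.
#' @return list(dataset = unscaled [QsarSet-class], truth =
#'   [SyntheticTruth-class]).
#' @examples
#' sim <- simulateQsar(nCompounds = 30, nInformative = 2, nNoise = 8,
#'                     noiseSd = 0, seed = 7)
#' subsetNames(sim$truth@informative, sim$dataset)
#' @export
simulateQsar <- function(nCompounds = 60L, nInformative = 5L, nNoise = 45L,
                         form = c("linear", "cluster"),
                         coefRange = c(0.5, 2), noiseSd = 0.25,
                         scaleSpread = 100, nClusters = 4L, seed = 1L) {
  form <- match.arg(form)
  nCompounds <- as.integer(nCompounds)
  nInformative <- as.integer(nInformative)
  nNoise <- as.integer(nNoise)
  if (nCompounds < 3L) stop("nCompounds must be >= 3")
  if (nInformative < 1L) stop("nInformative must be >= 1")
  if (nNoise < 0L) stop("nNoise must be >= 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (scaleSpread < 1) stop("scaleSpread must be >= 1")
  nDesc <- nInformative + nNoise
  .withLocalSeed(as.integer(seed), {
    scales <- exp(seq(0, log(scaleSpread), length.out = nDesc))
    scales <- scales[sample.int(nDesc)]          # decouple scale from position
    u <- matrix(stats::runif(nCompounds * nDesc), nCompounds, nDesc)
    informative <- sort(sample.int(nDesc, nInformative))
    centers <- matrix(numeric(0), 0L, nInformative)
    coefs <- numeric(0)
    if (form == "linear") {
      coefs <- stats::runif(nInformative, coefRange[1], coefRange[2]) *
        sample(c(-1, 1), nInformative, replace = TRUE)
      noiseless <- as.numeric(u[, informative, drop = FALSE] %*% coefs)
    } else {
      centers <- matrix(stats::runif(nClusters * nInformative),
                        nClusters, nInformative)
      label <- sample.int(nClusters, nCompounds, replace = TRUE)
      u[, informative] <- centers[label, , drop = FALSE] +
        matrix(stats::rnorm(nCompounds * nInformative, sd = 0.05),
               nCompounds, nInformative)
      centerValue <- stats::runif(nClusters, 0, 10)
      noiseless <- centerValue[label]
    }
    sdNoiseless <- stats::sd(noiseless)
    realizedSd <- noiseSd * sdNoiseless
    act <- noiseless +
      if (realizedSd > 0) stats::rnorm(nCompounds, sd = realizedSd) else 0
    x <- sweep(u, 2L, scales, "*")
    dimnames(x) <- list(sprintf("cmpd_%03d", seq_len(nCompounds)),
                        sprintf("d%02d", seq_len(nDesc)))
    truth <- methods::new("SyntheticTruth",
                          informative = methods::new("DescriptorSubset",
                                                     indices = informative),
                          form = form, coefficients = coefs,
                          centers = centers, noiseSd = realizedSd,
                          noiseless = noiseless)
    list(dataset = QsarSet(x, activity = act, scaled = FALSE), truth = truth)
  })
}

#' Duplicated-row fixture: every compound has an exact twin
#'
#' Builds a dataset in which each of `nPairs` random compounds appears twice
#' with distinct ids but identical descriptors and activity. With k = 1 the
#' zero-distance twin is always the nearest neighbour, so leave-one-out
#' prediction is exact and q-squared is 1 for any descriptor subset — a
#' convenient analytic fixture.
#'
#' @param nPairs number of distinct compounds (>= 2); the dataset has
#'   2 * nPairs rows.
#' @param nDescriptors number of descriptor columns.
#' @param seed integer seed.
#' @return An unscaled [QsarSet-class].
#' @export
makeTwinFixture <- function(nPairs = 5L, nDescriptors = 4L, seed = 1L) {
  nPairs <- as.integer(nPairs)
  if (nPairs < 2L) stop("nPairs must be >= 2")
  .withLocalSeed(as.integer(seed), {
    base <- matrix(stats::runif(nPairs * nDescriptors), nPairs, nDescriptors)
    act <- stats::rnorm(nPairs)
    x <- base[rep(seq_len(nPairs), each = 2L), , drop = FALSE]
    dimnames(x) <- list(paste0("cmpd_", rep(seq_len(nPairs), each = 2L),
                               c("a", "b")),
                        sprintf("d%02d", seq_len(nDescriptors)))
    QsarSet(x, activity = rep(act, each = 2L), scaled = FALSE)
  })
}

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth (%s): %d informative descriptor(s), noise SD %.4g\n",
              object@form, length(object@informative@indices), object@noiseSd))
})
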