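#' Range-scale a descriptor matrix to [0, 1]
#'
#' Maps every descriptor column x to (x - min)/(max - min), so that columns
#' on wildly different scales (orders of magnitude apart, as is common for
#' topological descriptors) contribute comparably to Euclidean distances.
#' Constant columns (max == min) are mapped to all-zero and flagged in the
#' returned parameters; they contribute nothing to any distance. Activities
#' are untouched.
#'
#' @param ds an unscaled [QsarSet-class].
#' @return A list with elements `dataset` (the scaled [QsarSet-class], with
#'   `isScaled(dataset)` TRUE) and `params` (a [ScalingParams-class]
#'   recording the transform so it can be replayed on new compounds with
#'   [applyScaling()]).
#' @examples
#' qs <- QsarSet(matrix(c(2, 4, 6, 5, 5, 5), ncol = 2,
#'                      dimnames = list(NULL, c("a", "b"))),
#'               activity = c(1, 2, 3))
#' sc <- rangeScale(qs)
#' descriptorMatrix(sc$dataset)   # column a -> 0, 0.5, 1; column b -> 0
#' @export
rangeScale <- function(ds) {
  stopifnot(methods::is(ds, "QsarSet"))
  if (isScaled(ds))
    stop("dataset is already range-scaled; scaling twice indicates a pipeline ordering bug")
  x <- descriptorMatrix(ds)
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  constant <- maxs == mins
  if (any(constant))
    warning("constant descriptor column(s) mapped to zero: ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
  params <- methods::new("ScalingParams", names = colnames(x),
                         min = unname(mins), max = unname(maxs),
                         constant = unname(constant))
  scaled <- .replayScaling(x, params)
  out <- QsarSet(scaled, activity = activity(ds), scaled = TRUE)
  list(dataset = out, params = params)
}

.replayScaling <- function(x, params) {
  range <- params@max - params@min
  range[params@constant] <- 1    # constant columns: (x - min) is 0 anyway
  sweep(sweep(x, 2L, params@min, "-"), 2L, range, "/")
}

#' Replay a range-scaling transform on new compounds
#'
#' Applies the affine map recorded in `params` to a new dataset. New values
#' outside the training range map outside [0, 1]; this is deliberate and no
#' clipping is performed, so out-of-domain compounds remain visible as such.
#'
#' @param ds a [QsarSet-class] with the same descriptor names, in the same
#'   order, as the dataset that produced `params`.
#' @param params a [ScalingParams-class] from [rangeScale()].
#' @return The transformed [QsarSet-class], flagged as scaled.
#' @export
applyScaling <- function(ds, params) {
  stopifnot(methods::is(ds, "QsarSet"), methods::is(params, "ScalingParams"))
  if (!identical(descriptorNames(ds), params@names))
    stop("descriptor names/order do not match the scaling parameters")
  scaled <- .replayScaling(descriptorMatrix(ds), params)
  QsarSet(scaled, activity = activity(ds), scaled = TRUE)
}

#' Read and write scaling parameters as JSON
#'
#' The on-disk form is `{"names": [...], "min": [...], "max": [...],
#' "constant": [...]}`.
#'
#' @param params a [ScalingParams-class].
#' @param path file path.
#' @return `readScalingParams` returns a [ScalingParams-class];
#'   `writeScalingParams` returns `path` invisibly.
#' @export
writeScalingParams <- function(params, path) {
  jsonlite::write_json(list(names = params@names, min = params@min,
                            max = params@max, constant = params@constant),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeScalingParams
#' @export
readScalingParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("ScalingParams", names = as.character(x$names),
               min = as.numeric(x$min), max = as.numeric(x$max),
               constant = as.logical(x$constant))
}
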