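#' Construct a QsarSet
#'
#' @param descriptors numeric matrix, compounds in rows and descriptors in
#'   columns (the user-facing orientation; internally stored transposed,
#'   following the features-by-samples assay convention).
#' @param activity numeric vector, one continuous activity value per compound
#'   (arbitrary activity units).
#' @param compoundIds character vector of unique compound identifiers;
#'   defaults to the row names of `descriptors`.
#' @param descriptorNames character vector of unique descriptor names;
#'   defaults to the column names of `descriptors`.
#' @param scaled logical flag recording whether range scaling has already
#'   been applied.
#'
#' @return A validated [QsarSet-class].
#' @examples
#' x <- matrix(runif(30), nrow = 6,
#'             dimnames = list(paste0("c", 1:6), paste0("d", 1:5)))
#' qs <- QsarSet(x, activity = rnorm(6))
#' qs
#' @export
QsarSet <- function(descriptors, activity, compoundIds = rownames(descriptors),
                    descriptorNames = colnames(descriptors), scaled = FALSE) {
  descriptors <- as.matrix(descriptors)
  if (is.null(compoundIds))
    compoundIds <- paste0("compound_", seq_len(nrow(descriptors)))
  if (is.null(descriptorNames))
    descriptorNames <- paste0("d", seq_len(ncol(descriptors)))
  compoundIds <- as.character(compoundIds)
  descriptorNames <- as.character(descriptorNames)
  if (length(compoundIds) != nrow(descriptors))
    stop("compoundIds must have one entry per row of the descriptor matrix")
  if (length(descriptorNames) != ncol(descriptors))
    stop("descriptorNames must have one entry per descriptor column")
  assay <- t(descriptors)
  dimnames(assay) <- list(descriptorNames, compoundIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(descriptors = assay),
    colData = S4Vectors::DataFrame(activity = as.numeric(activity),
                                   row.names = compoundIds))
  S4Vectors::metadata(se)$scaled <- isTRUE(scaled)
  methods::new("QsarSet", se)
}

setValidity("QsarSet", function(object) {
  if (!"descriptors" %in% SummarizedExperiment::assayNames(object))
    return("a 'descriptors' assay is required")
  if (!"activity" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain an 'activity' column")
  n <- ncol(object)
  if (n < 3L)
    return("at least 3 compounds are required (LOO with k >= 1 needs 2 training compounds)")
  ids <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids))
    return(sprintf("compound ids must be present and unique (duplicated: %s)",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  dn <- rownames(object)
  if (is.null(dn) || anyDuplicated(dn))
    return("descriptor names must be present and unique")
  a <- SummarizedExperiment::colData(object)$activity
  if (length(a) != n || any(!is.finite(a)))
    return("activity must be finite with one value per compound")
  d <- SummarizedExperiment::assay(object, "descriptors")
  if (any(!is.finite(d)))
    return("descriptor matrix contains non-finite entries")
  if (!is.logical(S4Vectors::metadata(object)$scaled))
    return("metadata 'scaled' flag must be logical")
  TRUE
})

#' Accessors for QsarSet
#'
#' `descriptorMatrix` returns the compounds-by-descriptors matrix (the
#' transpose of the stored assay), `activity` the per-compound activity
#' vector, `compoundIds` and `descriptorNames` the identifiers,
#' `nCompounds`/`nDescriptors` the dimensions, and `isScaled` whether range
#' scaling has been applied.
#'
#' @param x a [QsarSet-class].
#' @return See description; `descriptorMatrix` carries compound ids as row
#'   names and descriptor names as column names.
#' @name QsarSet-accessors
#' @aliases descriptorMatrix activity compoundIds descriptorNames
#'   nCompounds nDescriptors isScaled
NULL

#' @rdname QsarSet-accessors
#' @export
descriptorMatrix <- function(x) {
  stopifnot(methods::is(x, "QsarSet"))
  t(SummarizedExperiment::assay(x, "descriptors"))
}

#' @rdname QsarSet-accessors
#' @export
activity <- function(x) {
  stopifnot(methods::is(x, "QsarSet"))
  stats::setNames(SummarizedExperiment::colData(x)$activity, colnames(x))
}

#' @rdname QsarSet-accessors
#' @export
compoundIds <- function(x) colnames(x)

#' @rdname QsarSet-accessors
#' @export
descriptorNames <- function(x) rownames(x)

#' @rdname QsarSet-accessors
#' @export
nCompounds <- function(x) ncol(x)

#' @rdname QsarSet-accessors
#' @export
nDescriptors <- function(x) nrow(x)

#' @rdname QsarSet-accessors
#' @export
isScaled <- function(x) isTRUE(S4Vectors::metadata(x)$scaled)

setMethod("show", "QsarSet", function(object) {
  cat(sprintf("QsarSet: %d compounds x %d descriptors (%s)\n",
              ncol(object), nrow(object),
              if (isScaled(object)) "range-scaled" else "unscaled"))
  a <- SummarizedExperiment::colData(object)$activity
  cat(sprintf("activity: range [%.4g, %.4g], sd %.4g\n",
              min(a), max(a), stats::sd(a)))
})

#' Construct a descriptor subset
#'
#' Indices are sorted and validated (1-based, duplicate-free). Names may be
#' used instead of indices when the dataset is supplied.
#'
#' @param indices integer vector of descriptor column indices, or a character
#'   vector of descriptor names when `ds` is given.
#' @param ds optional [QsarSet-class] used to resolve names and to check that
#'   indices are in range.
#' @return A [DescriptorSubset-class].
#' @examples
#' descriptorSubset(c(3, 1))          # sorted to 1, 3
#' @export
descriptorSubset <- function(indices, ds = NULL) {
  if (is.character(indices)) {
    if (is.null(ds)) stop("a dataset is required to resolve descriptor names")
    pos <- match(indices, descriptorNames(ds))
    if (anyNA(pos))
      stop("unknown descriptor name(s): ",
           paste(indices[is.na(pos)], collapse = ", "))
    indices <- pos
  }
  idx <- sort(unique(as.integer(indices)))
  if (length(idx) != length(indices))
    stop("duplicate descriptor indices in subset")
  if (!is.null(ds) && length(idx) && max(idx) > nDescriptors(ds))
    stop("subset index out of range: ", max(idx))
  methods::new("DescriptorSubset", indices = idx)
}

#' @rdname descriptorSubset
#' @param x a [DescriptorSubset-class].
#' @export
subsetIndices <- function(x) x@indices

#' @rdname descriptorSubset
#' @export
subsetSize <- function(x) length(x@indices)

#' Descriptor names of a subset
#' @param x a [DescriptorSubset-class].
#' @param ds the [QsarSet-class] providing the name table.
#' @export
subsetNames <- function(x, ds) descriptorNames(ds)[x@indices]

setMethod("show", "DescriptorSubset", function(object) {
  cat(sprintf("DescriptorSubset of size %d: %s\n", length(object@indices),
              paste(object@indices, collapse = ", ")))
})

setMethod("show", "ScalingParams", function(object) {
  cat(sprintf("ScalingParams for %d descriptors (%d constant)\n",
              length(object@names), sum(object@constant)))
})
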