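#' Read a QSAR descriptor table from CSV
#'
#' Expects a UTF-8 CSV with a header row, one identifier column, one activity
#' column, and all remaining columns numeric descriptors. Descriptor column
#' order in the file is the canonical index order used by
#' [DescriptorSubset-class] throughout.
#'
#' @param path path to a readable CSV file.
#' @param activityColumn,idColumn names of the activity and identifier
#'   columns (defaults `"activity"` and `"id"`).
#' @return A validated, unscaled [QsarSet-class].
#' @section Errors: missing file; missing named columns; a non-numeric
#'   descriptor cell (reported with its row and column); duplicate compound
#'   ids; fewer than 3 rows.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("a", "b", "c"), act = c(1, 2, 3),
#'                      d1 = c(0.1, 0.2, 0.3), d2 = c(5, 6, 7)),
#'           tf, row.names = FALSE)
#' qs <- readQsarCsv(tf, activityColumn = "act")
#' @export
readQsarCsv <- function(path, activityColumn = "activity", idColumn = "id") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c(idColumn, activityColumn))
    if (!col %in% names(df)) stop("column not found in ", path, ": ", col)
  ids <- df[[idColumn]]
  if (anyDuplicated(ids))
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (nrow(df) < 3L) stop("at least 3 compounds are required, got ", nrow(df))
  act <- suppressWarnings(as.numeric(df[[activityColumn]]))
  if (anyNA(act))
    stop("non-numeric activity value at row ", which(is.na(act))[1L])
  descCols <- setdiff(names(df), c(idColumn, activityColumn))
  if (length(descCols) < 1L) stop("no descriptor columns found")
  x <- matrix(NA_real_, nrow(df), length(descCols),
              dimnames = list(ids, descCols))
  for (j in seq_along(descCols)) {
    v <- suppressWarnings(as.numeric(df[[descCols[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric descriptor cell at row %d, column '%s': '%s'",
                   i, descCols[j], df[[descCols[j]]][i]))
    }
    x[, j] <- v
  }
  QsarSet(x, activity = act, compoundIds = ids, scaled = FALSE)
}

#' Write a QsarSet to CSV
#'
#' Numeric values are serialized with 17 significant digits, so a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param ds a [QsarSet-class].
#' @param path output file path.
#' @param activityColumn,idColumn column names to use in the output header.
#' @return `path`, invisibly.
#' @export
writeQsarCsv <- function(ds, path, activityColumn = "activity",
                         idColumn = "id") {
  x <- descriptorMatrix(ds)
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   stats::setNames(list(compoundIds(ds)), idColumn),
                   stats::setNames(list(.fmt(activity(ds))), activityColumn))
  for (j in seq_len(ncol(x))) df[[colnames(x)[j]]] <- .fmt(x[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Export a LooResult as a per-compound table
#'
#' @param x a [LooResult-class].
#' @param row.names,optional,... ignored (S3 contract).
#' @return data.frame with columns compound_id, actual, predicted, residual.
#' @export
as.data.frame.LooResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(compound_id = names(x@predictions),
             actual = unname(x@predictions + x@residuals),
             predicted = unname(x@predictions),
             residual = unname(x@residuals),
             stringsAsFactors = FALSE)
}

#' Save a fitted kNN model as a self-contained directory
#'
#' Writes `model.json` (subset names and indices, k, q-squared, an md5
#' content hash of the reference CSV), `reference.csv` (the scaled reference
#' dataset) and `scaling.json` (when scaling was applied), so the directory
#' can be shipped and reloaded with [readKnnModel()].
#'
#' @param model a [KnnModel-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveKnnModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refPath <- file.path(dir, "reference.csv")
  writeQsarCsv(model@reference, refPath)
  hasScaling <- !is.null(model@scaling)
  if (hasScaling)
    writeScalingParams(model@scaling, file.path(dir, "scaling.json"))
  meta <- list(
    subset = list(indices = model@subset@indices,
                  names = subsetNames(model@subset, model@reference)),
    k = model@k, q2 = model@q2, scaled = hasScaling,
    reference_md5 = unname(tools::md5sum(refPath)))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model directory written by [saveKnnModel()]
#'
#' @param dir model directory containing model.json and reference.csv.
#' @return A [KnnModel-class].
#' @export
readKnnModel <- function(dir) {
  metaPath <- file.path(dir, "model.json")
  if (!file.exists(metaPath)) stop("not a model directory: ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  refPath <- file.path(dir, "reference.csv")
  md5 <- unname(tools::md5sum(refPath))
  if (!identical(md5, meta$reference_md5))
    stop("reference.csv content hash mismatch; model directory is corrupt")
  reference <- readQsarCsv(refPath)
  S4Vectors::metadata(reference)$scaled <- isTRUE(meta$scaled)
  scaling <- if (isTRUE(meta$scaled))
    readScalingParams(file.path(dir, "scaling.json")) else NULL
  methods::new("KnnModel",
               subset = descriptorSubset(meta$subset$indices, reference),
               k = as.integer(meta$k), reference = reference,
               scaling = scaling, q2 = as.numeric(meta$q2))
}
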