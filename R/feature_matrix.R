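#' Construct a binary feature matrix
#'
#' A `feature_matrix` holds a strictly binary (0/1) table of molecular
#' features (rows) by samples (columns), the atomic data structure of the
#' package: a raw-ingredient reference library, a cohort of phenotyped
#' samples, and a complex query sample are all feature matrices (the latter
#' with a single column). Entries encode detection of a molecular feature
#' (a library-matched compound or clustered MS/MS spectrum) in a sample;
#' missing values are not permitted — absence must be encoded as 0.
#'
#' @param values numeric or integer matrix containing only 0 and 1.
#' @param feature_ids character vector of unique row identifiers; defaults
#'   to `rownames(values)`.
#' @param sample_ids character vector of unique column identifiers; defaults
#'   to `colnames(values)`.
#' @return An object of class `feature_matrix`: a list with elements
#'   `values` (integer matrix with dimnames), `feature_ids`, `sample_ids`.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' fm <- feature_matrix(m)
#' dim(fm)
#' @export
feature_matrix <- function(values, feature_ids = rownames(values),
                           sample_ids = colnames(values)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(feature_ids)) stop("feature_ids are required (no rownames found)")
  if (is.null(sample_ids)) stop("sample_ids are required (no colnames found)")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_ids))
  fm <- structure(list(values = values,
                       feature_ids = as.character(feature_ids),
                       sample_ids = as.character(sample_ids)),
                  class = "feature_matrix")
  validate_feature_matrix(fm)
  fm
}

#' Validate a feature matrix
#'
#' Checks the binary invariant (every entry exactly 0 or 1), dimension
#' agreement and uniqueness of identifiers. Called by the constructor and
#' by all readers; user code rarely needs it directly.
#'
#' @param fm a `feature_matrix`.
#' @return `fm`, invisibly, if valid; otherwise an error naming the first
#'   offending feature and sample.
#' @export
validate_feature_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  if (length(fm$feature_ids) != nrow(v))
    stop("feature_ids length does not match number of rows")
  if (length(fm$sample_ids) != ncol(v))
    stop("sample_ids length does not match number of columns")
  if (anyDuplicated(fm$feature_ids))
    stop("duplicate feature_ids: ",
         paste(unique(fm$feature_ids[duplicated(fm$feature_ids)]), collapse = ", "))
  if (anyDuplicated(fm$sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(fm$sample_ids[duplicated(fm$sample_ids)]), collapse = ", "))
  bad <- which(is.na(v) | (v != 0L & v != 1L))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(v))
    stop(sprintf(
      "non-binary value %s at feature '%s', sample '%s' (entries must be 0 or 1)",
      format(v[bad[1]]), fm$feature_ids[i[1]], fm$sample_ids[i[2]]))
  }
  invisible(fm)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples (%d nonzero)\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Extract feature identifiers
#' @param fm a `feature_matrix`.
#' @return Character vector of row (feature) identifiers.
#' @export
feature_ids <- function(fm) fm$feature_ids

#' Extract sample identifiers
#' @param fm a `feature_matrix`.
#' @return Character vector of column (sample) identifiers.
#' @export
sample_ids <- function(fm) fm$sample_ids

#' Read a binary feature table from disk
#'
#' Two dialects are supported. `"dense"` is a tab-separated table whose
#' first column holds feature IDs and whose header row holds sample IDs —
#' the layout of common metabolomics bucket-table exports. `"sparse"` is
#' MatrixMarket coordinate format listing the positions of the 1 entries,
#' with two sidecar files (`<path>.features`, `<path>.samples`, one ID per
#' line) carrying the axis identifiers; repository-scale binary tables are
#' sparse, so the coordinate form is far smaller.
#'
#' @param path file path; for the sparse dialect, the `.mtx` file (sidecars
#'   are located by appending `.features` / `.samples` to `path`).
#' @param dialect `"dense"` or `"sparse"`.
#' @return A validated [feature_matrix()]; any entry other than 0 or 1 is
#'   rejected with an error naming the feature and sample.
#' @export
read_feature_table <- function(path, dialect = c("dense", "sparse")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "dense") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L)
      stop("malformed header at line 1 of ", path,
           ": expected a feature-ID column followed by sample IDs")
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    fids <- tab[[1]]
    vals <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "numeric")
    if (anyNA(vals)) {
      i <- arrayInd(which(is.na(vals))[1], dim(vals))
      stop(sprintf("non-numeric value at feature '%s', sample '%s' in %s",
                   fids[i[1]], colnames(vals)[i[2]], path))
    }
    feature_matrix(vals, feature_ids = fids, sample_ids = colnames(vals))
  } else {
    fside <- paste0(path, ".features")
    sside <- paste0(path, ".samples")
    if (!file.exists(fside) || !file.exists(sside))
      stop("sparse dialect requires sidecar ID files ", fside, " and ", sside)
    m <- as.matrix(Matrix::readMM(path))
    fids <- readLines(fside)
    sids <- readLines(sside)
    if (length(fids) != nrow(m) || length(sids) != ncol(m))
      stop("sidecar ID counts do not match matrix dimensions in ", path)
    feature_matrix(m, feature_ids = fids, sample_ids = sids)
  }
}

#' Write a binary feature table to disk
#'
#' Inverse of [read_feature_table()]; `read(write(fm))` is bit-exact for
#' valid binary matrices in both dialects.
#'
#' @param fm a `feature_matrix`.
#' @param path output path (for `"sparse"`, the `.mtx` path; sidecars are
#'   written alongside).
#' @param dialect `"dense"` or `"sparse"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path, dialect = c("dense", "sparse")) {
  dialect <- match.arg(dialect)
  validate_feature_matrix(fm)
  if (dialect == "dense") {
    tab <- data.frame(feature_id = fm$feature_ids, fm$values,
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    Matrix::writeMM(Matrix::Matrix(fm$values, sparse = TRUE), path)
    writeLines(fm$feature_ids, paste0(path, ".features"))
    writeLines(fm$sample_ids, paste0(path, ".samples"))
  }
  invisible(path)
}

#' Align two feature matrices onto a common feature axis
#'
#' The decomposition objective requires the reference library `D` and the
#' query vector `c` to share one row space; more generally any model/query
#' pair must agree on feature order. This aligns both inputs onto the union
#' of their feature IDs, filling features absent from one input with 0
#' (absence), and preserves column order. Matching is exact string equality
#' on feature IDs — mass-tolerance matching belongs to upstream feature
#' extraction.
#'
#' @param reference,query `feature_matrix` objects.
#' @return A list with elements `reference` and `query`, both over the
#'   identical union feature axis (sorted), columns untouched.
#' @export
align_features <- function(reference, query) {
  validate_feature_matrix(reference)
  validate_feature_matrix(query)
  ids <- sort(union(reference$feature_ids, query$feature_ids))
  if (length(ids) == 0L) stop("empty feature union")
  expand <- function(fm) {
    v <- matrix(0L, length(ids), ncol(fm$values),
                dimnames = list(ids, fm$sample_ids))
    v[fm$feature_ids, ] <- fm$values
    feature_matrix(v, feature_ids = ids, sample_ids = fm$sample_ids)
  }
  list(reference = expand(reference), query = expand(query))
}

#' Read a phenotype/metadata table
#'
#' Expects a tab-separated file with at least the columns `sample_id`,
#' `label` (the phenotype class) and `dataset_id` (the source study the
#' sample came from, used for protocol/batch auditing). An optional
#' `standard_feature_ids` column may list, per sample, comma-separated
#' feature IDs of internal standards spiked in under that dataset's
#' protocol.
#'
#' @param path TSV file path.
#' @return A `data.frame` of class `phenotype_table` with character columns
#'   `sample_id`, `label`, `dataset_id` and, if present, a list column
#'   `standard_feature_ids`.
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE)
  phenotype_table(tab)
}

#' Construct a phenotype table from a data frame
#'
#' @param df data frame with columns `sample_id`, `label`, `dataset_id`
#'   (and optionally `standard_feature_ids`, comma-separated).
#' @return The validated `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("sample_id", "label", "dataset_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in phenotype table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("standard_feature_ids" %in% names(df) &&
      !is.list(df$standard_feature_ids))
    df$standard_feature_ids <- strsplit(as.character(df$standard_feature_ids),
                                        ",", fixed = TRUE)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write an analysis result to disk
#'
#' Serializes a [decomposition result][lambda_path_to_k] or a
#' [biomarker report][rank_biomarkers] as JSON (full structure,
#' round-trippable) or TSV (tabular view: one row per selected ingredient
#' with its abundance, or one row per ranked biomarker).
#'
#' @param result a `decomposition_result` or `biomarker_report`.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @seealso [read_result()]
#' @export
write_result <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  kind <- if (inherits(result, "decomposition_result")) "decomposition_result"
          else if (inherits(result, "biomarker_report")) "biomarker_report"
          else stop("unsupported result type: ", paste(class(result), collapse = "/"))
  if (format == "json") {
    payload <- unclass(result)
    if (kind == "decomposition_result")
      payload$x <- as.list(payload$x)   # keep ingredient names in JSON
    payload$.kind <- kind
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else if (kind == "decomposition_result") {
    tab <- data.frame(ingredient_id = result$selected,
                      abundance = unname(result$x[result$selected]))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON result written by [write_result()]
#'
#' @param path JSON file path.
#' @return The restored `decomposition_result` or `biomarker_report`;
#'   round-trips to an object equal to the one written.
#' @export
read_result <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- payload$.kind
  payload$.kind <- NULL
  if (is.null(kind)) stop("not a metsum result file: ", path)
  if (kind == "decomposition_result") {
    x <- unlist(payload$x)
    payload$x <- stats::setNames(as.numeric(x), names(x))
    payload$selected <- as.character(payload$selected)
    payload$path_log <- as.data.frame(payload$path_log)
    structure(payload, class = "decomposition_result")
  } else {
    payload$table <- as.data.frame(payload$table)
    structure(payload, class = "biomarker_report")
  }
}
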