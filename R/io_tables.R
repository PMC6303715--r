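# Plain-table I/O: sample metadata CSV, square distance-matrix CSV, and the
# TSV audit artifacts (QC ledger, calibration table, resolution table).

#' Read a sample metadata table
#'
#' CSV with columns `individual_id`, `location_code`, `dataset` and optional
#' `lat`, `lon` (decimal degrees WGS84; informational only, never used for
#' distance computation -- distances are supplied separately).
#'
#' @param path CSV file.
#' @return data frame, one row per individual.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("individual_id", "location_code", "dataset")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("metadata ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$individual_id))
    stop("metadata has duplicated individual_id")
  meta$lat <- if ("lat" %in% names(meta)) as.numeric(meta$lat) else NA_real_
  meta$lon <- if ("lon" %in% names(meta)) as.numeric(meta$lon) else NA_real_
  meta
}

build_sample_table <- function(meta) {
  key <- !duplicated(meta$location_code)
  tab <- table(meta$location_code)
  data.frame(location_code = meta$location_code[key],
             dataset = meta$dataset[key],
             n_individuals = as.integer(tab[meta$location_code[key]]),
             lat = meta$lat[key], lon = meta$lon[key],
             stringsAsFactors = FALSE)
}

write_sample_metadata <- function(panel, path) {
  s <- panel$samples
  i <- match(panel$individuals$location_code, s$location_code)
  meta <- data.frame(individual_id = panel$individuals$individual_id,
                     location_code = panel$individuals$location_code,
                     dataset = s$dataset[i], lat = s$lat[i], lon = s$lon[i],
                     stringsAsFactors = FALSE)
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a square distance matrix
#'
#' CSV with a header row and first column of location codes; entries in km.
#' Validates symmetry (within 1e-9), a zero diagonal, non-negativity and
#' label uniqueness.
#'
#' @param path CSV file.
#' @return numeric matrix with dimnames set to the location codes.
#' @export
read_distance_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  validate_distance_matrix(m)
  m
}

#' @rdname read_distance_matrix
#' @param m numeric matrix with matching row/column labels.
#' @export
write_distance_matrix <- function(m, path) {
  validate_distance_matrix(m)
  df <- data.frame(location_code = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_distance_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("distance matrix must carry location labels")
  if (!identical(rownames(m), colnames(m)))
    stop("distance matrix row/column labels differ")
  if (anyDuplicated(rownames(m))) stop("duplicated distance-matrix labels")
  if (any(m < 0)) stop("negative distances")
  if (any(abs(diag(m)) > 1e-9)) stop("distance matrix diagonal must be zero")
  if (any(abs(m - t(m)) > 1e-9)) stop("distance matrix not symmetric")
  invisible(m)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the QC ledger to TSV
#'
#' Two files: `<path>` holds the per-locus event log (rule id, outcome,
#' detail) and `<path>` gains a companion `*.status.tsv` with each locus's
#' final RETAINED/DISCARDED status.
#'
#' @param ledger a `qc_ledger` from [run_harmonization()].
#' @param path TSV path for the event log.
#' @return `path`, invisibly.
#' @export
write_qc_ledger <- function(ledger, path) {
  write_tsv(ledger$events, path)
  write_tsv(ledger$status, sub("(\\.tsv)?$", ".status.tsv", path))
  invisible(path)
}
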