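#' Write a CT slice as a plain-text array fixture
#'
#' The array-fixture dialect stores the HU matrix as a headerless CSV
#' (shortest round-trip decimal representation, so reloading is
#' bit-identical) next to a JSON sidecar holding pixel spacing, slice
#' location, and source id. It exists so the whole pipeline can be
#' exercised without DICOM files.
#'
#' @param ct A [ct_slice].
#' @param stem Path stem; `<stem>.json` and `<stem>.hu.csv` are written.
#' @return The sidecar path, invisibly.
#' @export
write_slice_fixture <- function(ct, stem) {
  stopifnot(inherits(ct, "ct_slice"))
  hu_file <- paste0(stem, ".hu.csv")
  ## %.17g guarantees the decimal text parses back to the identical double
  writeLines(apply(ct$hu, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), hu_file)
  sidecar <- paste0(stem, ".json")
  jsonlite::write_json(
    list(dialect = "array-fixture", hu_file = basename(hu_file),
         spacing_mm = ct$spacing_mm, slice_location = ct$slice_location,
         source_id = ct$source_id),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

.load_array_fixture <- function(path) {
  meta <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e)
                     adq_error(paste("unreadable fixture sidecar:", path),
                               "adipoquant_format_error"))
  for (f in c("hu_file", "spacing_mm"))
    if (is.null(meta[[f]]))
      adq_error(sprintf("fixture sidecar %s lacks '%s'", path, f),
                "adipoquant_metadata_error")
  hu_path <- file.path(dirname(path), meta$hu_file)
  if (!file.exists(hu_path))
    adq_error(paste("missing HU file:", hu_path), "adipoquant_format_error")
  hu <- as.matrix(data.table::fread(hu_path, header = FALSE))
  dimnames(hu) <- NULL
  ct_slice(hu, spacing_mm = meta$spacing_mm,
           slice_location = if (is.null(meta$slice_location)) 0
                            else meta$slice_location,
           source_id = if (is.null(meta$source_id)) basename(path)
                       else meta$source_id)
}

#' Load one CT slice
#'
#' @param path File path: a fixture JSON sidecar (array dialect) or a
#'   single-frame CT DICOM file.
#' @param dialect `"auto"` (by extension), `"array"`, or `"dicom"`.
#' @return A [ct_slice] in HU (`stored_value * RescaleSlope +
#'   RescaleIntercept` for DICOM; fixtures store HU directly).
#' @export
load_ct_slice <- function(path, dialect = c("auto", "array", "dicom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    adq_error(paste("file not found:", path), "adipoquant_format_error")
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "array"
               else "dicom"
  switch(dialect,
         array = .load_array_fixture(path),
         dicom = read_dicom_slice(path))
}

#' Load a directory of slices as a CT series
#'
#' Reads every fixture sidecar (`*.json`) or DICOM file (`*.dcm`) in
#' `dir`, sorts ascending by slice location (ties broken by file name),
#' and validates uniform pixel spacing.
#'
#' @param dir Directory path.
#' @return A [ct_series].
#' @export
load_ct_series <- function(dir) {
  if (!dir.exists(dir))
    adq_error(paste("not a directory:", dir), "adipoquant_format_error")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  ## keep only fixture sidecars; a slice directory may also hold truth or
  ## config JSON files
  if (length(files)) {
    is_fixture <- vapply(files, function(f) {
      meta <- tryCatch(jsonlite::read_json(f), error = function(e) NULL)
      !is.null(meta$hu_file)
    }, logical(1))
    files <- files[is_fixture]
  }
  dialect <- "array"
  if (length(files) == 0L) {
    files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                        ignore.case = TRUE)
    dialect <- "dicom"
  }
  if (length(files) == 0L)
    adq_error(paste("no slices found in", dir), "adipoquant_format_error")
  slices <- lapply(files, load_ct_slice, dialect = dialect)
  ord <- order(vapply(slices, function(s) s$slice_location, numeric(1)),
               basename(files))
  ct_series(slices[ord])
}

#' Write per-slice adipose measures to CSV
#'
#' Fixed column order: `source_id, slice_location, tat_cm2, vat_cm2,
#' sat_cm2, vsr, vtr, wc_cm`. Undefined ratios are written as empty
#' fields.
#'
#' @param measures Non-empty list of [measure_slice] results (or a data
#'   frame with those columns).
#' @param path Output path.
#' @return The data frame written, invisibly.
#' @export
write_measures <- function(measures, path) {
  df <- measures_to_df(measures)
  if (is.null(df) || nrow(df) == 0L)
    adq_error("no measures to write", "adipoquant_invalid_params")
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    adq_error(paste("cannot write", path), "adipoquant_format_error")
  invisible(df)
}

#' @rdname write_measures
#' @export
measures_to_df <- function(measures) {
  cols <- c("source_id", "slice_location", "tat_cm2", "vat_cm2", "sat_cm2",
            "vsr", "vtr", "wc_cm")
  if (is.data.frame(measures)) return(measures[, cols])
  if (inherits(measures, "adipose_measures")) measures <- list(measures)
  do.call(rbind, lapply(measures, function(m)
    data.frame(source_id = m$source_id, slice_location = m$slice_location,
               tat_cm2 = m$tat_cm2, vat_cm2 = m$vat_cm2, sat_cm2 = m$sat_cm2,
               vsr = m$vsr, vtr = m$vtr, wc_cm = m$wc_cm)))
}

#' Read per-slice measures written by [write_measures]
#'
#' @param path CSV path.
#' @return Data frame; empty ratio fields come back as `NA`.
#' @export
read_measures <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read EHR extract tables
#'
#' Long-format delimited extracts are pivoted to the wide per-subject
#' layouts the association module consumes.
#'
#' `read_visits`: CSV with columns `subject_id, icd9_code, n_visits` ->
#' integer matrix subjects x codes (absent pairs are 0 visits).
#' `read_labs`: CSV with `subject_id, lab_name, value` -> data frame with
#' one column per lab. `read_covariates`: CSV with `subject_id, age, sex`
#' and optional `t2d`.
#'
#' @param path CSV path.
#' @return See details.
#' @export
read_visits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character",
                                icd9_code = "character"))
  .require_cols(df, c("subject_id", "icd9_code", "n_visits"), path)
  subjects <- unique(df$subject_id)
  codes <- sort(unique(df$icd9_code))
  m <- matrix(0L, length(subjects), length(codes),
              dimnames = list(subjects, codes))
  m[cbind(match(df$subject_id, subjects), match(df$icd9_code, codes))] <-
    as.integer(df$n_visits)
  m
}

#' @rdname read_visits
#' @export
read_labs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character"))
  .require_cols(df, c("subject_id", "lab_name", "value"), path)
  ## reshape warns when a subject lacks some lab; NA is the intended value
  wide <- suppressWarnings(
    stats::reshape(df, idvar = "subject_id", timevar = "lab_name",
                   direction = "wide"))
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' @rdname read_visits
#' @export
read_covariates <- function(path) {
  ## sex must be read as character: read.csv would otherwise parse a column
  ## of "F" values as logical FALSE
  hdr <- names(read.csv(path, nrows = 1L))
  classes <- c(subject_id = "character")
  if ("sex" %in% hdr) classes["sex"] <- "character"
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = classes)
  .require_cols(df, c("subject_id", "age", "sex"), path)
  if (!all(df$sex %in% c("F", "M")))
    adq_error("sex must be 'F' or 'M'", "adipoquant_schema_error")
  if (any(df$age <= 0))
    adq_error("age must be positive", "adipoquant_schema_error")
  df
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    adq_error(sprintf("%s lacks column(s): %s", path,
                      paste(missing, collapse = ", ")),
              "adipoquant_schema_error")
  invisible(df)
}
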