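#' Read visual-field records from delimited text
#'
#' One row per test. Required columns: `patient_id`, `eye` (`L`/`R`),
#' `test_date` (ISO-8601), `age` (years), `se_diopters` (spherical
#' equivalent), `md_db` (mean deviation), `psd_abnormal` (0/1 flag for an
#' abnormal pattern standard deviation), `ght` (`WNL`/`OTHER`),
#' `fixation_loss_rate`, `fp_rate`, `fn_rate` (fractions in 0-1),
#' `nbsl_h`, `nbsl_v` (blind-spot centre, integer degrees, true field
#' coordinates), and the 52 `pd_<h>_<v>` pattern-deviation columns (dB)
#' in row-major order (`v` descending, `h` ascending) on the right-eye
#' location template (see [transpose_to_right_eye()]).
#'
#' @param path File to read.
#' @param sep Field separator, default comma.
#' @return A record data frame.
#' @seealso [write_records()], [generate_cohort()]
#' @export
read_records <- function(path, sep = ",") {
  if (!file.exists(path)) stop("record table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "eye", "test_date", "age", "se_diopters",
                "md_db", "psd_abnormal", "ght", "fixation_loss_rate",
                "fp_rate", "fn_rate", "nbsl_h", "nbsl_v", pd_column_names())
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("record table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad_eye <- which(!raw$eye %in% c("L", "R"))
  if (length(bad_eye)) {
    stop("unknown eye code ", dQuote(raw$eye[bad_eye[1]]),
         " at line ", bad_eye[1] + 1L, " of ", path)
  }
  numcols <- c("age", "se_diopters", "md_db", "fixation_loss_rate",
               "fp_rate", "fn_rate", "nbsl_h", "nbsl_v", pd_column_names())
  for (cn in numcols) {
    vals <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(vals) & !is.na(raw[[cn]]) & raw[[cn]] != "NA")
    if (length(bad)) {
      stop("non-numeric value ", dQuote(raw[[cn]][bad[1]]), " in column ",
           cn, " at line ", bad[1] + 1L, " of ", path)
    }
    raw[[cn]] <- vals
  }
  raw$psd_abnormal <- as.integer(raw$psd_abnormal) != 0L
  raw$test_date <- as.Date(raw$test_date)
  raw
}

#' Write visual-field records to delimited text
#'
#' The inverse of [read_records()]: writing then reading reproduces every
#' field (dates to the day, numeric fields to full printed precision).
#'
#' @param records Record data frame.
#' @param path File to write.
#' @param sep Field separator, default comma.
#' @export
write_records <- function(records, path, sep = ",") {
  out <- records
  out$psd_abnormal <- as.integer(out$psd_abnormal)
  out$test_date <- format(out$test_date, "%Y-%m-%d")
  keep <- c("patient_id", "eye", "test_date", "age", "se_diopters",
            "md_db", "psd_abnormal", "ght", "fixation_loss_rate",
            "fp_rate", "fn_rate", "nbsl_h", "nbsl_v", pd_column_names())
  utils::write.table(out[, keep], path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Pattern-deviation values as a matrix
#'
#' @param records Record data frame.
#' @return Numeric matrix, one row per record, one column per analysis
#'   location in the order of [pd_column_names()].
#' @export
pd_matrix <- function(records) {
  as.matrix(records[, pd_column_names(), drop = FALSE])
}
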