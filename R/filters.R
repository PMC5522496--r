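#' Cohort inclusion filters
#'
#' Applies the study inclusion pipeline to a record table, in this fixed
#' order:
#'
#' 1. **reliability** -- keep tests with fixation losses <= 33%, false
#'    negatives <= 20% and false positives <= 20% (inclusive);
#' 2. **recency** -- per patient and eye, keep only the most recent
#'    surviving test;
#' 3. **normality** -- keep clinically unaffected tests: mean deviation
#'    >= -1 dB (inclusive), pattern standard deviation not flagged
#'    abnormal, glaucoma hemifield test within normal limits;
#' 4. **default_nbsl** -- drop tests whose reported blind-spot centre is
#'    the instrument default (15, -1) after right-eye transposition,
#'    since a default is indistinguishable from a failed or skipped
#'    blind-spot test;
#' 5. **fellow_eye** -- if both eyes of a patient survive, retain one
#'    chosen by a seeded uniform draw.
#'
#' Records with missing or malformed index fields are rejected up front
#' with reason `"malformed"` -- never silently dropped. Left-eye records
#' are transposed to right-eye format first (lossless, idempotent).
#'
#' @param records Record data frame.
#' @param seed Integer seed for the fellow-eye draw.
#' @param max_fl,max_fp,max_fn Reliability thresholds as fractions.
#' @param min_md Mean-deviation floor in dB.
#' @return A list of class `vf_filter_result`: `records` (the retained
#'   rows, right-eye format) and `exclusions` (data frame with
#'   `patient_id`, `eye`, `test_date`, `rule`). The number of retained
#'   plus excluded rows equals the input row count.
#' @export
apply_inclusion_filters <- function(records, seed = 1L,
                                    max_fl = 0.33, max_fp = 0.20,
                                    max_fn = 0.20, min_md = -1) {
  stopifnot(is.data.frame(records))
  records <- transpose_to_right_eye(records)
  n <- nrow(records)
  rule <- rep(NA_character_, n)

  idx_fields <- c("fixation_loss_rate", "fp_rate", "fn_rate", "md_db",
                  "psd_abnormal", "nbsl_h", "nbsl_v")
  malformed <- !stats::complete.cases(records[, idx_fields]) |
    is.na(records$patient_id) | is.na(records$test_date) |
    !records$ght %in% c("WNL", "OTHER")
  rule[malformed] <- "malformed"

  ok <- which(is.na(rule))
  fail_rel <- ok[records$fixation_loss_rate[ok] > max_fl |
                 records$fp_rate[ok] > max_fp |
                 records$fn_rate[ok] > max_fn]
  rule[fail_rel] <- "reliability"

  # most recent surviving test per patient-eye (eye_original distinguishes
  # the two eyes after transposition); date ties keep the first row read
  ok <- which(is.na(rule))
  if (length(ok)) {
    key <- paste(records$patient_id[ok], records$eye_original[ok])
    keep <- unlist(lapply(split(ok, key), function(ix) {
      ix[which.max(records$test_date[ix])]
    }), use.names = FALSE)
    rule[setdiff(ok, keep)] <- "recency"
  }

  ok <- which(is.na(rule))
  fail_norm <- ok[records$md_db[ok] < min_md | records$psd_abnormal[ok] |
                  records$ght[ok] != "WNL"]
  rule[fail_norm] <- "normality"

  ok <- which(is.na(rule))
  fail_def <- ok[is_default_nbsl(records$nbsl_h[ok], records$nbsl_v[ok])]
  rule[fail_def] <- "default_nbsl"

  ok <- which(is.na(rule))
  if (length(ok)) {
    by_pat <- split(ok, records$patient_id[ok])
    two_eyed <- Filter(function(ix) length(ix) > 1L, by_pat)
    if (length(two_eyed)) {
      two_eyed <- two_eyed[order(names(two_eyed))]
      drop <- local_seed(seed, {
        unlist(lapply(two_eyed, function(ix) {
          ix[-sample.int(length(ix), 1L)]
        }), use.names = FALSE)
      })
      rule[drop] <- "fellow_eye"
    }
  }

  kept <- which(is.na(rule))
  excl <- which(!is.na(rule))
  structure(list(
    records = records[kept, , drop = FALSE],
    exclusions = data.frame(
      patient_id = records$patient_id[excl],
      eye = records$eye_original[excl],
      test_date = records$test_date[excl],
      rule = rule[excl],
      stringsAsFactors = FALSE
    )
  ), class = "vf_filter_result")
}

#' @export
print.vf_filter_result <- function(x, ...) {
  cat("inclusion filtering:", nrow(x$records), "records retained,",
      nrow(x$exclusions), "excluded\n")
  if (nrow(x$exclusions)) print(table(x$exclusions$rule))
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
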