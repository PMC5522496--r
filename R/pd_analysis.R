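#' Split a cohort at the median blind-spot distance or angle
#'
#' Records whose transformed blind-spot coordinate is greater than or
#' equal to the cohort median form the high group; the rest form the
#' low group. The angle is the signed polar angle ([nbsl_angle()]), so
#' "high" means toward the upper hemifield.
#'
#' @param records Record data frame in right-eye format (left eyes are
#'   transposed automatically).
#' @param variable `"distance"` or `"angle"`.
#' @return An object of class `split_result`: list with
#'   `split_variable`, `median_value`, `group_high`, `group_low` and a
#'   `degenerate` flag (TRUE when every record falls in the high
#'   group).
#' @export
median_split <- function(records, variable = c("distance", "angle")) {
  variable <- match.arg(variable)
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2) stop("need at least 2 records to split")
  records <- transpose_to_right_eye(records)
  x <- switch(variable,
              distance = nbsl_distance(records$nbsl_h, records$nbsl_v),
              angle = nbsl_angle(records$nbsl_h, records$nbsl_v))
  med <- stats::median(x)
  hi <- x >= med
  structure(list(split_variable = variable,
                 median_value = med,
                 group_high = records[hi, , drop = FALSE],
                 group_low = records[!hi, , drop = FALSE],
                 degenerate = !any(!hi)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("median split on %s (median %.2f deg): %d high / %d low\n",
              x$split_variable, x$median_value,
              nrow(x$group_high), nrow(x$group_low)))
  if (x$degenerate) cat("NOTE: degenerate split (low group empty)\n")
  invisible(x)
}

new_stat_map <- function(effect, p, fdr_level) {
  loc <- location_grid_24_2()$analysis_locations
  q <- stats::p.adjust(p, method = "BH")
  structure(data.frame(h_deg = loc$h_deg, v_deg = loc$v_deg,
                       effect_db = effect, p = p, q = q,
                       significant = q < fdr_level),
            class = c("location_stat_map", "data.frame"),
            fdr_level = fdr_level)
}

#' Pointwise difference map between median-split groups
#'
#' At each of the 52 analysis locations the mean pattern-deviation
#' difference (high group minus low group) is computed and tested with
#' a two-sample t-test; p-values are adjusted across the 52 locations
#' by the Benjamini-Hochberg false-discovery-rate procedure.
#'
#' @param split A [median_split()] result with both groups of size >= 2.
#' @param test `"welch"` (unequal variances, default) or `"student"`
#'   (pooled).
#' @param fdr_level Significance level applied to the adjusted
#'   p-values, default 0.05.
#' @return A `location_stat_map`: data frame with `h_deg`, `v_deg`,
#'   `effect_db`, `p`, `q`, `significant`.
#' @export
difference_map <- function(split, test = c("welch", "student"),
                           fdr_level = 0.05) {
  test <- match.arg(test)
  stopifnot(inherits(split, "split_result"))
  if (nrow(split$group_high) < 2 || nrow(split$group_low) < 2) {
    stop("both groups need at least 2 records")
  }
  hi <- pd_matrix(split$group_high)
  lo <- pd_matrix(split$group_low)
  res <- vapply(seq_len(ncol(hi)), function(j) {
    tt <- stats::t.test(hi[, j], lo[, j], var.equal = (test == "student"))
    c(unname(tt$estimate[1] - tt$estimate[2]), tt$p.value)
  }, numeric(2))
  new_stat_map(effect = res[1, ], p = res[2, ], fdr_level = fdr_level)
}

#' Average difference over significant points (ADSP)
#'
#' Mean effect over the locations of a stat map that are significant
#' after FDR correction and carry the requested sign. When no location
#' qualifies the result is `NA` (a missing summary, not an error).
#'
#' @param map A `location_stat_map`.
#' @param sign `"negative"` or `"positive"`.
#' @return Mean effect in dB, or `NA_real_`.
#' @export
adsp <- function(map, sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  stopifnot(inherits(map, "location_stat_map"))
  sel <- map$significant &
    (if (sign == "negative") map$effect_db < 0 else map$effect_db > 0)
  if (!any(sel)) return(NA_real_)
  mean(map$effect_db[sel])
}

#' Pointwise regression of pattern deviation on blind-spot geometry and
#' fixation loss
#'
#' At each analysis location fits ordinary least squares
#' `PD ~ 1 + predictor + fixation_loss_rate`, where the predictor is
#' the blind-spot distance or signed angle. Coefficient p-values for
#' the predictor and for fixation loss are FDR-adjusted separately,
#' each across the 52 locations, disentangling genuine blind-spot
#' effects from the fixation-loss confound.
#'
#' @param records Record data frame (>= 3 rows).
#' @param predictor `"distance"` or `"angle"`.
#' @param fdr_level Significance level on adjusted p-values.
#' @return List with two `location_stat_map`s: `predictor` (effects are
#'   dB per degree) and `fixation_loss` (dB per unit rate).
#' @export
regression_map <- function(records, predictor = c("distance", "angle"),
                           fdr_level = 0.05) {
  predictor <- match.arg(predictor)
  stopifnot(is.data.frame(records))
  if (nrow(records) < 3) stop("need at least 3 records")
  records <- transpose_to_right_eye(records)
  x <- switch(predictor,
              distance = nbsl_distance(records$nbsl_h, records$nbsl_v),
              angle = nbsl_angle(records$nbsl_h, records$nbsl_v))
  fl <- records$fixation_loss_rate
  X <- cbind(1, x, fl)
  if (qr(X)$rank < 3) {
    stop("collinear design: ", predictor,
         " and fixation_loss_rate do not span two dimensions")
  }
  pd <- pd_matrix(records)
  fit <- stats::lm.fit(X, pd)
  rss <- colSums(fit$residuals^2)
  dfres <- nrow(X) - 3
  XtXinv <- chol2inv(chol(crossprod(X)))
  out <- lapply(2:3, function(k) {
    beta <- fit$coefficients[k, ]
    se <- sqrt(XtXinv[k, k] * rss / dfres)
    p <- 2 * stats::pt(-abs(beta / se), dfres)
    new_stat_map(effect = beta, p = p, fdr_level = fdr_level)
  })
  names(out) <- c("predictor", "fixation_loss")
  out
}

#' Correlation of blind-spot distance with spherical equivalent
#'
#' Pearson correlation (with the usual t-based p-value) between each
#' record's blind-spot distance from fixation and its spherical
#' equivalent of refractive error.
#'
#' @param records Record data frame (>= 3 rows with SE present).
#' @return The `htest` from [stats::cor.test()].
#' @export
se_correlation <- function(records) {
  stopifnot(is.data.frame(records))
  records <- transpose_to_right_eye(records)
  ok <- !is.na(records$se_diopters)
  if (sum(ok) < 3) stop("need at least 3 records with spherical equivalent")
  d <- nbsl_distance(records$nbsl_h[ok], records$nbsl_v[ok])
  se <- records$se_diopters[ok]
  if (stats::sd(d) == 0 || stats::sd(se) == 0) {
    stop("zero variance in distance or spherical equivalent")
  }
  stats::cor.test(d, se, method = "pearson")
}

#' Per-cell average of a record field over blind-spot cells
#'
#' Mean of the chosen field (by default the spherical equivalent) over
#' all eyes whose blind-spot centre falls in each 1-degree cell. Cells
#' with no eyes are absent; records at the instrument default (15, -1)
#' contribute to no cell.
#'
#' @param records Record data frame.
#' @param field Column to average, default `"se_diopters"`.
#' @return Data frame with `h_deg`, `v_deg`, `mean_value`, `n`.
#' @export
cell_average_map <- function(records, field = "se_diopters") {
  stopifnot(is.data.frame(records), field %in% names(records))
  records <- transpose_to_right_eye(records)
  keep <- !is_default_nbsl(records$nbsl_h, records$nbsl_v)
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) {
    return(data.frame(h_deg = integer(), v_deg = integer(),
                      mean_value = numeric(), n = integer()))
  }
  agg <- stats::aggregate(records[[field]],
                          by = list(h_deg = records$nbsl_h,
                                    v_deg = records$nbsl_v),
                          FUN = function(z) c(mean(z), length(z)))
  out <- data.frame(h_deg = agg$h_deg, v_deg = agg$v_deg,
                    mean_value = agg$x[, 1], n = as.integer(agg$x[, 2]))
  out[order(-out$v_deg, out$h_deg), , drop = FALSE]
}
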