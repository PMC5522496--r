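#' Build the NBSL frequency table from records
#'
#' Tallies eyes per 1-degree blind-spot cell (right-eye format). Records
#' at the instrument default (15, -1) are counted in
#' `excluded_default_count` and never enter the table.
#'
#' @param records Record data frame in right-eye format.
#' @return An object of class `nbsl_freq_table`: list with `counts`
#'   (data frame `h_deg`, `v_deg`, `count`), `excluded_default_count`,
#'   `sparse_excluded` (initially empty) and `total`.
#' @seealso [exclude_sparse_cells()], [read_frequency_table()]
#' @export
nbsl_frequency_table <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(records$eye == "L")) records <- transpose_to_right_eye(records)
  def <- is_default_nbsl(records$nbsl_h, records$nbsl_v)
  counted <- records[!def, c("nbsl_h", "nbsl_v")]
  if (nrow(counted)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(counted))),
                            by = list(h_deg = counted$nbsl_h,
                                      v_deg = counted$nbsl_v),
                            FUN = sum)
  } else {
    agg <- data.frame(h_deg = integer(), v_deg = integer(),
                      count = integer())
  }
  new_freq_table(agg, excluded_default_count = sum(def))
}

new_freq_table <- function(counts, excluded_default_count = 0L,
                           sparse_excluded = NULL) {
  if (is.null(sparse_excluded)) {
    sparse_excluded <- counts[0, , drop = FALSE]
  }
  counts <- counts[order(-counts$v_deg, counts$h_deg), , drop = FALSE]
  rownames(counts) <- NULL
  stopifnot(all(counts$count >= 0),
            !any(is_default_nbsl(counts$h_deg, counts$v_deg)))
  structure(list(counts = counts,
                 excluded_default_count = excluded_default_count,
                 sparse_excluded = sparse_excluded,
                 total = sum(counts$count)),
            class = "nbsl_freq_table")
}

#' Read / write an NBSL frequency table
#'
#' Delimited text with columns `h_deg`, `v_deg`, `count` and `bracketed`
#' (1 marks cells reported with fewer than 5 eyes). The reference table
#' of 11,449 eyes ships with the package at
#' `extdata/table1_nbsl_counts.csv`.
#'
#' @param path File to read; defaults to the shipped reference table.
#' @return An `nbsl_freq_table` (all counted cells in `counts`; use
#'   [exclude_sparse_cells()] before surface fitting).
#' @export
read_frequency_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_nbsl_counts.csv",
                        package = "nbslvf", mustWork = TRUE)
  }
  x <- utils::read.csv(path)
  need <- c("h_deg", "v_deg", "count")
  if (!all(need %in% names(x))) {
    stop("frequency table must have columns h_deg, v_deg, count")
  }
  new_freq_table(x[, need], excluded_default_count = NA_integer_)
}

#' @rdname read_frequency_table
#' @param table An `nbsl_freq_table`.
#' @export
write_frequency_table <- function(table, path) {
  out <- rbind(table$counts, table$sparse_excluded)
  out <- out[order(-out$v_deg, out$h_deg), ]
  out$bracketed <- as.integer(out$count < 5)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.nbsl_freq_table <- function(x, ...) {
  cat("NBSL frequency table:", nrow(x$counts), "cells,",
      x$total, "eyes")
  if (nrow(x$sparse_excluded))
    cat(";", nrow(x$sparse_excluded), "sparse cells excluded")
  if (!is.na(x$excluded_default_count) && x$excluded_default_count > 0)
    cat(";", x$excluded_default_count, "defaults excluded")
  cat("\n")
  invisible(x)
}

#' Exclude sparse cells from a frequency table
#'
#' Cells observed in fewer than `min_count` eyes tend to sit at large
#' eccentricities and are likely artifacts; they are moved to the
#' table's `sparse_excluded` component (and so are excluded from surface
#' fitting) but remain available for marginal statistics.
#'
#' @param table An `nbsl_freq_table`.
#' @param min_count Strict lower bound; cells with `count < min_count`
#'   are removed (a cell with exactly `min_count` is retained).
#' @return The filtered `nbsl_freq_table`.
#' @export
exclude_sparse_cells <- function(table, min_count = 5L) {
  stopifnot(inherits(table, "nbsl_freq_table"))
  sparse <- table$counts$count < min_count
  new_freq_table(table$counts[!sparse, , drop = FALSE],
                 excluded_default_count = table$excluded_default_count,
                 sparse_excluded = rbind(table$sparse_excluded,
                                         table$counts[sparse, , drop = FALSE]))
}

#' Count-weighted marginal statistics of the NBSL distribution
#'
#' Mean and population standard deviation of the horizontal or vertical
#' blind-spot coordinate, weighting each cell by its eye count. By
#' default all counted cells enter, including any moved to
#' `sparse_excluded` (the sparse-cell rule affects only surface
#' fitting); set `include_sparse = FALSE` for the alternative set.
#'
#' @param table An `nbsl_freq_table`.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param include_sparse Include sparse-excluded cells (default TRUE).
#' @return An object of class `summary_stat`: list with `mean`, `sd`
#'   (degrees) and `n` (eyes).
#' @export
marginal_stats <- function(table, axis = c("horizontal", "vertical"),
                           include_sparse = TRUE) {
  axis <- match.arg(axis)
  cells <- freq_cells(table, include_sparse)
  if (sum(cells$count) < 1) stop("empty frequency table")
  x <- if (axis == "horizontal") cells$h_deg else cells$v_deg
  w <- cells$count
  m <- sum(w * x) / sum(w)
  summary_stat(mean = m,
               sd = sqrt(sum(w * (x - m)^2) / sum(w)),
               n = sum(w))
}

freq_cells <- function(table, include_sparse = TRUE) {
  stopifnot(inherits(table, "nbsl_freq_table"))
  if (include_sparse) rbind(table$counts, table$sparse_excluded)
  else table$counts
}

#' Count-weighted median of a transformed NBSL coordinate
#'
#' Median of the blind-spot distance from fixation, or of the signed
#' polar angle, over the per-eye distribution implied by the table
#' (each cell repeated `count` times). For even effective counts the
#' lower-median convention is used: the smallest value whose cumulative
#' weight reaches half the total.
#'
#' @param table An `nbsl_freq_table`.
#' @param transform `"distance"` or `"angle"`.
#' @param include_sparse Include sparse-excluded cells (default TRUE).
#' @return Median in degrees.
#' @export
weighted_median <- function(table, transform = c("distance", "angle"),
                            include_sparse = TRUE) {
  transform <- match.arg(transform)
  cells <- freq_cells(table, include_sparse)
  if (sum(cells$count) < 1) stop("empty frequency table")
  x <- if (transform == "distance") {
    nbsl_distance(cells$h_deg, cells$v_deg)
  } else {
    nbsl_angle(cells$h_deg, cells$v_deg)
  }
  o <- order(x)
  x <- x[o]
  cw <- cumsum(cells$count[o])
  x[which(cw >= sum(cells$count) / 2)[1]]
}

#' Summary statistic triple
#'
#' @param mean,sd,n Mean (degrees), standard deviation (degrees, >= 0)
#'   and number of eyes (>= 1).
#' @return An object of class `summary_stat`.
#' @export
summary_stat <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 1)
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.2f +/- %.2f (n = %d)\n", x$mean, x$sd, as.integer(x$n)))
  invisible(x)
}

#' Welch's t-test from summary statistics
#'
#' Two-sample unequal-variance t-test computed from means, standard
#' deviations and sample sizes only -- the form needed to compare a
#' cohort's marginal NBSL statistics against published reference values
#' for which raw data are unavailable.
#'
#' @param a,b `summary_stat` objects (each with n >= 2).
#' @return An object of class `htest` with the t statistic,
#'   Welch-Satterthwaite degrees of freedom and two-sided p-value.
#' @examples
#' compare_summary_stats(summary_stat(14.35, 1.36, 11449),
#'                       summary_stat(15.50, 1.10, 104))
#' @export
compare_summary_stats <- function(a, b) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"),
            a$n >= 2, b$n >= 2)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    tstat <- if (a$mean == b$mean) 0 else Inf * sign(a$mean - b$mean)
    df <- a$n + b$n - 2
  } else {
    tstat <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df)
  structure(list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = p,
                 estimate = c(`mean difference` = a$mean - b$mean),
                 method = "Welch two-sample t-test from summary statistics",
                 data.name = "a vs b"),
            class = "htest")
}

#' Published reference values for blind-spot location
#'
#' Mean, standard deviation and sample size of the blind-spot (or optic
#' disc) centre reported by two earlier studies on healthy eyes, used as
#' comparison points for cohort marginals: a perimetric blind-spot
#' mapping study of 30 eyes and a fundus-photographic optic-disc
#' localisation study of 104 eyes.
#'
#' @return Data frame with columns `study`, `axis`, `mean`, `sd`, `n`.
#' @export
reference_nbsl_stats <- function() {
  data.frame(
    study = c("safran", "safran", "rohrschneider", "rohrschneider"),
    axis = c("horizontal", "vertical", "horizontal", "vertical"),
    mean = c(15.48, -2.03, 15.50, -1.50),
    sd = c(0.95, 0.91, 1.10, 0.90),
    n = c(30, 30, 104, 104),
    stringsAsFactors = FALSE
  )
}
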