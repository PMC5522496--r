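#' Configuration for an end-to-end analysis run
#'
#' Validates and collects every tunable of [run_pipeline()]. All
#' defaults equal the study thresholds, so a bare configuration
#' reproduces the reference pipeline on the shipped frequency table and
#' a default synthetic cohort.
#'
#' @param out_dir Output directory (created if needed).
#' @param counts_path Frequency-table file; `NULL` uses the shipped
#'   reference table.
#' @param records_path Record-table file; `NULL` simulates a cohort of
#'   `n_patients` with [default_cohort_spec()].
#' @param n_patients Cohort size when simulating.
#' @param seed Seed used for simulation and the fellow-eye draw.
#' @param sigma_f,gamma,jitter GP hyperparameters (see
#'   [gp_hyperparams()]).
#' @param optimize If TRUE, select hyperparameters by
#'   [optimize_hyperparams()] instead of using `sigma_f`/`gamma`.
#' @param resolution Surface grid resolution in degrees.
#' @param min_cell_count Sparse-cell exclusion threshold.
#' @param max_fl,max_fp,max_fn,min_md Inclusion-filter thresholds.
#' @param fdr_level False-discovery-rate level for the pointwise maps.
#' @param test t-test variant for difference maps.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       counts_path = NULL,
                       records_path = NULL,
                       n_patients = 2000,
                       seed = 1L,
                       sigma_f = 1.2, gamma = c(0.9, 0.8), jitter = 1e-8,
                       optimize = FALSE,
                       resolution = 0.1,
                       min_cell_count = 5L,
                       max_fl = 0.33, max_fp = 0.20, max_fn = 0.20,
                       min_md = -1,
                       fdr_level = 0.05,
                       test = c("welch", "student")) {
  test <- match.arg(test)
  rates <- c(max_fl = max_fl, max_fp = max_fp, max_fn = max_fn)
  if (any(rates < 0 | rates > 1)) {
    stop("reliability thresholds must lie in [0, 1]")
  }
  if (fdr_level <= 0 || fdr_level >= 1) {
    stop("fdr_level must lie in (0, 1)")
  }
  if (resolution <= 0) stop("resolution must be positive")
  hp <- gp_hyperparams(sigma_f, gamma, jitter)  # validates
  structure(list(out_dir = out_dir, counts_path = counts_path,
                 records_path = records_path, n_patients = n_patients,
                 seed = as.integer(seed), hyperparams = hp,
                 optimize = optimize, resolution = resolution,
                 min_cell_count = min_cell_count,
                 max_fl = max_fl, max_fp = max_fp, max_fn = max_fn,
                 min_md = min_md, fdr_level = fdr_level, test = test),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> transpose -> inclusion filters ->
#' frequency table -> GP surface -> summary statistics -> pointwise
#' difference and regression maps, and writes every artifact to the
#' configured output directory: `cohort.csv` (when simulated),
#' `surface.csv`, `map_<variable>.csv`, `regression_<variable>.csv`,
#' `summary.json` and `run_log.txt`. Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with the in-memory results: the filter
#'   result, frequency table, GP fit and surface, stat maps, and the
#'   summary list written to JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  records <- stage("records", {
    if (is.null(config$records_path)) {
      note("simulating cohort: n = ", config$n_patients,
           ", seed = ", config$seed)
      rec <- generate_cohort(default_cohort_spec(config$n_patients,
                                                 seed = config$seed))
      write_records(rec, file.path(config$out_dir, "cohort.csv"))
      rec
    } else {
      note("reading records from ", config$records_path)
      read_records(config$records_path)
    }
  })

  filt <- stage("filters", {
    apply_inclusion_filters(records, seed = config$seed,
                            max_fl = config$max_fl, max_fp = config$max_fp,
                            max_fn = config$max_fn, min_md = config$min_md)
  })
  note("filters: ", nrow(filt$records), " retained / ",
       nrow(filt$exclusions), " excluded")
  if (nrow(filt$exclusions)) {
    tab <- table(filt$exclusions$rule)
    note("  exclusions by rule: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }

  freq <- stage("frequency_table", {
    if (is.null(config$counts_path)) {
      note("using shipped reference frequency table")
      read_frequency_table()
    } else {
      read_frequency_table(config$counts_path)
    }
  })
  freq_fit <- exclude_sparse_cells(freq, config$min_cell_count)
  note("frequency table: ", nrow(freq_fit$counts), " cells for fitting, ",
       nrow(freq_fit$sparse_excluded), " sparse excluded")

  hp <- stage("hyperparameters", {
    if (config$optimize) {
      h <- optimize_hyperparams(freq_fit, jitter = config$hyperparams$jitter)
      note(sprintf("optimized hyperparameters: sigma_f = %g, gamma = (%g, %g)",
                   h$sigma_f, h$gamma[1], h$gamma[2]))
      h
    } else config$hyperparams
  })
  fit <- stage("gp_fit", gp_fit(freq_fit, hp))
  surf <- stage("gp_surface", gp_surface(fit, config$resolution))
  utils::write.csv(surf$grid, file.path(config$out_dir, "surface.csv"),
                   row.names = FALSE)
  note(sprintf("surface maximum %.1f eyes at (%.1f, %.1f)",
               surf$argmax$value, surf$argmax$h_deg, surf$argmax$v_deg))

  mh <- marginal_stats(freq, "horizontal")
  mv <- marginal_stats(freq, "vertical")
  med_d <- weighted_median(freq, "distance")
  med_a <- weighted_median(freq, "angle")
  obs <- freq_cells(freq)
  obs_max <- obs[which.max(obs$count), ]

  maps <- list()
  regs <- list()
  adsp_summary <- list()
  cor_summary <- NULL
  if (nrow(filt$records) >= 4) {
    for (variable in c("distance", "angle")) {
      sp <- stage(paste0("median_split_", variable),
                  median_split(filt$records, variable))
      mp <- stage(paste0("difference_map_", variable),
                  difference_map(sp, test = config$test,
                                 fdr_level = config$fdr_level))
      maps[[variable]] <- mp
      utils::write.csv(mp, file.path(config$out_dir,
                                     paste0("map_", variable, ".csv")),
                       row.names = FALSE)
      rg <- stage(paste0("regression_map_", variable),
                  regression_map(filt$records, variable,
                                 fdr_level = config$fdr_level))
      regs[[variable]] <- rg
      utils::write.csv(cbind(rg$predictor,
                             fl_effect = rg$fixation_loss$effect_db,
                             fl_q = rg$fixation_loss$q),
                       file.path(config$out_dir,
                                 paste0("regression_", variable, ".csv")),
                       row.names = FALSE)
      adsp_summary[[variable]] <- list(
        median = sp$median_value,
        adsp_negative = adsp(mp, "negative"),
        adsp_positive = adsp(mp, "positive"),
        n_significant = sum(mp$significant),
        max_abs_difference = max(abs(mp$effect_db)))
    }
    ct <- stage("se_correlation", se_correlation(filt$records))
    cor_summary <- list(r = unname(ct$estimate), p = ct$p.value)
  } else {
    note("too few records after filtering; skipping pointwise analyses")
  }

  summary <- list(
    n_input_records = nrow(records),
    n_retained = nrow(filt$records),
    exclusions = as.list(table(filt$exclusions$rule)),
    frequency_total = freq$total,
    observed_max = list(count = obs_max$count, h_deg = obs_max$h_deg,
                        v_deg = obs_max$v_deg),
    marginal_horizontal = list(mean = mh$mean, sd = mh$sd),
    marginal_vertical = list(mean = mv$mean, sd = mv$sd),
    median_distance = med_d,
    median_angle = med_a,
    gp = list(sigma_f = hp$sigma_f, gamma = hp$gamma,
              prediction_at_default = predict(fit, c(15, -1)),
              surface_max = surf$argmax$value,
              surface_argmax = c(surf$argmax$h_deg, surf$argmax$v_deg)),
    se_correlation = cor_summary,
    splits = adsp_summary,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(filter = filt, frequency = freq, fit = fit,
                 surface = surf, maps = maps, regressions = regs,
                 summary = summary))
}

#' Plot a GP frequency surface as a heat map
#'
#' @param x A `gp_surface`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.gp_surface <- function(x, ...) {
  hs <- sort(unique(x$grid$h_deg))
  vs <- sort(unique(x$grid$v_deg))
  z <- matrix(NA_real_, length(hs), length(vs))
  z[cbind(match(x$grid$h_deg, hs), match(x$grid$v_deg, vs))] <- x$grid$value
  graphics::image(hs, vs, z, xlab = "horizontal (deg, temporal +)",
                  ylab = "vertical (deg, superior +)",
                  main = "Estimated NBSL frequency", ...)
  graphics::points(x$argmax$h_deg, x$argmax$v_deg, pch = 3)
  invisible(x)
}

#' Plot a pointwise stat map
#'
#' Signed effects on the 24-2 layout; significant locations are drawn
#' as filled symbols.
#'
#' @param x A `location_stat_map`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.location_stat_map <- function(x, ...) {
  pal <- ifelse(x$effect_db < 0, "red", "blue")
  cex <- 0.5 + 4 * abs(x$effect_db) / max(abs(x$effect_db), 1e-12)
  graphics::plot(x$h_deg, x$v_deg, pch = ifelse(x$significant, 19, 1),
                 col = pal, cex = pmin(cex, 3),
                 xlab = "horizontal (deg)", ylab = "vertical (deg)", ...)
  invisible(x)
}
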