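# brute-force Benjamini-Hochberg step-up, written directly from the
# procedure's definition as an oracle for the packaged adjustment
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

test_that("median splits assign ties to the high group", {
  rec <- make_records(3, nbsl_h = list(13, 14, 15), nbsl_v = list(0, 0, 0))
  sp <- median_split(rec, "distance")
  expect_equal(sp$median_value, 14)
  expect_setequal(nbsl_distance(sp$group_high$nbsl_h, sp$group_high$nbsl_v),
                  c(14, 15))
  expect_equal(nbsl_distance(sp$group_low$nbsl_h, sp$group_low$nbsl_v), 13)
  expect_false(sp$degenerate)
  expect_error(median_split(rec[1, ], "distance"), "at least 2")
})

test_that("an all-identical cohort gives a degenerate split", {
  rec <- make_records(4, nbsl_h = 14, nbsl_v = -2)
  sp <- median_split(rec, "angle")
  expect_true(sp$degenerate)
  expect_equal(nrow(sp$group_low), 0)
  expect_equal(nrow(sp$group_high), 4)
})

test_that("difference maps equal brute-force group means", {
  rec <- generate_cohort(cohort_spec(300, seed = 51))
  rec <- transpose_to_right_eye(rec)
  sp <- median_split(rec, "distance")
  mp <- difference_map(sp)
  cols <- pd_column_names()
  brute <- colMeans(sp$group_high[, cols]) - colMeans(sp$group_low[, cols])
  expect_equal(mp$effect_db, unname(brute))
  expect_equal(nrow(mp), 52)
  expect_true(all(mp$q >= mp$p))
  expect_identical(mp$significant, mp$q < 0.05)
  # per-location p-values agree with a direct t.test call
  j <- 7
  ref <- t.test(sp$group_high[[cols[j]]], sp$group_low[[cols[j]]])
  expect_equal(mp$p[j], ref$p.value)
})

test_that("identical groups give zero effects and no significance", {
  rec <- generate_cohort(cohort_spec(60, seed = 52))
  sp <- structure(list(split_variable = "distance", median_value = 0,
                       group_high = rec, group_low = rec,
                       degenerate = FALSE), class = "split_result")
  mp <- difference_map(sp)
  expect_equal(mp$effect_db, rep(0, 52))
  expect_false(any(mp$significant))
})

test_that("swapping group labels negates effects and keeps p and q", {
  rec <- transpose_to_right_eye(generate_cohort(cohort_spec(400, seed = 53)))
  sp <- median_split(rec, "angle")
  swapped <- sp
  swapped$group_high <- sp$group_low
  swapped$group_low <- sp$group_high
  m1 <- difference_map(sp)
  m2 <- difference_map(swapped)
  expect_equal(m2$effect_db, -m1$effect_db)
  expect_equal(m2$p, m1$p)
  expect_equal(m2$q, m1$q)
})

test_that("the packaged FDR adjustment matches the brute-force step-up", {
  set.seed(54)
  for (i in 1:25) {
    p <- runif(52)^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), bh_bruteforce(p))
  }
})

test_that("ADSP averages significant effects by sign", {
  map <- structure(
    data.frame(h_deg = 1:4, v_deg = 1:4,
               effect_db = c(-0.20, -0.16, 0.30, -0.5),
               p = c(0.001, 0.001, 0.001, 0.9),
               q = c(0.01, 0.01, 0.01, 0.9),
               significant = c(TRUE, TRUE, TRUE, FALSE)),
    class = c("location_stat_map", "data.frame"))
  expect_equal(adsp(map, "negative"), -0.18)
  expect_equal(adsp(map, "positive"), 0.30)
  map$significant <- FALSE
  expect_true(is.na(adsp(map, "negative")))
})

test_that("noise-free linear fields are recovered exactly by regression", {
  rec <- transpose_to_right_eye(generate_cohort(cohort_spec(200, seed = 55)))
  d <- nbsl_distance(rec$nbsl_h, rec$nbsl_v)
  fl <- rec$fixation_loss_rate
  cols <- pd_column_names()
  rec[cols] <- matrix(rep(2 - 0.1 * d - 3 * fl, length(cols)),
                      ncol = length(cols))
  rg <- regression_map(rec, "distance")
  expect_equal(rg$predictor$effect_db, rep(-0.1, 52), tolerance = 1e-10)
  expect_equal(rg$fixation_loss$effect_db, rep(-3, 52), tolerance = 1e-10)
})

test_that("regression p-values match lm() at a single location", {
  rec <- transpose_to_right_eye(generate_cohort(cohort_spec(250, seed = 56)))
  rg <- regression_map(rec, "angle")
  d <- nbsl_angle(rec$nbsl_h, rec$nbsl_v)
  col <- pd_column_names()[13]
  ref <- summary(lm(rec[[col]] ~ d + rec$fixation_loss_rate))$coefficients
  expect_equal(rg$predictor$effect_db[13], ref["d", "Estimate"])
  expect_equal(rg$predictor$p[13], ref["d", "Pr(>|t|)"])
  expect_equal(rg$fixation_loss$p[13],
               ref["rec$fixation_loss_rate", "Pr(>|t|)"])
})

test_that("a collinear design is rejected by name", {
  rec <- transpose_to_right_eye(generate_cohort(cohort_spec(50, seed = 57)))
  rec$fixation_loss_rate <- 0.01 *
    nbsl_distance(rec$nbsl_h, rec$nbsl_v)
  expect_error(regression_map(rec, "distance"), "collinear")
})

test_that("distance-refraction correlation behaves at the extremes", {
  rec <- transpose_to_right_eye(generate_cohort(cohort_spec(100, seed = 58)))
  rec$se_diopters <- -nbsl_distance(rec$nbsl_h, rec$nbsl_v)
  ct <- se_correlation(rec)
  expect_equal(unname(ct$estimate), -1)
  rec$se_diopters <- 1.5
  expect_error(se_correlation(rec), "variance")
})

test_that("cell averages exclude the default cell and conserve the mean", {
  rec <- make_records(3, nbsl_h = list(14, 14, 15), nbsl_v = list(-2, -2, -1),
                      se_diopters = list(-2, -4, 1))
  cam <- cell_average_map(rec)
  expect_equal(nrow(cam), 1)
  expect_equal(cam$mean_value, -3)
  expect_equal(cam$n, 2L)
  # count-weighted mean over cells equals the cohort mean (non-default)
  big <- transpose_to_right_eye(generate_cohort(cohort_spec(500, seed = 59)))
  cam2 <- cell_average_map(big)
  expect_equal(sum(cam2$mean_value * cam2$n) / sum(cam2$n),
               mean(big$se_diopters))
  one <- cell_average_map(make_record(se_diopters = 2.5))
  expect_equal(one$mean_value, 2.5)
})
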