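# independent draw of the blind-spot model used as a Monte Carlo oracle:
# same distributional definition as the generator but written directly
# from the spec parameters (skew-normal via the delta representation,
# two-component mixture, integer rounding, grid clipping, conditioning
# on avoiding the default cell)
oracle_nbsl_draw <- function(spec, n) {
  sn <- spec$nbsl_horizontal
  delta <- sn$skew / sqrt(1 + sn$skew^2)
  h <- sn$location + sn$scale *
    (delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n))
  h <- pmin(pmax(round(h), 7), 21)
  mx <- spec$nbsl_vertical
  comp <- runif(n) < mx$weight
  v <- ifelse(comp, rnorm(n, mx$means[1], mx$sds[1]),
              rnorm(n, mx$means[2], mx$sds[2]))
  v <- pmin(pmax(round(v), -6), 3)
  keep <- !(h == 15 & v == -1)
  data.frame(h = h[keep], v = v[keep])
}

test_that("the generator is deterministic given the seed", {
  s <- cohort_spec(50, seed = 11)
  expect_identical(generate_cohort(s), generate_cohort(s))
  expect_false(identical(generate_cohort(s),
                         generate_cohort(cohort_spec(50, seed = 12))))
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(0), "positive")
  expect_error(cohort_spec(10, pd_noise_sd = -1))
  expect_error(cohort_spec(10, unreliable_fraction = 1))
  expect_error(cohort_spec(10, nbsl_vertical = list(means = c(-1, -3),
                                                    sds = c(1, 1),
                                                    weight = 1.2)))
})

test_that("generated marginals match the calibrated model", {
  spec <- default_cohort_spec(11449, seed = 3)
  rec <- transpose_to_right_eye(generate_cohort(spec))
  set.seed(301)
  oracle <- oracle_nbsl_draw(spec, 4e5)
  n <- nrow(rec)
  for (pair in list(list(rec$nbsl_h, oracle$h), list(rec$nbsl_v, oracle$v))) {
    got <- mean(pair[[1]])
    want <- mean(pair[[2]])
    se <- sd(pair[[2]]) * sqrt(1 / n + 1 / nrow(oracle))
    expect_lt(abs(got - want), 3 * se)
    expect_equal(sd(pair[[1]]), sd(pair[[2]]), tolerance = 0.03)
  }
  # calibration targets of the reference cohort
  expect_equal(mean(rec$nbsl_h), 14.35, tolerance = 0.005)
  expect_equal(sd(rec$nbsl_h), 1.36, tolerance = 0.02)
  expect_equal(mean(rec$nbsl_v), -2.06, tolerance = 0.01)
  expect_equal(sd(rec$nbsl_v), 1.28, tolerance = 0.02)
})

test_that("the vertical histogram is bimodal after 1-degree binning", {
  rec <- generate_cohort(default_cohort_spec(1e5, seed = 4))
  counts <- table(factor(rec$nbsl_v, levels = -6:3))
  x <- as.vector(counts)
  interior_max <- which(diff(sign(diff(x))) == -2) + 1L
  expect_gte(length(interior_max), 2L)
})

test_that("the generator never emits the default cell unless asked", {
  rec <- transpose_to_right_eye(generate_cohort(default_cohort_spec(5000,
                                                                    seed = 5)))
  expect_false(any(is_default_nbsl(rec$nbsl_h, rec$nbsl_v)))
  rec2 <- transpose_to_right_eye(
    generate_cohort(cohort_spec(5000, default_fraction = 0.1, seed = 5)))
  frac <- mean(is_default_nbsl(rec2$nbsl_h, rec2$nbsl_v))
  expect_equal(frac, 0.1, tolerance = 0.001)
})

test_that("a zero refraction slope yields no distance-SE correlation", {
  spec <- cohort_spec(4000, se_model = list(intercept = 0, slope = 0,
                                            noise_sd = 2.45), seed = 6)
  rec <- transpose_to_right_eye(generate_cohort(spec))
  r <- cor(nbsl_distance(rec$nbsl_h, rec$nbsl_v), rec$se_diopters)
  expect_lt(abs(r), 3 / sqrt(4000))
})

test_that("the calibrated slope reproduces the target correlation", {
  rec <- generate_cohort(default_cohort_spec(11449, seed = 8))
  ct <- se_correlation(rec)
  expect_lt(abs(unname(ct$estimate) - (-0.14)), 0.02)
})

test_that("unreliable_fraction feeds the reliability filter as planted", {
  f <- 0.25
  rec <- generate_cohort(cohort_spec(4000, unreliable_fraction = f,
                                     seed = 9))
  out <- apply_inclusion_filters(rec)
  removed <- mean(out$exclusions$rule == "reliability") *
    nrow(out$exclusions) / nrow(rec)
  expect_equal(removed, f, tolerance = 3 * sqrt(f * (1 - f) / 4000))
})

test_that("the median split of a default cohort lands at the reference median", {
  rec <- generate_cohort(default_cohort_spec(11449, seed = 10))
  sp <- median_split(rec, "distance")
  expect_equal(sp$median_value, 14.32, tolerance = 0.05)
})
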