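toy_table <- function(seed = 1, n_cells = 12, lambda = 60) {
  set.seed(seed)
  cells <- expand.grid(h_deg = 11:19, v_deg = -5:1)
  cells <- cells[!is_default_nbsl(cells$h_deg, cells$v_deg), ]
  cells <- cells[sample(nrow(cells), n_cells), ]
  cells$count <- 5 + rpois(n_cells, lambda)
  make_freq_table(cells$h_deg, cells$v_deg, cells$count)
}

test_that("the kernel follows the anisotropic squared-exponential formula", {
  hp <- gp_hyperparams(1.2, c(0.9, 0.8))
  # zero distance: the maximum allowable covariance sigma_f^2
  expect_equal(gp_kernel(c(3, -2), c(3, -2), hp)[1, 1], 1.44)
  # hand evaluation at a unit horizontal offset
  expect_equal(gp_kernel(c(0, 0), c(1, 0), hp)[1, 1],
               1.44 * exp(-1 / 0.81), tolerance = 1e-9)
  expect_equal(gp_kernel(c(0, 0), c(1, 0), hp)[1, 1], 0.41898,
               tolerance = 1e-4)
  # symmetry
  a <- matrix(c(1, 2, -3, 0.5), 2)
  expect_equal(gp_kernel(a, a, hp), t(gp_kernel(a, a, hp)))
  # hyperparameter validation
  expect_error(gp_hyperparams(-1, c(0.9, 0.8)))
  expect_error(gp_hyperparams(1, c(0.9, -0.8)))
})

test_that("the fit interpolates the training counts", {
  tab <- toy_table(2)
  fit <- gp_fit(tab, gp_hyperparams(1.2, c(0.9, 0.8), jitter = 1e-10))
  pred <- predict(fit, tab$counts)
  expect_equal(pred, tab$counts$count, tolerance = 1e-6)
})

test_that("predictions are invariant to training-cell order", {
  tab <- toy_table(3)
  shuffled <- tab$counts[sample(nrow(tab$counts)), ]
  tab2 <- make_freq_table(shuffled$h_deg, shuffled$v_deg, shuffled$count)
  f1 <- gp_fit(tab, gp_hyperparams())
  f2 <- gp_fit(tab2, gp_hyperparams())
  grid <- cbind(runif(20, 11, 19), runif(20, -5, 1))
  expect_equal(predict(f1, grid), predict(f2, grid), tolerance = 1e-9)
})

test_that("scaling all counts scales all predictions", {
  tab <- toy_table(4)
  tab3 <- make_freq_table(tab$counts$h_deg, tab$counts$v_deg,
                          tab$counts$count * 3)
  f1 <- gp_fit(tab, gp_hyperparams())
  f3 <- gp_fit(tab3, gp_hyperparams())
  grid <- cbind(runif(15, 11, 19), runif(15, -5, 1))
  expect_equal(3 * predict(f1, grid), predict(f3, grid), tolerance = 1e-8)
})

test_that("a constant-count table interpolates flat", {
  tab <- make_freq_table(h = c(12, 13, 14, 13), v = c(-2, -2, -2, -1),
                         count = rep(7, 4))
  fit <- gp_fit(tab, gp_hyperparams())
  expect_equal(predict(fit, tab$counts), rep(7, 4), tolerance = 1e-8)
  surf <- gp_surface(fit, resolution = 0.25)
  expect_equal(surf$grid$value, rep(7, nrow(surf$grid)), tolerance = 1e-6)
})

test_that("predictions match an independent GP implementation", {
  skip_if_not_installed("kernlab")
  # kernlab's gausspr with an rbf kernel on pre-scaled coordinates is an
  # independent route to the same predictive mean; its noise-variance
  # floor sets the jitter used on both sides
  jit <- 0.002
  for (seed in c(11, 12, 13)) {
    tab <- toy_table(seed, n_cells = 18)
    gamma <- c(1.1, 0.9)
    fit <- gp_fit(tab, gp_hyperparams(1, gamma, jitter = jit))
    grid <- as.matrix(expand.grid(h_deg = seq(11.5, 18.5, by = 0.7),
                                  v_deg = seq(-4.5, 0.5, by = 0.6)))
    mine <- predict(fit, grid)
    # replicate the documented standardization, then hand the
    # standardized problem to kernlab
    X <- as.matrix(tab$counts[, c("h_deg", "v_deg")])
    y <- tab$counts$count
    psd <- function(x) sqrt(mean((x - mean(x))^2))
    xc <- colMeans(X); xs <- apply(X, 2, psd)
    Z <- sweep(sweep(X, 2, xc), 2, xs * gamma, "/")
    Zs <- sweep(sweep(grid, 2, xc), 2, xs * gamma, "/")
    yy <- (y - mean(y)) / psd(y)
    gpo <- kernlab::gausspr(Z, yy, kernel = "rbfdot",
                            kpar = list(sigma = 1), var = jit,
                            scaled = FALSE)
    theirs <- mean(y) + psd(y) * as.vector(kernlab::predict(gpo, Zs))
    expect_equal(mine, theirs, tolerance = 1e-6)
  }
})

test_that("the surface argmax is the grid maximum and bounds are validated", {
  tab <- toy_table(6, n_cells = 16)
  fit <- gp_fit(tab, gp_hyperparams())
  surf <- gp_surface(fit, resolution = 0.2)
  expect_equal(surf$argmax$value, max(surf$grid$value))
  i <- which.max(surf$grid$value)
  expect_equal(surf$argmax$h_deg, surf$grid$h_deg[i])
  expect_error(gp_surface(fit, resolution = 0), "positive")
  # the hull grid is a subset of the bounding-box grid
  bb <- gp_surface(fit, resolution = 0.2, bounds = "bbox")
  expect_lte(nrow(surf$grid), nrow(bb$grid))
})

test_that("degenerate tables are rejected with helpful errors", {
  one <- make_freq_table(14, -1, 10)
  expect_error(gp_fit(one), "at least 2")
  line <- make_freq_table(c(12, 13, 14), c(-2, -2, -2), c(5, 9, 7))
  expect_error(gp_fit(line), "zero variance")
  # near-duplicate cells need jitter
  dup <- make_freq_table(c(12, 12, 13), c(-2, -2, -1), c(5, 9, 7))
  expect_error(gp_fit(dup, gp_hyperparams(jitter = 0)), "jitter")
})

test_that("hyperparameter search recovers known values within one grid step", {
  set.seed(41)
  cells <- expand.grid(h_deg = 10:19, v_deg = -6:1)
  cells <- cells[!is_default_nbsl(cells$h_deg, cells$v_deg), ]
  X <- as.matrix(cells)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, psd), "/")
  true <- gp_hyperparams(1.0, c(0.5, 0.4), jitter = 0)
  K <- gp_kernel(Z, Z, true) + diag(0.01, nrow(Z))
  yy <- drop(crossprod(chol(K), rnorm(nrow(Z))))
  # re-centre the sample so the fit's standardization reproduces it
  # exactly (up to count rounding), keeping sigma_f identifiable
  yy <- (yy - mean(yy)) / psd(yy)
  y <- pmax(round(400 + 200 * yy), 0)
  tab <- make_freq_table(cells$h_deg, cells$v_deg, y)
  grid <- seq(0.2, 1.6, by = 0.2)
  est <- optimize_hyperparams(tab, sigma_f_grid = grid, gamma_grid = grid,
                              jitter = 0.01)
  expect_lte(abs(est$sigma_f - 1.0), 0.2 + 1e-9)
  expect_lte(abs(est$gamma[1] - 0.5), 0.2 + 1e-9)
  expect_lte(abs(est$gamma[2] - 0.4), 0.2 + 1e-9)
})

test_that("a single-point search grid returns that point", {
  tab <- toy_table(7)
  est <- optimize_hyperparams(tab, sigma_f_grid = 1.3, gamma_grid = 0.7)
  expect_equal(est$sigma_f, 1.3)
  expect_equal(est$gamma, c(0.7, 0.7))
  expect_error(optimize_hyperparams(tab, sigma_f_grid = numeric()),
               "empty")
})
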