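#' Gaussian-process hyperparameters
#'
#' @param sigma_f Kernel amplitude (maximum allowable covariance is
#'   `sigma_f^2`), in standardized-count units. Must be positive.
#' @param gamma Length-scale pair `(gamma_h, gamma_v)`, in standardized
#'   coordinate units (see [gp_fit()] for the standardization). Both
#'   positive.
#' @param jitter Diagonal stabiliser added to the kernel matrix. The
#'   default `1e-8` keeps the fit a noiseless interpolator to numerical
#'   precision.
#' @return An object of class `gp_hyperparams`.
#' @export
gp_hyperparams <- function(sigma_f = 1.2, gamma = c(0.9, 0.8),
                           jitter = 1e-8) {
  stopifnot(sigma_f > 0, length(gamma) == 2, all(gamma > 0), jitter >= 0)
  structure(list(sigma_f = sigma_f, gamma = gamma, jitter = jitter),
            class = "gp_hyperparams")
}

#' @export
print.gp_hyperparams <- function(x, ...) {
  cat(sprintf("GP hyperparameters: sigma_f = %g, gamma = (%g, %g), jitter = %g\n",
              x$sigma_f, x$gamma[1], x$gamma[2], x$jitter))
  invisible(x)
}

#' Anisotropic squared-exponential covariance
#'
#' `k(xi, xj) = sigma_f^2 * exp(-[(dh/gamma_h)^2 + (dv/gamma_v)^2])`,
#' with per-dimension length scales and no factor of 2 in the
#' denominator. At zero distance the covariance equals `sigma_f^2`.
#'
#' @param xi,xj Two-column matrices (or length-2 vectors) of points.
#' @param hp A [gp_hyperparams()] object.
#' @return The `nrow(xi) x nrow(xj)` covariance matrix.
#' @examples
#' gp_kernel(c(0, 0), c(1, 0), gp_hyperparams(1.2, c(0.9, 0.8)))
#' # 1.44 * exp(-1/0.81) = 0.41866
#' @export
gp_kernel <- function(xi, xj, hp) {
  stopifnot(inherits(hp, "gp_hyperparams"))
  if (is.null(dim(xi))) xi <- matrix(xi, ncol = 2)
  if (is.null(dim(xj))) xj <- matrix(xj, ncol = 2)
  d2 <- outer(xi[, 1], xj[, 1], "-")^2 / hp$gamma[1]^2 +
        outer(xi[, 2], xj[, 2], "-")^2 / hp$gamma[2]^2
  hp$sigma_f^2 * exp(-d2)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Fit a Gaussian process to an NBSL frequency table
#'
#' Interpolates the discrete frequency-of-eyes table with a zero-mean
#' Gaussian process under the anisotropic squared-exponential kernel
#' ([gp_kernel()]), giving the best linear unbiased prediction of the
#' frequency at arbitrary field locations.
#'
#' With `standardize = "cells"` (the default, and the convention under
#' which the shipped reference table reproduces its published surface
#' statistics) both the counts and the cell coordinates are z-scored by
#' their population moments over the training cells before fitting;
#' predictions are transformed back to count units. `gamma` is then a
#' length scale in coordinate standard deviations. With
#' `standardize = "none"` the kernel acts on raw degrees and raw counts
#' (a zero-mean process, so predictions decay to zero far from data).
#'
#' With the default jitter the fit interpolates: the predictive mean at
#' a training cell equals its observed count to numerical precision.
#'
#' @param table An `nbsl_freq_table`, typically after
#'   [exclude_sparse_cells()]; needs at least 2 cells.
#' @param hp A [gp_hyperparams()] object.
#' @param standardize `"cells"` or `"none"`.
#' @return An object of class `nbsl_gp` with a [predict][predict.nbsl_gp]
#'   method.
#' @export
gp_fit <- function(table, hp = gp_hyperparams(),
                   standardize = c("cells", "none")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(table, "nbsl_freq_table"),
            inherits(hp, "gp_hyperparams"))
  X <- as.matrix(table$counts[, c("h_deg", "v_deg")])
  y <- table$counts$count
  if (nrow(X) < 2) stop("need at least 2 cells to fit a GP")
  if (standardize == "cells") {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, pop_sd)
    y_center <- mean(y)
    y_scale <- pop_sd(y)
    if (any(x_scale == 0)) {
      stop("degenerate table: zero variance in cell coordinates")
    }
    # constant counts: centred values are all zero and the fit is the
    # flat surface at that constant; any positive scale works
    if (y_scale == 0) y_scale <- 1
  } else {
    x_center <- c(0, 0); x_scale <- c(1, 1)
    y_center <- 0; y_scale <- 1
  }
  Z <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yy <- (y - y_center) / y_scale
  K <- gp_kernel(Z, Z, hp) + diag(hp$jitter, nrow(Z))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    stop("kernel matrix is numerically singular; increase `jitter` ",
         "(currently ", hp$jitter, ")")
  }
  alpha <- backsolve(ch, forwardsolve(t(ch), yy))
  structure(list(hyperparams = hp, standardize = standardize,
                 X = X, y = y, Z = Z, alpha = alpha, chol = ch,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 log_marginal_likelihood =
                   -0.5 * sum(yy * alpha) - sum(log(diag(ch))) -
                   length(yy) / 2 * log(2 * pi)),
            class = "nbsl_gp")
}

#' Predictive mean of a fitted NBSL Gaussian process
#'
#' @param object An `nbsl_gp` fit.
#' @param newdata Data frame with columns `h_deg`, `v_deg` (degrees), or
#'   a two-column matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted frequencies in count units.
#' @export
predict.nbsl_gp <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, c("h_deg", "v_deg")])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 2)
  Zs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  Ks <- gp_kernel(Zs, object$Z, object$hyperparams)
  object$y_center + object$y_scale * as.vector(Ks %*% object$alpha)
}

#' @export
print.nbsl_gp <- function(x, ...) {
  cat("NBSL Gaussian process:", nrow(x$X), "training cells,",
      "standardize =", x$standardize, "\n")
  print(x$hyperparams)
  cat(sprintf("log marginal likelihood: %.3f\n", x$log_marginal_likelihood))
  invisible(x)
}

#' Continuous NBSL frequency surface
#'
#' Evaluates the GP predictive mean on a regular sub-degree grid over
#' the convex hull of the training cells and records the grid argmax.
#'
#' @param fit An `nbsl_gp` object from [gp_fit()].
#' @param resolution Grid spacing in degrees (default 0.1, matching the
#'   precision at which the surface maximum location is reported).
#' @param bounds `"hull"` (default) restricts the grid to the convex
#'   hull of the training cells; `"bbox"` uses their bounding box.
#' @return An object of class `gp_surface`: list with `grid` (data
#'   frame `h_deg`, `v_deg`, `value`), `argmax` (list `h_deg`, `v_deg`,
#'   `value`), `resolution` and `hyperparams`.
#' @export
gp_surface <- function(fit, resolution = 0.1, bounds = c("hull", "bbox")) {
  bounds <- match.arg(bounds)
  stopifnot(inherits(fit, "nbsl_gp"))
  if (resolution <= 0) stop("resolution must be positive")
  hs <- seq(min(fit$X[, 1]), max(fit$X[, 1]), by = resolution)
  vs <- seq(min(fit$X[, 2]), max(fit$X[, 2]), by = resolution)
  G <- as.matrix(expand.grid(h_deg = hs, v_deg = vs))
  if (bounds == "hull") {
    hull <- grDevices::chull(fit$X)
    keep <- in_convex_hull(G, fit$X[hull, , drop = FALSE])
    G <- G[keep, , drop = FALSE]
  }
  vals <- predict(fit, G)
  i <- which.max(vals)
  structure(list(
    grid = data.frame(h_deg = G[, 1], v_deg = G[, 2], value = vals),
    argmax = list(h_deg = unname(G[i, 1]), v_deg = unname(G[i, 2]),
                  value = vals[i]),
    resolution = resolution, bounds = bounds,
    hyperparams = fit$hyperparams
  ), class = "gp_surface")
}

#' @export
print.gp_surface <- function(x, ...) {
  cat(sprintf(
    "GP frequency surface: %d grid points at %.2f deg resolution\n",
    nrow(x$grid), x$resolution))
  cat(sprintf("maximum %.1f eyes at (%.1f, %.1f)\n",
              x$argmax$value, x$argmax$h_deg, x$argmax$v_deg))
  invisible(x)
}

# points inside (or on, within eps) the convex polygon with the given
# counter-clockwise or clockwise vertex order
in_convex_hull <- function(pts, verts, eps = 1e-9) {
  nv <- nrow(verts)
  inside <- rep(TRUE, nrow(pts))
  sgn <- 0
  for (i in seq_len(nv)) {
    a <- verts[i, ]
    b <- verts[if (i == nv) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    if (sgn == 0) sgn <- sign(sum(cr))
    inside <- inside & (sgn * cr >= -eps)
  }
  inside
}

#' Hyperparameter selection by marginal likelihood
#'
#' Exhaustive grid search maximizing the GP log marginal likelihood of
#' the (standardized) counts over a Cartesian grid of `sigma_f`,
#' `gamma_h` and `gamma_v`. Ties are broken toward smaller `sigma_f`,
#' then smaller `gamma_h`, then smaller `gamma_v`. Hyperparameter
#' combinations whose kernel matrix is not numerically positive
#' definite at the given jitter are treated as infeasible.
#'
#' @param table An `nbsl_freq_table` (after sparse-cell exclusion).
#' @param sigma_f_grid,gamma_grid Candidate values; default 0.1 to 3.0
#'   in steps of 0.1.
#' @param jitter Diagonal stabiliser used during the search.
#' @param standardize Passed to [gp_fit()].
#' @return The winning [gp_hyperparams()], with the achieved log
#'   marginal likelihood in attribute `"log_marginal_likelihood"`.
#' @export
optimize_hyperparams <- function(table,
                                 sigma_f_grid = seq(0.1, 3.0, by = 0.1),
                                 gamma_grid = seq(0.1, 3.0, by = 0.1),
                                 jitter = 1e-8,
                                 standardize = c("cells", "none")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(table, "nbsl_freq_table"))
  if (!length(sigma_f_grid) || !length(gamma_grid)) {
    stop("empty hyperparameter grid")
  }
  X <- as.matrix(table$counts[, c("h_deg", "v_deg")])
  y <- table$counts$count
  if (nrow(X) < 2 || pop_sd(y) == 0) stop("degenerate frequency table")
  if (standardize == "cells") {
    Z <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, pop_sd), "/")
    yy <- (y - mean(y)) / pop_sd(y)
  } else {
    Z <- X
    yy <- y
  }
  n <- length(yy)
  Dh <- outer(Z[, 1], Z[, 1], "-")^2
  Dv <- outer(Z[, 2], Z[, 2], "-")^2
  best <- -Inf
  best_hp <- NULL
  # exact ties broken toward smaller sigma_f, then smaller gamma_h,
  # then smaller gamma_v (lexicographic)
  better_tie <- function(cand, incumbent) {
    d <- cand - incumbent
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] < 0
  }
  for (gv in sort(gamma_grid)) for (gh in sort(gamma_grid)) {
    R <- exp(-Dh / gh^2 - Dv / gv^2)
    for (sf in sort(sigma_f_grid)) {
      K <- sf^2 * R
      diag(K) <- diag(K) + jitter
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      a <- backsolve(ch, forwardsolve(t(ch), yy))
      lml <- -0.5 * sum(yy * a) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
      if (!is.finite(lml)) next
      if (is.null(best_hp) || lml > best + 1e-9 ||
          (abs(lml - best) <= 1e-9 && better_tie(c(sf, gh, gv), best_hp))) {
        best <- lml
        best_hp <- c(sf, gh, gv)
      }
    }
  }
  if (is.null(best_hp)) {
    stop("no hyperparameter combination gave a positive-definite kernel; ",
         "increase `jitter`")
  }
  out <- gp_hyperparams(best_hp[1], best_hp[2:3], jitter)
  attr(out, "log_marginal_likelihood") <- best
  out
}
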