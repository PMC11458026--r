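# Semivariogram estimation and model fitting.
#
# gamma(h) = c0 + gamma_struct(h) for h > 0 and 0 at h = 0, with
#   spherical:   gamma_struct(h) = c1 * (1.5 h/a - 0.5 (h/a)^3) for h <= a, c1 beyond
#   exponential: gamma_struct(h) = c1 * (1 - exp(-3 h/a))   (practical range a)
# c0 = nugget, c1 = partial sill, a = range in km.

#' Construct a variogram model
#'
#' @param family `"spherical"` or `"exponential"` (practical-range form,
#'   factor 3 in the exponent).
#' @param nugget nugget variance c0 (>= 0).
#' @param psill partial sill c1 (>= 0).
#' @param range range a in km (> 0).
#' @param trend_order polynomial trend order the model was fitted on (0, 1, 2).
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("spherical", "exponential"),
                            nugget, psill, range, trend_order = 0L) {
  family <- match.arg(family)
  .check(nugget >= 0, "nugget must be >= 0")
  .check(psill >= 0, "partial sill must be >= 0")
  .check(range > 0, "range must be > 0")
  structure(
    list(family = family, nugget = nugget, psill = psill, range = range,
         trend_order = as.integer(trend_order)),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model (%s): nugget %.4g, partial sill %.4g, range %.4g km",
              x$family, x$nugget, x$psill, x$range))
  if (!is.null(x$fit)) cat(sprintf("  [WLS objective %.4g]", x$fit$objective))
  cat("\n")
  invisible(x)
}

# structured component only (no nugget)
gamma_struct <- function(model, h) {
  a <- model$range; c1 <- model$psill
  if (model$family == "spherical") {
    hr <- pmin(h / a, 1)
    c1 * (1.5 * hr - 0.5 * hr^3)
  } else {
    c1 * (1 - exp(-3 * h / a))
  }
}

#' Evaluate a variogram model
#'
#' `gamma(0) = 0`; `gamma(h) = c0 + gamma_struct(h)` for h > 0.
#'
#' @param object a `variogram_model`.
#' @param h distances in km.
#' @param ... unused.
#' @return semivariance at each `h`.
#' @export
predict.variogram_model <- function(object, h, ...) {
  ifelse(h > 0, object$nugget + gamma_struct(object, h), 0)
}

#' Remove a polynomial spatial trend
#'
#' Ordinary least squares on monomials of (x, y) up to total degree `order`;
#' order 0 returns the values unchanged (no fit).
#'
#' @param points data.frame or matrix with planar km columns x, y.
#' @param values numeric response.
#' @param order 0, 1 or 2.
#' @return list with `residuals`, `coefficients`, `order`, and the model
#'   `aic` (Gaussian) used by automatic order selection.
#' @export
detrend <- function(points, values, order = 0L) {
  points <- as.data.frame(points)
  n <- length(values)
  .check(order %in% 0:2, "trend order must be 0, 1 or 2")
  if (order == 0L) {
    rss <- sum((values - mean(values))^2)
    # AIC of the intercept-only Gaussian model, comparable across orders
    aic <- n * log(rss / n) + 2 * 2
    return(list(residuals = values, coefficients = numeric(0), order = 0L, aic = aic))
  }
  X <- cbind(1, points$x, points$y)
  if (order == 2L) X <- cbind(X, points$x^2, points$x * points$y, points$y^2)
  p <- ncol(X)
  .check(n >= p, "need at least %d points for trend order %d", p, order)
  fit <- lm.fit(X, values)
  if (fit$rank < p) stop("rank-deficient trend design (collinear stations)", call. = FALSE)
  rss <- sum(fit$residuals^2)
  aic <- n * log(rss / n) + 2 * (p + 1)
  list(residuals = as.numeric(fit$residuals), coefficients = fit$coefficients,
       order = as.integer(order), aic = aic)
}

#' Pick the trend order with the smallest AIC
#' @param points planar km coordinates (columns x, y).
#' @param values numeric response.
#' @return the [detrend()] result of the winning order (0, 1 or 2).
#' @export
detrend_auto <- function(points, values) {
  fits <- lapply(0:2, function(o) try(detrend(points, values, o), silent = TRUE))
  fits <- Filter(function(f) !inherits(f, "try-error"), fits)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
}

#' Empirical semivariogram
#'
#' Matheron estimator over unordered station pairs:
#' `gamma_hat(b) = sum over pairs in bin b of (z_i - z_j)^2 / (2 N_b)`,
#' with equal-width distance bins on (0, max_lag]. Empty bins are omitted.
#'
#' @param points planar km coordinates (columns x, y).
#' @param values numeric values at the points.
#' @param n_lags number of distance bins (default 15).
#' @param max_lag maximum pair distance used; default half the maximum
#'   pairwise distance.
#' @param trend_order trend order recorded on the result (metadata only;
#'   detrend beforehand).
#' @return object of class `empirical_variogram`: data.frame with
#'   `lag_center`, `gamma_hat`, `n_pairs`.
#' @export
empirical_variogram <- function(points, values, n_lags = 15L, max_lag = NULL,
                                trend_order = 0L) {
  points <- as.data.frame(points)
  n <- length(values)
  .check(n >= 2, "need at least 2 points")
  d <- as.numeric(stats::dist(cbind(points$x, points$y)))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  .check(max_lag > 0, "max_lag must be positive")
  dz2 <- as.numeric(stats::dist(values))^2
  keep <- d > 0 & d <= max_lag
  if (!any(keep)) stop("no station pairs within max_lag: empty variogram", call. = FALSE)
  breaks <- seq(0, max_lag, length.out = n_lags + 1L)
  bin <- findInterval(d[keep], breaks, left.open = TRUE, rightmost.closed = TRUE)
  np <- tabulate(bin, nbins = n_lags)
  gsum <- vapply(seq_len(n_lags), function(b) sum(dz2[keep][bin == b]), numeric(1))
  nz <- np > 0
  out <- data.frame(
    lag_center = (breaks[-1] + breaks[-length(breaks)])[nz] / 2,
    gamma_hat = gsum[nz] / (2 * np[nz]),
    n_pairs = np[nz]
  )
  structure(out, class = c("empirical_variogram", "data.frame"),
            max_lag = max_lag, trend_order = as.integer(trend_order))
}

# Cressie-weighted objective: sum_b N_b (gamma_hat_b - gamma_b)^2 / gamma_b^2
.vgm_objective <- function(par, emp, family) {
  m <- list(family = family, nugget = par[1], psill = par[2], range = par[3])
  g <- par[1] + gamma_struct(m, emp$lag_center)
  g <- pmax(g, 1e-10)
  sum(emp$n_pairs * (emp$gamma_hat - g)^2 / g^2)
}

# Given a, solve (c0, c1) by iteratively reweighted linear least squares with
# non-negativity clipping; weights follow the Cressie objective.
.vgm_profile_fit <- function(a, emp, family) {
  gs <- gamma_struct(list(family = family, psill = 1, range = a), emp$lag_center)
  X <- cbind(1, gs)
  w <- emp$n_pairs / pmax(emp$gamma_hat, 1e-10)^2
  beta <- c(0, max(emp$gamma_hat))
  for (iter in 1:12) {
    W <- sqrt(w)
    fit <- tryCatch(qr.solve(X * W, emp$gamma_hat * W), error = function(e) beta)
    beta <- pmax(fit, 0)
    g <- pmax(X %*% beta, 1e-10)
    w <- emp$n_pairs / as.numeric(g)^2
  }
  beta
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes the Cressie-weighted objective
#' `sum_b N_b (gamma_hat_b - gamma(h_b))^2 / gamma(h_b)^2` over
#' (nugget, partial sill, range) with non-negativity and range box
#' constraints. A coarse profile over the range (linear sub-fit for the two
#' variance parameters) seeds five multistart L-BFGS-B polishes; the best
#' objective is kept.
#'
#' @param emp an [empirical_variogram()].
#' @param family `"spherical"` or `"exponential"`.
#' @param a_max upper bound on the range; default `2 * max_lag`.
#' @return a [variogram_model()] with a `fit` element (objective,
#'   convergence, starts).
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential"),
                          a_max = NULL) {
  family <- match.arg(family)
  .check(nrow(emp) >= 4, "need at least 4 variogram bins to fit 3 parameters")
  max_lag <- attr(emp, "max_lag") %||% max(emp$lag_center)
  if (is.null(a_max)) a_max <- 2 * max_lag
  a_min <- min(emp$lag_center) / 10
  sill_cap <- 10 * max(emp$gamma_hat)

  a_grid <- exp(seq(log(a_min), log(a_max), length.out = 60))
  prof <- vapply(a_grid, function(a) {
    b <- .vgm_profile_fit(a, emp, family)
    .vgm_objective(c(b, a), emp, family)
  }, numeric(1))
  starts_a <- a_grid[order(prof)][1:5]

  best <- NULL
  for (a0 in starts_a) {
    b0 <- .vgm_profile_fit(a0, emp, family)
    op <- tryCatch(
      stats::optim(c(b0[1], max(b0[2], 1e-8), a0), .vgm_objective,
                   emp = emp, family = family, method = "L-BFGS-B",
                   lower = c(0, 0, a_min), upper = c(sill_cap, sill_cap, a_max),
                   control = list(maxit = 500, factr = 1e3)),
      error = function(e) NULL
    )
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) {
    stop("variogram fit failed on all starts (family=", family,
         ", bins=", nrow(emp), ")", call. = FALSE)
  }
  par <- best$par
  # a range below the first lag is indistinguishable from nugget at every
  # observed distance: canonicalize to the pure-nugget representation
  h1 <- min(emp$lag_center)
  degenerate <- if (family == "spherical") par[3] <= h1 else 3 * h1 / par[3] > 7
  if (degenerate) {
    cand <- c(par[1] + par[2], 0, par[3])
    if (.vgm_objective(cand, emp, family) <= best$value + 1e-9) par <- cand
  }
  m <- variogram_model(family, nugget = par[1], psill = par[2],
                       range = par[3],
                       trend_order = attr(emp, "trend_order") %||% 0L)
  m$fit <- list(objective = best$value, convergence = best$convergence,
                starts = starts_a)
  m
}

#' Plot an empirical variogram with an optional fitted model
#' @param x an `empirical_variogram`.
#' @param model optional `variogram_model` overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.empirical_variogram <- function(x, model = NULL, ...) {
  graphics::plot(x$lag_center, x$gamma_hat, xlab = "lag (km)",
                 ylab = expression(hat(gamma)(h)), pch = 16,
                 ylim = c(0, max(x$gamma_hat) * 1.05), ...)
  if (!is.null(model)) {
    h <- seq(1e-6, max(x$lag_center), length.out = 200)
    graphics::lines(h, predict(model, h), col = "firebrick", lwd = 2)
  }
  invisible(x)
}
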