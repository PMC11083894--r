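#' Maximum intensity projection
#'
#' Per-(y, x) maximum over z, the standard 2D rendering used before measuring
#' ROI intensities in a repetitive-imaging series.
#'
#' @param stack A [voxel_grid()].
#' @return A numeric matrix (height x width).
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "voxel_grid"))
  apply(stack$data, c(2, 3), max)
}

#' Mean intensity inside a rectangular ROI
#'
#' @param image Numeric matrix (e.g. a maximum intensity projection).
#' @param roi One-row [roi_table()] (or a list with `y0, x0, height, width`).
#' @return Arithmetic mean over the rectangle.
#' @export
roi_mean_intensity <- function(image, roi) {
  y <- roi$y0 + seq_len(roi$height)
  x <- roi$x0 + seq_len(roi$width)
  if (max(y) > nrow(image) || max(x) > ncol(image)) {
    abort("ROI extends beyond the image.")
  }
  mean(image[y, x])
}

#' Build relative-intensity series from a repetitive acquisition
#'
#' For each ROI: project every stack to its maximum intensity image, measure
#' the ROI mean, and normalise to the first acquisition ("relative
#' intensity"). Acquisition times are normalised to `[0, 1]` across the
#' series, so a fitted slope of -0.16 reads as a 16% relative-intensity loss
#' over the whole series. ROIs whose physical area falls outside the
#' conventional 100-150 square-micrometre window trigger a warning but are
#' still measured.
#'
#' @param stacks List of >= 2 [voxel_grid()]s sharing shape and geometry,
#'   in acquisition order (typically 10 consecutive volumes of one field).
#' @param rois An [roi_table()] (typically 3-5 rectangles).
#' @param dye,microscope Labels carried into the output (e.g. `"TMRM"`,
#'   `"SDCM"`).
#' @return An `intensity_series` tibble: one row per ROI x acquisition with
#'   columns `roi_id, dye, microscope, acquisition, t, raw, relative`.
#' @export
build_series <- function(stacks, rois, dye = "TMRM", microscope = "SDCM") {
  if (length(stacks) < 2L) abort("Need at least 2 acquisitions.")
  ref <- stacks[[1]]
  for (s in stacks) check_same_shape(s$data, ref$data, "acquisition stacks")
  area <- rois$height * rois$width * ref$dy * ref$dx
  off <- area < 100 | area > 150
  if (any(off)) {
    warn(sprintf("%d ROI(s) outside the 100-150 um^2 convention (areas: %s).",
                 sum(off), paste(signif(area[off], 4), collapse = ", ")))
  }
  mips <- lapply(stacks, max_intensity_projection)
  n <- length(stacks)
  t_norm <- (seq_len(n) - 1) / (n - 1)
  out <- purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    raw <- vapply(mips, roi_mean_intensity, numeric(1), roi = roi)
    if (raw[1] <= 0) abort("First-acquisition ROI mean is non-positive.")
    tibble::tibble(
      roi_id = roi$roi_id, dye = dye, microscope = microscope,
      acquisition = seq_len(n), t = t_norm,
      raw = raw, relative = raw / raw[1]
    )
  })
  class(out) <- c("intensity_series", class(out))
  out
}

#' Spread of relative intensity across ROIs at one acquisition
#'
#' Max/min ratio of the relative values across series at a given
#' acquisition — the "fold variation between cells" summary.
#'
#' @param series An `intensity_series` tibble with >= 2 ROIs.
#' @param acquisition Acquisition index (default: the last).
#' @return A single fold value (>= 1).
#' @export
fold_variation <- function(series, acquisition = max(series$acquisition)) {
  at <- dplyr::filter(series, .data$acquisition == !!acquisition)
  if (length(unique(at$roi_id)) < 2L) abort("Need at least 2 ROIs.")
  if (min(at$relative) <= 0) abort("Relative intensities must be positive.")
  max(at$relative) / min(at$relative)
}

neg_loglik_gaussian <- function(par, t, y, location, dispersion) {
  mu <- if (location == "linear") par["alpha"] + par["beta"] * t else par["alpha"]
  lsd <- if (dispersion == "loglinear") par["gamma"] + par["delta"] * t else par["gamma"]
  if (any(!is.finite(lsd)) || any(lsd > 50)) return(1e10)
  # dispersion floor: intensities have finite resolution, sigma >= 1e-8
  lsd <- pmax(lsd, log(1e-8))
  nll <- -sum(stats::dnorm(y, mean = mu, sd = exp(lsd), log = TRUE))
  if (!is.finite(nll)) 1e10 else nll
}

#' Fit the relative-intensity trend model
#'
#' Gaussian maximum-likelihood regression of relative intensity on
#' normalised time, modelling location and dispersion jointly:
#' `y ~ N(mu(t), sigma(t))` with `mu(t) = alpha + beta t` (or constant
#' `alpha`) and `sigma(t) = exp(gamma + delta t)` (or constant
#' `exp(gamma)`). Estimates are obtained by numerical minimisation of the
#' minus log-likelihood (BFGS from `alpha = 1`, `beta` at the OLS slope,
#' `gamma` at the log residual SD, `delta = 0`, refined by Nelder-Mead if it
#' improves). Model fits are compared by `aic = -logL + k`, the minimised
#' minus log-likelihood penalised by the number of estimated parameters.
#'
#' The first acquisition is excluded from the likelihood: its relative value
#' is 1 by construction (each ROI is normalised to itself), a deterministic
#' datum that carries no information and would make the log-linear
#' dispersion likelihood unbounded.
#'
#' @param series An `intensity_series` tibble for a single dye x microscope
#'   group.
#' @param location `"linear"` or `"constant"` mean trend.
#' @param dispersion `"constant"` or `"loglinear"` SD trend.
#' @return A `trend_fit` object with elements `alpha, beta, gamma, delta,
#'   minus_log_likelihood, n_params, aic, converged, n_obs` plus the model
#'   forms. `beta` is identically 0 for the constant location form, `delta`
#'   0 for constant dispersion.
#' @seealso [fit_trend_models()], [compare_models_aic()], [tidy.trend_fit()]
#' @export
fit_trend <- function(series, location = c("linear", "constant"),
                      dispersion = c("constant", "loglinear")) {
  location <- match.arg(location)
  dispersion <- match.arg(dispersion)
  if (length(unique(series$dye)) > 1L || length(unique(series$microscope)) > 1L) {
    abort("Fit one dye x microscope group at a time (see fit_trend_groups()).")
  }
  fitdat <- dplyr::filter(series, .data$t > 0)
  t <- fitdat$t
  y <- fitdat$relative
  if (length(unique(t)) < 2L) abort("Need >= 2 distinct positive time points.")

  ols <- stats::lm(y ~ t)
  res_sd <- max(sd(stats::residuals(ols)), 1e-6)
  if (!is.finite(res_sd)) res_sd <- 1e-3
  par <- c(alpha = 1)
  if (location == "linear") par["beta"] <- unname(coef(ols)[2])
  par["gamma"] <- log(res_sd)
  if (dispersion == "loglinear") par["delta"] <- 0

  zero_var <- sd(y) < 1e-12 ||
    (location == "linear" && res_sd <= 1e-6)
  fn <- function(p) {
    names(p) <- names(par)
    neg_loglik_gaussian(p, t, y, location, dispersion)
  }
  opt <- suppressWarnings(stats::optim(par, fn, method = "BFGS",
                                       control = list(maxit = 500, reltol = 1e-10)))
  opt2 <- suppressWarnings(stats::optim(opt$par, fn, method = "Nelder-Mead",
                                        control = list(maxit = 2000, reltol = 1e-10)))
  if (opt2$value < opt$value) opt <- opt2
  est <- opt$par
  names(est) <- names(par)
  k <- length(par)
  converged <- opt$convergence == 0 || zero_var
  if (!converged) {
    warn(sprintf("Trend fit did not converge (code %d, -logL %.4g).",
                 opt$convergence, opt$value))
  }
  structure(
    list(location = location, dispersion = dispersion,
         alpha = unname(est["alpha"]),
         beta = if (location == "linear") unname(est["beta"]) else 0,
         gamma = unname(est["gamma"]),
         delta = if (dispersion == "loglinear") unname(est["delta"]) else 0,
         minus_log_likelihood = opt$value,
         n_params = k,
         aic = opt$value + k,
         converged = converged,
         zero_variance = zero_var,
         n_obs = length(y),
         dye = series$dye[1], microscope = series$microscope[1]),
    class = "trend_fit"
  )
}

#' Fit all location x dispersion model forms
#'
#' Convenience wrapper fitting the four combinations of
#' `{linear, constant}` location and `{constant, loglinear}` dispersion to
#' one group.
#'
#' @inheritParams fit_trend
#' @return A list of `trend_fit` objects.
#' @export
fit_trend_models <- function(series) {
  grid <- expand.grid(location = c("linear", "constant"),
                      dispersion = c("constant", "loglinear"),
                      stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(grid)), function(i) {
    fit_trend(series, grid$location[i], grid$dispersion[i])
  })
}

#' Select the best model by AIC
#'
#' Returns the fit with the smallest `aic` (`-logL + k`); ties are broken
#' toward fewer parameters, preferring the simpler model.
#'
#' @param fits List of `trend_fit` objects of the same data.
#' @return The selected `trend_fit`.
#' @export
compare_models_aic <- function(fits) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, logical(1), "trend_fit")))
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  grp <- vapply(fits, function(f) paste(f$dye, f$microscope), character(1))
  if (length(unique(n_obs)) > 1L || length(unique(grp)) > 1L) {
    abort("All fits must be of the same data.")
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "n_params")
  fits[[order(aic, k)[1]]]
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s/%s  location: %s, dispersion: %s\n",
              x$dye, x$microscope, x$location, x$dispersion))
  cat(sprintf("  alpha %.4f  beta %.4f  sigma(0) %.4f  delta %.4f\n",
              x$alpha, x$beta, exp(x$gamma), x$delta))
  cat(sprintf("  -logL %.4f  k %d  AIC %.4f\n",
              x$minus_log_likelihood, x$n_params, x$aic))
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return One row per estimated parameter with `term` and `estimate`.
#' @export
tidy.trend_fit <- function(x, ...) {
  terms <- c("alpha",
             if (x$location == "linear") "beta",
             "gamma",
             if (x$dispersion == "loglinear") "delta")
  tibble::tibble(term = terms,
                 estimate = unlist(x[terms], use.names = FALSE))
}

#' One-row summary of a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A one-row tibble with model forms, slope, `-logL`, `k` and AIC.
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    dye = x$dye, microscope = x$microscope,
    location = x$location, dispersion = x$dispersion,
    alpha = x$alpha, beta = x$beta, gamma = x$gamma, delta = x$delta,
    minus_log_likelihood = x$minus_log_likelihood,
    n_params = x$n_params, aic = x$aic, converged = x$converged
  )
}

#' Plot a relative-intensity series with its fitted trend
#'
#' @param object A `trend_fit`.
#' @param series The `intensity_series` the fit was made from (optional; if
#'   omitted only the fitted mean and dispersion band are drawn).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_fit <- function(object, series = NULL, ...) {
  tt <- seq(0, 1, length.out = 50)
  mu <- object$alpha + object$beta * tt
  sdv <- exp(object$gamma + object$delta * tt)
  band <- tibble::tibble(t = tt, mu = mu, lo = mu - 2 * sdv, hi = mu + 2 * sdv)
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu), linewidth = 0.8) +
    ggplot2::labs(
      x = "normalised acquisition time", y = "relative intensity",
      title = sprintf("%s / %s: slope %.3f (AIC %.2f)",
                      object$dye, object$microscope, object$beta, object$aic)
    )
  if (!is.null(series)) {
    p <- p + ggplot2::geom_point(
      data = series,
      ggplot2::aes(x = .data$t, y = .data$relative, group = .data$roi_id),
      alpha = 0.6)
  }
  p
}

#' Plot size-class composition
#'
#' Bar chart of the percentage of mitochondrial objects in the small /
#' medium / network volume classes, optionally per group.
#'
#' @param class_pct Tibble with columns `size_class`, `pct` and optionally
#'   `group` (e.g. stacked outputs of [size_class_percentages()]).
#' @return A ggplot object.
#' @export
plot_size_classes <- function(class_pct) {
  class_pct$size_class <- factor(class_pct$size_class,
                                 levels = c("small", "medium", "network"))
  p <- ggplot2::ggplot(class_pct,
                       ggplot2::aes(x = .data$size_class, y = .data$pct)) +
    ggplot2::labs(x = "object volume class", y = "% of objects")
  if ("group" %in% names(class_pct)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$group),
                          position = "dodge")
  } else {
    p + ggplot2::geom_col()
  }
}
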