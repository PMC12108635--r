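# Companion assay analyses: DSF melting temperatures and cell-binding fits.
#
# Units: temperature degC, concentration nM, fluorescence arbitrary units.

#' Construct a melt-curve object
#'
#' @param temperature ascending degC grid (>= 8 points).
#' @param fluorescence numeric vector (one replicate) or matrix/data.frame
#'   with one column per replicate, on the shared grid.
#' @return an object of class `MeltCurve`.
#' @export
melt_curve <- function(temperature, fluorescence) {
  temperature <- as.numeric(temperature)
  if (length(temperature) < 8) stop("melt curve needs at least 8 points")
  if (is.unsorted(temperature, strictly = TRUE))
    stop("temperature grid must be strictly ascending")
  F <- as.matrix(fluorescence)
  if (nrow(F) != length(temperature))
    stop("fluorescence rows must match the temperature grid")
  structure(list(temperature = temperature, fluorescence = F,
                 replicates = ncol(F)), class = "MeltCurve")
}

#' Read a melt curve from CSV
#'
#' Expects columns `temperature`, `fluorescence` and optionally `replicate`;
#' replicates must share one grid.
#'
#' @param path CSV path.
#' @return a `MeltCurve`.
#' @export
read_melt_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("temperature", "fluorescence") %in% names(df)))
    stop("melt-curve CSV needs temperature and fluorescence columns")
  if (is.null(df$replicate)) df$replicate <- 1
  reps <- split(df, df$replicate)
  grid <- reps[[1]]$temperature
  F <- vapply(reps, function(d) {
    if (!isTRUE(all.equal(d$temperature, grid)))
      stop("replicates use different temperature grids")
    d$fluorescence
  }, numeric(length(grid)))
  melt_curve(grid, F)
}

# Parabolic refinement of an extremum: least-squares quadratic over a
# window of grid points around the argmax, returning the vertex (clamped to
# the window).  On a peak symmetric about a grid point the vertex is that
# grid point exactly.
.parabolic_peak <- function(x, y, i, half = 8L) {
  lo <- max(1L, i - half); hi <- min(length(x), i + half)
  xi <- x[lo:hi] - x[i]; yi <- y[lo:hi]
  fit <- stats::lm.fit(cbind(1, xi, xi^2), yi)
  A <- fit$coefficients[3]; B <- fit$coefficients[2]
  if (!is.finite(A) || A >= 0 || abs(A) < 1e-15) return(x[i])
  v <- x[i] - B / (2 * A)
  min(max(v, x[lo]), x[hi])
}

#' Melting temperature from the fluorescence first derivative
#'
#' Per replicate: smooth with a local-quadratic (Savitzky-Golay) filter,
#' differentiate by central differences, and take the temperature of the
#' dominant interior extremum of |dF/dT| -- correct for either sign
#' convention of the derivative plot.  The peak temperature is refined by a
#' three-point parabolic fit.  An extremum on the grid boundary means no
#' interior transition and is an error.
#'
#' @param curves a `MeltCurve`.
#' @param smooth_window odd Savitzky-Golay window length in points
#'   (default 5); use 1 to disable smoothing.
#' @return an object of class `TmResult` with `tm_per_replicate`, `tm_mean`,
#'   `tm_sd` (degC).
#' @export
tm_from_melt <- function(curves, smooth_window = 5) {
  stopifnot(inherits(curves, "MeltCurve"))
  if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
  Tg <- curves$temperature
  tms <- apply(curves$fluorescence, 2, function(f) {
    fs <- if (smooth_window > 1)
      as.numeric(signal::sgolayfilt(f, p = 2, n = smooth_window)) else f
    n <- length(fs)
    dFdT <- numeric(n)
    dFdT[2:(n - 1)] <- (fs[3:n] - fs[1:(n - 2)]) / (Tg[3:n] - Tg[1:(n - 2)])
    dFdT[1] <- (fs[2] - fs[1]) / (Tg[2] - Tg[1])
    dFdT[n] <- (fs[n] - fs[n - 1]) / (Tg[n] - Tg[n - 1])
    mag <- abs(dFdT)
    i <- which.max(mag)
    if (i == 1 || i == n) stop("no interior transition (derivative extremum on grid boundary)")
    if (max(mag) <= 0) stop("no interior transition (flat curve)")
    .parabolic_peak(Tg, mag, i)
  })
  structure(list(tm_per_replicate = as.numeric(tms),
                 tm_mean = mean(tms),
                 tm_sd = if (length(tms) > 1) stats::sd(tms) else NA_real_),
            class = "TmResult")
}

#' @export
print.TmResult <- function(x, ...) {
  cat(sprintf("Tm = %.2f +/- %s degC (%d replicate%s)\n", x$tm_mean,
              if (is.na(x$tm_sd)) "NA" else sprintf("%.2f", x$tm_sd),
              length(x$tm_per_replicate),
              if (length(x$tm_per_replicate) > 1) "s" else ""))
  invisible(x)
}

#' Construct a binding titration object
#'
#' @param concentration strictly positive, distinct concentrations (nM).
#' @param signal numeric vector or one-column-per-replicate matrix of
#'   signals on the shared concentration grid.
#' @return an object of class `BindingCurve`.
#' @export
binding_curve <- function(concentration, signal) {
  concentration <- as.numeric(concentration)
  if (any(concentration <= 0)) stop("concentrations must be strictly positive")
  if (anyDuplicated(concentration)) stop("concentrations must be distinct")
  S <- as.matrix(signal)
  if (nrow(S) != length(concentration))
    stop("signal rows must match the concentration grid")
  structure(list(concentration = concentration, signal = S,
                 replicates = ncol(S)), class = "BindingCurve")
}

#' Read a binding titration from CSV
#'
#' Expects columns `concentration`, `signal` and optionally `replicate`.
#'
#' @param path CSV path.
#' @return a `BindingCurve`.
#' @export
read_binding_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("concentration", "signal") %in% names(df)))
    stop("binding CSV needs concentration and signal columns")
  if (is.null(df$replicate)) df$replicate <- 1
  reps <- split(df, df$replicate)
  grid <- reps[[1]]$concentration
  S <- vapply(reps, function(d) {
    if (!isTRUE(all.equal(d$concentration, grid)))
      stop("replicates use different concentration grids")
    d$signal
  }, numeric(length(grid)))
  binding_curve(grid, S)
}

# Stack replicates into long x/y vectors (replicates are fitted jointly).
.stack_curve <- function(curve) {
  list(x = rep(curve$concentration, curve$replicates),
       y = as.numeric(curve$signal))
}

#' One-site saturation binding fit (KD, Bmax)
#'
#' Least-squares fit of `Y = Bmax * X / (KD + X)` by Levenberg-Marquardt,
#' with positivity bounds; replicates are stacked and fitted jointly.
#' Started at `Bmax0 = max(signal)` and `KD0` the concentration nearest
#' half-maximal signal.
#'
#' @param curve a `BindingCurve` with at least 5 distinct concentrations.
#' @return an object of class `BindingFit` with `kd` (nM), `bmax`, standard
#'   errors, residual summary, and `saturating` (FALSE flags a curve whose
#'   top concentration is below the fitted KD).
#' @export
fit_saturation_binding <- function(curve) {
  stopifnot(inherits(curve, "BindingCurve"))
  if (length(curve$concentration) < 5)
    stop("need at least 5 distinct concentrations")
  d <- .stack_curve(curve)
  bmax0 <- max(d$y)
  kd0 <- d$x[which.min(abs(d$y - bmax0 / 2))]
  fit <- minpack.lm::nlsLM(
    y ~ bmax * x / (kd + x), data = d,
    start = list(bmax = bmax0, kd = max(kd0, 1e-6)),
    lower = c(bmax = 1e-12, kd = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  kd <- co["kd", "Estimate"]
  out <- structure(list(
    kd = kd, bmax = co["bmax", "Estimate"],
    kd_se = co["kd", "Std. Error"], bmax_se = co["bmax", "Std. Error"],
    residual_sd = stats::sigma(fit),
    saturating = max(curve$concentration) >= kd,
    model = "one-site saturation", fit = fit), class = "BindingFit")
  if (!out$saturating)
    warning("titration does not reach the fitted KD; estimates are extrapolated")
  out
}

#' Four-parameter logistic dose-response fit (EC50, Hill slope)
#'
#' Least-squares fit of
#' `Y = Bottom + (Top - Bottom) / (1 + (EC50 / X)^h)` with free Hill slope
#' `h`; replicates stacked and fitted jointly.
#'
#' @param curve a `BindingCurve` with at least 5 distinct concentrations.
#' @return an object of class `BindingFit` with `ec50` (nM), `hill`, `top`,
#'   `bottom`, standard errors and residual summary.
#' @export
fit_ec50 <- function(curve) {
  stopifnot(inherits(curve, "BindingCurve"))
  if (length(curve$concentration) < 5)
    stop("need at least 5 distinct concentrations")
  d <- .stack_curve(curve)
  top0 <- max(d$y); bot0 <- min(d$y)
  ec0 <- d$x[which.min(abs(d$y - (top0 + bot0) / 2))]
  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + (ec50 / x)^h), data = d,
    start = list(bottom = bot0, top = top0, ec50 = max(ec0, 1e-6), h = 1),
    lower = c(bottom = -Inf, top = 1e-12, ec50 = 1e-12, h = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  structure(list(
    ec50 = co["ec50", "Estimate"], hill = co["h", "Estimate"],
    top = co["top", "Estimate"], bottom = co["bottom", "Estimate"],
    ec50_se = co["ec50", "Std. Error"],
    residual_sd = stats::sigma(fit),
    model = "four-parameter logistic", fit = fit), class = "BindingFit")
}

#' @export
print.BindingFit <- function(x, ...) {
  if (x$model == "one-site saturation") {
    cat(sprintf("One-site saturation fit: KD = %.3g nM (SE %.2g), Bmax = %.4g (SE %.2g)\n",
                x$kd, x$kd_se, x$bmax, x$bmax_se))
    if (!x$saturating) cat("  warning: curve does not saturate\n")
  } else {
    cat(sprintf("4PL fit: EC50 = %.3g nM (SE %.2g), Hill = %.2f, Top = %.4g, Bottom = %.3g\n",
                x$ec50, x$ec50_se, x$hill, x$top, x$bottom))
  }
  cat(sprintf("  residual SD %.3g\n", x$residual_sd))
  invisible(x)
}
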