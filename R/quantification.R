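# Capture-rate quantification: blockade frequency, the linear capture-rate
# law f_sig = k_on * [analyte], and its inversion to estimate concentration
# from an observed event frequency.

#' Blockade event frequency
#'
#' `f_sig`, the number of (filtered) blockade events per second of
#' recording. Frequencies should be computed after the standard event
#' filters (see [filter_events()]) so that only genuine blockade signals are
#' counted.
#'
#' @param events List or data frame of events, or a single event count.
#' @param recording_duration_s Recording duration in seconds (> 0).
#' @return Frequency in Hz.
#' @examples
#' event_frequency(10, 10)  # 1 Hz
#' @export
event_frequency <- function(events, recording_duration_s) {
  if (recording_duration_s <= 0) stop("recording duration must be positive")
  n <- if (is.data.frame(events)) nrow(events)
  else if (is.list(events)) length(events)
  else as.numeric(events)
  n / recording_duration_s
}

#' Fit the capture-rate law
#'
#' Least-squares fit of `f_sig = k_on * c` through the origin (the law has
#' no intercept: zero analyte gives zero signal). A free-intercept fit is
#' also run as a linearity diagnostic but is not used for estimation.
#'
#' @param concentration Analyte concentrations (> 0), at least 3 points.
#' @param f_sig Observed event frequencies (Hz), aligned.
#' @param weights Optional fit weights. Event counting obeys Poisson
#'   statistics, so the frequency variance grows with concentration;
#'   `weights = 1 / concentration` is the matching inverse-variance
#'   weighting. Default `NULL` (ordinary least squares).
#' @return Object of class `capture_fit`: `k_on` (Hz per concentration
#'   unit), `se`, the data, the underlying `lm` fits and the concentration
#'   range.
#' @examples
#' fit <- fit_capture_rate(c(1, 2, 3), c(2, 4, 6))
#' coef(fit)  # k_on = 2
#' @export
fit_capture_rate <- function(concentration, f_sig, weights = NULL) {
  stopifnot(length(concentration) == length(f_sig))
  if (length(concentration) < 3L) stop("need at least 3 calibration points")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (all(f_sig == 0)) stop("all frequencies are zero: nothing to fit")
  df <- data.frame(concentration = concentration, f_sig = f_sig)
  df$w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  m0 <- stats::lm(f_sig ~ 0 + concentration, data = df, weights = w)
  m1 <- stats::lm(f_sig ~ concentration, data = df, weights = w)
  k_on <- unname(stats::coef(m0)[1])
  # summary.lm warns on an exactly proportional fit; the zero SE is correct
  se <- unname(suppressWarnings(summary(m0))$coefficients[1, 2])
  if (k_on <= 0) stop("fitted k_on is not positive (", signif(k_on, 3),
                      "): frequencies do not increase with concentration")
  structure(list(k_on = k_on, se = se, data = df,
                 range = range(concentration),
                 lm_origin = m0, lm_free = m1),
            class = "capture_fit")
}

#' @export
print.capture_fit <- function(x, ...) {
  cat(sprintf("<capture_fit> f_sig = k_on * c, k_on = %.4g +/- %.2g Hz per unit\n",
              x$k_on, x$se))
  cat(sprintf("  fitted over c in [%g, %g] (%d points)\n",
              x$range[1], x$range[2], nrow(x$data)))
  ic <- stats::coef(x$lm_free)
  cat(sprintf("  free-intercept diagnostic: intercept %.3g, slope %.4g\n",
              ic[1], ic[2]))
  invisible(x)
}

#' @export
coef.capture_fit <- function(object, ...) c(k_on = object$k_on)

#' @export
predict.capture_fit <- function(object, concentration, ...) {
  object$k_on * concentration
}

#' @export
plot.capture_fit <- function(x, ...) {
  graphics::plot(x$data$concentration, x$data$f_sig, log = "xy",
                 xlab = "concentration", ylab = expression(f[sig] ~ "(Hz)"),
                 ...)
  cc <- exp(seq(log(x$range[1]), log(x$range[2]), length.out = 50))
  graphics::lines(cc, x$k_on * cc)
  invisible(x)
}

#' Estimate concentration from an event frequency
#'
#' Inverts the capture-rate law: `c = f_sig / k_on`, with first-order error
#' propagation from the slope uncertainty (and optionally from the
#' frequency's own SE).
#'
#' @param fit A [fit_capture_rate()] object.
#' @param f_sig Observed event frequency (Hz, >= 0).
#' @param f_se Optional SE of `f_sig`.
#' @return Named vector `c(concentration = ..., se = ...)`.
#' @export
estimate_concentration <- function(fit, f_sig, f_se = 0) {
  stopifnot(inherits(fit, "capture_fit"))
  if (fit$k_on == 0) stop("k_on is zero: cannot invert the capture-rate law")
  if (any(f_sig < 0)) stop("f_sig must be non-negative")
  conc <- f_sig / fit$k_on
  se <- sqrt((f_se / fit$k_on)^2 + (f_sig * fit$se / fit$k_on^2)^2)
  c(concentration = conc, se = se)
}
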