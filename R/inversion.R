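#' Invert observed transparency to aragonite saturation state
#'
#' Solves the transparency model for intensity at a known exposure
#' duration: `Omega = ((T - slope*D - beta)/alpha)^(1/b)`. With the
#' default `"eq5_verbatim"` profile this is the published omega-inversion
#' `Omega = 10^(log10((T + 0.0238 D + 0.0344)/0.81)/0.255)`.
#'
#' @param transparency observed shell transparency `T`.
#' @param duration_days assumed exposure duration `D`, days.
#' @param profile a [transparency_profile()] or its name.
#' @return Saturation state(s), dimensionless.
#' @examples
#' invert_omega(0.7756, 0)  # numerator equals alpha: Omega = 1
#' @export
invert_omega <- function(transparency, duration_days,
                         profile = "eq5_verbatim") {
  p <- transparency_profile(profile)
  num <- (transparency - p$duration_slope * duration_days - p$beta) / p$alpha
  if (any(!is.finite(num)) || any(num <= 0))
    stop("transparency - slope*D - beta must be positive: observed ",
         "transparency too low for this duration under profile '", p$name,
         "'", call. = FALSE)
  num^(1 / p$exponent_b)
}

#' Invert observed transparency to exposure duration
#'
#' Solves the transparency model for duration at a known intensity:
#' `D = (T - alpha*Omega^b - beta)/slope`. With the default
#' `"eq6_verbatim"` profile this is the published duration inversion
#' `D = (T - 0.82 Omega^0.0255 - 0.0555)/(-0.0239)` (the exponent is kept
#' exactly as printed; use `"results_text"` for the 0.255 exponent).
#' Negative durations (transparency above the zero-deficit point, i.e.
#' below the emergence threshold) are returned, not clamped, with a
#' logical `below_emergence` attribute.
#'
#' @param transparency observed shell transparency `T`.
#' @param omega_ar assumed saturation state (> 0).
#' @param profile a [transparency_profile()] or its name.
#' @return Duration(s) in days, attribute `below_emergence`.
#' @examples
#' invert_duration(0.8755, 1)  # zero-deficit point: D = 0
#' @export
invert_duration <- function(transparency, omega_ar,
                            profile = "eq6_verbatim") {
  p <- transparency_profile(profile)
  if (any(!is.finite(omega_ar)) || any(omega_ar <= 0))
    stop("omega_ar must be positive", call. = FALSE)
  d <- (transparency - p$alpha * omega_ar^p$exponent_b - p$beta) /
    p$duration_slope
  structure(d, below_emergence = d < 0)
}

#' Exposure duration at which transparency changes emerge
#'
#' For a pristine shell, the duration at which the duration-adjusted
#' transparency deficit first reaches zero: `D = -beta / slope`. Under the
#' `"eq6_verbatim"` constants this is 0.0555/0.0239 ~ 2.3 days; under the
#' `"results_text"` constants it is 0.1026/0.0238 ~ 4.3 days (the printed
#' constant sets are not mutually consistent, see
#' [transparency_profile()]).
#'
#' @param profile a [transparency_profile()] or its name.
#' @return Days (scalar). `Inf` (with a warning) if the profile's duration
#'   slope is zero, in which case emergence is undefined.
#' @examples
#' emergence_time("eq6_verbatim")   # ~ 2.3 days
#' emergence_time("results_text")   # ~ 4.3 days
#' @export
emergence_time <- function(profile = "eq6_verbatim") {
  p <- transparency_profile(profile)
  if (p$duration_slope == 0) {
    warning("duration slope is zero: emergence time is undefined",
            call. = FALSE)
    return(Inf)
  }
  -p$beta / p$duration_slope
}

#' Exposure envelope consistent with an observed transparency
#'
#' Maps one observed shell transparency to the locus of (intensity,
#' duration) exposures that would produce it: for each saturation state on
#' a grid (capped at the 1.5 response threshold), the duration from
#' [invert_duration()]. Points shorter than the duration floor (default
#' 2 days, below which transparency changes have not yet emerged) are
#' excluded. Curves for more severe (lower) transparencies lie at longer
#' durations everywhere, so envelopes for distinct transparencies never
#' cross.
#'
#' @param transparency observed shell transparency; values outside the
#'   observed biological range \[0.4, 0.9\] trigger a warning (and below
#'   the observed minimum 0.44 a `below_floor` flag), but a curve is still
#'   produced.
#' @param omega_grid saturation-state grid (default 0.5 to 1.5 by 0.01).
#' @param profile a [transparency_profile()] or its name.
#' @param duration_floor_days minimum duration retained on the curve.
#' @return A data.frame of class `"exposure_envelope"` with columns
#'   `omega_ar`, `duration_days`, ordered and monotone increasing in
#'   `omega_ar`; attributes `transparency`, `profile`, `below_floor`.
#' @examples
#' env <- exposure_envelope(0.7)
#' head(env)
#' @export
exposure_envelope <- function(transparency,
                              omega_grid = seq(0.5, 1.5, by = 0.01),
                              profile = "eq6_verbatim",
                              duration_floor_days = 2.0) {
  stopifnot(length(transparency) == 1)
  p <- transparency_profile(profile)
  if (transparency < 0.4 || transparency > 0.9)
    warning("transparency ", transparency,
            " is outside the observed biological range [0.4, 0.9]",
            call. = FALSE)
  below_floor <- transparency < 0.44
  om <- sort(omega_grid[omega_grid > 0 & omega_grid <= 1.5])
  d <- as.numeric(invert_duration(transparency, om, p))
  keep <- d >= duration_floor_days
  out <- data.frame(omega_ar = om[keep], duration_days = d[keep])
  structure(out, transparency = transparency, profile = p$name,
            below_floor = below_floor,
            class = c("exposure_envelope", "data.frame"))
}

#' Plot exposure envelopes
#'
#' @param x an [exposure_envelope()] (further envelopes can be added with
#'   `lines()`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.exposure_envelope <- function(x, ...) {
  graphics::plot(x$omega_ar, x$duration_days, type = "l",
                 xlab = expression(Omega[Ar]), ylab = "Duration (days)",
                 main = sprintf("Exposure envelope, T = %.2f",
                                attr(x, "transparency")), ...)
  invisible(x)
}
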