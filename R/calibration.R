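#' Fit a single-season transparency power law
#'
#' Fits `T = alpha * Omega^b` to one season's Day-4 observations by
#' ordinary least squares in log-log space (`log T = log alpha + b log
#' Omega`), the deterministic reading of a multiplicative-error power
#' regression. A nonlinear least-squares alternative (additive error) is
#' available.
#'
#' @param omega_ar aragonite saturation states (> 0).
#' @param transparency shell transparencies in (0, 1\].
#' @param method `"loglog"` (default) or `"nls"`.
#' @return A list with `alpha`, `exponent`, `n`, and the underlying `fit`.
#' @examples
#' om <- c(0.7, 1.0, 1.6)
#' fit_power_per_season(om, 0.7 * om^0.255)  # exact: alpha 0.7, b 0.255
#' @export
fit_power_per_season <- function(omega_ar, transparency,
                                 method = c("loglog", "nls")) {
  method <- match.arg(method)
  ok <- is.finite(omega_ar) & is.finite(transparency)
  if (!all(ok)) stop("non-finite omega_ar or transparency", call. = FALSE)
  if (any(omega_ar <= 0) || any(transparency <= 0))
    stop("omega_ar and transparency must be positive for a power fit",
         call. = FALSE)
  if (length(unique(omega_ar)) < 3)
    stop("need >= 3 distinct omega_ar values to fit a power law",
         call. = FALSE)
  ll <- stats::lm(log(transparency) ~ log(omega_ar))
  alpha <- exp(unname(stats::coef(ll)[1]))
  b <- unname(stats::coef(ll)[2])
  fit <- ll
  if (method == "nls") {
    # Levenberg-Marquardt: robust to the zero-residual (noiseless) case
    fit <- minpack.lm::nlsLM(transparency ~ a * omega_ar^bb,
                             start = list(a = alpha, bb = b))
    alpha <- unname(stats::coef(fit)["a"])
    b <- unname(stats::coef(fit)["bb"])
  }
  list(alpha = alpha, exponent = b, n = length(omega_ar), fit = fit)
}

#' Average per-season power-law exponents
#'
#' The cross-season exponent is the arithmetic mean of the independent
#' per-season exponents, with SE = SD / sqrt(n).
#'
#' @param exponents numeric vector of per-season exponents (n >= 2).
#' @return A list with `mean` and `se`.
#' @examples
#' average_exponent(c(0.2, 0.3))  # mean 0.25, se 0.05
#' @export
average_exponent <- function(exponents) {
  exponents <- exponents[is.finite(exponents)]
  n <- length(exponents)
  if (n < 2) stop("need >= 2 seasonal exponents to average", call. = FALSE)
  list(mean = mean(exponents), se = stats::sd(exponents) / sqrt(n))
}

#' Seasonal power-law intercept from Day-0 (field) transparency
#'
#' The seasonal intercept alpha of the transparency power law tracks the
#' transparency of freshly field-caught shells (Day 0) linearly:
#' `alpha = 1.0293 * day0 - 0.1087`. Evaluated at the highest observed
#' Day-0 transparency (0.90) this gives alpha ~ 0.82, the pristine-shell
#' intercept.
#'
#' @param day0_transparency Day-0 transparency, within
#'   \[0.1087/1.0293, 1\] (below the line's root alpha would be negative).
#' @param slope,intercept calibration-line coefficients.
#' @return alpha (dimensionless).
#' @examples
#' alpha_from_day0(0.90)  # 0.8177, rounds to 0.82
#' @export
alpha_from_day0 <- function(day0_transparency, slope = 1.0293,
                            intercept = -0.1087) {
  lo <- -intercept / slope
  if (any(!is.finite(day0_transparency)) ||
      any(day0_transparency < lo - 1e-12) || any(day0_transparency > 1))
    stop(sprintf("day0_transparency must lie within [%.4f, 1]", lo),
         call. = FALSE)
  slope * day0_transparency + intercept
}

#' Predicted Day-4 transparency (D4T)
#'
#' The baseline transparency expected after 4 days of exposure at
#' saturation state `omega_ar` for a season with intercept `alpha`:
#' `D4T = alpha * omega_ar^b`. Duration effects are measured as
#' departures from this baseline.
#'
#' @param omega_ar aragonite saturation state (> 0).
#' @param alpha seasonal intercept.
#' @param exponent_b power-law exponent.
#' @return Predicted transparency.
#' @examples
#' predict_d4t(1.5, alpha = 0.82)  # 0.9087
#' @export
predict_d4t <- function(omega_ar, alpha, exponent_b = 0.255) {
  if (any(!is.finite(omega_ar)) || any(omega_ar <= 0))
    stop("omega_ar must be positive", call. = FALSE)
  alpha * omega_ar^exponent_b
}

#' Fit the duration effect on shell transparency
#'
#' Regresses the transparency deficit (observed minus D4T) on exposure
#' duration by OLS, over medium/high-treatment records only: ambient
#' exposures (above the ~1.5 saturation-state response threshold) show no
#' duration effect and are excluded.
#'
#' @param records data.frame with columns `season`, `treatment`
#'   (`"ambient"`, `"medium"`, `"high"`), `omega_ar`, `duration_days`,
#'   `transparency`.
#' @param alpha_by_season named numeric vector of per-season intercepts.
#' @param exponent_b power-law exponent used for the D4T baseline.
#' @return A list with `duration_slope` (transparency per day), `beta`
#'   (intercept), `n`, and the underlying `fit`.
#' @export
fit_duration_effect <- function(records, alpha_by_season,
                                exponent_b = 0.255) {
  need <- c("season", "treatment", "omega_ar", "duration_days",
            "transparency")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec <- records[records$treatment != "ambient", , drop = FALSE]
  if (!nrow(rec))
    stop("duration regression needs medium/high records; ambient-only input",
         call. = FALSE)
  if (length(unique(rec$duration_days)) < 2)
    stop("need >= 2 distinct exposure durations", call. = FALSE)
  alpha <- alpha_by_season[as.character(rec$season)]
  if (any(is.na(alpha)))
    stop("alpha_by_season lacks entries for some seasons", call. = FALSE)
  deficit <- rec$transparency -
    predict_d4t(rec$omega_ar, unname(alpha), exponent_b)
  fit <- stats::lm(deficit ~ rec$duration_days)
  list(duration_slope = unname(stats::coef(fit)[2]),
       beta = unname(stats::coef(fit)[1]),
       n = nrow(rec), fit = fit)
}

#' Fit the seasonal shell-transparency calibration model
#'
#' Runs the full calibration chain on per-individual transparency records
#' from the seasonal CO2-exposure design:
#'
#' 1. a power law `T = alpha_s * Omega^b_s` is fit per season to the Day-4
#'    records (log-log OLS);
#' 2. the cross-season exponent `b` is the mean of the per-season
#'    exponents (SE = SD/sqrt(n_seasons));
#' 3. if Day-0 (field) transparencies are supplied, the seasonal
#'    intercepts are calibrated linearly against them and the pristine
#'    intercept is the line evaluated at `day0_pristine`;
#' 4. the duration effect is an OLS regression of the deficit
#'    (observed - D4T) on exposure duration over medium/high records.
#'
#' @param data data.frame with columns `season`, `treatment` (levels
#'   `"ambient"`, `"medium"`, `"high"`), `omega_ar`, `duration_days` and
#'   `transparency`, e.g. from [generate_transparency_dataset()] or from
#'   [score_shell_images()] joined with [carb_solve()] output.
#' @param day0 optional named numeric vector (by season) of Day-0 field
#'   transparencies; enables the alpha-vs-Day-0 line. Taken from
#'   `attr(data, "day0_by_season")` when present.
#' @param day0_pristine Day-0 transparency of a pristine shell at which
#'   the alpha line is evaluated (default 0.90, the highest observed).
#' @param reference_day the exposure duration (days) whose records anchor
#'   the power fits and the D4T baseline.
#' @param method power-fit method, see [fit_power_per_season()].
#' @return An object of class `"shellcal"`: a list with elements
#'   `seasons` (per-season alpha/exponent table), `exponent_b`,
#'   `exponent_se`, `alpha_by_season`, `alpha_line`, `alpha_pristine`,
#'   `duration_slope`, `beta`, `n`, `data`, `call`.
#' @seealso [predict.shellcal()], [simulate.shellcal()],
#'   [exposure_envelope()]
#' @examples
#' d <- generate_transparency_dataset(generator_config(), seed = 1)
#' fit <- fit_transparency_model(d)
#' coef(fit)
#' @export
fit_transparency_model <- function(data, day0 = attr(data, "day0_by_season"),
                                   day0_pristine = 0.90, reference_day = 4,
                                   method = c("loglog", "nls")) {
  method <- match.arg(method)
  cl <- match.call()
  d4 <- data[data$duration_days == reference_day, , drop = FALSE]
  if (!nrow(d4))
    stop("no records at the reference duration (", reference_day, " d)",
         call. = FALSE)
  seasons <- unique(as.character(d4$season))
  per <- lapply(seasons, function(s) {
    sub <- d4[d4$season == s, ]
    fit_power_per_season(sub$omega_ar, sub$transparency, method)
  })
  alpha_by_season <- stats::setNames(vapply(per, `[[`, 0, "alpha"), seasons)
  exps <- stats::setNames(vapply(per, `[[`, 0, "exponent"), seasons)
  avg <- if (length(exps) >= 2) average_exponent(exps) else
    list(mean = unname(exps), se = NA_real_)

  alpha_line <- NULL
  alpha_pristine <- NA_real_
  if (!is.null(day0)) {
    day0 <- day0[seasons]
    if (any(is.na(day0)))
      stop("day0 lacks entries for some seasons", call. = FALSE)
    lf <- stats::lm(alpha_by_season ~ day0)
    alpha_line <- c(slope = unname(stats::coef(lf)[2]),
                    intercept = unname(stats::coef(lf)[1]),
                    r2 = summary(lf)$r.squared)
    alpha_pristine <- unname(alpha_line["slope"] * day0_pristine +
                               alpha_line["intercept"])
  }

  dur <- tryCatch(
    fit_duration_effect(data, alpha_by_season, avg$mean),
    error = function(e) list(duration_slope = NA_real_, beta = NA_real_,
                             n = 0L, fit = NULL))

  structure(list(
    seasons = data.frame(season = seasons, alpha = unname(alpha_by_season),
                         exponent = unname(exps),
                         n = vapply(per, `[[`, 0L, "n")),
    exponent_b = avg$mean, exponent_se = avg$se,
    alpha_by_season = alpha_by_season,
    alpha_line = alpha_line, alpha_pristine = alpha_pristine,
    day0 = day0, day0_pristine = day0_pristine,
    duration_slope = dur$duration_slope, beta = dur$beta,
    duration_n = dur$n, reference_day = reference_day,
    n = nrow(data), data = data, call = cl), class = "shellcal")
}

#' @export
print.shellcal <- function(x, digits = 4, ...) {
  cat("Seasonal shell-transparency calibration (T = alpha * Omega^b)\n")
  cat(sprintf("  %d records, %d seasons\n", x$n, nrow(x$seasons)))
  cat(sprintf("  exponent b: %.*g (SE %.*g, n = %d seasons)\n",
              digits, x$exponent_b, digits, x$exponent_se, nrow(x$seasons)))
  cat(sprintf("  duration slope: %.*g transparency/day, beta: %.*g (n = %d)\n",
              digits, x$duration_slope, digits, x$beta, x$duration_n))
  if (!is.null(x$alpha_line))
    cat(sprintf("  alpha = %.*g * Day0 %+.*g (R2 %.3f); pristine alpha %.*g\n",
                digits, x$alpha_line["slope"], digits,
                x$alpha_line["intercept"], x$alpha_line["r2"],
                digits, x$alpha_pristine))
  invisible(x)
}

#' @export
summary.shellcal <- function(object, ...) {
  structure(object, class = c("summary.shellcal", "shellcal"))
}

#' @export
print.summary.shellcal <- function(x, digits = 4, ...) {
  print.shellcal(x, digits = digits, ...)
  cat("\nPer-season power fits (Day-", x$reference_day, " records):\n",
      sep = "")
  print(x$seasons, row.names = FALSE, digits = digits)
  invisible(x)
}

#' @export
coef.shellcal <- function(object, ...) {
  c(exponent_b = object$exponent_b,
    duration_slope = object$duration_slope,
    beta = object$beta,
    alpha_pristine = object$alpha_pristine,
    stats::setNames(unname(object$alpha_by_season),
                    paste0("alpha_", names(object$alpha_by_season))))
}

#' Predict shell transparency from a fitted calibration
#'
#' Predicts `T = alpha_s * Omega^b` (the D4T baseline), plus the fitted
#' duration deficit `slope * D + beta` for records below the saturation
#' response threshold when their duration differs from the reference day.
#'
#' @param object a [fit_transparency_model()] fit.
#' @param newdata data.frame with `season`, `omega_ar`, and optionally
#'   `duration_days`; defaults to the training data.
#' @param omega_threshold saturation state above which no duration effect
#'   is applied (default 1.5, the biological response threshold).
#' @param ... unused.
#' @return Numeric vector of predicted transparencies.
#' @export
predict.shellcal <- function(object, newdata = NULL, omega_threshold = 1.5,
                             ...) {
  if (is.null(newdata)) newdata <- object$data
  alpha <- object$alpha_by_season[as.character(newdata$season)]
  if (any(is.na(alpha)))
    stop("newdata contains seasons absent from the fit", call. = FALSE)
  pred <- predict_d4t(newdata$omega_ar, unname(alpha), object$exponent_b)
  if (!is.null(newdata$duration_days) && is.finite(object$duration_slope)) {
    apply_dur <- newdata$omega_ar < omega_threshold &
      newdata$duration_days != object$reference_day
    pred[apply_dur] <- pred[apply_dur] +
      object$duration_slope * newdata$duration_days[apply_dur] + object$beta
  }
  pred
}

#' @export
residuals.shellcal <- function(object, ...) {
  object$data$transparency - predict(object)
}

#' Simulate transparency datasets from a fitted calibration
#'
#' Draws new datasets from the fitted model (per-season alphas, mean
#' exponent, duration slope) under the same design as the training data,
#' using the synthetic-data generator.
#'
#' @param object a [fit_transparency_model()] fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param noise_sd residual SD of transparency (default: SD of the fit
#'   residuals).
#' @param ... unused.
#' @return A list of `nsim` data.frames (a single data.frame if
#'   `nsim = 1`).
#' @export
simulate.shellcal <- function(object, nsim = 1, seed = NULL,
                              noise_sd = stats::sd(stats::residuals(object)),
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- generator_config(
    n_seasons = nrow(object$seasons),
    durations_days = sort(unique(object$data$duration_days)),
    noise_sd_transparency = noise_sd,
    exponent_b = object$exponent_b,
    duration_slope = if (is.finite(object$duration_slope))
      object$duration_slope else -0.0238)
  out <- lapply(seq_len(nsim), function(i)
    generate_transparency_dataset(
      cfg, seed = sample.int(.Machine$integer.max / 2, 1),
      alpha_by_season = object$alpha_by_season))
  if (nsim == 1) out[[1]] else out
}

#' Plot a fitted transparency calibration
#'
#' Two panels: per-season Day-4 transparency against saturation state with
#' the fitted power laws (log-log), and the duration regression of the
#' transparency deficit for medium/high records.
#'
#' @param x a [fit_transparency_model()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shellcal <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  d4 <- x$data[x$data$duration_days == x$reference_day, ]
  cols <- stats::setNames(seq_len(nrow(x$seasons)) + 1, x$seasons$season)
  graphics::plot(d4$omega_ar, d4$transparency, log = "xy",
                 col = cols[as.character(d4$season)], pch = 16,
                 xlab = expression(Omega[Ar]), ylab = "Transparency",
                 main = "Day-4 power fits", ...)
  for (i in seq_len(nrow(x$seasons))) {
    om <- seq(min(d4$omega_ar), max(d4$omega_ar), length.out = 50)
    graphics::lines(om, x$seasons$alpha[i] * om^x$seasons$exponent[i],
                    col = i + 1)
  }
  mh <- x$data[x$data$treatment != "ambient", ]
  if (nrow(mh) && is.finite(x$duration_slope)) {
    defic <- mh$transparency -
      predict_d4t(mh$omega_ar,
                  unname(x$alpha_by_season[as.character(mh$season)]),
                  x$exponent_b)
    graphics::plot(mh$duration_days, defic, pch = 16,
                   col = cols[as.character(mh$season)],
                   xlab = "Duration (days)",
                   ylab = "Observed - D4T", main = "Duration effect")
    graphics::abline(x$beta, x$duration_slope)
  }
  invisible(x)
}
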