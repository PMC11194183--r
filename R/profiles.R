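#' Transparency-model constants profiles
#'
#' The published calibration constants for the transparency model
#' `T = alpha * Omega^b + slope * D + beta` are printed with small mutual
#' inconsistencies in different places (the Results text, the
#' omega-inversion equation and the duration-inversion equation). No
#' attempt is made to reconcile them: each set is preserved verbatim and
#' selectable by name, so results computed with any one profile are
#' internally consistent and traceable.
#'
#' * `"results_text"` — alpha = 0.82, b = 0.255, slope = -0.0238,
#'   beta = 0.1026 (the Results-section constants).
#' * `"self_consistent"` — alias of `"results_text"`; the set recommended
#'   for exact forward/inverse round-trips.
#' * `"eq5_verbatim"` — the omega-inversion constants: alpha = 0.81,
#'   b = 0.255, slope = -0.0238, beta = -0.0344.
#' * `"eq6_verbatim"` — the duration-inversion constants: alpha = 0.82,
#'   b = 0.0255 (printed as such; 0.255 is presumably intended),
#'   slope = -0.0239, beta = 0.0555.
#'
#' @param profile profile name (or an existing `"transparency_profile"`
#'   object, returned unchanged).
#' @return A list of class `"transparency_profile"` with elements
#'   `name`, `alpha`, `exponent_b`, `duration_slope`, `beta`.
#' @examples
#' transparency_profile("eq6_verbatim")
#' @export
transparency_profile <- function(profile = c("eq5_verbatim", "eq6_verbatim",
                                             "results_text",
                                             "self_consistent")) {
  if (inherits(profile, "transparency_profile")) return(profile)
  profile <- match.arg(profile)
  p <- switch(profile,
    results_text    = list(alpha = 0.82, exponent_b = 0.255,
                           duration_slope = -0.0238, beta = 0.1026),
    self_consistent = list(alpha = 0.82, exponent_b = 0.255,
                           duration_slope = -0.0238, beta = 0.1026),
    eq5_verbatim    = list(alpha = 0.81, exponent_b = 0.255,
                           duration_slope = -0.0238, beta = -0.0344),
    eq6_verbatim    = list(alpha = 0.82, exponent_b = 0.0255,
                           duration_slope = -0.0239, beta = 0.0555))
  structure(c(list(name = profile), p), class = "transparency_profile")
}

#' @export
print.transparency_profile <- function(x, ...) {
  cat(sprintf(
    "Transparency constants profile '%s':\n  T = %.4g * Omega^%.4g %+.4g * D %+.4g\n",
    x$name, x$alpha, x$exponent_b, x$duration_slope, x$beta))
  invisible(x)
}

# Forward transparency model under a profile (duration term included).
.profile_forward <- function(omega, duration, p) {
  p$alpha * omega^p$exponent_b + p$duration_slope * duration + p$beta
}
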