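#' Constants profile for carbonate-system speciation
#'
#' Bundles the choice of dissociation constants used to speciate the seawater
#' CO2 system. Defaults match the common open-ocean CO2SYS configuration:
#' K1/K2 from the Mehrbach data as refit by Dickson and Millero (1987),
#' the bisulfate constant of Dickson (1990), the total-boron/salinity ratio
#' of Uppstrom (1974) (Lee et al. 2010 selectable), and the aragonite
#' solubility product of Mucci (1983). All computations are at surface
#' pressure (0 dbar) on the total pH scale.
#'
#' @param k1k2 carbonic-acid constants; only the Mehrbach refit is provided.
#' @param khso4 bisulfate dissociation constant source.
#' @param borate total boron-to-salinity relationship, `"uppstrom1974"` or
#'   `"lee2010"`.
#' @param ksp_aragonite aragonite solubility product source.
#' @return An object of class `"carb_constants"` (a list of the four choices
#'   plus `pressure_dbar = 0`).
#' @examples
#' carb_constants()
#' carb_constants(borate = "lee2010")
#' @export
carb_constants <- function(k1k2 = "mehrbach_refit_dickson_millero_1987",
                           khso4 = "dickson1990",
                           borate = c("uppstrom1974", "lee2010"),
                           ksp_aragonite = "mucci1983") {
  k1k2 <- match.arg(k1k2)
  khso4 <- match.arg(khso4)
  borate <- match.arg(borate)
  ksp_aragonite <- match.arg(ksp_aragonite)
  structure(list(k1k2 = k1k2, khso4 = khso4, borate = borate,
                 ksp_aragonite = ksp_aragonite, pressure_dbar = 0),
            class = "carb_constants")
}

#' @export
print.carb_constants <- function(x, ...) {
  cat("Carbonate-system constants (total pH scale, 0 dbar):\n")
  cat("  K1/K2:    ", x$k1k2, "\n")
  cat("  KHSO4:    ", x$khso4, "\n")
  cat("  Total B:  ", x$borate, "\n")
  cat("  Ksp(arag):", x$ksp_aragonite, "\n")
  invisible(x)
}

.check_st <- function(salinity, temperature) {
  if (any(!is.finite(salinity)) || any(salinity < 0) || any(salinity > 45))
    stop("salinity must be finite and within [0, 45]", call. = FALSE)
  if (any(!is.finite(temperature)) || any(temperature < -2) ||
      any(temperature > 40))
    stop("temperature must be finite and within [-2, 40] degC", call. = FALSE)
  invisible(TRUE)
}

# Equilibrium constants at (S, T, 0 dbar), total pH scale where relevant.
# Units: K0 mol kg-SW^-1 atm^-1; K1, K2, KB, KW on mol kg-SW^-1; KS, KF free
# scale; Ksp_ar mol^2 kg^-2. Totals (BT, ST, FT, Ca) mol kg-SW^-1.
.carb_k <- function(salinity, temperature, constants = carb_constants()) {
  S <- salinity
  TK <- temperature + 273.15
  lnTK <- log(TK)
  sqS <- sqrt(S)
  IonS <- 19.924 * S / (1000 - 1.005 * S)

  ST <- 0.02 / 96.062 * S / 1.80655       # total sulfate, Morris & Riley
  FT <- 0.000067 / 18.998 * S / 1.80655   # total fluoride, Riley
  BT <- switch(constants$borate,
               uppstrom1974 = 0.0004157 * S / 35,
               lee2010      = 0.0004326 * S / 35)
  Ca <- 0.02128 / 40.087 * S / 1.80655    # Riley & Tongudai convention

  # bisulfate (Dickson 1990a), free scale, converted mol/kg-H2O -> mol/kg-SW
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnTK +
    (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(IonS) +
    (35474 / TK - 771.54 + 114.723 * lnTK) * IonS -
    2698 / TK * IonS^1.5 + 1776 / TK * IonS^2
  KS <- exp(lnKS) * (1 - 0.001005 * S)

  # hydrogen fluoride (Dickson & Riley 1979), free scale
  KF <- exp(1590.2 / TK - 12.641 + 1.525 * sqrt(IonS)) * (1 - 0.001005 * S)

  free_to_tot <- 1 + ST / KS
  sws_to_tot <- (1 + ST / KS) / (1 + ST / KS + FT / KF)

  # CO2 solubility (Weiss 1974)
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)
  K0 <- exp(lnK0)

  # carbonic acid, Mehrbach refit by Dickson & Millero (1987): SWS -> total
  pK1 <- 3670.7 / TK - 62.008 + 9.7944 * lnTK - 0.0118 * S + 0.000116 * S^2
  pK2 <- 1394.7 / TK + 4.777 - 0.0184 * S + 0.000118 * S^2
  K1 <- 10^(-pK1) * sws_to_tot
  K2 <- 10^(-pK2) * sws_to_tot

  # boric acid (Dickson 1990b), already total scale
  lnKB <- (-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * S +
    (-24.4344 - 25.085 * sqS - 0.2474 * S) * lnTK +
    0.053105 * sqS * TK
  KB <- exp(lnKB)

  # water (Millero 1995), SWS -> total
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnTK +
    (118.67 / TK - 5.977 + 1.0495 * lnTK) * sqS - 0.01615 * S
  KW <- exp(lnKW) * sws_to_tot

  # aragonite solubility (Mucci 1983)
  log10Kar <- -171.945 - 0.077993 * TK + 2903.293 / TK +
    71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqS -
    0.10018 * S + 0.0059415 * S^1.5
  Kar <- 10^log10Kar

  list(K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, KS = KS, KF = KF,
       Kar = Kar, BT = BT, ST = ST, FT = FT, Ca = Ca,
       free_to_tot = free_to_tot)
}

# Total alkalinity (mol/kg) implied by total-scale [H+], DIC in mol/kg.
.ta_from_h <- function(h, dic, k) {
  hfree <- h / k$free_to_tot
  denom <- h * h + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  balk <- k$BT * k$KB / (k$KB + h)
  oh <- k$KW / h
  hso4 <- k$ST / (1 + k$KS / hfree)
  hf <- k$FT / (1 + k$KF / hfree)
  hco3 + 2 * co3 + balk + oh - hfree - hso4 - hf
}

.speciate_at_ph <- function(ph, dic, k) {
  h <- 10^(-ph)
  denom <- h * h + k$K1 * h + k$K1 * k$K2
  co2 <- dic * h * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  list(pco2 = co2 / k$K0 * 1e6,             # uatm
       omega_ar = k$Ca * co3 / k$Kar)
}

#' Solve the seawater CO2 system from a DIC-TA pair
#'
#' Finds the total-scale pH at which the modelled total alkalinity
#' (carbonate + borate + water + bisulfate + fluoride terms; zero nutrients)
#' matches the measured TA, then derives pCO2 and the aragonite saturation
#' state. The pH root is bracketed on \[5.5, 9.5\] and solved to a TA
#' residual below 1e-3 umol kg-1.
#'
#' @param dic dissolved inorganic carbon, umol kg-1.
#' @param ta total alkalinity, umol kg-1.
#' @param salinity practical salinity.
#' @param temperature temperature, degC.
#' @param constants a [carb_constants()] profile.
#' @return A one-row data.frame of class `"water_sample"` with columns
#'   `salinity`, `temperature_C`, `dic_umol_kg`, `ta_umol_kg`, `ph`
#'   (total scale), `pco2_uatm`, `omega_ar`. Vector inputs recycle to
#'   multiple rows.
#' @examples
#' solve_from_dic_ta(2101.1, 2248.2, 32, 8.02)  # ~ pH 7.95, omega_ar 1.69
#' @seealso [solve_from_ph_ta()], [carb_solve()]
#' @export
solve_from_dic_ta <- function(dic, ta, salinity, temperature,
                              constants = carb_constants()) {
  n <- max(length(dic), length(ta), length(salinity), length(temperature))
  dic <- rep_len(dic, n); ta <- rep_len(ta, n)
  salinity <- rep_len(salinity, n); temperature <- rep_len(temperature, n)
  .check_st(salinity, temperature)
  if (any(!is.finite(dic)) || any(dic <= 0) ||
      any(!is.finite(ta)) || any(ta <= 0))
    stop("dic and ta must be finite and positive (umol kg-1)", call. = FALSE)

  ph <- pco2 <- omega <- numeric(n)
  for (i in seq_len(n)) {
    k <- .carb_k(salinity[i], temperature[i], constants)
    dic_m <- dic[i] * 1e-6
    ta_m <- ta[i] * 1e-6
    f <- function(p) .ta_from_h(10^(-p), dic_m, k) - ta_m
    root <- tryCatch(
      stats::uniroot(f, interval = c(5.5, 9.5), tol = 1e-11),
      error = function(e) stop(sprintf(
        "carbonate solver failed to bracket a pH root for input row %d (DIC=%g, TA=%g)",
        i, dic[i], ta[i]), call. = FALSE))
    ph[i] <- root$root
    if (abs(f(ph[i])) * 1e6 > 1e-3)
      stop(sprintf("carbonate solver did not converge for input row %d", i),
           call. = FALSE)
    sp <- .speciate_at_ph(ph[i], dic_m, k)
    pco2[i] <- sp$pco2
    omega[i] <- sp$omega_ar
  }
  out <- data.frame(salinity = salinity, temperature_C = temperature,
                    dic_umol_kg = dic, ta_umol_kg = ta, ph = ph,
                    pco2_uatm = pco2, omega_ar = omega)
  class(out) <- c("water_sample", "data.frame")
  out
}

#' Solve the seawater CO2 system from a pH-TA pair
#'
#' Closed-form speciation at a fixed total-scale pH: the carbonate
#' alkalinity is the measured TA minus the borate/water/bisulfate/fluoride
#' terms, which yields DIC directly, then pCO2 and the aragonite saturation
#' state. Round-trips with [solve_from_dic_ta()] on (pH, DIC).
#'
#' @param ph total-scale pH, within \[6, 9\].
#' @inheritParams solve_from_dic_ta
#' @return A `"water_sample"` data.frame as in [solve_from_dic_ta()].
#' @examples
#' solve_from_ph_ta(7.95, 2248.2, 32, 8.02)  # DIC ~ 2101 umol kg-1
#' @export
solve_from_ph_ta <- function(ph, ta, salinity, temperature,
                             constants = carb_constants()) {
  n <- max(length(ph), length(ta), length(salinity), length(temperature))
  ph <- rep_len(ph, n); ta <- rep_len(ta, n)
  salinity <- rep_len(salinity, n); temperature <- rep_len(temperature, n)
  .check_st(salinity, temperature)
  if (any(!is.finite(ph)) || any(ph < 6) || any(ph > 9))
    stop("ph must be within [6, 9] (total scale)", call. = FALSE)
  if (any(!is.finite(ta)) || any(ta <= 0))
    stop("ta must be finite and positive (umol kg-1)", call. = FALSE)

  dic <- pco2 <- omega <- numeric(n)
  for (i in seq_len(n)) {
    k <- .carb_k(salinity[i], temperature[i], constants)
    h <- 10^(-ph[i])
    hfree <- h / k$free_to_tot
    calk <- ta[i] * 1e-6 -
      (k$BT * k$KB / (k$KB + h) + k$KW / h - hfree -
         k$ST / (1 + k$KS / hfree) - k$FT / (1 + k$KF / hfree))
    denom <- h * h + k$K1 * h + k$K1 * k$K2
    dic_m <- calk * denom / (k$K1 * h + 2 * k$K1 * k$K2)
    if (!is.finite(dic_m) || dic_m <= 0)
      stop(sprintf("pH-TA pair in row %d implies non-positive DIC", i),
           call. = FALSE)
    sp <- .speciate_at_ph(ph[i], dic_m, k)
    dic[i] <- dic_m * 1e6
    pco2[i] <- sp$pco2
    omega[i] <- sp$omega_ar
  }
  out <- data.frame(salinity = salinity, temperature_C = temperature,
                    dic_umol_kg = dic, ta_umol_kg = ta, ph = ph,
                    pco2_uatm = pco2, omega_ar = omega)
  class(out) <- c("water_sample", "data.frame")
  out
}

#' Aragonite saturation state from a carbonate-ion concentration
#'
#' Omega = \[Ca2+\]\[CO3 2-\] / Ksp(aragonite), with \[Ca2+\] proportional to
#' salinity and Ksp from Mucci (1983). Omega < 1 means seawater is
#' thermodynamically corrosive to aragonite.
#'
#' @param co3 carbonate-ion concentration, mol kg-1.
#' @inheritParams solve_from_dic_ta
#' @return Dimensionless saturation state (vectorised).
#' @examples
#' k <- shellcal:::.carb_k(32, 8)
#' omega_aragonite(k$Kar / k$Ca, 32, 8)  # exactly 1 at saturation
#' @export
omega_aragonite <- function(co3, salinity, temperature,
                            constants = carb_constants()) {
  .check_st(salinity, temperature)
  if (any(!is.finite(co3)) || any(co3 <= 0))
    stop("co3 must be finite and positive (mol kg-1)", call. = FALSE)
  n <- max(length(co3), length(salinity), length(temperature))
  co3 <- rep_len(co3, n); salinity <- rep_len(salinity, n)
  temperature <- rep_len(temperature, n)
  vapply(seq_len(n), function(i) {
    k <- .carb_k(salinity[i], temperature[i], constants)
    k$Ca * co3[i] / k$Kar
  }, numeric(1))
}

#' Batch speciation of a sample table
#'
#' Applies [solve_from_dic_ta()] (`pair = "dic-ta"`) or [solve_from_ph_ta()]
#' (`pair = "ph-ta"`) to each row of a data.frame with columns
#' `salinity`, `temperature_C`, and `dic_umol_kg`/`ta_umol_kg` or
#' `ph`/`ta_umol_kg`. Extra columns (e.g. `sample_id`) are carried through.
#'
#' @param samples a data.frame of water samples.
#' @param pair which measured pair to speciate from.
#' @param constants a [carb_constants()] profile.
#' @return `samples` with `ph`, `dic_umol_kg`, `pco2_uatm`, `omega_ar`
#'   filled in.
#' @export
carb_solve <- function(samples, pair = c("dic-ta", "ph-ta"),
                       constants = carb_constants()) {
  pair <- match.arg(pair)
  stopifnot(is.data.frame(samples))
  need <- c("salinity", "temperature_C", "ta_umol_kg",
            if (pair == "dic-ta") "dic_umol_kg" else "ph")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  sol <- if (pair == "dic-ta") {
    solve_from_dic_ta(samples$dic_umol_kg, samples$ta_umol_kg,
                      samples$salinity, samples$temperature_C, constants)
  } else {
    solve_from_ph_ta(samples$ph, samples$ta_umol_kg,
                     samples$salinity, samples$temperature_C, constants)
  }
  samples$ph <- sol$ph
  samples$dic_umol_kg <- sol$dic_umol_kg
  samples$pco2_uatm <- sol$pco2_uatm
  samples$omega_ar <- sol$omega_ar
  samples
}
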