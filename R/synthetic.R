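#' Mean carbonate chemistry of the seasonal exposure experiments
#'
#' The per-season, per-treatment mean (and SD where printed) carbonate
#' system state of the five seasonal laboratory exposures: salinity,
#' temperature, DIC, TA, measured pH, and the computed pCO2 and aragonite
#' saturation state. These values parameterise the synthetic-data
#' generators and anchor the carbonate-solver tests.
#'
#' @return A 15-row data.frame with columns `season`, `treatment`,
#'   `salinity`, `temperature_C`, `dic_umol_kg`, `ta_umol_kg`, `ph`,
#'   `pco2_uatm`, `pco2_sd`, `omega_ar`, `omega_sd`.
#' @export
seasonal_chemistry <- function() {
  data.frame(
    season = rep(c("Jan14", "Apr14", "Aug14", "Nov14", "Apr15"), each = 3),
    treatment = rep(c("ambient", "medium", "high"), 5),
    salinity = rep(c(32, 34, 34, 33, 33), each = 3),
    temperature_C = rep(c(8.02, 8.05, 7.77, 7.57, 8.04), each = 3),
    dic_umol_kg = c(2101.1, 2177.8, 2224.6, 2084.7, 2167.0, 2202.8,
                    2039.8, 2113.4, 2154.0, 2084.6, 2150.8, 2199.7,
                    2081.3, 2152.3, 2202.0),
    ta_umol_kg = c(2248.2, 2250.0, 2257.2, 2219.0, 2223.4, 2219.2,
                   2182.5, 2188.3, 2189.7, 2210.7, 2198.8, 2202.4,
                   2218.5, 2221.8, 2216.8),
    ph = c(7.95, 7.73, 7.59, 7.97, 7.74, 7.60, 8.02, 7.75, 7.64,
           8.01, 7.71, 7.58, 7.99, 7.78, 7.59),
    pco2_uatm = c(421, 728, 1016, 471, 852, 1189, 430, 718, 985,
                  476, 864, 1310, 449, 750, 1183),
    pco2_sd = c(14, 13, 32, 11, 20, 45, 14, 40, 39, 17, 14, 58, 3, 35, 61),
    omega_ar = c(1.69, 1.08, 0.81, 1.54, 0.95, 0.71, 1.60, 1.07, 0.80,
                 1.48, 0.88, 0.63, 1.58, 1.04, 0.70),
    omega_sd = c(0.05, 0.02, 0.03, 0.03, 0.02, 0.02, 0.04, 0.06, 0.03,
                 0.03, 0.01, 0.02, 0.01, 0.04, 0.02))
}

#' Configuration for the synthetic-data generators
#'
#' Encodes the seasonal exposure design and the transparency model the
#' generators draw from: five seasons x three CO2 treatments (saturation
#' states from [seasonal_chemistry()]), exposure durations 1.5-15 days,
#' seven individuals per cell, a power-law transparency response with
#' additive Gaussian noise and a biological floor, and expression matrices
#' with a planted subset of saturation-correlated genes.
#'
#' @param n_seasons number of seasons (<= 5 uses the observed seasonal
#'   chemistry; more recycles it).
#' @param treatments data.frame with columns `season`, `treatment`,
#'   `omega_ar`, `omega_sd` giving the per-cell saturation-state
#'   distributions (default from [seasonal_chemistry()]).
#' @param durations_days exposure durations sampled, days.
#' @param n_per_cell individuals per season x treatment x duration cell
#'   (default 7, the experiments' average replication).
#' @param noise_sd_transparency additive Gaussian residual SD of
#'   transparency.
#' @param transparency_floor lower biological limit of transparency.
#' @param alpha_range range of the per-season power-law intercepts
#'   (pristine alpha 0.82 down to a winter-exposed 0.55).
#' @param exponent_b power-law exponent of transparency on saturation
#'   state.
#' @param duration_slope change in transparency per day of exposure below
#'   the response threshold (negative).
#' @param beta empirical intercept of the deficit-vs-duration regression
#'   (kept for the constants profiles; the structural generator anchors
#'   the deficit at zero on the Day-4 baseline).
#' @param omega_range if non-NULL, draw saturation states uniformly from
#'   this range instead of the per-treatment distributions.
#' @param n_genes,n_strong,n_very_strong expression-matrix sizes: total
#'   genes, genes planted with `|r| > 0.5`, and genes planted with
#'   `r^2 > 0.4` (`n_very_strong <= n_strong <= n_genes`).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_seasons = 5,
                             treatments = NULL,
                             durations_days = c(1.5, 4, 8, 15),
                             n_per_cell = 7,
                             noise_sd_transparency = 0.03,
                             transparency_floor = 0.40,
                             alpha_range = c(0.55, 0.82),
                             exponent_b = 0.255,
                             duration_slope = -0.0238,
                             beta = 0.1026,
                             omega_range = NULL,
                             n_genes = 2000, n_strong = 229,
                             n_very_strong = 30) {
  if (is.null(treatments)) {
    chem <- seasonal_chemistry()
    treatments <- chem[c("season", "treatment", "omega_ar", "omega_sd")]
  }
  stopifnot(n_seasons >= 1, n_per_cell >= 1,
            all(durations_days >= 0), noise_sd_transparency >= 0,
            length(alpha_range) == 2, alpha_range[1] <= alpha_range[2],
            exponent_b > 0, duration_slope <= 0,
            n_very_strong <= n_strong, n_strong <= n_genes)
  if (transparency_floor >= alpha_range[1])
    stop("transparency_floor must sit below the lowest seasonal intercept",
         call. = FALSE)
  structure(list(
    n_seasons = n_seasons, treatments = treatments,
    durations_days = durations_days, n_per_cell = n_per_cell,
    noise_sd_transparency = noise_sd_transparency,
    transparency_floor = transparency_floor, alpha_range = alpha_range,
    exponent_b = exponent_b, duration_slope = duration_slope, beta = beta,
    omega_range = omega_range, n_genes = n_genes, n_strong = n_strong,
    n_very_strong = n_very_strong), class = "generator_config")
}

#' Generate a synthetic transparency dataset
#'
#' Draws per-individual transparency records from the seasonal exposure
#' design: per season a power-law intercept alpha (uniform in
#' `alpha_range`, unless supplied), per record a saturation state from its
#' treatment's distribution (or uniformly from `omega_range`), then
#' `T = alpha * Omega^b`, plus for medium/high treatments the duration
#' deficit `slope * (D - 4)` (zero at the Day-4 baseline that defines
#' D4T), plus additive Gaussian noise, truncated to the biological floor
#' and to at most 1. Deterministic given `seed`.
#'
#' The per-season Day-0 field transparencies implied by the alpha
#' calibration line (alpha = 1.0293 day0 - 0.1087) are attached as
#' attribute `day0_by_season`, so the full calibration chain (including
#' the alpha-vs-Day-0 line) can be refit on generated data.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param alpha_by_season optional named vector of per-season intercepts
#'   (overrides the uniform draw).
#' @return A data.frame with columns `individual_id`, `season`,
#'   `treatment`, `omega_ar`, `duration_days`, `transparency`.
#' @examples
#' d <- generate_transparency_dataset(generator_config(), seed = 42)
#' head(d)
#' @export
generate_transparency_dataset <- function(config = generator_config(),
                                          seed = NULL,
                                          alpha_by_season = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  chem <- config$treatments
  seasons <- rep_len(unique(as.character(chem$season)), config$n_seasons)
  if (is.null(alpha_by_season)) {
    alpha_by_season <- stats::setNames(
      stats::runif(length(seasons), config$alpha_range[1],
                   config$alpha_range[2]), seasons)
  } else {
    alpha_by_season <- alpha_by_season[seasons]
    if (any(is.na(alpha_by_season)))
      stop("alpha_by_season lacks entries for some seasons", call. = FALSE)
  }
  treatments <- unique(as.character(chem$treatment))
  grid <- expand.grid(rep = seq_len(config$n_per_cell),
                      treatment = treatments,
                      duration_days = config$durations_days,
                      season = seasons, stringsAsFactors = FALSE)
  n <- nrow(grid)
  if (is.null(config$omega_range)) {
    key <- paste(grid$season, grid$treatment)
    ckey <- paste(chem$season, chem$treatment)
    mu <- chem$omega_ar[match(key, ckey)]
    sd <- chem$omega_sd[match(key, ckey)]
    omega <- pmax(stats::rnorm(n, mu, sd), 0.05)
  } else {
    omega <- stats::runif(n, config$omega_range[1], config$omega_range[2])
  }
  alpha <- alpha_by_season[grid$season]
  deficit <- ifelse(grid$treatment == "ambient", 0,
                    config$duration_slope * (grid$duration_days - 4))
  tr <- unname(alpha) * omega^config$exponent_b + deficit +
    stats::rnorm(n, 0, config$noise_sd_transparency)
  tr <- pmin(pmax(tr, config$transparency_floor), 1)
  out <- data.frame(individual_id = sprintf("ind%04d", seq_len(n)),
                    season = grid$season, treatment = grid$treatment,
                    omega_ar = omega, duration_days = grid$duration_days,
                    transparency = tr)
  attr(out, "alpha_by_season") <- alpha_by_season
  attr(out, "day0_by_season") <- (alpha_by_season + 0.1087) / 1.0293
  out
}

#' Generate synthetic shell micrographs
#'
#' For each target transparency, builds a white-background (255) greyscale
#' image containing an elliptical shell whose mean intensity equals
#' `target * 255` (to well under one grey level), optionally with a
#' punched square hole carrying a matching exclusion polygon. Scoring the
#' images with [segment_shell()] and [transparency_score()] recovers the
#' targets.
#'
#' @param transparency_targets numeric vector of targets in (0, 1\].
#' @param size image side length, pixels.
#' @param hole punch a dark square hole (intensity 0) into each shell and
#'   record it as an exclusion polygon.
#' @param seed integer seed for the ellipse geometry.
#' @return A list of [shell_image()] objects, each with attributes
#'   `target` and `exclusions` (a list of polygons, possibly empty).
#' @export
generate_shell_images <- function(transparency_targets, size = 64,
                                  hole = FALSE, seed = NULL) {
  if (any(transparency_targets <= 0) || any(transparency_targets > 1))
    stop("transparency targets must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(transparency_targets, function(target) {
    cr <- size / 2 + stats::runif(1, -2, 2)
    cc <- size / 2 + stats::runif(1, -2, 2)
    a <- stats::runif(1, size / 4, size / 3)
    b <- stats::runif(1, size / 5, size / 3.5)
    px <- matrix(255L, size, size)
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    inside <- ((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1
    px[inside] <- as.integer(round(target * 255))
    exclusions <- list()
    if (hole) {
      r0 <- floor(cr - 3); r1 <- floor(cr); c0 <- floor(cc - 3); c1 <- floor(cc)
      px[r0:r1, c0:c1] <- 0L
      # polygon drawn half a pixel beyond the hole pixel centres
      exclusions <- list(cbind(c(r0 - .5, r0 - .5, r1 + .5, r1 + .5),
                               c(c0 - .5, c1 + .5, c1 + .5, c0 - .5)))
    }
    img <- shell_image(px)
    attr(img, "target") <- target
    attr(img, "exclusions") <- exclusions
    img
  })
}

#' Generate a synthetic duration-regression dataset
#'
#' Emulates the duration experiments in the form the deficit regression
#' models them: medium/high-treatment individuals at each exposure
#' duration, with transparency built as the D4T baseline (known per-season
#' alpha, exponent `b`) plus a deficit *linear in duration*
#' (`slope * D + beta`) plus additive Gaussian noise. The biological floor
#' is not applied here: the deficit is the modelled quantity and the
#' generating model is exactly the linear one the regression assumes, so
#' refitting recovers `duration_slope` without truncation bias.
#'
#' @param config a [generator_config()] (`duration_slope`, `beta`,
#'   `exponent_b`, `noise_sd_transparency`, `durations_days`,
#'   `n_per_cell`, `alpha_range` and the treatment saturation-state
#'   distributions are used).
#' @param seed integer seed.
#' @return A transparency-record data.frame (medium/high only) with the
#'   generating intercepts in attribute `alpha_by_season`.
#' @seealso [fit_duration_effect()]
#' @export
generate_duration_dataset <- function(config = generator_config(),
                                      seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  chem <- config$treatments
  chem <- chem[chem$treatment != "ambient", , drop = FALSE]
  seasons <- unique(as.character(chem$season))
  alpha_by_season <- stats::setNames(
    stats::runif(length(seasons), config$alpha_range[1],
                 config$alpha_range[2]), seasons)
  grid <- expand.grid(rep = seq_len(config$n_per_cell),
                      treatment = unique(as.character(chem$treatment)),
                      duration_days = config$durations_days,
                      season = seasons, stringsAsFactors = FALSE)
  n <- nrow(grid)
  key <- paste(grid$season, grid$treatment)
  ckey <- paste(chem$season, chem$treatment)
  omega <- pmax(stats::rnorm(n, chem$omega_ar[match(key, ckey)],
                             chem$omega_sd[match(key, ckey)]), 0.05)
  tr <- unname(alpha_by_season[grid$season]) * omega^config$exponent_b +
    config$duration_slope * grid$duration_days + config$beta +
    stats::rnorm(n, 0, config$noise_sd_transparency)
  out <- data.frame(individual_id = sprintf("ind%04d", seq_len(n)),
                    season = grid$season, treatment = grid$treatment,
                    omega_ar = omega, duration_days = grid$duration_days,
                    transparency = tr)
  attr(out, "alpha_by_season") <- alpha_by_season
  out
}

#' Generate a synthetic respiration-chamber dataset
#'
#' Emulates the closed-chamber respiration design: per season a baseline
#' mass-specific rate (elevated in April, the spring bloom), chamber
#' volumes of 2-3 ml, ~24-h incubations at the season's holding
#' temperature (5.6 degC for the August chiller failure, else ~8 degC),
#' animal wet masses around 5 mg, and a control (animal-free) chamber
#' every fourth position with only weak bacterial O2 uptake
#' (0.0002 umol h^-1).
#'
#' @param config a [generator_config()] (season list reused).
#' @param seed integer seed.
#' @param n_per_treatment animal chambers per season x treatment.
#' @return A data.frame ready for [oxygen_consumption_rate()], with the
#'   true generating rate in `rate_true_umol_gwm_h`.
#' @export
generate_respiration_dataset <- function(config = generator_config(),
                                         seed = NULL,
                                         n_per_treatment = 8) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  seasons <- unique(as.character(config$treatments$season))
  base <- stats::setNames(
    rep_len(c(0.45, 0.95, 0.55, 0.40, 0.60), length(seasons)), seasons)
  temp <- stats::setNames(rep_len(c(8.1, 8.0, 5.6, 7.9, 8.1),
                                  length(seasons)), seasons)
  treatments <- unique(as.character(config$treatments$treatment))
  grid <- expand.grid(rep = seq_len(n_per_treatment),
                      treatment = treatments, season = seasons,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  is_control <- seq_len(n) %% 4 == 0
  vol_ml <- stats::runif(n, 2, 3)
  mass_g <- stats::rlnorm(n, log(0.005), 0.25)
  elapsed <- stats::rnorm(n, 24, 0.5)
  rate <- pmax(stats::rnorm(n, base[grid$season], 0.12), 0.02)
  o2_init <- stats::rnorm(n, 310, 5)
  uptake_h <- ifelse(is_control, 0.0002, rate * mass_g)   # umol h^-1
  drop <- uptake_h * elapsed / (vol_ml / 1000)            # umol l^-1
  data.frame(individual_id = sprintf("ch%04d", seq_len(n)),
             season = grid$season, treatment = grid$treatment,
             o2_initial_umol_l = o2_init, o2_final_umol_l = o2_init - drop,
             elapsed_h = elapsed, chamber_volume_ml = vol_ml,
             animal_wet_mass_g = mass_g,
             temp_mean_C = unname(temp[grid$season]) +
               stats::rnorm(n, 0, 0.1),
             is_control = is_control, alive = TRUE,
             rate_true_umol_gwm_h = ifelse(is_control, NA, rate))
}

#' Generate a synthetic TMM-like expression matrix with planted biomarkers
#'
#' Builds a genes x samples abundance matrix over the 36-sample seasonal
#' design (four seasons x three treatments x three replicates), with each
#' sample's saturation state drawn from its treatment's distribution.
#' `n_strong` genes are planted with log(1 + x) expression linear in
#' saturation state at noise levels targeting `|r| > 0.5` (of which
#' `n_very_strong` target `r^2 > 0.4`); the remaining genes carry seasonal
#' block effects but no saturation-state dependence. Values are
#' non-negative TMM-like abundances.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param n_replicates replicates per season x treatment.
#' @return A list with `values` (matrix, genes x samples), `meta`
#'   (data.frame: `sample_id`, `season`, `treatment`, `omega_ar`) and
#'   `planted` (data.frame: `gene`, `class` in
#'   `"strong"`/`"very_strong"`/`"background"`).
#' @export
generate_expression_matrix <- function(config = generator_config(),
                                       seed = NULL, n_replicates = 3) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  chem <- config$treatments
  seasons <- utils::head(unique(as.character(chem$season)), 4)  # 2014 design
  treatments <- unique(as.character(chem$treatment))
  meta <- expand.grid(rep = seq_len(n_replicates), treatment = treatments,
                      season = seasons, stringsAsFactors = FALSE)
  key <- paste(meta$season, meta$treatment)
  ckey <- paste(chem$season, chem$treatment)
  meta$omega_ar <- pmax(stats::rnorm(nrow(meta),
                                     chem$omega_ar[match(key, ckey)],
                                     chem$omega_sd[match(key, ckey)]), 0.05)
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  ns <- nrow(meta)

  ng <- config$n_genes
  cls <- rep("background", ng)
  cls[seq_len(config$n_strong)] <- "strong"
  cls[seq_len(config$n_very_strong)] <- "very_strong"
  om_c <- meta$omega_ar - mean(meta$omega_ar)
  logv <- matrix(0, ng, ns)
  for (g in seq_len(ng)) {
    if (cls[g] == "background") {
      block <- stats::setNames(stats::rnorm(length(seasons), 0, 0.4),
                               seasons)
      logv[g, ] <- stats::runif(1, 2.5, 4.5) + block[meta$season] +
        stats::rnorm(ns, 0, 0.5)
    } else {
      # plant the target *sample* correlation exactly: residual noise is
      # orthogonalised against omega, then scaled to the implied SD
      r_target <- if (cls[g] == "very_strong")
        stats::runif(1, 0.70, 0.90) else stats::runif(1, 0.53, 0.60)
      slope <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
      e <- stats::rnorm(ns)
      e <- stats::residuals(stats::lm(e ~ om_c))
      e <- e / stats::sd(e) * abs(slope) * stats::sd(om_c) *
        sqrt(1 / r_target^2 - 1)
      logv[g, ] <- stats::runif(1, 2.5, 4.5) + slope * om_c + e
    }
  }
  logv[logv < 0] <- 0
  values <- expm1(logv)
  rownames(values) <- sprintf("gene%05d", seq_len(ng))
  colnames(values) <- meta$sample_id
  list(values = values,
       meta = meta[c("sample_id", "season", "treatment", "omega_ar")],
       planted = data.frame(gene = rownames(values), class = cls))
}
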