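# Seeded generator of randomized-block N-rate trials with a known
# ground-truth dilution curve, so the whole construction/validation/diagnosis
# pipeline can be tested by parameter recovery without external data.

#' Configuration for a synthetic N-rate trial
#'
#' Defines the study conditions the generator emulates: a single-factor
#' randomized block design with six N rates (0--300 kg/ha in 60 kg/ha steps),
#' four replicate blocks, and four diagnostic growth stages, whose whole-plant
#' N concentration follows a known power-law dilution curve
#' `Nc = true_a * DW^-true_b`, with luxury uptake above the curve at
#' supra-optimal rates and sub-critical depression below it at deficient
#' rates, plus multiplicative lognormal replicate noise.
#'
#' Biomass responds to effective N supply (`soil_n_supply + n_rate`) through a
#' Michaelis-type saturating factor with half-saturation
#' `supply_half_saturation`, hard-plateaued at `optimal_rate` so that all
#' rates at or above the optimum share exactly the stage's potential biomass
#' and form a clean non-limited group.
#'
#' Sub-optimal (N-limited) treatments place their noiseless concentrations on
#' a straight line through the stage's true critical point
#' `(W_max, true_a * W_max^-true_b)` with slope equal to the curve tangent
#' divided by `1 + deficiency_slope`; being shallower than the tangent of a
#' convex curve, this line lies strictly below the dilution curve away from
#' the plateau, and the intersection-rule construction recovers the true
#' curve exactly on noiseless data. With `deficiency_slope = 0` (and
#' `luxury_slope = 0`) every noiseless point sits exactly on the curve
#' instead.
#'
#' @param n_rates N application rates, kg N/ha (default 0--300 by 60).
#' @param n_blocks Number of replicate blocks (default 4).
#' @param years Calendar years to simulate (one trial per year; later years
#'   perturb nothing by default and differ only in noise draws).
#' @param stages Named numeric vector: potential (plateau) whole-plant
#'   biomass `W_max` per ordered stage, t/ha.
#' @param true_a Curve coefficient: critical N concentration at DW = 1 t/ha,
#'   g/kg. Default 26.936, a realistic whole-plant value for cotton.
#' @param true_b Dilution exponent in (0, 1). Default 0.284.
#' @param soil_n_supply Indigenous soil N supply, kg/ha, giving unfertilized
#'   plots a nonzero biomass intercept.
#' @param supply_half_saturation Half-saturation constant of the biomass
#'   response to effective N supply, kg/ha.
#' @param optimal_rate Rate at which biomass reaches its plateau and the
#'   concentration sits exactly on the critical curve, kg/ha.
#' @param luxury_slope Fractional concentration excess per unit relative N
#'   surplus above `optimal_rate`.
#' @param deficiency_slope Controls how far sub-optimal concentrations fall
#'   below the curve (0 = exactly on the curve).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise applied to biomass and concentration.
#' @param repro_fraction Named numeric vector: reproductive fraction of
#'   whole-plant biomass per stage.
#' @param repro_conc_ratio Ratio of reproductive-organ to whole-plant N
#'   concentration (vegetative concentration solves the weighted mean).
#' @param yield_quad Coefficients `c(a, b, c)` of the seed-cotton yield
#'   response `Y = a x^2 + b x + c` (kg/ha vs kg N/ha), `a < 0`.
#' @param seed RNG seed for [generate_trial()].
#' @return A `synthetic_trial_config` list.
#' @export
synthetic_trial_config <- function(n_rates = c(0, 60, 120, 180, 240, 300),
                                   n_blocks = 4,
                                   years = 2023L,
                                   stages = c(initial_flowering = 3.5,
                                              peak_flowering = 7,
                                              peak_boll = 11,
                                              boll_opening = 14),
                                   true_a = 26.936,
                                   true_b = 0.284,
                                   soil_n_supply = 60,
                                   supply_half_saturation = 120,
                                   optimal_rate = 240,
                                   luxury_slope = 0.10,
                                   deficiency_slope = 0.5,
                                   noise_cv = 0.05,
                                   repro_fraction = c(initial_flowering = 0.15,
                                                      peak_flowering = 0.30,
                                                      peak_boll = 0.50,
                                                      boll_opening = 0.65),
                                   repro_conc_ratio = 1.15,
                                   yield_quad = c(a = -0.02, b = 18, c = 2400),
                                   seed = 42L) {
  cfg <- list(n_rates = sort(unique(n_rates)), n_blocks = as.integer(n_blocks),
              years = as.integer(years), stages = stages,
              true_a = true_a, true_b = true_b,
              soil_n_supply = soil_n_supply,
              supply_half_saturation = supply_half_saturation,
              optimal_rate = optimal_rate,
              luxury_slope = luxury_slope,
              deficiency_slope = deficiency_slope,
              noise_cv = noise_cv,
              repro_fraction = repro_fraction,
              repro_conc_ratio = repro_conc_ratio,
              yield_quad = unname(yield_quad),
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "synthetic_trial_config")
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$true_a), length(cfg$true_a) == 1)
  if (cfg$true_a <= 0) abort("true_a must be > 0", class = "cndc_config_error")
  if (cfg$true_b <= 0 || cfg$true_b >= 1)
    abort("true_b must lie in (0, 1)", class = "cndc_config_error")
  if (cfg$noise_cv < 0) abort("noise_cv must be >= 0", class = "cndc_config_error")
  if (cfg$n_blocks < 1) abort("n_blocks must be >= 1", class = "cndc_config_error")
  if (cfg$yield_quad[1] >= 0)
    abort("yield_quad leading coefficient must be negative", class = "cndc_config_error")
  if (is.null(names(cfg$stages)) || any(cfg$stages <= 0))
    abort("stages must be a named vector of positive plateau biomasses", class = "cndc_config_error")
  if (!setequal(names(cfg$repro_fraction), names(cfg$stages)))
    abort("repro_fraction must name the same stages as `stages`", class = "cndc_config_error")
  if (any(cfg$repro_fraction <= 0 | cfg$repro_fraction >= 1))
    abort("repro_fraction must lie in (0, 1)", class = "cndc_config_error")
  if (any(cfg$repro_fraction * cfg$repro_conc_ratio >= 1))
    abort("repro_conc_ratio too large: vegetative concentration would be non-positive",
          class = "cndc_config_error")
  invisible(cfg)
}

# Saturating biomass response: Michaelis factor in effective supply,
# hard-plateaued at the optimal rate.
biomass_response <- function(n_rate, cfg) {
  k <- cfg$supply_half_saturation
  s <- cfg$soil_n_supply + pmin(n_rate, cfg$optimal_rate)
  s_plateau <- cfg$soil_n_supply + cfg$optimal_rate
  (s / (s + k)) / (s_plateau / (s_plateau + k))
}

# Noiseless whole-plant concentration (vectorized) at rate r, biomass w and
# stage plateau w_max.
noiseless_conc <- function(n_rate, w, w_max, cfg) {
  nc_ref <- cfg$true_a * w_max^(-cfg$true_b)
  curve <- cfg$true_a * w^(-cfg$true_b)
  surplus <- pmax(n_rate - cfg$optimal_rate, 0) / cfg$optimal_rate
  luxury <- curve * (1 + cfg$luxury_slope * surplus)
  tangent <- -cfg$true_a * cfg$true_b * w_max^(-cfg$true_b - 1)
  line <- nc_ref + tangent / (1 + cfg$deficiency_slope) * (w - w_max)
  deficient <- if (cfg$deficiency_slope == 0) curve else line
  ifelse(n_rate >= cfg$optimal_rate, luxury, deficient)
}

lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Generate a synthetic randomized-block N-rate trial
#'
#' Produces plot-level trial observations (vegetative and reproductive organ
#' records), plot-level yield records, and a truth record carrying the
#' generating curve and per-sample noiseless values. Output is a
#' deterministic function of the configuration, including its seed.
#'
#' @param config A [synthetic_trial_config()].
#' @return A list of class `synthetic_trial` with elements `observations`
#'   (tibble of plot-level organ records), `yields` (tibble of plot-level
#'   yield records), and `truth` (list with `true_a`, `true_b`, and a
#'   `noiseless` tibble of treatment x stage whole-plant values).
#' @export
generate_trial <- function(config) {
  validate_config(config)
  cfg <- config
  stage_names <- names(cfg$stages)

  grid <- tidyr::expand_grid(
    year = cfg$years,
    n_rate = cfg$n_rates,
    stage = stage_names
  ) %>%
    mutate(
      treatment = paste0("N", .data$n_rate),
      w_max = unname(cfg$stages[.data$stage]),
      f_repro = unname(cfg$repro_fraction[.data$stage]),
      biomass = .data$w_max * biomass_response(.data$n_rate, cfg),
      n_conc = noiseless_conc(.data$n_rate, .data$biomass, .data$w_max, cfg)
    )

  truth_tbl <- grid %>%
    mutate(nc_critical = cfg$true_a * .data$biomass^(-cfg$true_b)) %>%
    select("year", "treatment", "n_rate", "stage",
           biomass = "biomass", n_conc = "n_conc", nc_critical = "nc_critical")

  # organ split preserving the biomass-weighted whole-plant concentration
  organs <- grid %>%
    tidyr::expand_grid(part = c("vegetative", "reproductive")) %>%
    mutate(
      dry_matter0 = ifelse(.data$part == "reproductive",
                           .data$f_repro * .data$biomass,
                           (1 - .data$f_repro) * .data$biomass),
      n_conc0 = ifelse(.data$part == "reproductive",
                       cfg$repro_conc_ratio * .data$n_conc,
                       .data$n_conc * (1 - .data$f_repro * cfg$repro_conc_ratio) /
                         (1 - .data$f_repro))
    )

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  obs <- organs %>%
    tidyr::expand_grid(block = paste0("B", seq_len(cfg$n_blocks))) %>%
    mutate(
      dry_matter = .data$dry_matter0 * lnorm_noise(dplyr::n(), cfg$noise_cv),
      n_conc = .data$n_conc0 * lnorm_noise(dplyr::n(), cfg$noise_cv)
    ) %>%
    select("year", "treatment", "n_rate", "block", "stage", "part",
           "dry_matter", "n_conc") %>%
    arrange(.data$year, .data$n_rate, .data$block, .data$stage, .data$part)
  obs$stage <- factor(obs$stage, levels = stage_names, ordered = TRUE)

  q <- cfg$yield_quad
  yields <- tidyr::expand_grid(year = cfg$years, n_rate = cfg$n_rates,
                               block = paste0("B", seq_len(cfg$n_blocks))) %>%
    mutate(
      treatment = paste0("N", .data$n_rate),
      rel = biomass_response(.data$n_rate, cfg),
      yield0 = pmax(q[1] * .data$n_rate^2 + q[2] * .data$n_rate + q[3], 0),
      seed_cotton_yield = .data$yield0 * lnorm_noise(dplyr::n(), cfg$noise_cv),
      boll_weight = (2.7 + 1.0 * .data$rel) * lnorm_noise(dplyr::n(), cfg$noise_cv / 2),
      boll_density = .data$yield0 / (10 * (2.7 + 1.0 * .data$rel)) *
        lnorm_noise(dplyr::n(), cfg$noise_cv),
      lint_percentage = (36 + 5 * .data$rel) * lnorm_noise(dplyr::n(), cfg$noise_cv / 4)
    ) %>%
    select("year", "treatment", "n_rate", "block", "seed_cotton_yield",
           "boll_density", "boll_weight", "lint_percentage") %>%
    arrange(.data$year, .data$n_rate, .data$block)

  structure(
    list(observations = obs, yields = yields,
         truth = list(true_a = cfg$true_a, true_b = cfg$true_b,
                      noiseless = truth_tbl),
         config = cfg),
    class = "synthetic_trial"
  )
}

#' Ground-truth dilution curve of a synthetic configuration
#'
#' Packages the generating coefficients as a fitted-curve object usable by
#' [predict_nc()], for parameter-recovery tests.
#'
#' @param config A [synthetic_trial_config()].
#' @return A `power_curve_fit` with `a_c = true_a`, `b = true_b`.
#' @export
true_curve <- function(config) {
  validate_config(config)
  new_power_curve_fit(a_c = config$true_a, b = config$true_b,
                      r2 = NA_real_, r2_log = NA_real_,
                      n_points = 0L, part = "whole_plant",
                      points = tibble(stage = character(0),
                                      dw = numeric(0), nc = numeric(0)))
}

#' @export
print.synthetic_trial_config <- function(x, ...) {
  cat("Synthetic N-rate trial configuration\n")
  cat("  rates (kg N/ha):", paste(x$n_rates, collapse = ", "),
      "| blocks:", x$n_blocks, "| years:", paste(x$years, collapse = ", "), "\n")
  cat(sprintf("  true curve: Nc = %.4g * DW^-%.4g\n", x$true_a, x$true_b))
  cat(sprintf("  noise CV: %.3g | luxury %.3g | deficiency %.3g | seed %d\n",
              x$noise_cv, x$luxury_slope, x$deficiency_slope, x$seed))
  invisible(x)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic trial: %d plot-organ records, %d yield records\n",
              nrow(x$observations), nrow(x$yields)))
  cat(sprintf("  truth: Nc = %.4g * DW^-%.4g\n", x$truth$true_a, x$truth$true_b))
  invisible(x)
}
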