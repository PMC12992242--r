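# Data model and I/O for multi-year, multi-rate, multi-stage N trials.
#
# Canonical units are fixed package-wide: biomass in t/ha, N concentration in
# g N per kg dry matter, N rates and N uptake in kg/ha, yields in kg/ha.
# Readers convert from kg/ha biomass or % N only via explicit unit flags.

trial_csv_columns <- function() {
  c(year = "year", treatment = "treatment", n_rate = "n_rate",
    block = "block", stage = "stage", part = "part",
    dry_matter = "dry_matter_t_ha", n_conc = "n_conc_g_kg")
}

yield_csv_columns <- function() {
  c(year = "year", treatment = "treatment", n_rate = "n_rate",
    block = "block", seed_cotton_yield = "seed_cotton_kg_ha",
    boll_density = "boll_density_m2", boll_weight = "boll_weight_g",
    lint_percentage = "lint_pct")
}

check_columns <- function(df, wanted, path) {
  missing <- setdiff(unname(wanted), names(df))
  if (length(missing) > 0) {
    abort(sprintf("File '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "cndc_schema_error")
  }
}

coerce_numeric <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("File '%s', column '%s': non-numeric value(s) at data row(s) %s",
                  path, col, paste(head(bad, 5), collapse = ", ")),
          class = "cndc_parse_error")
  }
  out
}

#' Read plot-level trial observations from CSV
#'
#' Reads a UTF-8 CSV of plot-level organ records with columns
#' `year,treatment,n_rate,block,stage,part,dry_matter_t_ha,n_conc_g_kg`
#' (names remappable via `schema`) and validates every row against the data
#' model: non-negative dry matter, N concentration in \[0, 100\] g/kg, stage
#' labels drawn from the configured ordered stage list, organ class one of
#' vegetative / reproductive / root.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector remapping canonical names to
#'   file column names, e.g. `c(dry_matter = "dm_kg")`. Names are the
#'   canonical fields `year, treatment, n_rate, block, stage, part,
#'   dry_matter, n_conc`.
#' @param stages Ordered character vector of admissible stage labels.
#' @param biomass_unit Unit of the dry-matter column: `"t_ha"` (canonical) or
#'   `"kg_ha"` (divided by 1000 on read).
#' @param conc_unit Unit of the concentration column: `"g_kg"` (canonical) or
#'   `"percent"` (multiplied by 10 on read).
#' @return A tibble of validated observations with canonical columns `year,
#'   treatment, n_rate, block, stage, part, dry_matter, n_conc`; `stage` is a
#'   factor ordered as `stages`.
#' @export
read_trial_csv <- function(path, schema = NULL,
                           stages = trial_stages(),
                           biomass_unit = c("t_ha", "kg_ha"),
                           conc_unit = c("g_kg", "percent")) {
  biomass_unit <- match.arg(biomass_unit)
  conc_unit <- match.arg(conc_unit)
  if (!file.exists(path)) {
    abort(sprintf("Trial file not found: '%s'", path), class = "cndc_io_error")
  }
  cols <- trial_csv_columns()
  if (!is.null(schema)) cols[names(schema)] <- unname(schema)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, cols, path)
  obs <- tibble(
    year = as.integer(coerce_numeric(raw[[cols["year"]]], cols["year"], path)),
    treatment = as.character(raw[[cols["treatment"]]]),
    n_rate = coerce_numeric(raw[[cols["n_rate"]]], cols["n_rate"], path),
    block = as.character(raw[[cols["block"]]]),
    stage = as.character(raw[[cols["stage"]]]),
    part = as.character(raw[[cols["part"]]]),
    dry_matter = coerce_numeric(raw[[cols["dry_matter"]]], cols["dry_matter"], path),
    n_conc = coerce_numeric(raw[[cols["n_conc"]]], cols["n_conc"], path)
  )
  if (biomass_unit == "kg_ha") obs$dry_matter <- obs$dry_matter / 1000
  if (conc_unit == "percent") obs$n_conc <- obs$n_conc * 10
  validate_trial_observations(obs, stages = stages)
}

#' Validate a data frame of trial observations
#'
#' Applies the row-level invariants of the trial data model and rejects
#' offending rows with row-indexed diagnostics.
#'
#' @param obs Data frame with canonical observation columns.
#' @param stages Ordered character vector of admissible stage labels.
#' @return The validated tibble, `stage` converted to an ordered factor.
#' @export
validate_trial_observations <- function(obs, stages = trial_stages()) {
  obs <- as_tibble(obs)
  problems <- character(0)
  bad_dm <- which(is.na(obs$dry_matter) | obs$dry_matter < 0)
  if (length(bad_dm) > 0) {
    problems <- c(problems, sprintf(
      "row %d: dry_matter = %s violates bound dry_matter >= 0",
      bad_dm, format(obs$dry_matter[bad_dm])))
  }
  bad_nc <- which(is.na(obs$n_conc) | obs$n_conc < 0 | obs$n_conc > 100)
  if (length(bad_nc) > 0) {
    problems <- c(problems, sprintf(
      "row %d: n_conc = %s outside [0, 100] g/kg",
      bad_nc, format(obs$n_conc[bad_nc])))
  }
  bad_rate <- which(is.na(obs$n_rate) | obs$n_rate < 0)
  if (length(bad_rate) > 0) {
    problems <- c(problems, sprintf(
      "row %d: n_rate = %s violates bound n_rate >= 0",
      bad_rate, format(obs$n_rate[bad_rate])))
  }
  bad_stage <- which(!obs$stage %in% stages)
  if (length(bad_stage) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown stage label '%s' (expected one of: %s)",
      bad_stage, obs$stage[bad_stage], paste(stages, collapse = ", ")))
  }
  bad_part <- which(!obs$part %in% trial_parts())
  if (length(bad_part) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown organ class '%s' (expected one of: %s)",
      bad_part, obs$part[bad_part], paste(trial_parts(), collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(c("Invalid trial observation(s):", setNames(head(problems, 10), rep("x", min(10, length(problems))))),
          class = "cndc_validation_error")
  }
  obs$stage <- factor(obs$stage, levels = stages, ordered = TRUE)
  obs
}

#' Write trial observations to CSV
#'
#' Writes the canonical trial schema plus the derived column
#' `n_uptake_kg_ha = dry_matter_t_ha * n_conc_g_kg`. Values round-trip
#' through [read_trial_csv()] bit-for-bit for text-representable numbers.
#'
#' @param obs Tibble of validated observations.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(obs, path) {
  out <- tibble(
    year = obs$year, treatment = obs$treatment, n_rate = obs$n_rate,
    block = obs$block, stage = as.character(obs$stage), part = obs$part,
    dry_matter_t_ha = obs$dry_matter, n_conc_g_kg = obs$n_conc,
    n_uptake_kg_ha = population_n_uptake(obs$dry_matter, obs$n_conc)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read treatment yield records from CSV
#'
#' Reads plot-level yield records with columns
#' `year,treatment,n_rate,block,seed_cotton_kg_ha,boll_density_m2,
#' boll_weight_g,lint_pct` and validates non-negativity and
#' lint percentage in (0, 100).
#'
#' @param path Path to the CSV file.
#' @return Tibble with canonical columns `year, treatment, n_rate, block,
#'   seed_cotton_yield, boll_density, boll_weight, lint_percentage`.
#' @export
read_yield_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Yield file not found: '%s'", path), class = "cndc_io_error")
  }
  cols <- yield_csv_columns()
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, cols, path)
  out <- tibble(
    year = as.integer(coerce_numeric(raw[[cols["year"]]], "year", path)),
    treatment = as.character(raw[[cols["treatment"]]]),
    n_rate = coerce_numeric(raw[[cols["n_rate"]]], "n_rate", path),
    block = as.character(raw[[cols["block"]]]),
    seed_cotton_yield = coerce_numeric(raw[[cols["seed_cotton_yield"]]],
                                       cols["seed_cotton_yield"], path),
    boll_density = coerce_numeric(raw[[cols["boll_density"]]],
                                  cols["boll_density"], path),
    boll_weight = coerce_numeric(raw[[cols["boll_weight"]]],
                                 cols["boll_weight"], path),
    lint_percentage = coerce_numeric(raw[[cols["lint_percentage"]]],
                                     cols["lint_percentage"], path)
  )
  bad <- which(out$seed_cotton_yield < 0 | out$boll_density < 0 |
                 out$boll_weight < 0 |
                 out$lint_percentage <= 0 | out$lint_percentage >= 100)
  if (length(bad) > 0) {
    abort(sprintf("Invalid yield record(s) at row(s) %s: fields must be >= 0 and lint_pct in (0, 100)",
                  paste(head(bad, 5), collapse = ", ")),
          class = "cndc_validation_error")
  }
  out
}

#' Write yield records to CSV
#'
#' @param yields Tibble of yield records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yield_csv <- function(yields, path) {
  out <- tibble(
    year = yields$year, treatment = yields$treatment, n_rate = yields$n_rate,
    block = yields$block, seed_cotton_kg_ha = yields$seed_cotton_yield,
    boll_density_m2 = yields$boll_density, boll_weight_g = yields$boll_weight,
    lint_pct = yields$lint_percentage
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Population nitrogen uptake
#'
#' Uptake is the product of population biomass and measured N concentration.
#' With biomass in t/ha and concentration in g/kg the product is numerically
#' in kg N/ha: `t/ha * 1000 kg/t * g/kg / 1000 g/kg-per-fraction = kg/ha`.
#'
#' @param biomass Population dry matter, t/ha (>= 0).
#' @param n_conc Measured N concentration, g N per kg dry matter (>= 0).
#' @return N uptake in kg N/ha.
#' @export
#' @examples
#' population_n_uptake(5, 20) # 100 kg N/ha
population_n_uptake <- function(biomass, n_conc) {
  if (any(biomass < 0, na.rm = TRUE) || any(n_conc < 0, na.rm = TRUE)) {
    abort("population_n_uptake() requires biomass >= 0 and n_conc >= 0",
          class = "cndc_domain_error")
  }
  biomass * n_conc
}

resolve_part <- function(part) {
  part <- match.arg(part, c("whole_plant", "vegetative", "reproductive"))
  part
}

# Block-level samples: one row per (year, treatment, block, stage) for the
# requested plant fraction. Whole-plant biomass is the sum over organ classes
# present in the data; whole-plant concentration is the biomass-weighted mean
# of organ concentrations, so block uptake is additive over organs.
#' Block-level stage samples
#'
#' Collapses organ-level plot records to one record per
#' (year, treatment, block, stage) for a chosen plant fraction. For
#' `part = "whole_plant"` biomass is summed over organ classes and the
#' concentration is the biomass-weighted mean, making N uptake exactly
#' additive over organs.
#'
#' @param obs Tibble of validated trial observations.
#' @param part `"whole_plant"`, `"vegetative"` or `"reproductive"`.
#' @param include_root Whether `root` organ records (when present) count
#'   toward whole-plant mass; the default `FALSE` is the aboveground
#'   convention under which the curve coefficient `a_c` is the
#'   concentration at 1 t/ha of aboveground dry matter.
#' @return Tibble with columns `year, treatment, n_rate, block, stage,
#'   biomass, n_conc, n_uptake`.
#' @export
block_stage_samples <- function(obs, part = "whole_plant", include_root = FALSE) {
  part <- resolve_part(part)
  whole_parts <- c("vegetative", "reproductive", if (include_root) "root")
  if (part == "whole_plant") {
    organ_counts <- obs %>%
      filter(.data$part %in% c("vegetative", "reproductive")) %>%
      distinct(.data$year, .data$treatment, .data$block, .data$stage, .data$part) %>%
      dplyr::count(.data$year, .data$treatment, .data$block, .data$stage)
    incomplete <- organ_counts %>% filter(.data$n < 2)
    if (nrow(incomplete) > 0) {
      keys <- sprintf("%s/%s/%s/%s", incomplete$year, incomplete$treatment,
                      incomplete$block, incomplete$stage)
      abort(c("whole_plant aggregation needs both organ classes per plot; incomplete keys (year/treatment/block/stage):",
              setNames(head(keys, 10), rep("x", min(10, length(keys))))),
            class = "cndc_validation_error")
    }
    dat <- obs %>% filter(.data$part %in% whole_parts)
  } else {
    dat <- obs %>% filter(.data$part == .env$part)
  }
  dat %>%
    group_by(.data$year, .data$treatment, .data$n_rate, .data$block, .data$stage) %>%
    summarise(
      n_conc = if (sum(.data$dry_matter) > 0)
        sum(.data$dry_matter * .data$n_conc) / sum(.data$dry_matter)
      else mean(.data$n_conc),
      biomass = sum(.data$dry_matter),
      .groups = "drop"
    ) %>%
    mutate(n_uptake = .data$biomass * .data$n_conc) %>%
    select("year", "treatment", "n_rate", "block", "stage",
           "biomass", "n_conc", "n_uptake") %>%
    arrange(.data$year, .data$stage, .data$n_rate, .data$block)
}

#' Aggregate plot records to treatment-level stage samples
#'
#' Builds one sample per (year, treatment, stage) for a chosen plant
#' fraction. Block-level values are computed first (preserving the
#' randomized-block structure), then summarised: biomass is the arithmetic
#' block mean with its sample SD, and the treatment concentration is the
#' biomass-weighted mean over blocks (total N over total dry matter), so
#' that `n_uptake = biomass * n_conc` holds exactly and uptake remains
#' additive over organ fractions.
#'
#' @inheritParams block_stage_samples
#' @return Tibble with columns `year, treatment, n_rate, stage, part,
#'   biomass, biomass_sd, n_conc, n_uptake, n_blocks`.
#' @export
aggregate_stage_samples <- function(obs, part = "whole_plant",
                                    include_root = FALSE) {
  part <- resolve_part(part)
  block_stage_samples(obs, part, include_root = include_root) %>%
    group_by(.data$year, .data$treatment, .data$n_rate, .data$stage) %>%
    summarise(
      biomass_sd = sd(.data$biomass),
      n_conc = if (sum(.data$biomass) > 0)
        sum(.data$biomass * .data$n_conc) / sum(.data$biomass)
      else mean(.data$n_conc),
      biomass = mean(.data$biomass),
      n_blocks = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(part = .env$part, n_uptake = .data$biomass * .data$n_conc) %>%
    select("year", "treatment", "n_rate", "stage", "part",
           "biomass", "biomass_sd", "n_conc", "n_uptake", "n_blocks") %>%
    arrange(.data$year, .data$stage, .data$n_rate)
}
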