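# Orchestration: simulate -> fit -> validate -> diagnose -> metrics, with a
# machine-readable run report on disk.

file_hash <- function(path) unname(tools::md5sum(path))

provenance <- function(config_echo, inputs = character(0)) {
  list(package = "cndc",
       version = as.character(utils::packageVersion("cndc")),
       input_hashes = as.list(vapply(inputs, file_hash, character(1))),
       config = config_echo)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  path
}

#' Configuration for a pipeline run
#'
#' Either point `trial` / `yields` (and optionally `holdout_trial`) at CSV
#' files in the canonical schemas, or set `simulate = TRUE` to generate a
#' construction year and a hold-out year from a
#' [synthetic_trial_config()].
#'
#' @param out_dir Output directory (created if missing).
#' @param trial,yields,holdout_trial Optional CSV paths.
#' @param simulate Generate synthetic data instead of reading files.
#' @param synthetic A [synthetic_trial_config()] used when `simulate = TRUE`.
#' @param part Plant fraction for the curve (`"whole_plant"` or
#'   `"reproductive"`).
#' @param alpha Significance level for the limiting classification, in
#'   (0, 0.5).
#' @param tolerance NNI optimal-band half width.
#' @param ry_stage Stage for the relative-yield vs NNI fit.
#' @param prices Price list for the economics step.
#' @param seed Seed for any simulation randomness.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, trial = NULL, yields = NULL,
                       holdout_trial = NULL, simulate = is.null(trial),
                       synthetic = synthetic_trial_config(),
                       part = "whole_plant", alpha = 0.05, tolerance = 0,
                       ry_stage = "boll_opening", prices = default_prices(),
                       seed = 42L) {
  if (alpha <= 0 || alpha >= 0.5) {
    abort("alpha must lie in (0, 0.5)", class = "cndc_config_error")
  }
  if (!simulate) {
    for (p in c(trial, yields, holdout_trial)) {
      if (!is.null(p) && !file.exists(p)) {
        abort(sprintf("configured input file does not exist: '%s'", p),
              class = "cndc_config_error")
      }
    }
    if (is.null(trial) || is.null(yields)) {
      abort("non-simulated runs need both `trial` and `yields` files",
            class = "cndc_config_error")
    }
  }
  structure(list(out_dir = out_dir, trial = trial, yields = yields,
                 holdout_trial = holdout_trial, simulate = simulate,
                 synthetic = synthetic, part = part, alpha = alpha,
                 tolerance = tolerance, ry_stage = ry_stage, prices = prices,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full CNDC analysis pipeline
#'
#' Executes simulate (optional) -> curve construction -> hold-out validation
#' -> NNI diagnosis -> relative-yield/NNI fit -> NUE, stability and economic
#' analytics, writing `fit.json`, `validation.json`, `nni.csv`, `lp.json`,
#' `nue.csv`, `stability.csv` and `economics.json` (plus the simulated
#' `trial.csv`, `holdout.csv`, `yields.csv` and `truth.json` when
#' simulating) under `config$out_dir`. Each JSON output carries the package
#' version, input-file hashes, and a config echo. Narrates each construction
#' step via messages.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `run_report` list with the in-memory results and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "cndc_pipeline_error", parent = e)
    })
  }

  inputs <- character(0)
  truth <- NULL
  if (config$simulate) {
    inform("stage simulate: generating construction and hold-out years")
    sim <- step("simulate", {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      generate_trial(cfg)
    })
    holdout_cfg <- config$synthetic
    holdout_cfg$seed <- (config$seed + 1L) %% .Machine$integer.max
    holdout_cfg$years <- config$synthetic$years + 1L
    sim_holdout <- step("simulate", generate_trial(holdout_cfg))
    obs <- sim$observations
    holdout_obs <- sim_holdout$observations
    yields <- bind_rows(sim$yields, sim_holdout$yields)
    truth <- sim$truth
    paths$trial <- write_trial_csv(obs, file.path(config$out_dir, "trial.csv"))
    paths$holdout <- write_trial_csv(holdout_obs, file.path(config$out_dir, "holdout.csv"))
    paths$yields <- write_yield_csv(yields, file.path(config$out_dir, "yields.csv"))
    write_json(list(true_a = truth$true_a, true_b = truth$true_b),
               file.path(config$out_dir, "truth.json"))
    paths$truth <- file.path(config$out_dir, "truth.json")
    inputs <- c(unlist(paths[c("trial", "holdout", "yields")]))
  } else {
    inform("stage read: loading trial and yield files")
    obs <- step("read", read_trial_csv(config$trial))
    yields <- step("read", read_yield_csv(config$yields))
    holdout_obs <- if (!is.null(config$holdout_trial)) {
      step("read", read_trial_csv(config$holdout_trial))
    } else NULL
    inputs <- c(config$trial, config$yields, config$holdout_trial)
  }
  config_echo <- list(part = config$part, alpha = config$alpha,
                      tolerance = config$tolerance, ry_stage = config$ry_stage,
                      seed = config$seed, simulate = config$simulate)
  prov <- provenance(config_echo, inputs)

  inform(sprintf("stage fit: constructing the %s dilution curve", config$part))
  fit <- step("fit", fit_cndc(obs, part = config$part, alpha = config$alpha))
  for (s in names(fit$groupings)) {
    g <- fit$groupings[[s]]
    inform(sprintf("  %s: limited {%s} | non-limited {%s}%s", s,
                   paste(g$limited, collapse = ","),
                   paste(g$non_limited, collapse = ","),
                   if (!is.na(g$flag)) paste0(" [", g$flag, "]") else ""))
  }
  paths$fit <- write_json(list(
    a_c = fit$curve$a_c, b = fit$curve$b, r2 = fit$curve$r2,
    r2_log = fit$curve$r2_log, n_points = fit$curve$n_points,
    part = fit$part,
    critical_points = fit$critical_points,
    skipped = fit$skipped, provenance = prov
  ), file.path(config$out_dir, "fit.json"))

  validation <- NULL
  if (!is.null(holdout_obs)) {
    inform("stage validate: scoring the curve on the hold-out year")
    validation <- step("validate", validate_cndc(fit, holdout_obs))
    paths$validation <- write_json(list(
      rmse = validation$rmse, nrmse = validation$nrmse, r2 = validation$r2,
      n = validation$n, rating = validation$rating, provenance = prov
    ), file.path(config$out_dir, "validation.json"))
  }

  inform("stage diagnose: NNI per treatment and stage")
  diag_obs <- if (!is.null(holdout_obs)) bind_rows(obs, holdout_obs) else obs
  nni <- step("diagnose", diagnose_nni(diag_obs, fit, tolerance = config$tolerance))
  paths$nni <- file.path(config$out_dir, "nni.csv")
  readr::write_csv(nni %>% mutate(stage = as.character(.data$stage)), paths$nni)

  inform("stage ry-fit: linear-plateau fit of relative yield on NNI")
  lp <- step("ry_fit", fit_ry_nni(nni, yields, stage = config$ry_stage, pool = TRUE)$pooled)
  paths$lp <- write_json(list(
    slope = lp$slope, intercept = lp$intercept, breakpoint = lp$breakpoint,
    plateau = lp$plateau, r2 = lp$r2, n_points = lp$n_points,
    stage = config$ry_stage, provenance = prov
  ), file.path(config$out_dir, "lp.json"))

  inform("stage metrics: NUE, stability, economics")
  uptake <- step("nue", aggregate_stage_samples(diag_obs, "whole_plant"))
  nue <- step("nue", nue_indices(yields, uptake))
  paths$nue <- file.path(config$out_dir, "nue.csv")
  readr::write_csv(nue, paths$nue)

  stability <- if (dplyr::n_distinct(yields$year) >= 2) {
    yearly <- yields %>%
      group_by(.data$year, .data$treatment, .data$n_rate) %>%
      summarise(seed_cotton_yield = mean(.data$seed_cotton_yield), .groups = "drop")
    step("stability", stability_indices(yearly))
  } else NULL
  if (!is.null(stability)) {
    paths$stability <- file.path(config$out_dir, "stability.csv")
    readr::write_csv(stability, paths$stability)
  }

  yq <- step("economics", fit_yield_quadratic(yields$n_rate, yields$seed_cotton_yield))
  econ <- step("economics",
               economic_optimum(build_benefit_curve(yq, config$prices), config$prices))
  paths$economics <- write_json(list(
    yield_quad = list(a = yq$a, b = yq$b, c = yq$c, r2 = yq$r2,
                      vertex_rate = yq$vertex_rate),
    benefit_quad = list(a = econ$quad[1], b = econ$quad[2], c = econ$quad[3]),
    optimal_rate = econ$optimal_rate, max_benefit = econ$max_benefit,
    prices = config$prices, provenance = prov
  ), file.path(config$out_dir, "economics.json"))

  report <- structure(list(fit = fit, validation = validation, nni = nni,
                           lp = lp, nue = nue, stability = stability,
                           yield_quad = yq, economics = econ, truth = truth,
                           paths = paths, config = config),
                      class = "run_report")
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("CNDC pipeline run\n")
  print(x$fit$curve)
  if (!is.null(x$validation)) print(x$validation)
  print(x$economics)
  cat("outputs:", paste(unlist(x$paths), collapse = ", "), "\n")
  invisible(x)
}
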