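# Critical nitrogen dilution curve construction: per-stage limiting /
# non-limiting classification, critical points by the intersection rule,
# power-law fitting, and hold-out validation.

new_power_curve_fit <- function(a_c, b, r2, r2_log, n_points, part, points,
                                converged = TRUE) {
  structure(list(a_c = a_c, b = b, r2 = r2, r2_log = r2_log,
                 n_points = n_points, part = part, points = points,
                 converged = converged),
            class = "power_curve_fit")
}

#' Classify treatments as N-limited or non-limited at one stage
#'
#' Within a sampling date, treatments whose population biomass still
#' increases significantly with N rate are N-limited; treatments on the
#' biomass plateau are non-limited. Block-level biomass is compared by
#' one-way ANOVA across treatments, then each treatment is tested against
#' the maximum-biomass treatment (Welch t-test by default, Tukey HSD as the
#' alternative); treatments statistically indistinguishable from the top
#' treatment at level `alpha` form the non-limited group.
#'
#' The grouping also records the ordinary least-squares line of treatment
#' mean N concentration on treatment mean biomass over the limited group,
#' and the reference biomass `dw_ref` (mean biomass of the non-limited
#' group) at which the critical concentration is read off.
#'
#' When replicate variance is numerically zero (noiseless synthetic data)
#' the pairwise tests are undefined; the classifier then falls back to exact
#' mean equality at 1e-9 relative tolerance.
#'
#' @param samples Block-level stage samples (see [block_stage_samples()])
#'   restricted to a single stage (and year): columns `treatment, n_rate,
#'   block, biomass, n_conc`.
#' @param alpha Significance level for the pairwise comparisons.
#' @param method `"welch"` (pairwise Welch t-tests vs the top treatment) or
#'   `"tukey"` (Tukey HSD contrasts vs the top treatment).
#' @return A `stage_grouping` list: `stage`, `limited`, `non_limited`,
#'   `linear_slope`, `linear_intercept`, `dw_ref`, `alpha`, `flag`
#'   (`NA`, `"no_critical_point"` or `"insufficient_limited"`),
#'   `anova_p`, and the `treatment_means` tibble.
#' @export
classify_limiting <- function(samples, alpha = 0.05,
                              method = c("welch", "tukey")) {
  method <- match.arg(method)
  stage <- unique(as.character(samples$stage))
  if (length(stage) > 1) {
    abort("classify_limiting() expects samples from a single stage",
          class = "cndc_domain_error")
  }
  if (length(stage) == 0) stage <- NA_character_
  trt_n <- samples %>% dplyr::count(.data$treatment)
  if (dplyr::n_distinct(samples$treatment) < 2) {
    abort("classification needs at least 2 treatments", class = "cndc_domain_error")
  }
  if (any(trt_n$n < 2)) {
    abort("classification needs >= 2 replicate blocks per treatment",
          class = "cndc_replication_error")
  }

  means <- samples %>%
    group_by(.data$treatment, .data$n_rate) %>%
    summarise(
      n_conc = if (sum(.data$biomass) > 0)
        sum(.data$biomass * .data$n_conc) / sum(.data$biomass)
      else mean(.data$n_conc),
      biomass_sd = sd(.data$biomass),
      biomass = mean(.data$biomass),
      n_blocks = dplyr::n(), .groups = "drop") %>%
    arrange(.data$n_rate)

  top <- means$treatment[which.max(means$biomass)]
  top_vals <- samples$biomass[samples$treatment == top]

  zero_var <- all(tapply(samples$biomass, samples$treatment, sd) < 1e-12 *
                    pmax(abs(tapply(samples$biomass, samples$treatment, mean)), 1))
  aov_fit <- NULL
  anova_p <- NA_real_
  if (!zero_var) {
    dat <- samples %>% mutate(treatment = factor(.data$treatment))
    aov_fit <- aov(biomass ~ treatment, data = dat)
    anova_p <- summary(aov_fit)[[1]][["Pr(>F)"]][1]
  }

  indistinct <- vapply(means$treatment, function(trt) {
    if (trt == top) return(TRUE)
    vals <- samples$biomass[samples$treatment == trt]
    if (zero_var) {
      m1 <- mean(vals); m2 <- mean(top_vals)
      return(abs(m1 - m2) <= 1e-9 * max(abs(m1), abs(m2), 1))
    }
    p <- if (method == "welch") {
      if (sd(vals) < .Machine$double.eps^0.5 && sd(top_vals) < .Machine$double.eps^0.5) {
        if (abs(mean(vals) - mean(top_vals)) <= 1e-9 * max(abs(mean(top_vals)), 1)) 1 else 0
      } else {
        tryCatch(t.test(vals, top_vals)$p.value, error = function(e) 0)
      }
    } else {
      tk <- TukeyHSD(aov_fit)$treatment
      pair <- rownames(tk)
      hit <- pair == paste(trt, top, sep = "-") | pair == paste(top, trt, sep = "-")
      tk[hit, "p adj"][1]
    }
    p > alpha
  }, logical(1))

  non_limited <- means$treatment[indistinct]
  limited <- setdiff(means$treatment, non_limited)

  flag <- NA_character_
  if (length(limited) == 0) flag <- "no_critical_point"
  else if (length(limited) < 2) flag <- "insufficient_limited"

  slope <- intercept <- NA_real_
  if (length(limited) >= 2) {
    lm_dat <- means %>% filter(.data$treatment %in% limited)
    fit <- lm(n_conc ~ biomass, data = lm_dat)
    intercept <- unname(coef(fit)[1])
    slope <- unname(coef(fit)[2])
  }
  dw_ref <- mean(means$biomass[means$treatment %in% non_limited])

  structure(list(stage = stage, limited = limited, non_limited = non_limited,
                 linear_slope = slope, linear_intercept = intercept,
                 dw_ref = dw_ref, alpha = alpha, method = method,
                 flag = flag, anova_p = anova_p, treatment_means = means),
            class = "stage_grouping")
}

#' @export
print.stage_grouping <- function(x, ...) {
  cat(sprintf("Stage '%s': limited {%s} | non-limited {%s}\n", x$stage,
              paste(x$limited, collapse = ", "),
              paste(x$non_limited, collapse = ", ")))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  else cat(sprintf("  line: Nconc = %.4g + %.4g * DW; dw_ref = %.4g t/ha\n",
                   x$linear_intercept, x$linear_slope, x$dw_ref))
  invisible(x)
}

#' Critical point of one stage by the intersection rule
#'
#' Evaluates the limited-group regression line of N concentration on biomass
#' at the non-limited group's mean biomass `dw_ref`; the ordinate is the
#' stage's critical N concentration.
#'
#' @param grouping A `stage_grouping` from [classify_limiting()].
#' @return One-row tibble: `stage, dw, nc, n_limited_points`.
#' @export
critical_point <- function(grouping) {
  if (!is.na(grouping$flag)) {
    abort(sprintf("stage '%s' has no valid critical point: %s",
                  grouping$stage, grouping$flag),
          class = "cndc_skipped_stage")
  }
  nc <- grouping$linear_intercept + grouping$linear_slope * grouping$dw_ref
  if (!is.finite(nc) || nc <= 0) {
    abort(sprintf("degenerate_critical_point: stage '%s' yields nc = %.4g <= 0",
                  grouping$stage, nc),
          class = "cndc_degenerate_critical_point")
  }
  tibble(stage = grouping$stage, dw = grouping$dw_ref, nc = nc,
         n_limited_points = length(grouping$limited))
}

#' Fit the power-law dilution curve through critical points
#'
#' Fits `nc = a_c * dw^-b` by nonlinear least squares on the original scale
#' (Levenberg-Marquardt), initialized from the log-log ordinary
#' least-squares solution. R-squared is reported on the original scale
#' (`1 - SSE/SStot`) with the log-log value kept alongside. Two points
#' determine the curve exactly.
#'
#' @param points Tibble with columns `dw` (t/ha, > 0) and `nc` (g/kg, > 0);
#'   at least 2 rows.
#' @param part Plant fraction label carried on the fit.
#' @return A `power_curve_fit` object with elements `a_c`, `b`, `r2`,
#'   `r2_log`, `n_points`, `part`, `points`.
#' @export
fit_power_curve <- function(points, part = "whole_plant") {
  if (nrow(points) < 2) {
    abort("fit_power_curve() needs at least 2 critical points",
          class = "cndc_domain_error")
  }
  if (any(points$dw <= 0) || any(points$nc <= 0)) {
    abort("fit_power_curve() requires dw > 0 and nc > 0",
          class = "cndc_domain_error")
  }
  loglog <- lm(log(nc) ~ log(dw), data = points)
  a0 <- exp(unname(coef(loglog)[1]))
  b0 <- -unname(coef(loglog)[2])
  r2_log <- suppressWarnings(summary(loglog)$r.squared)

  converged <- TRUE
  fit <- tryCatch(
    minpack.lm::nlsLM(nc ~ a * dw^(-b), data = points,
                      start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # carry the log-log solution as the fallback
    converged <- FALSE
    a_c <- a0; b <- b0
  } else {
    a_c <- unname(coef(fit)["a"])
    b <- unname(coef(fit)["b"])
  }
  pred <- a_c * points$dw^(-b)
  sse <- sum((points$nc - pred)^2)
  sstot <- sum((points$nc - mean(points$nc))^2)
  r2 <- if (sstot > 0) 1 - sse / sstot else NA_real_
  new_power_curve_fit(a_c = a_c, b = b, r2 = r2, r2_log = r2_log,
                      n_points = nrow(points), part = part,
                      points = as_tibble(points), converged = converged)
}

#' Predict critical N concentration from a fitted dilution curve
#'
#' @param fit A `power_curve_fit` (or any list with `a_c` and `b`).
#' @param dw Dry matter, t/ha (> 0); vectorized.
#' @return Critical N concentration, g/kg.
#' @export
#' @examples
#' predict_nc(list(a_c = 2, b = 0.5), 4) # 1
predict_nc <- function(fit, dw) {
  if (any(dw <= 0, na.rm = TRUE)) {
    abort("predict_nc() requires dw > 0", class = "cndc_domain_error")
  }
  fit$a_c * dw^(-fit$b)
}

#' Construct a critical N dilution curve from trial observations
#'
#' Runs the full three-step construction: per-stage classification of
#' treatments into N-limited and non-limited groups, critical-point
#' extraction by the intersection rule, and power-law fitting across the
#' per-stage critical points. Stages without a valid critical point are
#' dropped with a warning rather than failing the run.
#'
#' @param obs Tibble of validated plot-level trial observations (a single
#'   construction year; filter beforehand for multi-year data).
#' @param part Plant fraction the curve is based on: `"whole_plant"` or
#'   `"reproductive"` (or `"vegetative"`).
#' @param alpha Significance level for the limiting classification.
#' @param method Pairwise comparison method, see [classify_limiting()].
#' @return A `cndc_fit` object: the `curve` (`power_curve_fit`), the
#'   per-stage `groupings`, the `critical_points` tibble, and `skipped`
#'   (tibble of stage/reason for stages without a critical point).
#' @export
fit_cndc <- function(obs, part = "whole_plant", alpha = 0.05,
                     method = c("welch", "tukey")) {
  method <- match.arg(method)
  part <- resolve_part(part)
  blocks <- block_stage_samples(obs, part)
  stages <- levels(blocks$stage) %||% unique(as.character(blocks$stage))
  stages <- intersect(stages, as.character(blocks$stage))

  groupings <- list()
  pts <- list()
  skipped <- tibble(stage = character(0), reason = character(0))
  for (s in stages) {
    g <- classify_limiting(blocks %>% filter(.data$stage == s),
                           alpha = alpha, method = method)
    groupings[[s]] <- g
    if (!is.na(g$flag)) {
      warn(sprintf("stage '%s' skipped: %s", s, g$flag))
      skipped <- bind_rows(skipped, tibble(stage = s, reason = g$flag))
      next
    }
    cp <- tryCatch(critical_point(g), error = function(e) {
      warn(sprintf("stage '%s' skipped: %s", s, conditionMessage(e)))
      NULL
    })
    if (is.null(cp)) {
      skipped <- bind_rows(skipped, tibble(stage = s, reason = "degenerate_critical_point"))
    } else {
      pts[[s]] <- cp
    }
  }
  critical_points <- bind_rows(pts)
  if (nrow(critical_points) < 2) {
    abort("fewer than 2 stages produced a valid critical point; cannot fit a dilution curve",
          class = "cndc_domain_error")
  }
  curve <- fit_power_curve(critical_points[, c("dw", "nc")], part = part)
  curve$points <- critical_points
  structure(list(curve = curve, groupings = groupings,
                 critical_points = critical_points, skipped = skipped,
                 part = part, alpha = alpha, method = method),
            class = "cndc_fit")
}

#' @export
print.power_curve_fit <- function(x, ...) {
  cat(sprintf("Dilution curve (%s): Nc = %.4f * DW^-%.4f\n", x$part, x$a_c, x$b))
  cat(sprintf("  n = %d critical points | R2 = %.4f (original scale), %.4f (log-log)\n",
              x$n_points, x$r2, x$r2_log))
  if (!x$converged) cat("  note: nonlinear fit did not converge; log-log OLS coefficients reported\n")
  invisible(x)
}

#' @export
print.cndc_fit <- function(x, ...) {
  print(x$curve)
  if (nrow(x$skipped) > 0) {
    cat("  skipped stages:",
        paste(sprintf("%s (%s)", x$skipped$stage, x$skipped$reason), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname fit_cndc
#' @param x A `cndc_fit` object.
#' @param ... Unused.
#' @export
tidy.cndc_fit <- function(x, ...) {
  tibble(term = c("a_c", "b"), estimate = c(x$curve$a_c, x$curve$b))
}

#' @rdname fit_cndc
#' @export
glance.cndc_fit <- function(x, ...) {
  tibble(r.squared = x$curve$r2, r.squared.log = x$curve$r2_log,
         n.points = x$curve$n_points, n.stages.skipped = nrow(x$skipped),
         part = x$part, alpha = x$alpha)
}

#' @rdname fit_cndc
#' @export
augment.cndc_fit <- function(x, ...) {
  x$critical_points %>%
    mutate(.fitted = predict_nc(x$curve, .data$dw),
           .resid = .data$nc - .data$.fitted)
}

#' Validation metrics for predicted vs observed concentrations
#'
#' Computes RMSE, normalized RMSE (nRMSE, percent of the observed mean), and
#' R-squared (squared Pearson correlation of predictions and observations),
#' and assigns the standard agreement rating from the nRMSE bands:
#' excellent below 10%, good in \[10, 20)%, fair in \[20, 30)%, poor at or
#' above 30%.
#'
#' @param predicted Numeric vector of model predictions (g/kg).
#' @param observed Numeric vector of measurements, same length.
#' @return A `validation_report` list: `rmse`, `nrmse`, `r2`, `n`, `rating`.
#' @export
validate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("predicted and observed must have equal length", class = "cndc_domain_error")
  }
  n <- length(predicted)
  if (n < 2) abort("validation needs at least 2 pairs", class = "cndc_domain_error")
  if (mean(observed) <= 0) {
    abort("nRMSE undefined: observed mean must be > 0", class = "cndc_domain_error")
  }
  rmse <- sqrt(sum((predicted - observed)^2) / n)
  nrmse <- rmse * 100 / mean(observed)
  if (sd(observed) == 0 || sd(predicted) == 0) {
    abort("R2 undefined: zero variance in predicted or observed values",
          class = "cndc_domain_error")
  }
  r2 <- cor(predicted, observed)^2
  structure(list(rmse = rmse, nrmse = nrmse, r2 = r2, n = n,
                 rating = nrmse_rating(nrmse)),
            class = "validation_report")
}

#' Agreement rating from an nRMSE value
#'
#' @param nrmse nRMSE in percent.
#' @return `"excellent"` (< 10), `"good"` (\[10, 20)), `"fair"`
#'   (\[20, 30)), or `"poor"` (>= 30).
#' @export
nrmse_rating <- function(nrmse) {
  cut(nrmse, breaks = c(-Inf, 10, 20, 30, Inf),
      labels = c("excellent", "good", "fair", "poor"),
      right = FALSE) %>% as.character()
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation (n = %d): RMSE = %.3f g/kg | nRMSE = %.2f%% | R2 = %.4f | rating: %s\n",
              x$n, x$rmse, x$nrmse, x$r2, x$rating))
  invisible(x)
}

#' @rdname validate_predictions
#' @param x A `validation_report`.
#' @param ... Unused.
#' @export
glance.validation_report <- function(x, ...) {
  tibble(rmse = x$rmse, nrmse = x$nrmse, r2 = x$r2, n = x$n, rating = x$rating)
}

#' Validate a fitted dilution curve against hold-out trial data
#'
#' Pairs the curve's prediction at each hold-out plot's observed biomass
#' with that plot's measured concentration, pooled over all treatments and
#' stages, and computes the agreement metrics of [validate_predictions()].
#'
#' @param fit A `cndc_fit` or `power_curve_fit`.
#' @param obs Hold-out plot-level trial observations.
#' @param part Plant fraction; defaults to the fraction the curve was built
#'   on when `fit` is a `cndc_fit`.
#' @param blocks_per_treatment Optional number of blocks sampled per
#'   treatment x stage (takes the first ones in block order), for designs
#'   validated on a subset of the sown replicates. `NULL` uses all blocks.
#' @return A `validation_report` with an added `pairs` tibble.
#' @export
validate_cndc <- function(fit, obs, part = NULL, blocks_per_treatment = NULL) {
  curve <- if (inherits(fit, "cndc_fit")) fit$curve else fit
  part <- part %||% (if (inherits(fit, "cndc_fit")) fit$part else "whole_plant")
  samples <- block_stage_samples(obs, part)
  if (!is.null(blocks_per_treatment)) {
    samples <- samples %>%
      group_by(.data$year, .data$treatment, .data$stage) %>%
      arrange(.data$block, .by_group = TRUE) %>%
      dplyr::slice_head(n = blocks_per_treatment) %>%
      ungroup()
  }
  report <- validate_predictions(predict_nc(curve, samples$biomass),
                                 samples$n_conc)
  report$pairs <- samples %>%
    mutate(predicted = predict_nc(curve, .data$biomass),
           observed = .data$n_conc)
  report
}
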