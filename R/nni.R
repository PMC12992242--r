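# Nitrogen nutrition index diagnosis and the linear-plateau relationship of
# relative yield with NNI.

#' Nitrogen nutrition index
#'
#' `NNI = Nt / Nc`: measured N concentration over the critical concentration
#' predicted at the same biomass. `NNI = 1` marks adequate nutrition, values
#' above 1 luxury uptake (surplus), values below 1 deficiency.
#'
#' @param nt Measured N concentration, g/kg (>= 0); vectorized.
#' @param nc Critical N concentration, g/kg (> 0); vectorized.
#' @return NNI, dimensionless.
#' @export
#' @examples
#' compute_nni(20, 20) # 1
compute_nni <- function(nt, nc) {
  if (any(nc <= 0, na.rm = TRUE)) {
    abort("compute_nni() requires nc > 0", class = "cndc_domain_error")
  }
  if (any(nt < 0, na.rm = TRUE)) {
    abort("compute_nni() requires nt >= 0", class = "cndc_domain_error")
  }
  nt / nc
}

#' Nitrogen status label from NNI
#'
#' Labels each NNI value `surplus` when above `1 + tolerance`, `deficient`
#' when below `1 - tolerance`, and `optimal` otherwise. The default
#' tolerance of 0 makes 1 the exact adequacy point.
#'
#' @param nni NNI values (>= 0).
#' @param tolerance Half-width of the `optimal` band around 1 (>= 0).
#' @return Factor with levels `deficient, optimal, surplus`.
#' @export
nni_status <- function(nni, tolerance = 0) {
  if (length(tolerance) != 1 || tolerance < 0) {
    abort("tolerance must be a single value >= 0", class = "cndc_config_error")
  }
  out <- case_when(
    nni > 1 + tolerance ~ "surplus",
    nni < 1 - tolerance ~ "deficient",
    TRUE ~ "optimal"
  )
  factor(out, levels = c("deficient", "optimal", "surplus"))
}

#' Diagnose nitrogen status of every treatment x stage
#'
#' Computes NNI records for each (year, treatment, stage) of a trial from a
#' fitted dilution curve: the critical concentration is predicted at the
#' sample's biomass, divided into the measured concentration, and labelled.
#' By default treatment-mean concentrations are used; `level = "block"`
#' diagnoses each replicate plot.
#'
#' @param obs Plot-level trial observations.
#' @param fit A `cndc_fit` or `power_curve_fit`.
#' @param part Plant fraction; defaults to the curve's fraction.
#' @param tolerance Optimal-band half width for [nni_status()].
#' @param level `"treatment"` (default) or `"block"`.
#' @return Tibble of NNI records: `year, treatment, n_rate, stage`
#'   (`block` when `level = "block"`), `part, biomass, nt, nc, nni, status`.
#' @export
diagnose_nni <- function(obs, fit, part = NULL, tolerance = 0,
                         level = c("treatment", "block")) {
  level <- match.arg(level)
  curve <- if (inherits(fit, "cndc_fit")) fit$curve else fit
  part <- part %||% (if (inherits(fit, "cndc_fit")) fit$part else "whole_plant")
  samples <- if (level == "treatment") {
    aggregate_stage_samples(obs, part)
  } else {
    block_stage_samples(obs, part) %>% mutate(part = .env$part)
  }
  samples %>%
    mutate(nt = .data$n_conc,
           nc = predict_nc(curve, .data$biomass),
           nni = compute_nni(.data$nt, .data$nc),
           status = nni_status(.data$nni, tolerance)) %>%
    select(dplyr::any_of(c("year", "treatment", "n_rate", "block", "stage",
                           "part", "biomass", "nt", "nc", "nni", "status")))
}

#' Relative yield within year
#'
#' Normalizes treatment-mean seed cotton yield by the maximum treatment mean
#' of the same year, so the best treatment scores 1.
#'
#' @param yields Tibble with columns `year, treatment, n_rate,
#'   seed_cotton_yield` (block- or treatment-level rows).
#' @return Tibble: `year, treatment, n_rate, yield_mean, ry`.
#' @export
relative_yield <- function(yields) {
  if (nrow(yields) == 0) {
    abort("relative_yield() needs at least one yield record", class = "cndc_domain_error")
  }
  if (any(yields$seed_cotton_yield <= 0)) {
    abort("relative_yield() requires strictly positive yields", class = "cndc_domain_error")
  }
  yields %>%
    group_by(.data$year, .data$treatment, .data$n_rate) %>%
    summarise(yield_mean = mean(.data$seed_cotton_yield), .groups = "drop") %>%
    group_by(.data$year) %>%
    mutate(ry = .data$yield_mean / max(.data$yield_mean)) %>%
    ungroup() %>%
    arrange(.data$year, .data$n_rate)
}

#' Linear-plateau fit of a response on a driver
#'
#' Fits the continuous piecewise model `y = intercept + slope * x` for
#' `x <= breakpoint` and `y = plateau` for `x > breakpoint`, with
#' `plateau = intercept + slope * breakpoint` (continuity). The breakpoint
#' is found by profiling the least-squares SSE over a dense grid of
#' candidates between `min(x)` and `max(x)`, then refined by golden-section
#' search around the best grid cell; the procedure is deterministic. The
#' grid includes `max(x)`, where the model reduces to a pure line, so the
#' fit's SSE never exceeds that of the best straight line.
#'
#' @param x Driver values (e.g. NNI); at least 4 points spanning more than
#'   one distinct value.
#' @param y Response values (e.g. relative yield), same length.
#' @param n_grid Number of breakpoint candidates (default 200).
#' @return A `linear_plateau_fit`: `slope`, `intercept`, `breakpoint`,
#'   `plateau`, `r2`, `sse`, `n_points`, and the `data`.
#' @export
fit_linear_plateau <- function(x, y, n_grid = 200) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "cndc_domain_error")
  }
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) {
    abort("fit_linear_plateau() needs at least 4 points", class = "cndc_domain_error")
  }
  if (length(unique(x)) < 2) {
    abort("no_breakpoint_support: all x values coincide", class = "cndc_no_breakpoint_support")
  }

  sse_at <- function(bp) {
    z <- pmin(x, bp)
    if (length(unique(z)) < 2) return(Inf)
    f <- lm(y ~ z)
    sum(f$residuals^2)
  }
  grid <- seq(min(x), max(x), length.out = n_grid)
  sses <- vapply(grid, sse_at, numeric(1))
  if (!any(is.finite(sses))) {
    abort("no_breakpoint_support: no candidate breakpoint admits a fit",
          class = "cndc_no_breakpoint_support")
  }
  i <- which.min(sses)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  bp <- if (lo < hi) {
    opt <- optimize(sse_at, interval = c(lo, hi), tol = 1e-10)
    if (opt$objective <= sses[i]) opt$minimum else grid[i]
  } else grid[i]

  z <- pmin(x, bp)
  f <- lm(y ~ z)
  intercept <- unname(coef(f)[1])
  slope <- unname(coef(f)[2])
  plateau <- intercept + slope * bp
  sse <- sum(f$residuals^2)
  sstot <- sum((y - mean(y))^2)
  structure(list(slope = slope, intercept = intercept, breakpoint = bp,
                 plateau = plateau, sse = sse,
                 r2 = if (sstot > 0) 1 - sse / sstot else NA_real_,
                 n_points = length(x), data = tibble(x = x, y = y)),
            class = "linear_plateau_fit")
}

#' Linear-plateau fit of relative yield on NNI
#'
#' Convenience wrapper joining NNI records at one stage with within-year
#' relative yields and fitting [fit_linear_plateau()] per part/year panel or
#' pooled.
#'
#' @param nni Tibble of NNI records from [diagnose_nni()].
#' @param yields Tibble of yield records.
#' @param stage Stage at which NNI drives yield (default `"boll_opening"`).
#' @param pool If `TRUE`, one fit pooled over years; otherwise (default) a
#'   fit per year.
#' @param n_grid Breakpoint grid size.
#' @return A named list of `linear_plateau_fit` objects (one per year, or
#'   `pooled`).
#' @export
fit_ry_nni <- function(nni, yields, stage = "boll_opening", pool = FALSE,
                       n_grid = 200) {
  ry <- relative_yield(yields)
  dat <- nni %>%
    filter(as.character(.data$stage) == .env$stage) %>%
    left_join(ry, by = c("year", "treatment", "n_rate"))
  if (pool) {
    return(list(pooled = fit_linear_plateau(dat$nni, dat$ry, n_grid = n_grid)))
  }
  dat %>%
    dplyr::group_split(.data$year) %>%
    setNames(vapply(., function(d) as.character(d$year[1]), character(1))) %>%
    purrr::map(~ fit_linear_plateau(.x$nni, .x$ry, n_grid = n_grid))
}

#' @export
print.linear_plateau_fit <- function(x, ...) {
  cat(sprintf("Linear-plateau fit (n = %d): y = %.4f x %+.4f for x <= %.4f; plateau %.4f\n",
              x$n_points, x$slope, x$intercept, x$breakpoint, x$plateau))
  cat(sprintf("  R2 = %.4f | SSE = %.4g\n", x$r2, x$sse))
  invisible(x)
}

#' @rdname fit_linear_plateau
#' @param x A `linear_plateau_fit`.
#' @param ... Unused.
#' @export
tidy.linear_plateau_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept", "breakpoint", "plateau"),
         estimate = c(x$slope, x$intercept, x$breakpoint, x$plateau))
}

#' @rdname fit_linear_plateau
#' @export
glance.linear_plateau_fit <- function(x, ...) {
  tibble(r.squared = x$r2, sse = x$sse, n.points = x$n_points)
}

#' @rdname fit_linear_plateau
#' @export
augment.linear_plateau_fit <- function(x, ...) {
  x$data %>%
    mutate(.fitted = predict_linear_plateau(x, .data$x),
           .resid = .data$y - .data$.fitted)
}

#' Evaluate a linear-plateau fit
#'
#' @param fit A `linear_plateau_fit`.
#' @param x Driver values.
#' @return Fitted response values.
#' @export
predict_linear_plateau <- function(fit, x) {
  fit$intercept + fit$slope * pmin(x, fit$breakpoint)
}
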