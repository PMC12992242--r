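# Downstream agronomic analytics: N use efficiency indices, yield stability
# and sustainability, quadratic yield response and economic optimum N rate,
# percent-change arithmetic, and the trait correlation matrix.

#' Default input prices for the economic analysis
#'
#' Seed cotton purchase price, manual harvest cost and urea price in
#' yuan/kg, the N mass fraction of urea, and the pure-N price available as
#' an override for the urea-derived N cost.
#'
#' @return Named list of prices.
#' @export
default_prices <- function() {
  list(seed_cotton_price = 5.8, harvest_cost = 2.6, urea_price = 3.8,
       urea_n_fraction = 0.464, pure_n_price = 8.3)
}

#' Nitrogen use efficiency indices per treatment
#'
#' Computes, for each fertilized treatment and year (with the zero-N control
#' as reference):
#' agronomic efficiency `NUEa = (Yn - Y0) / Fn`,
#' internal efficiency `NUEi = Yn * LP / NU` (lint yield per kg N taken up;
#' LP as a fraction, percent inputs above 1 auto-converted),
#' physiological efficiency `NUEp = (Yn - Y0) / (NUn - NU0)`,
#' apparent recovery `AREN = (NUn - NU0) / Fn`,
#' harvest index `HI = Yn / biomass * 100` (biomass in kg/ha),
#' and partial factor productivity `NPFP = Yn / Fn`.
#' Rate-normalized indices are undefined for the control and reported `NA`
#' with a reason; `NUEi` and `HI` are reported for every treatment.
#'
#' @param yields Plot- or treatment-level yield records: `year, treatment,
#'   n_rate, seed_cotton_yield, lint_percentage`.
#' @param uptake_samples Treatment-level stage samples (whole plant) from
#'   [aggregate_stage_samples()], providing end-of-season `biomass` (t/ha)
#'   and `n_uptake` (kg/ha); filtered to `stage`.
#' @param stage Stage whose uptake and biomass represent the season total
#'   (default `"boll_opening"`).
#' @return Tibble: one row per year x treatment with the six indices and a
#'   `note` column for excluded indices.
#' @export
nue_indices <- function(yields, uptake_samples, stage = "boll_opening") {
  y <- yields %>%
    group_by(.data$year, .data$treatment, .data$n_rate) %>%
    summarise(yn = mean(.data$seed_cotton_yield),
              lp = mean(.data$lint_percentage), .groups = "drop") %>%
    mutate(lp = ifelse(.data$lp > 1, .data$lp / 100, .data$lp))
  u <- uptake_samples %>%
    filter(as.character(.data$stage) == .env$stage) %>%
    select("year", "treatment", "n_rate", "biomass", "n_uptake")
  dat <- y %>% left_join(u, by = c("year", "treatment", "n_rate"))
  if (any(is.na(dat$n_uptake))) {
    abort(sprintf("missing uptake samples at stage '%s' for some treatments", stage),
          class = "cndc_domain_error")
  }
  ctrl <- dat %>% filter(.data$n_rate == 0) %>%
    select("year", y0 = "yn", nu0 = "n_uptake")
  if (nrow(ctrl) == 0) {
    abort("nue_indices() needs a zero-N control treatment", class = "cndc_domain_error")
  }
  dat %>%
    left_join(ctrl, by = "year") %>%
    mutate(
      fn = .data$n_rate,
      nue_i = .data$yn * .data$lp / .data$n_uptake,
      hi = .data$yn / (.data$biomass * 1000) * 100,
      nue_a = ifelse(.data$fn > 0, (.data$yn - .data$y0) / .data$fn, NA_real_),
      npfp = ifelse(.data$fn > 0, .data$yn / .data$fn, NA_real_),
      aren = ifelse(.data$fn > 0, (.data$n_uptake - .data$nu0) / .data$fn, NA_real_),
      nue_p = ifelse(.data$fn > 0 & .data$n_uptake != .data$nu0,
                     (.data$yn - .data$y0) / (.data$n_uptake - .data$nu0), NA_real_),
      note = case_when(
        .data$fn == 0 ~ "rate-normalized indices undefined for the zero-N control",
        .data$n_uptake == .data$nu0 ~ "nue_p undefined: uptake equals the control's",
        TRUE ~ NA_character_
      )
    ) %>%
    select("year", "treatment", "n_rate",
           "nue_a", "nue_i", "nue_p", "aren", "hi", "npfp", "note") %>%
    arrange(.data$year, .data$n_rate)
}

#' Yield stability and sustainability indices per treatment
#'
#' For each treatment, over its yearly (or replicate-year) yield
#' observations: mean yield `Y`, sample SD, stability index `SI = Y / SD`
#' (the `sd_over_y` convention gives the reciprocal), and sustainability
#' index `SYI = (Y - SD) / Ymax` where `Ymax` is the largest treatment mean.
#'
#' @param yields Tibble with `treatment, n_rate, seed_cotton_yield` (one row
#'   per year or replicate-year observation; at least 2 per treatment).
#' @param convention `"y_over_sd"` (default) or `"sd_over_y"`.
#' @return Tibble: `treatment, n_rate, mean_yield, sd_yield, si, syi`.
#' @export
stability_indices <- function(yields, convention = c("y_over_sd", "sd_over_y")) {
  convention <- match.arg(convention)
  out <- yields %>%
    group_by(.data$treatment, .data$n_rate) %>%
    summarise(mean_yield = mean(.data$seed_cotton_yield),
              sd_yield = sd(.data$seed_cotton_yield),
              n_obs = dplyr::n(), .groups = "drop")
  if (any(out$n_obs < 2)) {
    abort("stability_indices() needs >= 2 yield observations per treatment",
          class = "cndc_domain_error")
  }
  ymax <- max(out$mean_yield)
  if (any(out$sd_yield == 0)) {
    warn("zero yield SD for some treatment(s); SI reported as Inf")
  }
  out %>%
    mutate(
      si = if (convention == "y_over_sd") .data$mean_yield / .data$sd_yield
           else .data$sd_yield / .data$mean_yield,
      syi = (.data$mean_yield - .data$sd_yield) / ymax
    ) %>%
    select("treatment", "n_rate", "mean_yield", "sd_yield", "si", "syi") %>%
    arrange(.data$n_rate)
}

#' Quadratic yield response to N rate
#'
#' Least-squares fit of `Y = a x^2 + b x + c` over (rate, yield) pairs, with
#' the vertex rate `-b / (2a)` reported as the maximum-yield N rate when the
#' curvature is negative.
#'
#' @param n_rates N rates, kg/ha; at least 3 distinct values.
#' @param yields Yields, kg/ha, same length.
#' @return A `yield_quadratic` list: `a, b, c, vertex_rate, vertex_yield,
#'   r2, has_maximum`.
#' @export
fit_yield_quadratic <- function(n_rates, yields) {
  if (length(unique(n_rates)) < 3) {
    abort("fit_yield_quadratic() needs >= 3 distinct N rates", class = "cndc_domain_error")
  }
  fit <- lm(yields ~ n_rates + I(n_rates^2))
  cc <- coef(fit)
  a <- unname(cc[3]); b <- unname(cc[2]); c0 <- unname(cc[1])
  has_max <- is.finite(a) && a < 0
  if (!has_max) {
    warn("quadratic curvature is non-negative; vertex is not a maximum")
  }
  vertex <- if (is.finite(a) && a != 0) -b / (2 * a) else NA_real_
  structure(list(a = a, b = b, c = c0,
                 vertex_rate = vertex,
                 vertex_yield = if (!is.na(vertex)) c0 - b^2 / (4 * a) else NA_real_,
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 has_maximum = has_max,
                 n = length(yields)),
            class = "yield_quadratic")
}

#' @export
print.yield_quadratic <- function(x, ...) {
  cat(sprintf("Yield response: Y = %.5g x^2 + %.5g x + %.5g (R2 = %.3f, n = %d)\n",
              x$a, x$b, x$c, x$r2, x$n))
  if (x$has_maximum) {
    cat(sprintf("  maximum-yield N rate: %.2f kg/ha (Y = %.1f kg/ha)\n",
                x$vertex_rate, x$vertex_yield))
  }
  invisible(x)
}

#' Net-benefit curve from a yield response and prices
#'
#' Transforms a quadratic seed-cotton response `Y(x)` into the net benefit
#' `w(x) = (P_sc - C_harvest) * Y(x) - cost_N * x`, where the per-kg-N cost
#' is the urea price divided by the urea N fraction by default, or the
#' stated pure-N price when `use_pure_n_price = TRUE`.
#'
#' @param yield_quad A `yield_quadratic` or numeric `c(a, b, c)`.
#' @param prices Price list as in [default_prices()].
#' @param use_pure_n_price Use `pure_n_price` instead of
#'   `urea_price / urea_n_fraction` for the N cost.
#' @return Numeric `c(a, b, c)` of the benefit quadratic, yuan/ha vs kg N/ha.
#' @export
build_benefit_curve <- function(yield_quad, prices = default_prices(),
                                use_pure_n_price = FALSE) {
  q <- if (inherits(yield_quad, "yield_quadratic"))
    c(yield_quad$a, yield_quad$b, yield_quad$c) else unname(yield_quad)
  margin <- prices$seed_cotton_price - prices$harvest_cost
  n_cost <- if (use_pure_n_price) prices$pure_n_price
            else prices$urea_price / prices$urea_n_fraction
  c(a = margin * q[1], b = margin * q[2] - n_cost, c = margin * q[3])
}

#' Economic optimum N rate from a benefit quadratic
#'
#' For a concave benefit curve `w(x) = a x^2 + b x + c` (`a < 0`), the
#' optimum rate is the vertex `-b / (2a)` and the maximum benefit the
#' vertex value `c - b^2 / (4a)`.
#'
#' @param benefit_quad Numeric `c(a, b, c)` with `a < 0`.
#' @param prices Price list echoed on the result.
#' @return An `economic_result` list: `quad, optimal_rate, max_benefit,
#'   prices`.
#' @export
#' @examples
#' economic_optimum(c(-0.02656, 15.22544, 3756.48))
economic_optimum <- function(benefit_quad, prices = default_prices()) {
  q <- unname(benefit_quad)
  if (q[1] >= 0) {
    abort("benefit quadratic has no maximum (leading coefficient >= 0)",
          class = "cndc_no_maximum_error")
  }
  structure(list(quad = q,
                 optimal_rate = -q[2] / (2 * q[1]),
                 max_benefit = q[3] - q[2]^2 / (4 * q[1]),
                 prices = prices),
            class = "economic_result")
}

#' @export
print.economic_result <- function(x, ...) {
  cat(sprintf("Benefit curve: w = %.5g x^2 + %.5g x + %.5g\n",
              x$quad[1], x$quad[2], x$quad[3]))
  cat(sprintf("  economic optimum N rate: %.2f kg/ha | maximum benefit: %.2f yuan/ha\n",
              x$optimal_rate, x$max_benefit))
  invisible(x)
}

#' @rdname economic_optimum
#' @param x An `economic_result`.
#' @param ... Unused.
#' @export
glance.economic_result <- function(x, ...) {
  tibble(optimal_rate = x$optimal_rate, max_benefit = x$max_benefit,
         a = x$quad[1], b = x$quad[2], c = x$quad[3])
}

#' Percent change relative to a reference
#'
#' `100 * (new - ref) / ref`; the round trip
#' `percent_change(ref * (1 + p/100), ref) = p` holds for all `p`.
#'
#' @param new New value(s).
#' @param ref Reference value(s), nonzero.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(103.13, 29.08) # ~254.64
percent_change <- function(new, ref) {
  if (any(ref == 0, na.rm = TRUE)) {
    abort("percent_change() requires a nonzero reference", class = "cndc_domain_error")
  }
  100 * (new - ref) / ref
}

#' Pairwise Pearson correlation matrix with significance
#'
#' Pearson coefficients and two-sided p-values for every pair of numeric
#' columns. Zero-variance columns are flagged: their rows and columns are
#' `NA` with a warning.
#'
#' @param table Data frame of numeric columns, at least 3 rows.
#' @param alpha Significance level for the `signif` flag.
#' @return A `correlation_matrix` list: `r` and `p` matrices, `signif`
#'   logical matrix, `n` rows used.
#' @export
correlation_matrix <- function(table, alpha = 0.05) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  if (!all(num)) {
    abort(sprintf("non-numeric column(s): %s",
                  paste(names(table)[!num], collapse = ", ")),
          class = "cndc_domain_error")
  }
  if (nrow(table) < 3) {
    abort("correlation_matrix() needs at least 3 rows", class = "cndc_domain_error")
  }
  vars <- names(table)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  degenerate <- vapply(table, function(col) sd(col) == 0, logical(1))
  if (any(degenerate)) {
    warn(sprintf("zero-variance column(s) flagged undefined: %s",
                 paste(vars[degenerate], collapse = ", ")))
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (degenerate[i] || degenerate[j]) next
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (j < i) { r[i, j] <- r[j, i]; p[i, j] <- p[j, i]; next }
      ct <- cor.test(table[[i]], table[[j]], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, signif = p < alpha, n = nrow(table),
                 alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation matrix (n = %d):\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' @rdname correlation_matrix
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @export
tidy.correlation_matrix <- function(x, ...) {
  vars <- rownames(x$r)
  tidyr::expand_grid(var1 = vars, var2 = vars) %>%
    filter(match(.data$var1, vars) < match(.data$var2, vars)) %>%
    mutate(r = x$r[cbind(.data$var1, .data$var2)],
           p_value = x$p[cbind(.data$var1, .data$var2)],
           signif = .data$p_value < x$alpha)
}
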