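make_nue_inputs <- function(yn, y0, fn, nun, nu0, lp = 40, biomass = 10) {
  yields <- tibble::tibble(
    year = 2023L, treatment = c("N0", "Nx"), n_rate = c(0, fn),
    seed_cotton_yield = c(y0, yn), lint_percentage = lp)
  uptake <- tibble::tibble(
    year = 2023L, treatment = c("N0", "Nx"), n_rate = c(0, fn),
    stage = "boll_opening", part = "whole_plant",
    biomass = biomass, n_uptake = c(nu0, nun))
  list(yields = yields, uptake = uptake)
}

test_that("NUE indices reproduce hand arithmetic", {
  inp <- make_nue_inputs(yn = 3600, y0 = 2400, fn = 240, nun = 150, nu0 = 60,
                         lp = 40, biomass = 10)
  out <- nue_indices(inp$yields, inp$uptake)
  trt <- out[out$treatment == "Nx", ]
  expect_equal(trt$nue_a, (3600 - 2400) / 240) # 5.0
  expect_equal(trt$npfp, 3600 / 240)           # 15.0
  expect_equal(trt$aren, (150 - 60) / 240)     # 0.375
  expect_equal(trt$nue_p, (3600 - 2400) / (150 - 60))
  expect_equal(trt$nue_i, 3600 * 0.40 / 150)   # percent LP auto-converted
  expect_equal(trt$hi, 3600 / (10 * 1000) * 100) # 36%
  ctrl <- out[out$treatment == "N0", ]
  expect_true(is.na(ctrl$nue_a) && is.na(ctrl$npfp) && is.na(ctrl$aren))
  expect_equal(ctrl$nue_i, 2400 * 0.40 / 60)
  expect_match(ctrl$note, "zero-N control")
})

test_that("zero yield increment gives zero agronomic efficiency; equal uptake flags nue_p", {
  inp <- make_nue_inputs(yn = 2400, y0 = 2400, fn = 120, nun = 60, nu0 = 60)
  out <- nue_indices(inp$yields, inp$uptake)
  trt <- out[out$treatment == "Nx", ]
  expect_equal(trt$nue_a, 0)
  expect_true(is.na(trt$nue_p))
  expect_match(trt$note, "nue_p undefined")
})

test_that("NUE scale relations hold under common rescaling", {
  inp <- make_nue_inputs(yn = 3600, y0 = 2400, fn = 240, nun = 150, nu0 = 60)
  base <- nue_indices(inp$yields, inp$uptake)[2, ]
  k <- 1.7
  inp2 <- inp
  inp2$yields$seed_cotton_yield <- inp$yields$seed_cotton_yield * k
  inp2$uptake$n_uptake <- inp$uptake$n_uptake * k
  inp2$uptake$biomass <- inp$uptake$biomass * k
  scaled <- nue_indices(inp2$yields, inp2$uptake)[2, ]
  expect_equal(scaled$nue_a, base$nue_a * k)
  expect_equal(scaled$npfp, base$npfp * k)
  expect_equal(scaled$aren, base$aren * k)
  expect_equal(scaled$hi, base$hi)        # yield and biomass scale together
  expect_equal(scaled$nue_i, base$nue_i)  # ratio of two k-scaled quantities
})

test_that("a missing zero-N control is an error", {
  inp <- make_nue_inputs(yn = 3600, y0 = 2400, fn = 240, nun = 150, nu0 = 60)
  expect_error(nue_indices(inp$yields[2, ], inp$uptake[2, ]),
               class = "cndc_domain_error")
})

test_that("stability and sustainability indices match hand arithmetic", {
  y <- tibble::tibble(
    treatment = rep(c("A", "B"), each = 2), n_rate = rep(c(120, 240), each = 2),
    seed_cotton_yield = c(4000, 5000, 5000, 5000))
  expect_warning(out <- stability_indices(y), "Inf")
  a <- out[out$treatment == "A", ]
  expect_equal(a$mean_yield, 4500)
  expect_equal(a$sd_yield, sqrt(((4000 - 4500)^2 + (5000 - 4500)^2) / 1),
               tolerance = 1e-12) # ~707.1068
  expect_equal(a$syi, (4500 - a$sd_yield) / 5000, tolerance = 1e-12) # ~0.7586
  expect_equal(round(a$syi, 4), 0.7586)
  b <- out[out$treatment == "B", ]
  expect_equal(b$sd_yield, 0)
  expect_equal(b$syi, 1) # identical yields at the top treatment
  expect_true(is.infinite(b$si))

  flipped <- suppressWarnings(stability_indices(y, convention = "sd_over_y"))
  expect_equal(flipped$si[flipped$treatment == "A"],
               1 / a$si)
  expect_error(stability_indices(y[c(1, 3, 4), ]), class = "cndc_domain_error")
})

test_that("quadratic yield response recovers exact polynomials and flags non-maxima", {
  x <- c(0, 60, 120, 180, 240, 300)
  y <- -0.01 * x^2 + 4 * x + 1000
  fit <- fit_yield_quadratic(x, y)
  expect_equal(fit$a, -0.01, tolerance = 1e-9)
  expect_equal(fit$b, 4, tolerance = 1e-9)
  expect_equal(fit$c, 1000, tolerance = 1e-9)
  expect_equal(fit$vertex_rate, 200, tolerance = 1e-6)
  expect_true(fit$has_maximum)

  expect_warning(up <- fit_yield_quadratic(x, 0.01 * x^2 + x), "not a maximum")
  expect_false(up$has_maximum)
  expect_error(fit_yield_quadratic(c(0, 60), c(1, 2)), class = "cndc_domain_error")
})

test_that("economic optimum matches the closed form and a fine grid scan", {
  econ <- economic_optimum(c(-0.02656, 15.22544, 3756.48))
  expect_equal(econ$optimal_rate, -15.22544 / (2 * -0.02656))
  expect_equal(econ$max_benefit, 3756.48 - 15.22544^2 / (4 * -0.02656))
  expect_equal(round(econ$optimal_rate, 2), 286.62)
  expect_equal(round(econ$max_benefit, 2), 5938.46)

  unitp <- economic_optimum(c(-1, 2, 0))
  expect_equal(unitp$optimal_rate, 1)
  expect_equal(unitp$max_benefit, 1)

  grid <- seq(0, 600, by = 0.001)
  w <- -0.02656 * grid^2 + 15.22544 * grid + 3756.48
  expect_equal(econ$optimal_rate, grid[which.max(w)], tolerance = 1e-3)
  expect_equal(econ$max_benefit, max(w), tolerance = 1e-6)

  expect_error(economic_optimum(c(0.1, 1, 1)), class = "cndc_no_maximum_error")
})

test_that("the benefit curve applies margin and N cost to a yield response", {
  prices <- default_prices()
  q <- c(-0.02, 18, 2400)
  w <- build_benefit_curve(q, prices)
  margin <- 5.8 - 2.6
  expect_equal(unname(w["a"]), margin * -0.02)
  expect_equal(unname(w["b"]), margin * 18 - 3.8 / 0.464)
  expect_equal(unname(w["c"]), margin * 2400)
  w2 <- build_benefit_curve(q, prices, use_pure_n_price = TRUE)
  expect_equal(unname(w2["b"]), margin * 18 - 8.3)
})

test_that("percent change matches printed-table arithmetic and round-trips", {
  expect_equal(round(percent_change(103.13, 29.08), 2), 254.64)
  expect_equal(round(percent_change(1526.7, 974.9), 2), 56.60)
  expect_equal(percent_change(5, 5), 0)
  for (p in c(-50, -1, 0, 3.7, 254.64)) {
    expect_equal(percent_change(100 * (1 + p / 100), 100), p)
  }
  expect_error(percent_change(1, 0), class = "cndc_domain_error")
})

test_that("correlation matrix matches the textbook formula oracle", {
  set.seed(13)
  tab <- data.frame(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  cm <- correlation_matrix(tab)
  for (i in 1:3) for (j in 1:3) {
    x <- tab[[i]]; y <- tab[[j]]
    r_o <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cm$r[i, j], r_o, tolerance = 1e-12)
    if (i != j) {
      t_o <- r_o * sqrt(3) / sqrt(1 - r_o^2)
      expect_equal(cm$p[i, j], 2 * pt(-abs(t_o), 3), tolerance = 1e-12)
    }
  }
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(cm$r))

  anti <- data.frame(x = 1:5, y = -(1:5))
  expect_equal(correlation_matrix(anti)$r["x", "y"], -1)

  degen <- data.frame(x = 1:5, z = rep(2, 5))
  expect_warning(cmd <- correlation_matrix(degen), "zero-variance")
  expect_true(all(is.na(cmd$r["z", ])))

  td <- tidy(cm)
  expect_equal(nrow(td), 3)
  expect_equal(td$r[td$var1 == "a" & td$var2 == "b"], cm$r["a", "b"])
})
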