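# Construction and validation of the dilution curve, checked against
# independent oracles (textbook Welch test, normal-equation OLS, grid-search
# SSE minimization).

test_that("limiting classification separates treatments as pairwise tests dictate", {
  # biomass means 1.0, 2.0, 2.02 t/ha with tight SD: T1 clearly below the
  # top treatment, T2 indistinguishable from T3
  blocks <- make_stage_blocks(c("T1", "T2", "T3"), c(0, 120, 240),
                              means = c(1.0, 2.0, 2.02), sds = rep(0.02, 3))
  g <- classify_limiting(blocks, alpha = 0.05)
  # oracle: textbook Welch p-values against the top-biomass treatment
  b3 <- blocks$biomass[blocks$treatment == "T3"]
  p1 <- welch_p(blocks$biomass[blocks$treatment == "T1"], b3)
  p2 <- welch_p(blocks$biomass[blocks$treatment == "T2"], b3)
  expect_lt(p1, 0.05)
  expect_gt(p2, 0.05)
  expect_setequal(g$limited, "T1")
  expect_setequal(g$non_limited, c("T2", "T3"))
  expect_equal(g$dw_ref, mean(c(2.0, 2.02)))

  # strictly separated biomasses: only the top treatment is non-limited
  wide <- make_stage_blocks(c("T1", "T2", "T3"), c(0, 120, 240),
                            means = c(1, 2, 3), sds = rep(0.001, 3))
  g2 <- classify_limiting(wide, alpha = 0.05)
  expect_setequal(g2$limited, c("T1", "T2"))
  expect_setequal(g2$non_limited, "T3")
})

test_that("degenerate classifications are flagged, not guessed", {
  same <- make_stage_blocks(c("T1", "T2", "T3"), c(0, 120, 240),
                            means = rep(2, 3), sds = rep(0, 3))
  g <- classify_limiting(same)
  expect_length(g$limited, 0)
  expect_equal(g$flag, "no_critical_point")
  expect_error(critical_point(g), class = "cndc_skipped_stage")

  two <- make_stage_blocks(c("T1", "T2", "T3"), c(0, 120, 240),
                           means = c(1, 2.9995, 3), sds = rep(0.001, 3))
  g2 <- classify_limiting(two)
  expect_equal(g2$flag, "insufficient_limited")

  one_block <- make_stage_blocks(c("T1", "T2"), c(0, 240),
                                 means = c(1, 2), sds = c(0.1, 0.1))[c(1, 5), ]
  expect_error(classify_limiting(one_block), class = "cndc_replication_error")
})

test_that("tukey contrasts are accepted as the post-hoc alternative", {
  blocks <- make_stage_blocks(c("T1", "T2", "T3"), c(0, 120, 240),
                              means = c(1, 2, 2.02), sds = rep(0.02, 3))
  g <- classify_limiting(blocks, method = "tukey")
  expect_setequal(g$limited, "T1")
  expect_setequal(g$non_limited, c("T2", "T3"))
})

test_that("critical point is the limited line evaluated at the plateau biomass", {
  # exact line: N = 10 + 2*DW over limited treatments; dw_ref = 5
  blocks <- make_stage_blocks(c("T1", "T2", "T3"), c(0, 60, 300),
                              means = c(2, 3, 5), sds = rep(0.001, 3),
                              conc = c(10 + 2 * 2, 10 + 2 * 3, 19))
  g <- classify_limiting(blocks)
  expect_setequal(g$limited, c("T1", "T2"))
  cp <- critical_point(g)
  expect_equal(cp$dw, 5, tolerance = 1e-3)
  expect_equal(cp$nc, 10 + 2 * cp$dw, tolerance = 1e-6)
})

test_that("limited-group line matches a normal-equation OLS oracle", {
  xs <- c(2.0, 2.5, 3.0)
  ys <- c(14.0, 15.0, 16.4)
  dw_ref <- 3.4
  # independent brute-force OLS via the closed-form normal equations
  slope_o <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  int_o <- mean(ys) - slope_o * mean(xs)
  blocks <- make_stage_blocks(c("T1", "T2", "T3", "T4"), c(0, 60, 120, 300),
                              means = c(xs, dw_ref), sds = rep(1e-4, 4),
                              conc = c(ys, 18))
  g <- classify_limiting(blocks)
  expect_setequal(g$limited, c("T1", "T2", "T3"))
  cp <- critical_point(g)
  expect_equal(cp$nc, int_o + slope_o * dw_ref, tolerance = 1e-3)
})

test_that("two exact points determine the power curve; noiseless points recover it", {
  fit2 <- fit_power_curve(tibble::tibble(dw = c(1, 4), nc = c(5.0, 2.5)))
  expect_equal(fit2$a_c, 5, tolerance = 1e-9)
  expect_equal(fit2$b, 0.5, tolerance = 1e-9)

  dw <- c(1, 2, 4, 8)
  pts <- tibble::tibble(dw = dw, nc = 26.936 * dw^(-0.284))
  fit <- fit_power_curve(pts)
  expect_equal(fit$a_c, 26.936, tolerance = 1e-9)
  expect_equal(fit$b, 0.284, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("power fit matches a dense grid-search oracle on perturbed points", {
  set.seed(3)
  dw <- c(1.2, 2.5, 4, 6.5, 9, 13)
  nc <- 24 * dw^(-0.26) * exp(rnorm(6, 0, 0.03))
  fit <- fit_power_curve(tibble::tibble(dw = dw, nc = nc))
  # oracle: exhaustive SSE scan over an (a, b) grid, refined once
  sse <- function(a, b) sum((nc - a * dw^(-b))^2)
  best <- c(a = NA, b = NA, sse = Inf)
  a_grid <- seq(15, 35, length.out = 300)
  b_grid <- seq(0.05, 0.6, length.out = 300)
  for (a in a_grid) for (b in b_grid) {
    s <- sse(a, b)
    if (s < best["sse"]) best <- c(a = a, b = b, sse = s)
  }
  a_grid <- seq(best["a"] - 0.2, best["a"] + 0.2, length.out = 200)
  b_grid <- seq(best["b"] - 0.01, best["b"] + 0.01, length.out = 200)
  for (a in a_grid) for (b in b_grid) {
    s <- sse(a, b)
    if (s < best["sse"]) best <- c(a = a, b = b, sse = s)
  }
  expect_equal(fit$a_c, unname(best["a"]), tolerance = 1e-3)
  expect_equal(fit$b, unname(best["b"]), tolerance = 1e-2)
  expect_lte(sse(fit$a_c, fit$b), best[["sse"]] * (1 + 1e-9))
})

test_that("rescaling biomass rescales a_c by k^b and leaves b unchanged", {
  dw <- c(1, 3, 6, 10)
  pts <- tibble::tibble(dw = dw, nc = 20 * dw^(-0.3))
  f1 <- fit_power_curve(pts)
  for (k in c(0.5, 2, 10)) {
    f2 <- fit_power_curve(tibble::tibble(dw = k * dw, nc = pts$nc))
    expect_equal(f2$b, f1$b, tolerance = 1e-7)
    expect_equal(f2$a_c, f1$a_c * k^f1$b, tolerance = 1e-6)
  }
})

test_that("prediction honours its domain and the exponent identity", {
  fit <- list(a_c = 2, b = 0.5)
  expect_equal(predict_nc(fit, 4), 1.0)
  expect_equal(predict_nc(list(a_c = 23.504, b = 0.226), 1), 23.504)
  expect_error(predict_nc(fit, 0), class = "cndc_domain_error")
  expect_error(fit_power_curve(tibble::tibble(dw = 1, nc = 5)),
               class = "cndc_domain_error")
  expect_error(fit_power_curve(tibble::tibble(dw = c(1, -2), nc = c(5, 3))),
               class = "cndc_domain_error")
})

test_that("validation metrics match hand arithmetic and are permutation-invariant", {
  v <- validate_predictions(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(v$rmse, sqrt((0.01 + 0.01 + 0.04) / 3))
  expect_equal(v$nrmse, v$rmse * 100 / mean(c(1.1, 1.9, 3.2)))
  expect_equal(v$r2, cor(c(1, 2, 3), c(1.1, 1.9, 3.2))^2)

  # identity pairs: zero error, perfect rating
  id <- validate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$rmse, 0)
  expect_equal(id$nrmse, 0)
  expect_equal(id$r2, 1)
  expect_equal(id$rating, "excellent")

  # hand value: predictions (1,2,3) against constant observations have
  # rmse sqrt(2/3) and nRMSE ~40.82% (poor), with R2 undefined
  expect_equal(sqrt(mean((c(1, 2, 3) - 2)^2)), sqrt(2 / 3))
  expect_error(validate_predictions(c(1, 2, 3), c(2, 2, 2)),
               class = "cndc_domain_error")
  expect_equal(nrmse_rating(sqrt(2 / 3) * 100 / 2), "poor")

  perm <- sample(3)
  vp <- validate_predictions(c(1, 2, 3)[perm], c(1.1, 1.9, 3.2)[perm])
  expect_equal(vp$rmse, v$rmse)
  expect_equal(vp$r2, v$r2)
})

test_that("nRMSE rating bands fall exactly at 10, 20 and 30 percent", {
  expect_equal(nrmse_rating(c(0, 9.99, 10, 15.10, 19.99, 20, 25, 29.99, 30, 45)),
               c("excellent", "excellent", "good", "good", "good",
                 "fair", "fair", "fair", "poor", "poor"))
})

test_that("stages without a critical point are dropped with a warning, not an error", {
  cfg <- synthetic_trial_config(noise_cv = 0)
  tr <- generate_trial(cfg)
  obs <- tr$observations
  # flatten one stage: identical biomass for all treatments at initial_flowering
  flat <- obs$stage == "initial_flowering"
  obs$dry_matter[flat] <- ifelse(obs$part[flat] == "vegetative", 2, 1)
  expect_warning(fit <- fit_cndc(obs), "no_critical_point")
  expect_equal(nrow(fit$critical_points), 3)
  expect_true("initial_flowering" %in% fit$skipped$stage)
})
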