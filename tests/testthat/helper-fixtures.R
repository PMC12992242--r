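# Small programmatic fixtures shared across test files.

suppressMessages(library(dplyr))

# Plot-level observations for one year, arbitrary values passed as vectors
# recycled over the expanded design.
make_obs <- function(treatments, n_rates, blocks, stages, dry_matter, n_conc,
                     year = 2023L, parts = c("vegetative", "reproductive")) {
  grid <- expand.grid(part = parts, block = blocks, stage = stages,
                      treatment = treatments, stringsAsFactors = FALSE)
  grid$year <- year
  grid$n_rate <- n_rates[match(grid$treatment, treatments)]
  grid$dry_matter <- rep_len(dry_matter, nrow(grid))
  grid$n_conc <- rep_len(n_conc, nrow(grid))
  validate_trial_observations(
    tibble::as_tibble(grid[, c("year", "treatment", "n_rate", "block",
                               "stage", "part", "dry_matter", "n_conc")]),
    stages = stages)
}

# Block-level samples for one stage, from per-treatment means and SDs with a
# deterministic symmetric block pattern (mean-preserving, sample SD exact).
make_stage_blocks <- function(treatments, n_rates, means, sds, n_blocks = 4,
                              conc = NULL, stage = "peak_boll") {
  # symmetric offsets with sample SD exactly `sd`
  offsets <- c(-1, -1/3, 1/3, 1)
  offsets <- offsets / sd(offsets)
  stopifnot(n_blocks == 4)
  conc <- conc %||% rep(20, length(treatments))
  purrr::map_dfr(seq_along(treatments), function(i) {
    tibble::tibble(
      year = 2023L, treatment = treatments[i], n_rate = n_rates[i],
      block = paste0("B", 1:n_blocks), stage = stage,
      biomass = means[i] + sds[i] * offsets,
      n_conc = conc[i]
    ) %>% dplyr::mutate(n_uptake = biomass * n_conc)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Welch t-test p-value from the textbook formulas (oracle).
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}
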