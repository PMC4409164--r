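test_that("percentile diameters interpolate on the phi scale", {
  # exact crossing is returned verbatim
  d1 <- grain_size_distribution(c(62.5, 250, 1000), c(10, 50, 100))
  expect_equal(percentile_diameter(d1, 50), 250)
  # two-bin log-linear interpolation lands on the geometric mean
  d2 <- grain_size_distribution(c(62.5, 250), c(0, 100))
  expect_equal(percentile_diameter(d2, 50), 125)
  # monotone in q, D10 <= D50, over random valid distributions
  set.seed(4)
  for (i in 1:20) {
    edges <- 2^seq(0, 12, length.out = 9)
    cum <- sort(runif(9, 0, 100)); cum[9] <- 100
    d <- grain_size_distribution(edges, cum)
    qs <- c(10, 25, 50, 75, 90)
    qs <- qs[qs >= min(cum)]
    vals <- vapply(qs, function(q) percentile_diameter(d, q), numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
  expect_error(percentile_diameter(d1, 5), "outside the observed")
  expect_error(grain_size_distribution(c(100, 50), c(50, 100)), "increasing")
})

test_that("size fractions partition the mass into the six classes", {
  # all mass below 4 um -> pure clay
  all_clay <- grain_size_distribution(c(1, 2, 4), c(40, 80, 100))
  expect_equal(unname(size_fractions(all_clay)["clay"]), 100)
  # everything between 63 and 250 um -> pure fine sand
  fine <- grain_size_distribution(c(63, 125, 250), c(0, 50, 100))
  expect_equal(unname(size_fractions(fine)["fine_sand"]), 100)
  # arbitrary 8-bin fixture vs brute-force bin accounting (log-uniform
  # within each input bin, split at the class bounds)
  edges <- c(2, 8, 31.5, 63, 125, 500, 1000, 4000)
  cum <- c(5, 15, 30, 42, 60, 85, 92, 100)
  d <- grain_size_distribution(edges, cum)
  bounds <- c(4, 63, 250, 500, 2000)
  mass_below <- function(s) {
    if (s <= edges[1]) return(0)
    if (s >= edges[length(edges)]) return(100)
    i <- findInterval(s, edges)
    cum[i] + (cum[i + 1] - cum[i]) *
      (log2(s) - log2(edges[i])) / (log2(edges[i + 1]) - log2(edges[i]))
  }
  oracle <- diff(c(0, vapply(bounds, mass_below, numeric(1)), 100))
  # the first input bin already holds 5% with no recorded lower edge; the
  # package credits that mass to the first edge (2 um), i.e. clay
  oracle[1] <- oracle[1] + (5 - mass_below(4)) * 0 # bounds[1] > edges[1]: none
  expect_equal(unname(size_fractions(d)), oracle, tolerance = 1e-9)
  expect_equal(sum(size_fractions(d)), 100, tolerance = 0.1)
})

test_that("size fractions are invariant under bin refinement", {
  set.seed(11)
  edges <- 2^seq(1, 12, length.out = 12)
  cum <- c(sort(runif(11, 0, 100)), 100)
  coarse <- grain_size_distribution(edges, cum)
  # refine: insert log-midpoints with interpolated cumulative values
  phi <- log2(edges)
  phi_f <- sort(c(phi, phi[-1] - diff(phi) / 2))
  cum_f <- approx(phi, cum, xout = phi_f)$y
  fine <- grain_size_distribution(2^phi_f, cum_f)
  expect_equal(size_fractions(coarse), size_fractions(fine), tolerance = 1e-9)
})

test_that("granulometry summary satisfies its invariants", {
  set.seed(9)
  edges <- 2^seq(-1, 13, by = 0.5)
  cum <- 100 * pnorm(log2(edges), mean = 7, sd = 1.5)
  cum <- cum / max(cum) * 100
  g <- granulometry_summary(grain_size_distribution(edges, cum))
  expect_lte(g$D10, g$D50)
  expect_equal(g$pct_clay + g$pct_silt + g$pct_fine_sand + g$pct_medium_sand +
                 g$pct_coarse_sand + g$pct_gravel, 100, tolerance = 0.1)
})

test_that("salinity-range regression fits, predicts and clips", {
  # exact line is recovered to near machine precision
  x <- c(4.50, 12, 20, 30, 41.67)
  y <- 2 + 0.31 * x
  m <- suppressWarnings(fit_salinity_range_model(x, y, kind = "distance"))
  expect_equal(m$intercept, 2, tolerance = 1e-10)
  expect_equal(m$slope, 0.31, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_equal(predict_salinity_range(m, x), y, tolerance = 1e-10)
  # batch prediction preserves order and equals scalar calls
  xs <- seq(5, 40, length.out = 15)
  batch <- predict_salinity_range(m, xs)
  expect_equal(batch, vapply(xs, function(v) predict_salinity_range(m, v),
                             numeric(1)))
  # negative extrapolation clips at zero with a warning
  m2 <- suppressWarnings(fit_salinity_range_model(c(1, 2, 3), c(3, 2, 1)))
  expect_warning(v <- predict_salinity_range(m2, 10), "clip")
  expect_equal(v, 0)
  expect_error(fit_salinity_range_model(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(predict_salinity_range(list(), 1), "fitted")
  # externally established coefficients bypass fitting
  ext <- fit_salinity_range_model(coefficients = c(1, 0.5),
                                  kind = "mean_salinity")
  expect_equal(predict_salinity_range(ext, 10), 6)
})

test_that("noisy regression recovers the slope with honest uncertainty", {
  hits <- 0L
  set.seed(17)
  for (i in 1:200) {
    x <- runif(50, 0, 40)
    y <- 1 + 0.3 * x + rnorm(50, 0, 1.5)
    f <- lm(y ~ x)
    se <- summary(f)$coefficients["x", "Std. Error"]
    m <- fit_salinity_range_model(x, y)
    if (abs(m$slope - 0.3) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("env matrix assembly joins on stations and tracks macrofauna", {
  env <- generate_env_gradient(estuary_scenario(seed = 71))
  hydro <- env[, c("station", "spring_tidal_range", "mean_velocity",
                   "max_velocity", "mean_bed_shear_stress",
                   "max_bed_shear_stress")]
  gran <- env[, c("station", "D50", "D10", "pct_clay", "pct_silt",
                  "pct_fine_sand", "pct_medium_sand", "pct_coarse_sand",
                  "pct_gravel")]
  sal <- env[, c("station", "salinity_range")]
  full <- assemble_env_matrix(hydro, gran, sal)
  expect_equal(dim(env_values(full)), c(20L, 14L))
  expect_identical(colnames(env_values(full)), env_driver_names())
  # macrofauna for 17 of 20 stations: core view keeps 20, macro view 17
  set.seed(2)
  macro <- data.frame(station = env$station[-c(3, 7, 11)],
                      macrofauna_species_richness = rpois(17, 8),
                      macrofauna_abundance = rpois(17, 40),
                      macrofauna_biomass = runif(17, 1, 5))
  withm <- assemble_env_matrix(hydro, gran, sal, macro)
  expect_equal(sum(withm$macrofauna_complete), 17)
  expect_equal(nrow(env_values(withm)), 20)
  expect_equal(nrow(env_values(withm, include_macrofauna = TRUE)), 17)
  expect_equal(ncol(env_values(withm, include_macrofauna = TRUE)), 17)
  # broken join names the offending station
  expect_error(assemble_env_matrix(hydro, gran[-4, ], sal), gran$station[4])
  gran_na <- gran; gran_na$D50[2] <- NA
  expect_error(assemble_env_matrix(hydro, gran_na, sal),
               "missing values")
})
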