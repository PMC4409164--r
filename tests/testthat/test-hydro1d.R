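test_that("quiescent channel stays quiescent", {
  geom <- linear_channel(L = 10e3)
  ser <- solve_tides(geom, tidal_forcing("M2", 0, 0, 12.4206012),
                     hydro_params(dt = 25, ramp_days = 0.2, run_days = 0.5))
  expect_equal(max(abs(ser$eta)), 0)
  expect_equal(max(abs(ser$U)), 0)
})

test_that("input validation catches bad geometry, CFL and drying", {
  expect_error(channel_geometry(c(0, 500, 900), rep(100, 3), rep(5, 3)),
               "uniform")
  expect_error(channel_geometry(seq(0, 1000, 500), rep(100, 3), c(5, -1, 5)),
               "positive")
  expect_error(channel_geometry(seq(0, 1000, 500), rep(100, 3), rep(5, 3),
                                area = c(500, 5000, 500)),
               "deviates")
  geom <- linear_channel(L = 10e3, depth = 10)
  expect_error(
    solve_tides(geom, tidal_forcing("M2", 1, 0, 12.42),
                hydro_params(dt = 200, ramp_days = 0.1, run_days = 0.2)),
    "CFL.*limiting dt")
  shallow <- linear_channel(L = 10e3, depth = 1)
  expect_error(
    solve_tides(shallow, tidal_forcing("M2", 2, 0, 12.42),
                hydro_params(dt = 10, ramp_days = 0.2, run_days = 0.5,
                             on_dry = "error")),
    "drying")
  # clamped wet/dry handling keeps the run finite
  ser <- solve_tides(shallow, tidal_forcing("M2", 2, 0, 12.42),
                     hydro_params(dt = 10, ramp_days = 0.2, run_days = 0.5))
  expect_true(all(is.finite(ser$eta)))
})

test_that("bed shear stress follows the quadratic law", {
  par <- hydro_params(C_D = 0.0025, rho = 1025)
  expect_equal(bed_shear_stress(1, par), 2.5625)
  expect_equal(bed_shear_stress(0, par), 0)
  U <- c(-1.3, 0.4, 2)
  expect_equal(abs(bed_shear_stress(U, par)), abs(bed_shear_stress(-U, par)))
  expect_equal(sign(bed_shear_stress(U, par)), sign(U))
  expect_error(hydro_params(C_D = -1), "C_D")
})

test_that("frictionless linear run matches the analytic co-oscillation", {
  L <- 50e3; dx <- 500
  geom <- linear_channel(L = L, dx = dx, depth = 10)
  a <- 0.05
  per <- 12.4206012
  ser <- solve_tides(geom, tidal_forcing("M2", a, 0, per),
                     hydro_params(C_D = 0, dt = 20, ramp_days = 2,
                                  run_days = 4, output_every = 15))
  om <- 2 * pi / (per * 3600)
  k <- om / sqrt(9.81 * 10)
  analytic <- a * cos(k * (L - geom$x)) / cos(k * L)
  num <- harmonic_amplitude(ser, om)
  expect_lt(sqrt(mean((num - analytic)^2)) / mean(abs(analytic)), 0.02)
})

test_that("volume change balances boundary flux to round-off", {
  geom <- channel_geometry(seq(250, 50e3 - 250, by = 500),
                           width = 500 * exp(-seq(0, 1, length.out = 100)),
                           depth = seq(12, 4, length.out = 100))
  ser <- solve_tides(geom, tidal_constituents(2),
                     hydro_params(dt = 20, ramp_days = 1, run_days = 2,
                                  output_every = 10))
  Tcyc <- 12.4206012 * 3600
  i2 <- which.min(abs(ser$times - (ser$times[1] + Tcyc)))
  dV <- ser$volume[i2] - ser$volume[1]
  dQ <- ser$boundary_influx[i2] - ser$boundary_influx[1]
  expect_lt(abs(dV - dQ) / mean(ser$volume), 1e-6)
})

test_that("friction monotonically damps interior currents", {
  geom <- linear_channel(L = 30e3, depth = 8)
  umax <- vapply(c(0.001, 0.0025, 0.005), function(cd) {
    ser <- solve_tides(geom, tidal_forcing("M2", 1, 0, 12.4206012),
                       hydro_params(C_D = cd, dt = 20, ramp_days = 1,
                                    run_days = 1.5, output_every = 20))
    max(abs(ser$U[30, ]))
  }, numeric(1))
  expect_true(all(diff(umax) < 0))
})

test_that("station statistics reduce elevation and velocity correctly", {
  # hand-built series: pure sinusoid elevation, known velocities
  t <- seq(0, 3 * 12.42 * 3600, by = 600)
  a <- 1.2
  eta <- rbind(a * cos(2 * pi * t / (12.42 * 3600)),
               a * cos(2 * pi * t / (12.42 * 3600)),
               a * cos(2 * pi * t / (12.42 * 3600)))
  U <- matrix(0.5, 4, length(t))
  geom <- channel_geometry(c(250, 750, 1250), rep(100, 3), rep(5, 3))
  fake <- structure(list(times = t, x = geom$x, eta = eta, U = U,
                         geom = geom, params = hydro_params(),
                         velocity_stat = "abs"),
                    class = "hydro_series")
  st <- station_statistics(fake, 750)
  # extrema are located on the sampled series: one output step of slack
  expect_equal(st$spring_tidal_range, 2 * a, tolerance = 1e-3)
  expect_equal(st$mean_velocity, 0.5)
  expect_equal(st$max_velocity, 0.5)
  expect_error(station_statistics(fake, 99e3), "outside the channel")
})

test_that("spring range of a two-constituent beat reaches the amplitude sum", {
  # boundary-signal oracle: eta = a1 cos(w1 t) + a2 cos(w2 t) over a
  # spring-neap cycle has a maximum high-to-low excursion of ~2(a1+a2)
  a1 <- 2; a2 <- 0.8
  w1 <- 2 * pi / (12.4206012 * 3600); w2 <- 2 * pi / (12 * 3600)
  t <- seq(0, 15 * 86400, by = 300)
  sig <- a1 * cos(w1 * t) + a2 * cos(w2 * t)
  eta <- rbind(sig, sig, sig)
  geom <- channel_geometry(c(250, 750, 1250), rep(100, 3), rep(8, 3))
  fake <- structure(list(times = t, x = geom$x, eta = eta,
                         U = matrix(0, 4, length(t)), geom = geom,
                         params = hydro_params(), velocity_stat = "abs"),
                    class = "hydro_series")
  st <- station_statistics(fake, 750)
  expect_equal(st$spring_tidal_range, 2 * (a1 + a2), tolerance = 0.01)
})

test_that("gauge validation reports bias and RMSE correctly", {
  geom <- linear_channel(L = 20e3, depth = 10)
  ser <- solve_tides(geom, tidal_forcing("M2", 1, 0, 12.4206012),
                     hydro_params(dt = 20, ramp_days = 0.5, run_days = 1,
                                  output_every = 10))
  at5 <- ser$eta[5, ]
  same <- validate_against_gauge(ser, ser$times, at5, ser$x[5])
  expect_equal(same$rmse, 0, tolerance = 1e-12)
  shift <- validate_against_gauge(ser, ser$times, at5 + 0.1, ser$x[5])
  expect_equal(shift$bias, 0.1, tolerance = 1e-12)
  expect_equal(shift$rmse, 0.1, tolerance = 1e-12)
  # closed-form RMSE of two equal-amplitude sinusoids offset in phase:
  # rmse = a * sqrt(1 - cos(psi)) over whole periods
  a <- 0.7; psi <- 1.1
  per <- 12.42 * 3600
  t <- seq(0, 10 * per, by = 60)
  eta <- rbind(a * cos(2 * pi * t / per), a * cos(2 * pi * t / per),
               a * cos(2 * pi * t / per))
  geom2 <- channel_geometry(c(250, 750, 1250), rep(100, 3), rep(5, 3))
  fake <- structure(list(times = t, x = geom2$x, eta = eta,
                         U = matrix(0, 4, length(t)), geom = geom2,
                         params = hydro_params(), velocity_stat = "abs"),
                    class = "hydro_series")
  g <- validate_against_gauge(fake, t, a * cos(2 * pi * t / per - psi), 750)
  expect_equal(g$rmse, a * sqrt(1 - cos(psi)), tolerance = 1e-3)
  expect_error(validate_against_gauge(ser, ser$times + 1e9, at5, ser$x[5]),
               "overlap")
})
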