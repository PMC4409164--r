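# One-dimensional sectional-averaged tidal model.
#
# Staggered grid: free-surface elevation eta at cell centres, depth-averaged
# velocity U at cell faces. Seaward boundary (face 1) is forced with a sum of
# tidal constituents applied to a ghost cell; the landward boundary is a
# closed weir (zero flux). Friction is treated semi-implicitly, advection by
# first-order upwinding, so the scheme is stable under quadratic friction at
# estuarine scales and conserves volume to round-off by construction.

#' Channel geometry for the 1-D tidal model
#'
#' Describes the along-channel discretisation of an estuary as rows of a
#' uniform grid: node position, channel width, mean water depth and
#' (optionally) an independently measured cross-sectional area.
#'
#' @param x Along-channel node positions in metres, uniformly spaced,
#'   increasing landward (the first node is the seaward/mouth end).
#' @param width Channel width in metres per node, positive.
#' @param depth Mean water depth in metres per node, positive.
#' @param area Optional cross-sectional area per node (m^2). Defaults to
#'   `width * depth`; if supplied it must agree with `width * depth` within
#'   `area_tol` (relative).
#' @param area_tol Relative tolerance for the area consistency check.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(x, width, depth, area = NULL, area_tol = 0.25) {
  n <- length(x)
  if (n < 3) stopf("geometry needs at least 3 nodes, got %d", n)
  if (length(width) != n || length(depth) != n)
    stopf("x, width and depth must have equal length")
  dx <- diff(x)
  if (any(dx <= 0) || max(abs(dx - dx[1])) > 1e-6 * dx[1])
    stopf("node spacing must be uniform and positive")
  if (any(width <= 0) || any(depth <= 0))
    stopf("width and depth must be positive everywhere")
  if (is.null(area)) area <- width * depth
  rel <- abs(area - width * depth) / (width * depth)
  if (any(rel > area_tol))
    stopf("supplied area deviates from width*depth by more than %g at node %d",
          area_tol, which.max(rel))
  structure(list(x = as.numeric(x), width = as.numeric(width),
                 depth = as.numeric(depth), area = as.numeric(area),
                 dx = dx[1], n = n),
            class = "channel_geometry")
}

#' Read channel geometry from CSV
#'
#' Expects columns `x_m`, `width_m`, `depth_m` and optionally `area_m2`.
#'
#' @param path CSV file path.
#' @return A [channel_geometry()] object.
#' @export
read_channel_geometry <- function(path) {
  d <- read.csv(path)
  need <- c("x_m", "width_m", "depth_m")
  if (!all(need %in% names(d)))
    stopf("geometry CSV must contain columns %s", paste(need, collapse = ", "))
  channel_geometry(d$x_m, d$width_m, d$depth_m,
                   area = if ("area_m2" %in% names(d)) d$area_m2 else NULL)
}

#' Tidal constituent forcing at the open boundary
#'
#' @param name Constituent names.
#' @param amplitude Amplitudes in metres (>= 0).
#' @param phase_deg Phases in degrees.
#' @param period_h Periods in hours.
#' @return An object of class `tidal_forcing` with angular frequencies in
#'   rad/s.
#' @export
tidal_forcing <- function(name, amplitude, phase_deg = 0, period_h) {
  k <- length(name)
  amplitude <- rep_len(amplitude, k)
  phase_deg <- rep_len(phase_deg, k)
  period_h <- rep_len(period_h, k)
  if (any(amplitude < 0)) stopf("amplitudes must be >= 0")
  if (any(period_h <= 0)) stopf("periods must be positive")
  structure(data.frame(name = name, amplitude = amplitude,
                       phase_rad = phase_deg * pi / 180,
                       omega = 2 * pi / (period_h * 3600)),
            class = c("tidal_forcing", "data.frame"))
}

#' Default four-constituent forcing (M2, S2, N2, K1)
#'
#' Standard astronomical periods; amplitudes scaled from a dominant M2
#' amplitude with typical shelf-sea ratios.
#'
#' @param m2_amplitude M2 amplitude in metres.
#' @return A [tidal_forcing()] object.
#' @export
tidal_constituents <- function(m2_amplitude = 2) {
  tidal_forcing(name = c("M2", "S2", "N2", "K1"),
                amplitude = m2_amplitude * c(1, 0.33, 0.19, 0.07),
                phase_deg = c(0, 0, 0, 0),
                period_h = c(12.4206012, 12, 12.65834751, 23.93447213))
}

#' Read tidal forcing from CSV
#'
#' Expects columns `name`, `amplitude_m`, `phase_deg`, `period_h`.
#'
#' @param path CSV file path.
#' @return A [tidal_forcing()] object.
#' @export
read_tidal_forcing <- function(path) {
  d <- read.csv(path)
  need <- c("name", "amplitude_m", "phase_deg", "period_h")
  if (!all(need %in% names(d)))
    stopf("forcing CSV must contain columns %s", paste(need, collapse = ", "))
  tidal_forcing(d$name, d$amplitude_m, d$phase_deg, d$period_h)
}

#' Numerical and physical parameters for the tidal solver
#'
#' @param C_D Dimensionless quadratic bottom-friction coefficient (>= 0).
#' @param rho Water density, kg/m^3.
#' @param g Gravitational acceleration, m/s^2.
#' @param dt Time step in seconds; `NULL` picks half the shallow-water CFL
#'   limit of the supplied geometry at run time.
#' @param ramp_days Smooth spin-up interval excluded from the returned series.
#' @param run_days Analysis window; the default covers a spring-neap cycle.
#' @param min_depth Wet/dry clamp on total water depth (m) when
#'   `on_dry = "clamp"`.
#' @param on_dry `"clamp"` or `"error"` behaviour when `h + eta` falls to or
#'   below zero.
#' @param output_every Store every k-th time step of the analysis window.
#' @return An object of class `hydro_params`.
#' @export
hydro_params <- function(C_D = 2.5e-3, rho = 1025, g = 9.81, dt = NULL,
                         ramp_days = 2, run_days = 14.77, min_depth = 0.1,
                         on_dry = c("clamp", "error"), output_every = 1L) {
  if (C_D < 0) stopf("C_D must be >= 0")
  check_number(rho, "rho", lower = 1e-6)
  check_number(g, "g", lower = 1e-6)
  if (!is.null(dt)) check_number(dt, "dt", lower = 1e-6)
  check_number(ramp_days, "ramp_days", lower = 0)
  check_number(run_days, "run_days", lower = 1e-6)
  structure(list(C_D = C_D, rho = rho, g = g, dt = dt, ramp_days = ramp_days,
                 run_days = run_days, min_depth = min_depth,
                 on_dry = match.arg(on_dry),
                 output_every = as.integer(output_every)),
            class = "hydro_params")
}

boundary_eta <- function(forcing, t, ramp_s) {
  ramp <- if (ramp_s > 0 && t < ramp_s) 0.5 * (1 - cos(pi * t / ramp_s)) else 1
  ramp * sum(forcing$amplitude * cos(forcing$omega * t - forcing$phase_rad))
}

#' Solve the 1-D sectional-averaged tidal equations
#'
#' Integrates the continuity equation `B deta/dt + d(AU)/dx = 0` and the
#' momentum equation `dU/dt + U dU/dx = -g deta/dx - C_D U|U|/(h+eta)` on a
#' staggered grid, forced at the seaward boundary by the supplied
#' constituents and closed at the landward end. The spin-up ramp is excluded
#' from the returned series.
#'
#' @param geom A [channel_geometry()].
#' @param forcing A [tidal_forcing()].
#' @param params A [hydro_params()].
#' @return An object of class `hydro_series`: list with `times` (s, analysis
#'   window), `x` (node positions), `eta` (nodes x times, m), `U` (faces x
#'   times, m/s; face `j` sits seaward of node `j`, face `n+1` is the closed
#'   head), `boundary_influx` (cumulative volume through the mouth, m^3, at
#'   `times`), `volume` (instantaneous channel volume, m^3), plus the inputs.
#' @export
solve_tides <- function(geom, forcing, params = hydro_params()) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(forcing, "tidal_forcing"))
  n <- geom$n
  dx <- geom$dx
  amax <- sum(forcing$amplitude)
  c_max <- sqrt(params$g * max(geom$depth + amax))
  dt_cfl <- dx / c_max
  dt <- params$dt %||% (0.5 * dt_cfl)
  if (dt > dt_cfl)
    stopf("CFL violation: dt = %.3f s exceeds the limiting dt = %.3f s", dt, dt_cfl)

  ramp_s <- params$ramp_days * 86400
  run_s <- params$run_days * 86400
  n_steps <- ceiling((ramp_s + run_s) / dt)
  keep_from <- floor(ramp_s / dt) + 1L
  every <- max(1L, params$output_every)

  # face-averaged geometry; face 1 reuses the first cell, face n+1 the last
  Bf <- c(geom$width[1], (geom$width[-1] + geom$width[-n]) / 2, geom$width[n])
  hf <- c(geom$depth[1], (geom$depth[-1] + geom$depth[-n]) / 2, geom$depth[n])

  eta <- numeric(n)
  U <- numeric(n + 1)        # U[n + 1] stays 0 (closed weir)
  vin <- 0                   # cumulative volume through the mouth

  keep_idx <- seq(keep_from, n_steps, by = every)
  n_out <- length(keep_idx)
  eta_out <- matrix(NA_real_, n, n_out)
  U_out <- matrix(NA_real_, n + 1, n_out)
  vin_out <- numeric(n_out)
  vol_out <- numeric(n_out)
  t_out <- numeric(n_out)
  out_ptr <- 1L
  next_keep <- keep_idx[1L]

  g <- params$g; C_D <- params$C_D
  iseq <- seq_len(n)

  for (step in seq_len(n_steps)) {
    t_old <- (step - 1) * dt
    eta_b <- boundary_eta(forcing, t_old, ramp_s)

    eta_ghost <- c(eta_b, eta)               # centre values seaward of each face
    # total depth at faces (from current eta)
    eta_face <- c((eta_b + eta[1]) / 2,
                  (eta[-1] + eta[-n]) / 2,
                  eta[n])
    H <- hf + eta_face
    if (any(H <= 0)) {
      if (params$on_dry == "error")
        stopf("drying: total depth <= 0 at face %d, t = %.0f s", which.min(H), t_old)
      H <- pmax(H, params$min_depth)
    }

    Ui <- U[iseq]
    grad <- (eta_ghost[iseq + 1L] - eta_ghost[iseq]) / dx
    # first-order upwind advection on faces 1..n
    Um <- c(Ui[1], Ui[-1])                    # seaward neighbour (zero-gradient at mouth)
    Up <- c(Ui[-1], 0)                        # landward neighbour (closed head)
    adv <- ifelse(Ui > 0, Ui * (Ui - Um) / dx, Ui * (Up - Ui) / dx)
    Ustar <- Ui + dt * (-adv - g * grad)
    Unew <- Ustar / (1 + dt * C_D * abs(Ui) / H[iseq])
    U[iseq] <- Unew

    flux <- Bf * H * U                        # faces 1..n+1; last is 0
    eta <- eta - dt * (flux[iseq + 1L] - flux[iseq]) / (geom$width * dx)
    vin <- vin + flux[1L] * dt

    if (step == next_keep) {
      t_out[out_ptr] <- step * dt
      eta_out[, out_ptr] <- eta
      U_out[, out_ptr] <- U
      vin_out[out_ptr] <- vin
      vol_out[out_ptr] <- sum(geom$width * (geom$depth + eta) * dx)
      out_ptr <- out_ptr + 1L
      next_keep <- if (out_ptr <= n_out) keep_idx[out_ptr] else Inf
    }
  }
  if (!all(is.finite(eta_out))) stopf("solver produced non-finite elevations")

  structure(list(times = t_out, x = geom$x, eta = eta_out, U = U_out,
                 boundary_influx = vin_out, volume = vol_out,
                 dt = dt, geom = geom, forcing = forcing, params = params,
                 velocity_stat = "abs"),
            class = "hydro_series")
}

#' Quadratic-law bed shear stress
#'
#' `tau = rho * C_D * U * |U|` (Pa); the sign carries the flow direction.
#'
#' @param U Velocity series (m/s).
#' @param params A [hydro_params()] supplying `rho` and `C_D`.
#' @return Stress series, same shape as `U`.
#' @export
bed_shear_stress <- function(U, params = hydro_params()) {
  if (params$C_D < 0) stopf("C_D must be >= 0")
  if (!all(is.finite(U))) stopf("U must be finite")
  params$rho * params$C_D * U * abs(U)
}

# elevation / velocity time series interpolated to an along-channel position
series_at <- function(series, pos) {
  x <- series$x
  if (pos < min(x) - series$geom$dx / 2 || pos > max(x) + series$geom$dx / 2)
    stopf("station position %.0f m lies outside the channel extent", pos)
  pos_c <- min(max(pos, min(x)), max(x))
  i <- findInterval(pos_c, x, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(x) - 1L)
  w <- (pos_c - x[i]) / (x[i + 1] - x[i])
  eta <- (1 - w) * series$eta[i, ] + w * series$eta[i + 1, ]
  # faces j and j+1 bracket node j; average to node, then interpolate
  Un <- (series$U[seq_len(length(x)), , drop = FALSE] +
           series$U[seq_len(length(x)) + 1L, , drop = FALSE]) / 2
  U <- (1 - w) * Un[i, ] + w * Un[i + 1, ]
  list(eta = eta, U = U)
}

# ranges between successive high and low waters of an elevation series
tidal_ranges <- function(eta) {
  d <- diff(eta)
  s <- sign(d)
  s[s == 0] <- 1
  turn <- which(diff(s) != 0) + 1L
  if (length(turn) < 2) return(numeric(0))
  abs(diff(eta[turn]))
}

#' Per-station hydrodynamic statistics
#'
#' Reduces a [solve_tides()] series to the per-station summary used as
#' environmental drivers: spring tidal range (the largest high-to-low water
#' excursion over the window), mean and maximum velocity magnitude, and mean
#' and maximum bed shear stress magnitude.
#'
#' @param series A `hydro_series`.
#' @param stations Along-channel station positions (m).
#' @param station_names Optional labels.
#' @return A data.frame with one row per station and columns `station`,
#'   `spring_tidal_range`, `mean_velocity`, `max_velocity`,
#'   `mean_bed_shear_stress`, `max_bed_shear_stress`. Velocity and stress
#'   statistics are computed on magnitudes (attribute `velocity_stat`).
#' @export
station_statistics <- function(series, stations, station_names = NULL) {
  stopifnot(inherits(series, "hydro_series"))
  station_names <- station_names %||% paste0("S", seq_along(stations))
  rows <- lapply(seq_along(stations), function(k) {
    at <- series_at(series, stations[k])
    tau <- bed_shear_stress(at$U, series$params)
    rng <- tidal_ranges(at$eta)
    data.frame(station = station_names[k],
               spring_tidal_range = if (length(rng)) max(rng) else max(at$eta) - min(at$eta),
               mean_velocity = mean(abs(at$U)),
               max_velocity = max(abs(at$U)),
               mean_bed_shear_stress = mean(abs(tau)),
               max_bed_shear_stress = max(abs(tau)))
  })
  out <- do.call(rbind, rows)
  attr(out, "velocity_stat") <- "abs"
  out
}

#' Compare modelled elevations against a tide gauge record
#'
#' Interpolates the modelled elevation at `position` onto the gauge time
#' base over the overlapping support and reports root-mean-square error and
#' bias (gauge minus model).
#'
#' @param series A `hydro_series`.
#' @param gauge_times Gauge observation times (s, same origin as the model).
#' @param gauge_eta Observed elevations (m).
#' @param position Along-channel position of the gauge (m).
#' @return List with `rmse`, `bias` and `n` (overlapping samples).
#' @export
validate_against_gauge <- function(series, gauge_times, gauge_eta, position) {
  stopifnot(length(gauge_times) == length(gauge_eta))
  at <- series_at(series, position)
  lo <- max(min(series$times), min(gauge_times))
  hi <- min(max(series$times), max(gauge_times))
  if (lo >= hi) stopf("gauge record and model series do not overlap in time")
  keep <- gauge_times >= lo & gauge_times <= hi
  mod <- approx(series$times, at$eta, xout = gauge_times[keep])$y
  res <- gauge_eta[keep] - mod
  list(rmse = sqrt(mean(res^2)), bias = mean(res), n = sum(keep))
}

#' Harmonic amplitude of the modelled elevation at each node
#'
#' Least-squares fit of `a cos(omega t) + b sin(omega t)` per node over the
#' analysis window; used to compare against analytic co-oscillation
#' solutions.
#'
#' @param series A `hydro_series`.
#' @param omega Angular frequency (rad/s).
#' @return Amplitude per node (m).
#' @export
harmonic_amplitude <- function(series, omega) {
  t <- series$times
  X <- cbind(cos(omega * t), sin(omega * t), 1)
  cf <- qr.solve(X, t(series$eta))
  sqrt(cf[1, ]^2 + cf[2, ]^2)
}
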