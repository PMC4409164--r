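# Non-hydrodynamic environmental drivers: granulometry summaries from
# cumulative grain-size curves and salinity-range inference, assembled with
# the hydrodynamic statistics into the 14-variable driver matrix.

# Wentworth-style class bounds (um); "fine sand" absorbs very fine sand so
# the six classes used as drivers are clay, silt, fine/medium/coarse sand,
# gravel.
size_class_bounds <- c(clay = 4, silt = 63, fine_sand = 250,
                       medium_sand = 500, coarse_sand = 2000)

#' Cumulative grain-size distribution
#'
#' @param size_um Bin edges in micrometres, strictly increasing.
#' @param cum_pct Cumulative percent finer at each edge, non-decreasing,
#'   ending at 100 (within 0.5).
#' @return Object of class `grain_size_distribution`.
#' @export
grain_size_distribution <- function(size_um, cum_pct) {
  if (length(size_um) != length(cum_pct) || length(size_um) < 2)
    stopf("size_um and cum_pct must be equal length >= 2")
  if (any(diff(size_um) <= 0)) stopf("size_um must be strictly increasing")
  if (any(size_um <= 0)) stopf("grain sizes must be positive")
  if (any(diff(cum_pct) < -1e-9)) stopf("cumulative percent must be non-decreasing")
  if (abs(cum_pct[length(cum_pct)] - 100) > 0.5)
    stopf("cumulative curve must end at 100%% (+/- 0.5), got %.2f",
          cum_pct[length(cum_pct)])
  structure(list(size_um = as.numeric(size_um), cum_pct = as.numeric(cum_pct)),
            class = "grain_size_distribution")
}

#' Percentile diameter of a grain-size distribution
#'
#' Diameter at which the cumulative curve crosses `q` percent, interpolating
#' linearly in log2 grain size (the sedimentological phi scale). `q = 50`
#' gives the median grain size D50, `q = 10` gives D10.
#'
#' @param dist A [grain_size_distribution()].
#' @param q Percent in (0, 100).
#' @return Diameter in micrometres.
#' @export
percentile_diameter <- function(dist, q) {
  stopifnot(inherits(dist, "grain_size_distribution"))
  check_number(q, "q", lower = 1e-9, upper = 100 - 1e-9)
  cp <- dist$cum_pct
  if (q < min(cp) || q > max(cp))
    stopf("q = %g%% lies outside the observed cumulative span [%.2f, %.2f]",
          q, min(cp), max(cp))
  hit <- which(abs(cp - q) < 1e-12)
  if (length(hit)) return(dist$size_um[hit[1]])
  phi <- log2(dist$size_um)
  2^approx(cp, phi, xout = q, ties = "ordered")$y
}

#' Percent of sediment mass in each size class
#'
#' Interpolates the cumulative curve (log2 scale) at the class bounds
#' 4 / 63 / 250 / 500 / 2000 um and differences to six Wentworth-style
#' fractions: clay, silt, fine sand, medium sand, coarse sand, gravel.
#'
#' @param dist A [grain_size_distribution()].
#' @return Named numeric vector of six percentages summing to 100.
#' @export
size_fractions <- function(dist) {
  stopifnot(inherits(dist, "grain_size_distribution"))
  phi <- log2(dist$size_um)
  cum_at <- function(s) {
    if (s <= dist$size_um[1]) return(if (s < dist$size_um[1]) 0 else dist$cum_pct[1])
    if (s >= dist$size_um[length(phi)]) return(dist$cum_pct[length(phi)])
    approx(phi, dist$cum_pct, xout = log2(s), ties = "ordered")$y
  }
  # below the first edge there is no recorded mass; treat the first recorded
  # cumulative value as attained at the first edge
  top <- dist$cum_pct[length(dist$cum_pct)]
  cuts <- vapply(size_class_bounds, cum_at, numeric(1))
  fr <- c(cuts[1], diff(cuts), top - cuts[length(cuts)])
  names(fr) <- c(names(size_class_bounds), "gravel")
  fr * 100 / top
}

#' Granulometry summary for one sample
#'
#' @param dist A [grain_size_distribution()].
#' @return Data.frame row with `D50`, `D10` (um) and the six class
#'   percentages (`pct_clay` ... `pct_gravel`).
#' @export
granulometry_summary <- function(dist) {
  fr <- size_fractions(dist)
  data.frame(D50 = percentile_diameter(dist, 50),
             D10 = percentile_diameter(dist, 10),
             pct_clay = fr[["clay"]], pct_silt = fr[["silt"]],
             pct_fine_sand = fr[["fine_sand"]],
             pct_medium_sand = fr[["medium_sand"]],
             pct_coarse_sand = fr[["coarse_sand"]],
             pct_gravel = fr[["gravel"]])
}

#' Read per-station grain-size curves from CSV
#'
#' Expects columns `station`, `size_um`, `cum_pct`; one cumulative curve per
#' station.
#'
#' @param path CSV file path.
#' @return Named list of [grain_size_distribution()] objects.
#' @export
read_grain_size_csv <- function(path) {
  d <- read.csv(path)
  need <- c("station", "size_um", "cum_pct")
  if (!all(need %in% names(d)))
    stopf("grain-size CSV must contain columns %s", paste(need, collapse = ", "))
  lapply(split(d, d$station),
         function(s) grain_size_distribution(s$size_um[order(s$size_um)],
                                             s$cum_pct[order(s$size_um)]))
}

#' Fit a salinity-range inference model
#'
#' The mean salinity range at a site (difference between mean high-tide and
#' mean low-tide salinity) is rarely measured directly; it is inferred from
#' a fitted linear relationship against either the site's mean salinity
#' (`kind = "mean_salinity"`) or its distance from the tidal head in km
#' (`kind = "distance"`).
#'
#' @param predictor Observed predictor values (mean salinity p.p.t., or
#'   distance from the head, km).
#' @param salinity_range Observed salinity ranges (p.p.t.).
#' @param kind Which predictor the model uses.
#' @param coefficients Optional externally established `(intercept, slope)`
#'   pair; when supplied no fit is performed and `predictor`/`salinity_range`
#'   may be omitted.
#' @return Object of class `salinity_range_model` with coefficients, R^2 and
#'   n.
#' @export
fit_salinity_range_model <- function(predictor = NULL, salinity_range = NULL,
                                     kind = c("mean_salinity", "distance"),
                                     coefficients = NULL) {
  kind <- match.arg(kind)
  if (!is.null(coefficients)) {
    stopifnot(length(coefficients) == 2)
    return(structure(list(kind = kind, intercept = coefficients[1],
                          slope = coefficients[2], r_squared = NA_real_,
                          n = 0L, external = TRUE),
                     class = "salinity_range_model"))
  }
  if (length(predictor) != length(salinity_range) || length(predictor) < 3)
    stopf("need at least 3 paired observations")
  if (sd(predictor) == 0) stopf("predictor has zero variance; cannot fit")
  fit <- lm(salinity_range ~ predictor)
  structure(list(kind = kind,
                 intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 n = length(predictor), external = FALSE),
            class = "salinity_range_model")
}

#' Predict salinity range from a fitted model
#'
#' `intercept + slope * x`, clipped at 0 p.p.t. (a warning reports clipping).
#'
#' @param model A [fit_salinity_range_model()] object.
#' @param x Predictor value(s).
#' @return Salinity range(s), p.p.t.
#' @export
predict_salinity_range <- function(model, x) {
  if (!inherits(model, "salinity_range_model"))
    stopf("`model` must be a fitted salinity_range_model")
  y <- model$intercept + model$slope * x
  if (any(y < 0)) {
    warning("negative predicted salinity range clipped to 0 p.p.t.")
    y <- pmax(y, 0)
  }
  y
}

#' Canonical names of the 14 environmental drivers
#'
#' Column order of the core driver block: five hydrodynamic statistics,
#' eight granulometry summaries and the salinity range.
#'
#' @return Character vector of length 14.
#' @export
env_driver_names <- function() {
  c("spring_tidal_range", "mean_velocity", "max_velocity",
    "mean_bed_shear_stress", "max_bed_shear_stress",
    "D50", "D10", "pct_clay", "pct_silt", "pct_fine_sand",
    "pct_medium_sand", "pct_coarse_sand", "pct_gravel", "salinity_range")
}

#' Assemble the environmental driver matrix
#'
#' Joins hydrodynamic station statistics, granulometry summaries and
#' salinity ranges (plus optional macrofauna metrics) on the station key
#' into the canonical 14-column driver matrix: spring tidal range, mean and
#' max velocity, mean and max bed shear stress, D50, D10, the six sediment
#' fractions and salinity range.
#'
#' @param hydro Data.frame from [station_statistics()] (column `station`).
#' @param gran Data.frame with `station` plus the [granulometry_summary()]
#'   columns.
#' @param sal Data.frame with `station`, `salinity_range`.
#' @param macro Optional data.frame with `station`,
#'   `macrofauna_species_richness`, `macrofauna_abundance`,
#'   `macrofauna_biomass`; stations missing from it are flagged, not
#'   dropped.
#' @return Object of class `env_matrix`: a data.frame keyed by `station`
#'   with the 14 drivers (in canonical order), any macrofauna columns, and a
#'   logical `macrofauna_complete` flag when `macro` is given.
#' @export
assemble_env_matrix <- function(hydro, gran, sal, macro = NULL) {
  for (nm in c("hydro", "gran", "sal")) {
    tb <- get(nm)
    if (!"station" %in% names(tb)) stopf("`%s` must have a station column", nm)
  }
  st <- hydro$station
  for (nm in c("gran", "sal")) {
    tb <- get(nm)
    miss <- setdiff(st, tb$station)
    extra <- setdiff(tb$station, st)
    if (length(miss) || length(extra))
      stopf("station key mismatch in `%s`: missing [%s], unmatched [%s]", nm,
            paste(miss, collapse = ", "), paste(extra, collapse = ", "))
    bad <- tb$station[!complete.cases(tb)]
    if (length(bad))
      stopf("`%s` has missing values for station(s): %s", nm,
            paste(bad, collapse = ", "))
  }
  out <- merge(merge(hydro, gran, by = "station"), sal, by = "station")
  out <- out[match(st, out$station), c("station", env_driver_names())]
  if (!is.null(macro)) {
    out <- merge(out, macro, by = "station", all.x = TRUE)
    out <- out[match(st, out$station), ]
    mcols <- setdiff(names(macro), "station")
    out$macrofauna_complete <- complete.cases(out[, mcols, drop = FALSE])
  }
  rownames(out) <- NULL
  class(out) <- c("env_matrix", "data.frame")
  out
}

#' Numeric driver matrix from an env_matrix
#'
#' @param env An `env_matrix` data.frame.
#' @param vars Variables to keep (default: the 14 core drivers).
#' @param include_macrofauna Append the three macrofauna metrics and drop
#'   stations lacking them.
#' @return Numeric matrix, rownames = stations.
#' @export
env_values <- function(env, vars = env_driver_names(),
                       include_macrofauna = FALSE) {
  if (include_macrofauna) {
    mcols <- c("macrofauna_species_richness", "macrofauna_abundance",
               "macrofauna_biomass")
    if (!all(mcols %in% names(env)))
      stopf("macrofauna columns not present in this env matrix")
    vars <- c(vars, mcols)
    env <- env[complete.cases(env[, mcols, drop = FALSE]), , drop = FALSE]
  }
  m <- as.matrix(env[, vars, drop = FALSE])
  rownames(m) <- env$station
  m
}

#' Venice-system salinity zone labels
#'
#' @param mean_salinity Mean salinity values, p.p.t.
#' @return Factor with levels freshwater (< 0.5), oligohaline (0.5-5),
#'   mesohaline (5-18), polyhaline (18-30), euhaline (30-40),
#'   hyperhaline (> 40).
#' @export
salinity_zone <- function(mean_salinity) {
  cut(mean_salinity, breaks = c(-Inf, 0.5, 5, 18, 30, 40, Inf),
      labels = c("freshwater", "oligohaline", "mesohaline", "polyhaline",
                 "euhaline", "hyperhaline"),
      right = FALSE)
}
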