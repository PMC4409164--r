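# Synthetic estuary scenarios with known ground truth: environmental
# gradients along the channel, phylum-structured OTU occupancy driven by
# chosen environmental variables on the logit scale, and multinomial read
# counts. Every downstream stage of the analysis chain can be exercised
# against the planted coefficients.

#' Default per-estuary phylum pools
#'
#' OTU pool sizes per phylum, dominated by Nematoda as in typical estuarine
#' meiofaunal metabarcoding surveys.
#'
#' @return Named integer vector.
#' @export
default_taxon_pool <- function() {
  c(Nematoda = 250, Arthropoda = 70, Platyhelminthes = 45, Annelida = 30,
    Mollusca = 16, Gastrotricha = 12, Rotifera = 12, Tardigrada = 10,
    Kinorhyncha = 10, Cnidaria = 8, Bryozoa = 6)
}

#' Default phylum-level driver effects
#'
#' Each phylum responds to one environmental driver on the logit-occupancy
#' scale; signs and magnitudes emulate contrasts seen in estuarine
#' meiofauna (e.g. molluscs depressed by large salinity ranges,
#' interstitial taxa favoured by coarser sediment).
#'
#' @return Data.frame with columns `phylum`, `driver`, `effect`.
#' @export
default_driver_effects <- function() {
  data.frame(
    phylum = c("Nematoda", "Arthropoda", "Platyhelminthes", "Annelida",
               "Mollusca", "Gastrotricha", "Rotifera", "Tardigrada",
               "Kinorhyncha", "Cnidaria", "Bryozoa"),
    driver = c("mean_velocity", "spring_tidal_range", "D10", "D10",
               "salinity_range", "D50", "salinity_range", "pct_fine_sand",
               "mean_bed_shear_stress", "max_velocity", "D50"),
    effect = c(1.0, 1.0, 1.2, 1.2, -1.5, 1.0, -1.0, 0.8, -0.8, 0.8, 1.0))
}

#' Synthetic estuary scenario configuration
#'
#' Defines the sampling design and generative model for one synthetic
#' estuary: stations along the channel, replicate cores per station, an OTU
#' pool per phylum, and phylum-level environmental effects on the logit
#' occupancy scale.
#'
#' @param estuary Estuary label.
#' @param n_stations Number of stations (>= 2).
#' @param n_replicates Replicate cores per station (>= 1).
#' @param channel_length_km Channel length, km (> 0).
#' @param taxon_pool Named vector: OTUs per phylum (>= 0).
#' @param driver_effects Data.frame `phylum`, `driver`, `effect` (logit
#'   scale); every phylum must appear in `taxon_pool`.
#' @param occupancy_intercept Baseline logit occupancy.
#' @param replicate_noise_sd SD of the per-replicate logit offset.
#' @param reads_range Integer range (min, max) of total reads per sample.
#' @param salinity_range_max Largest mean salinity range along the channel,
#'   p.p.t.
#' @param spring_range_bounds Spring tidal range at (head, mouth), m.
#' @param max_velocity_bounds Peak velocity bounds along the channel, m/s.
#' @param env_noise_sd Relative SD of independent station-level noise on
#'   each environmental variable.
#' @param seed Integer seed; all randomness in the generators derives from
#'   it.
#' @return Object of class `scenario_config`.
#' @export
estuary_scenario <- function(estuary = "Thames",
                             n_stations = 20,
                             n_replicates = 3,
                             channel_length_km = 106,
                             taxon_pool = default_taxon_pool(),
                             driver_effects = default_driver_effects(),
                             occupancy_intercept = -1.2,
                             replicate_noise_sd = 0.5,
                             reads_range = c(1044L, 30786L),
                             salinity_range_max = 14.16,
                             spring_range_bounds = c(6.56, 1.43),
                             max_velocity_bounds = c(0.3, 2.07),
                             env_noise_sd = 0.15,
                             seed = 1L) {
  if (n_stations < 2) stopf("n_stations must be >= 2")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (channel_length_km <= 0) stopf("channel_length_km must be positive")
  if (any(taxon_pool < 0)) stopf("taxon pool sizes must be >= 0")
  if (is.null(names(taxon_pool))) stopf("taxon_pool must be named by phylum")
  if (missing(driver_effects)) # default effects adapt to the chosen pool
    driver_effects <- driver_effects[driver_effects$phylum %in%
                                       names(taxon_pool), , drop = FALSE]
  bad <- setdiff(driver_effects$phylum, names(taxon_pool))
  if (length(bad))
    stopf("driver_effects phylum absent from taxon_pool: %s",
          paste(bad, collapse = ", "))
  if (length(reads_range) != 2 || reads_range[1] > reads_range[2])
    stopf("reads_range must be (min, max) with min <= max")
  structure(list(estuary = estuary, n_stations = as.integer(n_stations),
                 n_replicates = as.integer(n_replicates),
                 channel_length_km = channel_length_km,
                 taxon_pool = taxon_pool, driver_effects = driver_effects,
                 occupancy_intercept = occupancy_intercept,
                 replicate_noise_sd = replicate_noise_sd,
                 reads_range = as.integer(reads_range),
                 salinity_range_max = salinity_range_max,
                 spring_range_bounds = spring_range_bounds,
                 max_velocity_bounds = max_velocity_bounds,
                 env_noise_sd = env_noise_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' A Mersey-like companion scenario
#'
#' Same generative model as [estuary_scenario()] with the second estuary's
#' design: 15 stations over 46 km, salinity ranges up to 18.97 p.p.t.,
#' spring tidal range up to 8.64 m and peak velocities up to 1.70 m/s.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [estuary_scenario()].
#' @return A `scenario_config`.
#' @export
mersey_scenario <- function(seed = 2L, ...) {
  args <- modifyList(list(estuary = "Mersey", n_stations = 15,
                          channel_length_km = 46,
                          salinity_range_max = 18.97,
                          spring_range_bounds = c(8.64, 0.5),
                          max_velocity_bounds = c(0.1, 1.70),
                          seed = seed),
                     list(...))
  do.call(estuary_scenario, args)
}

# smooth positive along-channel profile with independent station noise
noisy_profile <- function(base, noise_sd, floor = 0) {
  pmax(base * (1 + rnorm(length(base), 0, noise_sd)), floor)
}

#' Generate the per-station environmental gradient
#'
#' Builds the 14-driver environmental matrix for a synthetic estuary:
#' distance from the tidal head, a seaward-increasing logistic mean
#' salinity, a salinity range peaking mid-estuary (scaled beta shape,
#' bounded by the configured maximum), hydrodynamic statistics growing
#' seaward within the configured bounds, and a full granulometry block
#' derived from per-station log-normal grain-size curves via
#' [granulometry_summary()]. Each variable carries independent
#' station-level noise. Deterministic given the config seed.
#'
#' @param config A [estuary_scenario()] configuration.
#' @return An `env_matrix` data.frame (see [assemble_env_matrix()]) with
#'   additional columns `distance_km` (from the head), `mean_salinity` and
#'   `salinity_zone`.
#' @export
generate_env_gradient <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_stations
  L <- config$channel_length_km
  with_seed_(derive_seed(config$seed, "env"), {
    dist_km <- seq(0, L, length.out = n)       # 0 = head, L = mouth
    s <- dist_km / L
    mean_sal <- 34 / (1 + exp(-8 * (s - 0.45)))
    mean_sal <- pmax(mean_sal + rnorm(n, 0, 0.4), 0.05)
    beta_shape <- (s^1.5) * ((1 - s)^1.5)
    sal_range <- config$salinity_range_max * beta_shape / max(beta_shape)
    sal_range <- pmin(pmax(sal_range * (1 + rnorm(n, 0, config$env_noise_sd)), 0),
                      config$salinity_range_max)

    rng <- config$spring_range_bounds          # (head, mouth)
    spring_range <- noisy_profile(rng[1] + (rng[2] - rng[1]) * s^0.8,
                                  config$env_noise_sd, floor = 0)
    vb <- config$max_velocity_bounds
    max_vel <- noisy_profile(vb[1] + (vb[2] - vb[1]) * sqrt(s * (1 - 0.3 * s)) /
                               max(sqrt(s * (1 - 0.3 * s))),
                             config$env_noise_sd, floor = 0)
    mean_vel <- max_vel * noisy_profile(rep(0.55, n), config$env_noise_sd / 2,
                                        floor = 0.2)
    rho <- 1025; cd <- 2.5e-3
    mean_tau <- rho * cd * mean_vel^2 * (1 + rnorm(n, 0, config$env_noise_sd))
    max_tau <- pmax(rho * cd * max_vel^2 * (1 + rnorm(n, 0, config$env_noise_sd)),
                    mean_tau)

    # grain size: coarse near head and mouth, fine mid-estuary (turbidity
    # maximum); per-station log-normal cumulative curve
    d50_target <- exp(log(30) + (log(420) - log(30)) *
                        pmin(1, abs(s - 0.45) / 0.45)^1.2)
    d50_target <- pmax(d50_target * (1 + rnorm(n, 0, config$env_noise_sd)), 5)
    sigma_phi <- runif(n, 1.2, 2.0)
    edges <- 2^seq(-1, 13, by = 0.5)           # 0.5 um .. 8192 um
    gran <- do.call(rbind, lapply(seq_len(n), function(i) {
      cum <- 100 * pnorm(log2(edges), mean = log2(d50_target[i]),
                         sd = sigma_phi[i])
      cum <- cum / cum[length(cum)] * 100
      granulometry_summary(grain_size_distribution(edges, cum))
    }))

    station <- sprintf("%s%02d", substr(config$estuary, 1, 1), seq_len(n))
    out <- data.frame(station = station,
                      spring_tidal_range = spring_range,
                      mean_velocity = mean_vel,
                      max_velocity = max_vel,
                      mean_bed_shear_stress = mean_tau,
                      max_bed_shear_stress = max_tau,
                      gran,
                      salinity_range = sal_range,
                      distance_km = dist_km,
                      mean_salinity = mean_sal,
                      salinity_zone = salinity_zone(mean_sal))
    out <- out[, c("station", env_driver_names(),
                   "distance_km", "mean_salinity", "salinity_zone")]
    rownames(out) <- NULL
    class(out) <- c("env_matrix", "data.frame")
    out
  })
}

#' Generate presence/absence communities with known driver effects
#'
#' Occupancy of OTU `j` in sample `i` is Bernoulli with
#' `logit p = beta0_j + sum_k beta_kj z_k(i) + replicate noise`, where
#' `z_k` are the standardised environmental variables and `beta_kj` is
#' non-zero only for the driver assigned to the OTU's phylum. Replicates
#' share their station's environment; the replicate noise is a
#' station-by-replicate logit offset.
#'
#' @param config A [estuary_scenario()].
#' @param env The matching [generate_env_gradient()] output.
#' @return List: `table` (an [otu_table()] of 0/1 presences) and `truth`
#'   (class `truth_record`: per-OTU `beta0`, `driver`, `beta`; per-station
#'   environment and salinity zone labels).
#' @export
generate_community <- function(config, env) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(env) < 2) stopf("env must have >= 2 station rows")
  pool <- config$taxon_pool[config$taxon_pool > 0]
  n_otu <- sum(pool)
  phyla <- rep(names(pool), pool)
  eff <- config$driver_effects
  bad <- setdiff(eff$driver, env_driver_names())
  if (length(bad)) stopf("unknown driver(s) in effects: %s",
                         paste(bad, collapse = ", "))
  with_seed_(derive_seed(config$seed, "community"), {
    # estuary-specific taxon pool: OTU identities are not shared across
    # estuaries
    otu_id <- sprintf("%s_OTU_%04d", substr(config$estuary, 1, 1),
                      seq_len(n_otu))
    beta0 <- config$occupancy_intercept + rnorm(n_otu, 0, 0.6)
    drv <- eff$driver[match(phyla, eff$phylum)]
    beta <- eff$effect[match(phyla, eff$phylum)]
    beta <- ifelse(is.na(beta), 0, beta * exp(rnorm(n_otu, 0, 0.25)))
    Z <- scale(as.matrix(env[, env_driver_names()]))
    zdrv <- matrix(0, nrow(env), n_otu)
    has <- !is.na(drv)
    zdrv[, has] <- Z[, drv[has], drop = FALSE]

    ns <- nrow(env); nr <- config$n_replicates
    sample_station <- rep(seq_len(ns), each = nr)
    rep_id <- rep(seq_len(nr), times = ns)
    noise <- matrix(rnorm(ns * nr * 1, 0, config$replicate_noise_sd),
                    ns * nr, 1)
    logit_p <- beta0[col(matrix(0, ns * nr, n_otu))] +
      sweep(zdrv[sample_station, , drop = FALSE], 2, beta, "*") +
      as.vector(noise)
    prob <- 1 / (1 + exp(-logit_p))
    pres <- matrix(rbinom(length(prob), 1, prob), ns * nr, n_otu)

    sample_id <- sprintf("%s_r%d", env$station[sample_station], rep_id)
    counts <- t(pres)
    dimnames(counts) <- list(otu_id, sample_id)
    taxonomy <- data.frame(otu = otu_id, phylum = phyla,
                           family = paste0(phyla, "_fam",
                                           1 + (seq_len(n_otu) %% 7)))
    samples <- data.frame(sample = sample_id,
                          station = env$station[sample_station],
                          replicate = rep_id, estuary = config$estuary)
    truth <- structure(list(
      otu = data.frame(otu = otu_id, phylum = phyla, beta0 = beta0,
                       driver = drv, beta = beta),
      env = env,
      zones = if (!is.null(env$salinity_zone))
        setNames(as.character(env$salinity_zone), env$station)
      else setNames(rep(NA_character_, ns), env$station)),
      class = "truth_record")
    list(table = otu_table(counts, taxonomy, samples), truth = truth)
  })
}

#' Generate read counts over a presence table
#'
#' Each sample's total read count is uniform on the configured range;
#' reads are multinomial over the present OTUs with log-normal relative
#' abundances. Absent OTUs receive zero reads. Samples with no present OTU
#' keep an all-zero column and are flagged.
#'
#' @param presence An [otu_table()] of 0/1 presences
#'   (from [generate_community()]).
#' @param config The [estuary_scenario()].
#' @return The [otu_table()] with counts; attribute `empty_samples` names
#'   all-zero samples.
#' @export
generate_reads <- function(presence, config) {
  stopifnot(inherits(presence, "otu_table"), inherits(config, "scenario_config"))
  P <- presence$counts
  if (!all(P %in% c(0, 1))) stopf("presence table must be 0/1")
  rr <- config$reads_range
  if (rr[1] > rr[2]) stopf("reads_range min > max")
  with_seed_(derive_seed(config$seed, "reads"), {
    counts <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
    totals <- sample(seq(rr[1], rr[2]), ncol(P), replace = TRUE)
    for (j in seq_len(ncol(P))) {
      present <- which(P[, j] > 0)
      if (!length(present)) next
      ab <- rlnorm(length(present), meanlog = 0, sdlog = 1.5)
      counts[present, j] <- as.integer(rmultinom(1, totals[j], prob = ab))
    }
    out <- presence
    out$counts <- counts
    attr(out, "empty_samples") <- colnames(P)[colSums(P) == 0]
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' Chains [generate_env_gradient()], [generate_community()] and
#' [generate_reads()] for one scenario.
#'
#' @param config A [estuary_scenario()].
#' @return List of class `synthetic_dataset`: `otu` (counts
#'   [otu_table()]), `presence` (0/1 [otu_table()]), `env` (`env_matrix`),
#'   `truth` (`truth_record`), `config`.
#' @export
generate_dataset <- function(config) {
  env <- generate_env_gradient(config)
  comm <- generate_community(config, env)
  reads <- generate_reads(comm$table, config)
  structure(list(otu = reads, presence = comm$table, env = env,
                 truth = comm$truth, config = config),
            class = "synthetic_dataset")
}
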