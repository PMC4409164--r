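# Shared fixture builders; everything is generated in code.

# tiny otu_table: counts matrix with taxonomy/sample metadata filled in
make_otu_fixture <- function(counts, phylum, station = NULL) {
  otus <- rownames(counts) %||% paste0("OTU", seq_len(nrow(counts)))
  samp <- colnames(counts) %||% paste0("smp", seq_len(ncol(counts)))
  rownames(counts) <- otus
  colnames(counts) <- samp
  station <- station %||% samp
  otu_table(counts,
            taxonomy = data.frame(otu = otus, phylum = phylum,
                                  family = paste0(phylum, "_fam")),
            samples = data.frame(sample = samp, station = station,
                                 replicate = 1L, estuary = "Test"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform rectangular channel for the linear co-oscillation oracle
linear_channel <- function(L = 50e3, dx = 500, depth = 10, width = 500) {
  n <- L / dx
  channel_geometry(seq(dx / 2, L - dx / 2, by = dx),
                   width = rep(width, n), depth = rep(depth, n))
}

# designed recovery environment: two planted orthogonal gradients plus
# twelve iid noise drivers across n stations
make_recovery_env <- function(seed, n = 20) {
  set.seed(seed)
  vals <- matrix(rnorm(n * 14), n, 14)
  colnames(vals) <- env_driver_names()
  g <- as.numeric(scale(seq_len(n)))
  vals[, "salinity_range"] <- g
  vals[, "D50"] <- g[sample.int(n)]
  env <- data.frame(station = sprintf("T%02d", seq_len(n)), vals)
  class(env) <- c("env_matrix", "data.frame")
  env
}

# two-phylum scenario whose community responds only to salinity range / D50
recovery_scenario <- function(seed) {
  estuary_scenario(
    seed = seed,
    taxon_pool = c(Nematoda = 100, Mollusca = 100),
    driver_effects = data.frame(phylum = c("Nematoda", "Mollusca"),
                                driver = c("salinity_range", "D50"),
                                effect = c(2.5, -2.5)),
    occupancy_intercept = -0.5, replicate_noise_sd = 0.3)
}

station_presence <- function(tab, filter = metazoan_phyla()) {
  P <- to_presence(tab, filter)
  pool_presence_by_station(P, tab$samples$station[match(rownames(P),
                                                        tab$samples$sample)])
}

# independent straight-line NIPALS PLS + VIP oracle (kept deliberately
# naive: explicit loops, no shared code with the package implementation)
oracle_pls <- function(X, y, A = 2) {
  X <- scale(X); y <- as.numeric(scale(y))
  p <- ncol(X)
  ss0 <- sum(y^2)
  W <- matrix(0, p, A); SS <- numeric(A)
  for (a in 1:A) {
    w <- numeric(p)
    for (j in 1:p) w[j] <- sum(X[, j] * y)
    w <- w / sqrt(sum(w^2))
    t_ <- as.numeric(X %*% w)
    q <- sum(y * t_) / sum(t_^2)
    pl <- numeric(p)
    for (j in 1:p) pl[j] <- sum(X[, j] * t_) / sum(t_^2)
    X <- X - outer(t_, pl)
    y <- y - q * t_
    W[, a] <- w
    SS[a] <- q^2 * sum(t_^2)
  }
  vip <- numeric(p)
  for (j in 1:p) vip[j] <- sqrt(p * sum(SS * W[j, ]^2) / sum(SS))
  list(vip = vip, r2 = SS / ss0)
}
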