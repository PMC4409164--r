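# End-to-end orchestration: simulate (or ingest) -> features -> community
# statistics -> driver inference -> report, under one configuration with a
# single master seed from which every stochastic stage derives its own.

#' Analysis configuration for the full pipeline
#'
#' @param scenarios List of [estuary_scenario()] configurations (synthetic
#'   mode), or `NULL` with `inputs` given (ingest mode).
#' @param inputs Ingest mode: named list per estuary with elements
#'   `otu` (TSV path) and `env` (CSV path).
#' @param taxon_filter Phyla entering the presence/absence analyses.
#' @param n_profile_perms,n_test_perms,alpha SIMPROF settings.
#' @param n_perm Permutations for Mantel/CCA/PLS significance.
#' @param max_subset_size,top_k BIOENV settings.
#' @param master_seed Single seed from which all stage seeds derive.
#' @param out_dir Output directory for stage files.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(scenarios = list(estuary_scenario(),
                                             mersey_scenario()),
                            inputs = NULL,
                            taxon_filter = metazoan_phyla(),
                            n_profile_perms = 1000, n_test_perms = 999,
                            alpha = 0.05, n_perm = 999,
                            max_subset_size = 5, top_k = 10,
                            master_seed = 1L,
                            out_dir = tempfile("estuaryr_run_")) {
  if (is.null(scenarios) && is.null(inputs))
    stopf("either scenarios (synthetic mode) or inputs (ingest mode) required")
  if (!is.null(inputs)) {
    for (nm in names(inputs)) {
      need <- c("otu", "env")
      if (!all(need %in% names(inputs[[nm]])))
        stopf("inputs$%s must list `otu` and `env` paths", nm)
      missing_files <- unlist(inputs[[nm]][need])
      missing_files <- missing_files[!file.exists(missing_files)]
      if (length(missing_files))
        stopf("input file(s) not found for %s: %s", nm,
              paste(missing_files, collapse = ", "))
    }
  }
  if (!is.null(scenarios)) {
    ok <- vapply(scenarios, inherits, logical(1), "scenario_config")
    if (!all(ok)) stopf("scenarios must be scenario_config objects")
  }
  structure(list(scenarios = scenarios, inputs = inputs,
                 taxon_filter = taxon_filter,
                 n_profile_perms = n_profile_perms,
                 n_test_perms = n_test_perms, alpha = alpha, n_perm = n_perm,
                 max_subset_size = max_subset_size, top_k = top_k,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Scenario entries accept the [estuary_scenario()] arguments; top-level
#' keys mirror [analysis_config()].
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  scen <- NULL
  if (!is.null(y$scenarios)) {
    scen <- lapply(y$scenarios, function(s) {
      if (!is.null(s$taxon_pool)) s$taxon_pool <- unlist(s$taxon_pool)
      if (!is.null(s$driver_effects))
        s$driver_effects <- do.call(rbind, lapply(s$driver_effects, as.data.frame))
      do.call(estuary_scenario, s)
    })
  }
  args <- y[setdiff(names(y), "scenarios")]
  do.call(analysis_config, c(list(scenarios = scen), args))
}

config_hash <- function(config) {
  # content hash over the deparsed configuration (stable across sessions)
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)))
}

pipeline_stage <- function(report, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  report$log[[name]] <- list(elapsed_s = proc.time()[["elapsed"]] - t0)
  report$stages[[name]] <- value
  report
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, community statistics (presence transform,
#' Sørensen, UPGMA + SIMPROF, NMDS, richness, between-estuary t-tests) and
#' driver inference (BIOENV, collinearity filter + stepwise-AIC CCA,
#' PLS-VIP) per estuary, writes all stage outputs under `config$out_dir`
#' and assembles a report. Re-running with an identical configuration and
#' intact output directory reuses the stored report.
#'
#' @param config An [analysis_config()].
#' @param force Recompute even when a matching cached report exists.
#' @return Object of class `estuary_report` (see [write_report()]).
#' @export
run_full <- function(config, force = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest <- file.path(config$out_dir, "manifest.json")
  cache <- file.path(config$out_dir, "report.rds")
  if (!force && file.exists(manifest) && file.exists(cache)) {
    m <- jsonlite::read_json(manifest)
    if (identical(m$config_hash, hash)) return(readRDS(cache))
  }
  seed_for <- function(label) derive_seed(config$master_seed, label)

  report <- list(stages = list(), log = list(), estuaries = list())
  # --- simulate / ingest -----------------------------------------------
  datasets <- if (!is.null(config$scenarios)) {
    ds <- lapply(config$scenarios, generate_dataset)
    names(ds) <- vapply(config$scenarios, `[[`, "", "estuary")
    ds
  } else {
    ds <- lapply(names(config$inputs), function(nm) {
      list(otu = read_otu_table(config$inputs[[nm]]$otu),
           env = read_env_matrix(config$inputs[[nm]]$env),
           truth = NULL, config = NULL)
    })
    names(ds) <- names(config$inputs)
    ds
  }

  per_estuary <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    pct <- reads_to_percent(d$otu)
    P <- to_presence(d$otu, config$taxon_filter)
    Pst <- pool_presence_by_station(P, d$otu$samples$station[
      match(rownames(P), d$otu$samples$sample)])
    D <- sorensen_dissimilarity(P)
    Dst <- sorensen_dissimilarity(Pst)
    sim <- simprof(P, n_profile_perms = config$n_profile_perms,
                   n_test_perms = config$n_test_perms, alpha = config$alpha,
                   seed = seed_for(paste0("simprof_", nm)))
    ord <- nmds(D, seed = seed_for(paste0("nmds_", nm)))
    rich <- richness_by_group(d$otu, "phylum", by_station = TRUE)
    Em <- env_values(d$env)[rownames(Dst), , drop = FALSE]
    be <- bioenv(Dst, Em, max_subset_size = config$max_subset_size,
                 top_k = config$top_k)
    Ered <- filter_collinear(Em, threshold = 0.7)
    cc <- cca_stepwise_aic(Pst[rownames(Ered), , drop = FALSE], Ered,
                           n_perm = config$n_perm,
                           seed = seed_for(paste0("cca_", nm)))
    pls <- pls_vip_table(Em, as.matrix(rich[rownames(Em), , drop = FALSE]),
                         n_perm = config$n_perm,
                         seed = seed_for(paste0("pls_", nm)))
    list(name = nm, dataset = d, percent = pct, presence = P,
         presence_station = Pst, dissimilarity = D,
         dissimilarity_station = Dst, simprof = sim, nmds = ord,
         richness = rich, bioenv = be, env_reduced = Ered, cca = cc,
         pls = pls)
  })
  names(per_estuary) <- names(datasets)
  report$estuaries <- per_estuary

  # --- between-estuary richness t-tests --------------------------------
  if (length(per_estuary) == 2) {
    r1 <- per_estuary[[1]]$richness
    r2 <- per_estuary[[2]]$richness
    shared <- intersect(colnames(r1), colnames(r2))
    tt <- lapply(shared, function(gr) {
      res <- welch_levene_ttest(r1[[gr]], r2[[gr]])
      data.frame(group = gr, t = res$t, df = res$df, p = res$p,
                 levene_p = res$levene_p, pooled = res$pooled)
    })
    report$t_tests <- do.call(rbind, tt)
  }
  report$provenance <- list(config_hash = hash,
                            master_seed = config$master_seed,
                            package_version = as.character(packageVersion("estuaryr")),
                            velocity_stat = "abs")
  class(report) <- "estuary_report"
  write_report(report, config$out_dir)
  saveRDS(report, cache)
  jsonlite::write_json(list(config_hash = hash), manifest, auto_unbox = TRUE)
  report
}

#' Write a pipeline report to files
#'
#' Per estuary: richness table, BIOENV top-k table (No. of variables,
#' correlation, variables), SIMPROF groups + dendrogram (Newick), NMDS
#' coordinates, CCA summary (JSON), PLS first-component VIP matrix. Plus
#' the between-estuary t-test table and a provenance block.
#'
#' @param report An `estuary_report`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "estuary_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path) written <<- c(written, path)
  for (nm in names(report$estuaries)) {
    e <- report$estuaries[[nm]]
    f <- function(x) file.path(dir, sprintf("%s_%s", nm, x))
    write.csv(e$richness, f("richness.csv"))
    emit(f("richness.csv"))
    write.csv(e$bioenv$table, f("bioenv.csv"), row.names = FALSE)
    emit(f("bioenv.csv"))
    write.csv(data.frame(sample = names(e$simprof$groups),
                         group = e$simprof$groups),
              f("simprof_groups.csv"), row.names = FALSE)
    emit(f("simprof_groups.csv"))
    dendrogram_newick(e$simprof$hclust, f("dendrogram.nwk"))
    emit(f("dendrogram.nwk"))
    write.csv(data.frame(sample = rownames(e$nmds$points), e$nmds$points),
              f("nmds.csv"), row.names = FALSE)
    emit(f("nmds.csv"))
    jsonlite::write_json(
      list(selected = e$cca$selected,
           total_inertia = e$cca$total_inertia,
           constrained_inertia = e$cca$constrained_inertia,
           constrained_fraction = e$cca$constrained_fraction,
           axis_fraction = e$cca$axis_fraction,
           variable_p = as.list(e$cca$variable_p)),
      f("cca.json"), auto_unbox = TRUE, digits = NA)
    emit(f("cca.json"))
    write.csv(as.data.frame(e$pls$vip1), f("pls_vip.csv"))
    emit(f("pls_vip.csv"))
    write_env_matrix(e$dataset$env, f("env.csv"))
    emit(f("env.csv"))
    if (!is.null(e$dataset$truth)) {
      write_truth_record(e$dataset$truth, f("truth.json"))
      emit(f("truth.json"))
    }
  }
  if (!is.null(report$t_tests)) {
    write.csv(report$t_tests, file.path(dir, "t_tests.csv"), row.names = FALSE)
    emit(file.path(dir, "t_tests.csv"))
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  emit(file.path(dir, "provenance.json"))
  invisible(written)
}

#' @export
print.estuary_report <- function(x, ...) {
  cat(sprintf("estuary_report: %d estuaries (%s)\n",
              length(x$estuaries), paste(names(x$estuaries), collapse = ", ")))
  for (nm in names(x$estuaries)) {
    e <- x$estuaries[[nm]]
    cat(sprintf("  %s: best BIOENV rho = %.3f [%s]; SIMPROF groups = %d; NMDS stress = %.3f\n",
                nm, e$bioenv$table$correlation[1], e$bioenv$table$variables[1],
                length(unique(e$simprof$groups)), e$nmds$stress))
  }
  invisible(x)
}
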