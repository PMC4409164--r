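# Community-structure statistics on OTU tables: relative abundances,
# presence/absence transform restricted to the metazoan target phyla,
# Sorensen dissimilarity, group-average clustering with SIMPROF permutation
# tests, NMDS ordination, richness tables and two-sample richness tests.

#' The eleven metazoan phyla retained for community analyses
#'
#' @return Character vector of phylum names.
#' @export
metazoan_phyla <- function() {
  c("Nematoda", "Platyhelminthes", "Arthropoda", "Mollusca", "Annelida",
    "Gastrotricha", "Tardigrada", "Kinorhyncha", "Rotifera", "Cnidaria",
    "Bryozoa")
}

#' OTU table container
#'
#' @param counts Integer matrix, OTUs x samples (rownames = OTU ids,
#'   colnames = sample ids).
#' @param taxonomy Data.frame with columns `otu`, `phylum`, `family`
#'   (may be `"NA"`).
#' @param samples Data.frame with columns `sample`, `station`, `replicate`,
#'   `estuary`.
#' @return Object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have OTU rownames and sample colnames")
  if (!all(c("otu", "phylum", "family") %in% names(taxonomy)))
    stopf("taxonomy needs columns otu, phylum, family")
  if (!all(rownames(counts) %in% taxonomy$otu))
    stopf("every OTU needs a taxonomy row")
  if (!all(c("sample", "station", "replicate", "estuary") %in% names(samples)))
    stopf("samples needs columns sample, station, replicate, estuary")
  if (!setequal(colnames(counts), samples$sample))
    stopf("sample metadata must cover exactly the count columns")
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$otu), ]
  samples <- samples[match(colnames(counts), samples$sample), ]
  rownames(taxonomy) <- rownames(samples) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy, samples = samples),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%d stations, estuaries: %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$station)),
              paste(unique(x$samples$estuary), collapse = ", ")))
  invisible(x)
}

#' Convert read counts to per-sample percentages
#'
#' Samples differ in sequencing depth, so analyses use the percentage of
#' reads in each sample rather than raw counts; each sample column sums to
#' 100.
#'
#' @param table An [otu_table()].
#' @return The table with `counts` replaced by percentages (class unchanged,
#'   flag `relative = TRUE`).
#' @export
reads_to_percent <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  tot <- colSums(table$counts)
  if (any(tot == 0))
    stopf("cannot normalise all-zero sample(s): %s",
          paste(colnames(table$counts)[tot == 0], collapse = ", "))
  table$counts <- sweep(table$counts, 2, tot, "/") * 100
  table$relative <- TRUE
  table
}

#' Presence/absence matrix restricted to a phylum filter
#'
#' @param table An [otu_table()].
#' @param phylum_filter Phyla to retain; defaults to the eleven metazoan
#'   phyla of [metazoan_phyla()].
#' @return Binary samples x OTUs matrix (class `presence_matrix`); OTUs
#'   absent from every retained sample are dropped.
#' @export
to_presence <- function(table, phylum_filter = metazoan_phyla()) {
  stopifnot(inherits(table, "otu_table"))
  keep <- table$taxonomy$phylum %in% phylum_filter
  if (!any(keep))
    stopf("no OTUs match the phylum filter (%s)",
          paste(phylum_filter, collapse = ", "))
  P <- t(table$counts[keep, , drop = FALSE] > 0) * 1L
  P <- P[, colSums(P) > 0, drop = FALSE]
  if (ncol(P) == 0) stopf("presence matrix is empty after dropping absent OTUs")
  class(P) <- c("presence_matrix", class(P))
  P
}

#' Pool replicate samples to station-level presence
#'
#' An OTU is present at a station if present in any replicate core.
#'
#' @param P Samples x OTUs binary matrix (rownames = sample ids).
#' @param stations Station label per row of `P`.
#' @return Stations x OTUs binary matrix.
#' @export
pool_presence_by_station <- function(P, stations) {
  stopifnot(nrow(P) == length(stations))
  G <- rowsum(unclass(P), group = stations, reorder = FALSE)
  out <- (G > 0) * 1L
  class(out) <- c("presence_matrix", class(out))
  out
}

#' Sørensen dissimilarity between samples
#'
#' `d = 1 - 2a / (2a + b + c)` where `a` counts OTUs shared by the two
#' samples and `b`, `c` those unique to each. A pair of empty samples is
#' assigned `d = 0` with a warning (the coefficient is undefined there).
#'
#' @param P Samples x OTUs binary matrix.
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
sorensen_dissimilarity <- function(P) {
  P <- unclass(as.matrix(P))
  if (nrow(P) < 2) stopf("need at least 2 samples")
  if (!all(P %in% c(0, 1))) stopf("presence matrix must be binary")
  a <- tcrossprod(P)
  n_i <- diag(a)
  denom <- outer(n_i, n_i, "+")
  d <- 1 - 2 * a / denom
  if (any(denom == 0)) {
    warning("pair(s) of empty samples: Sorensen dissimilarity set to 0")
    d[denom == 0] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(P), rownames(P))
  d
}

#' Group-average (UPGMA) clustering of a dissimilarity matrix
#'
#' Unweighted average-linkage agglomeration; merge heights equal the mean
#' between-cluster dissimilarity, so the tree is ultrametric. Ties are
#' broken deterministically by label order.
#'
#' @param D Symmetric dissimilarity matrix with labels.
#' @return An [stats::hclust] object.
#' @export
upgma <- function(D) {
  D <- check_distmat(D)
  hclust(as.dist(D), method = "average")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are differences of UPGMA merge heights.
#'
#' @param hc An [stats::hclust] object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# leaves under each internal node of an hclust merge tree
hclust_node_members <- function(hc, node) {
  row <- hc$merge[node, ]
  unlist(lapply(row, function(v) {
    if (v < 0) -v else hclust_node_members(hc, v)
  }))
}

# independent permutation of each column (OTU) across rows (samples);
# one order() call yields all within-column shuffles at once
permute_columns <- function(P) {
  m <- nrow(P); k <- ncol(P)
  ord <- order(rep.int(seq_len(k), rep.int(m, k)), runif(m * k))
  matrix(P[ord], m, k)
}

sorted_similarity_profile <- function(P) {
  sort(1 - lower_tri(suppressWarnings(sorensen_dissimilarity(P))))
}

# similarity-profile test of one group of samples
simprof_node_test <- function(P, n_profile_perms, n_test_perms) {
  obs <- sorted_similarity_profile(P)
  np <- length(obs)
  mean_prof <- numeric(np)
  for (b in seq_len(n_profile_perms))
    mean_prof <- mean_prof + sorted_similarity_profile(permute_columns(P))
  mean_prof <- mean_prof / n_profile_perms
  pi_obs <- sum(abs(obs - mean_prof))
  pi_null <- vapply(seq_len(n_test_perms), function(b)
    sum(abs(sorted_similarity_profile(permute_columns(P)) - mean_prof)),
    numeric(1))
  p <- (sum(pi_null >= pi_obs) + 1) / (n_test_perms + 1)
  list(pi = pi_obs, p = p)
}

#' SIMPROF: similarity-profile permutation tests down a dendrogram
#'
#' Tests, top-down from the root of the Sørensen/UPGMA dendrogram, whether
#' the samples under each node carry real multivariate structure. At each
#' node the ordered between-sample similarity profile is compared with its
#' expectation under independent within-OTU permutations; the statistic is
#' `pi = sum |obs_i - mean_i|` and the p-value comes from further
#' permutations as `(b + 1) / (m + 1)`. Recursion stops at non-significant
#' nodes, whose leaves form one homogeneous group. Nodes with fewer than 3
#' samples are not testable and are grouped.
#'
#' @param P Samples x OTUs binary matrix.
#' @param n_profile_perms Permutations used for the mean profile.
#' @param n_test_perms Permutations used for the p-value.
#' @param alpha Significance level for continuing the recursion.
#' @param seed Optional RNG seed.
#' @return Object of class `simprof_result`: `groups` (integer group id per
#'   sample), `tests` (data.frame per tested node: size, pi, p,
#'   significant), `hclust`, and the settings.
#' @export
simprof <- function(P, n_profile_perms = 1000, n_test_perms = 999,
                    alpha = 0.05, seed = NULL) {
  P <- unclass(as.matrix(P))
  D <- suppressWarnings(sorensen_dissimilarity(P))
  hc <- upgma(D)
  n <- nrow(P)
  groups <- integer(n)
  tests <- list()
  with_seed_(seed, {
    next_group <- 0L
    assign_group <- function(members) {
      next_group <<- next_group + 1L
      groups[members] <<- next_group
    }
    walk <- function(node) {
      members <- if (node < 0) -node else hclust_node_members(hc, node)
      if (length(members) < 3) {
        assign_group(members)
        return(invisible())
      }
      res <- simprof_node_test(P[members, , drop = FALSE],
                               n_profile_perms, n_test_perms)
      tests[[length(tests) + 1L]] <<-
        data.frame(n_samples = length(members), pi = res$pi, p = res$p,
                   significant = res$p <= alpha)
      if (res$p <= alpha) {
        walk(hc$merge[node, 1])
        walk(hc$merge[node, 2])
      } else {
        assign_group(members)
      }
    }
    walk(nrow(hc$merge))
  })
  names(groups) <- rownames(P)
  structure(list(groups = groups,
                 tests = if (length(tests)) do.call(rbind, tests) else
                   data.frame(n_samples = integer(), pi = numeric(),
                              p = numeric(), significant = logical()),
                 hclust = hc,
                 settings = list(n_profile_perms = n_profile_perms,
                                 n_test_perms = n_test_perms, alpha = alpha,
                                 seed = seed)),
            class = "simprof_result")
}

#' @export
print.simprof_result <- function(x, ...) {
  cat(sprintf("SIMPROF: %d samples -> %d groups (%d nodes tested, alpha = %g)\n",
              length(x$groups), length(unique(x$groups)), nrow(x$tests),
              x$settings$alpha))
  invisible(x)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (global non-metric model) with multiple restarts:
#' the first start is the metric (principal-coordinates) configuration, the
#' rest are random. The lowest-stress solution is returned with centred
#' coordinates.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param dims Number of ordination dimensions.
#' @param restarts Number of starts (>= 1).
#' @param max_iter Iteration cap per start.
#' @param seed Optional RNG seed.
#' @return Object of class `nmds_result`: `points` (n x dims), `stress`
#'   (Kruskal stress-1, 0-1 scale), `converged`, `restarts`.
#' @export
nmds <- function(D, dims = 2, restarts = 20, max_iter = 500, seed = NULL) {
  D <- check_distmat(D)
  n <- nrow(D)
  if (n == 2) {
    pts <- matrix(c(-D[1, 2] / 2, D[1, 2] / 2, rep(0, 2 * (dims - 1))), 2, dims)
    rownames(pts) <- rownames(D)
    return(structure(list(points = pts, stress = 0, converged = TRUE,
                          restarts = 0L),
                     class = "nmds_result"))
  }
  d <- as.dist(D)
  with_seed_(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      y0 <- if (r == 1) {
        y <- cmdscale(d, k = dims)
        if (ncol(y) < dims) cbind(y, matrix(0, n, dims - ncol(y))) else y
      } else {
        matrix(rnorm(n * dims), n, dims)
      }
      fit <- vegan::monoMDS(d, y = y0, k = dims, model = "global",
                            maxit = max_iter)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- scale(best$points, center = TRUE, scale = FALSE)
    attr(pts, "scaled:center") <- NULL
    rownames(pts) <- rownames(D)
    colnames(pts) <- paste0("NMDS", seq_len(dims))
    structure(list(points = pts, stress = best$stress,
                   converged = best$icause %in% c(2L, 3L, 4L) || best$stress < 1e-3,
                   restarts = restarts),
              class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points, %d dims, stress = %.4f (%d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$restarts))
  invisible(x)
}

#' Per-sample OTU richness by taxonomic group
#'
#' Counts OTUs with at least one read, per sample and per group at the
#' requested rank.
#'
#' @param table An [otu_table()].
#' @param rank `"phylum"` or `"family"`.
#' @param by_station Pool replicates: an OTU counts as present at a station
#'   if present in any replicate.
#' @return Data.frame, samples (or stations) x groups, plus a `total`
#'   column.
#' @export
richness_by_group <- function(table, rank = c("phylum", "family"),
                              by_station = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  rank <- match.arg(rank)
  pres <- table$counts > 0
  if (by_station) {
    pres <- t(rowsum(t(pres) * 1L, group = table$samples$station,
                     reorder = FALSE) > 0)
  }
  grp <- table$taxonomy[[rank]]
  grp[is.na(grp)] <- "NA"
  counts <- rowsum(pres * 1L, group = grp, reorder = TRUE)
  out <- as.data.frame(t(counts))
  out$total <- colSums(pres)
  out
}

#' Two-sample richness test with Levene's variance check
#'
#' Levene's test (absolute deviations from the group means) decides between
#' the pooled-variance and Welch t-test; the chosen two-sided t-test is then
#' applied.
#'
#' @param x,y Richness vectors for the two groups (each n >= 2).
#' @return List: `levene_p`, `pooled` (logical), `t`, `df`, `p`.
#' @export
welch_levene_ttest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("each group needs n >= 2")
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lev <- car::leveneTest(c(x, y) ~ g, center = mean)
  lev_p <- lev[["Pr(>F)"]][1]
  pooled <- is.na(lev_p) || lev_p > 0.05
  tt <- t.test(x, y, var.equal = pooled)
  list(levene_p = lev_p, pooled = pooled,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
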