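# BIOENV subset search and Mantel tests: which combination of environmental
# variables yields inter-station distances that best rank-correlate with the
# biotic (Sorensen) dissimilarities.

#' Standardise environmental variables
#'
#' Centres each column to mean 0 and scales to unit standard deviation.
#'
#' @param E Numeric matrix or data.frame of environmental variables.
#' @param subset Optional column names to keep.
#' @return Standardised numeric matrix.
#' @export
normalize_env <- function(E, subset = NULL) {
  E <- as.matrix(E)
  if (!is.null(subset)) {
    bad <- setdiff(subset, colnames(E))
    if (length(bad)) stopf("unknown variable(s): %s", paste(bad, collapse = ", "))
    E <- E[, subset, drop = FALSE]
  }
  if (anyNA(E)) stopf("missing values in environmental variables")
  s <- apply(E, 2, sd)
  if (any(s == 0))
    stopf("constant variable(s): %s", paste(colnames(E)[s == 0], collapse = ", "))
  scale(E)
}

#' Spearman correlation between two distance matrices
#'
#' Spearman rank correlation of the `n(n-1)/2` lower-triangle entries
#' (average ranks for ties).
#'
#' @param D_bio,D_env Symmetric matrices with matching row order.
#' @return Correlation coefficient.
#' @export
spearman_matrix_corr <- function(D_bio, D_env) {
  D_bio <- check_distmat(D_bio, "D_bio")
  D_env <- check_distmat(D_env, "D_env")
  if (nrow(D_bio) != nrow(D_env)) stopf("distance matrices must match in size")
  if (!is.null(rownames(D_bio)) && !is.null(rownames(D_env)) &&
      !identical(rownames(D_bio), rownames(D_env)))
    stopf("distance matrix labels do not match")
  cor(lower_tri(D_bio), lower_tri(D_env), method = "spearman")
}

#' BIOENV: exhaustive search for the best environmental subset
#'
#' For every non-empty subset of environmental variables up to
#' `max_subset_size`, computes Euclidean distances between stations on the
#' standardised variables and the Spearman rank correlation of those
#' distances with the biotic dissimilarities; subsets are ranked by the
#' correlation and the best `top_k` reported.
#'
#' @param D_bio Biotic (Sørensen) dissimilarity matrix among stations.
#' @param E Stations x variables environmental matrix (rows aligned with
#'   `D_bio`).
#' @param max_subset_size Largest subset examined (default: all variables).
#' @param top_k Number of best subsets to report.
#' @param max_vars Guard against runaway enumeration: more than this many
#'   variables with unrestricted subset size raises an error unless
#'   `force = TRUE`.
#' @param force Override the combinatorial guard.
#' @return Object of class `bioenv_result`: data.frame `table` with columns
#'   `n_variables`, `correlation`, `variables` (comma-joined names), plus
#'   `n_subsets` evaluated and the settings.
#' @export
bioenv <- function(D_bio, E, max_subset_size = NULL, top_k = 10,
                   max_vars = 20, force = FALSE) {
  D_bio <- check_distmat(D_bio, "D_bio")
  E <- as.matrix(E)
  if (nrow(E) != nrow(D_bio))
    stopf("env matrix rows (%d) must match D_bio (%d)", nrow(E), nrow(D_bio))
  p <- ncol(E)
  max_subset_size <- min(max_subset_size %||% p, p)
  if (p > max_vars && max_subset_size >= p && !force)
    stopf("%d variables with unlimited subset size: %g subsets; set force = TRUE",
          p, 2^p - 1)
  Z <- normalize_env(E)
  # squared z-score differences per variable and station pair; Spearman is
  # invariant to the final sqrt, so subsets are scored on squared distances
  pair_sq <- apply(Z, 2, function(z) lower_tri(outer(z, z, "-")^2))
  bio_rank <- rank(lower_tri(D_bio))
  bio_rank <- bio_rank - mean(bio_rank)
  bio_ss <- sqrt(sum(bio_rank^2))

  subsets <- unlist(lapply(seq_len(max_subset_size),
                           function(k) combn(p, k, simplify = FALSE)),
                    recursive = FALSE)
  rho <- vapply(subsets, function(idx) {
    d2 <- if (length(idx) == 1L) pair_sq[, idx] else
      rowSums(pair_sq[, idx, drop = FALSE])
    r <- rank(d2)
    r <- r - mean(r)
    sum(r * bio_rank) / (sqrt(sum(r^2)) * bio_ss)
  }, numeric(1))

  ord <- order(rho, decreasing = TRUE)
  keep <- head(ord, top_k)
  vars <- colnames(E) %||% paste0("V", seq_len(p))
  tab <- data.frame(
    n_variables = lengths(subsets[keep]),
    correlation = rho[keep],
    variables = vapply(subsets[keep],
                       function(idx) paste(vars[idx], collapse = ", "),
                       character(1)))
  structure(list(table = tab, n_subsets = length(subsets),
                 best_subset = vars[subsets[[ord[1]]]],
                 settings = list(max_subset_size = max_subset_size,
                                 top_k = top_k)),
            class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat(sprintf("BIOENV: %d subsets evaluated; best rho = %.3f\n",
              x$n_subsets, x$table$correlation[1]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Spearman correlation of the lower triangles; the null distribution comes
#' from simultaneously permuting the rows and columns of the second matrix.
#' The p-value is `(b + 1) / (n_perm + 1)`.
#'
#' @param D1,D2 Symmetric distance matrices with matching labels.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @return Object of class `mantel_result`: `rho`, `p`, `n_perm`.
#' @export
mantel <- function(D1, D2, n_perm = 999, seed = NULL) {
  D1 <- check_distmat(D1, "D1")
  D2 <- check_distmat(D2, "D2")
  rho <- spearman_matrix_corr(D1, D2)
  n <- nrow(D2)
  with_seed_(seed, {
    v1 <- rank(lower_tri(D1))
    v1 <- v1 - mean(v1)
    s1 <- sqrt(sum(v1^2))
    null <- vapply(seq_len(n_perm), function(b) {
      pm <- sample.int(n)
      v2 <- rank(lower_tri(D2[pm, pm]))
      v2 <- v2 - mean(v2)
      sum(v1 * v2) / (s1 * sqrt(sum(v2^2)))
    }, numeric(1))
    p <- (sum(null >= rho) + 1) / (n_perm + 1)
    structure(list(rho = rho, p = p, n_perm = n_perm, seed = seed),
              class = "mantel_result")
  })
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: rho = %.3f, p = %.4f (%d permutations)\n",
              x$rho, x$p, x$n_perm))
  invisible(x)
}

#' Remove collinear environmental variables
#'
#' Greedily removes variables until all pairwise |r| are at or below the
#' threshold. At each step the offending pair's member with the larger mean
#' |r| against all remaining variables is dropped (so the variable carrying
#' more redundant signal goes first); `keep` variables are never dropped.
#'
#' @param E Stations x variables numeric matrix or data.frame.
#' @param threshold Pairwise absolute-correlation cutoff.
#' @param keep Variables protected from removal.
#' @return The reduced matrix with attribute `removed` (character vector,
#'   in removal order).
#' @export
filter_collinear <- function(E, threshold = 0.7, keep = character()) {
  E <- as.matrix(E)
  if (ncol(E) < 2) stopf("need at least 2 variables")
  removed <- character()
  repeat {
    R <- abs(cor(E))
    diag(R) <- 0
    prot <- colnames(E) %in% keep
    Rm <- R
    Rm[prot, prot] <- 0 # pairs of protected variables cannot be resolved
    if (max(Rm) <= threshold) break
    worst <- which(Rm == max(Rm), arr.ind = TRUE)[1, ]
    cand <- setdiff(colnames(E)[worst], keep)
    drop_var <- cand[which.max(colMeans(R[, cand, drop = FALSE]))]
    removed <- c(removed, drop_var)
    E <- E[, setdiff(colnames(E), drop_var), drop = FALSE]
    if (ncol(E) < 2) break
  }
  attr(E, "removed") <- removed
  E
}
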