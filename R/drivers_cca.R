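# Canonical correspondence analysis: chi-square standardised community
# matrix regressed (row-weighted) on environmental predictors, constrained
# axes from the eigen-decomposition of the fitted matrix, stepwise AIC
# model selection and permutation significance.

cca_qbar <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stopf("community matrix must be non-negative")
  if (any(rowSums(Y) == 0) || any(colSums(Y) == 0))
    stopf("community matrix must have positive row and column sums")
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P)
  cc <- colSums(P)
  list(Qbar = (P - outer(r, cc)) / sqrt(outer(r, cc)), r = r, c = cc,
       total = tot)
}

# row-weighted standardisation and projection basis for the predictors
cca_basis <- function(E, r) {
  E <- as.matrix(E)
  mu <- colSums(E * r)
  Ec <- sweep(E, 2, mu)
  s <- sqrt(colSums(Ec^2 * r))
  if (any(s == 0)) stopf("constant predictor(s): %s",
                         paste(colnames(E)[s == 0], collapse = ", "))
  Xw <- sweep(Ec, 2, s, "/") * sqrt(r)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) {
    dep <- colnames(Xw)[qrX$pivot[(qrX$rank + 1):ncol(Xw)]]
    stopf("rank-deficient predictors; linearly dependent column(s): %s",
          paste(dep, collapse = ", "))
  }
  qr.Q(qrX)
}

cca_constrained_inertia <- function(Qbar, Qx) {
  fit <- Qx %*% crossprod(Qx, Qbar)
  sum(fit^2)
}

#' Canonical correspondence analysis
#'
#' The community matrix is chi-square standardised (inertia = Pearson
#' chi-square / grand total), regressed on the row-weight-standardised
#' predictors, and the fitted matrix eigen-decomposed into constrained
#' axes.
#'
#' @param Y Stations x OTUs non-negative matrix (presence/absence or
#'   abundances) with positive row and column sums.
#' @param E Stations x predictors matrix, rows aligned with `Y`.
#' @param n_perm Permutations for per-variable significance (0 skips the
#'   tests).
#' @param seed Optional RNG seed for the permutations.
#' @return Object of class `cca_result`: `eigenvalues` (constrained, sorted
#'   descending), `total_inertia`, `constrained_inertia`,
#'   `constrained_fraction`, `axis_fraction` (share of constrained inertia
#'   per axis), `site_scores` and `biplot_scores` (first two axes),
#'   `variable_p` (marginal permutation p per predictor), `variables`.
#' @export
cca_fit <- function(Y, E, n_perm = 999, seed = NULL) {
  E <- as.matrix(E)
  qb <- cca_qbar(Y)
  Qx <- cca_basis(E, qb$r)
  fit <- Qx %*% crossprod(Qx, qb$Qbar)
  sv <- svd(fit)
  keep <- sv$d > max(sv$d) * 1e-10
  ev <- sv$d[keep]^2
  total <- sum(qb$Qbar^2)
  constrained <- sum(ev)
  naxes <- min(2, sum(keep))
  U <- sv$u[, seq_len(naxes), drop = FALSE]
  site_scores <- U * rep(sv$d[seq_len(naxes)], each = nrow(U)) / sqrt(qb$r)
  rownames(site_scores) <- rownames(Y)
  colnames(site_scores) <- paste0("CCA", seq_len(naxes))
  biplot_scores <- cor(sweep(E, 1, sqrt(qb$r), "*"), U)
  colnames(biplot_scores) <- paste0("CCA", seq_len(naxes))

  variable_p <- NULL
  if (n_perm > 0 && ncol(E) >= 1) {
    variable_p <- with_seed_(seed, vapply(colnames(E), function(v) {
      cca_margin_perm_p(qb, E, v, n_perm)
    }, numeric(1)))
  }
  structure(list(eigenvalues = ev, total_inertia = total,
                 constrained_inertia = constrained,
                 constrained_fraction = constrained / total,
                 axis_fraction = if (length(ev)) ev / constrained else numeric(0),
                 site_scores = site_scores, biplot_scores = biplot_scores,
                 variable_p = variable_p, variables = colnames(E),
                 n_perm = n_perm),
            class = "cca_result")
}

# marginal significance of one predictor: Freedman-Lane permutation of the
# reduced-model residuals
cca_margin_perm_p <- function(qb, E, var, n_perm) {
  others <- setdiff(colnames(E), var)
  Qx_full <- cca_basis(E, qb$r)
  if (length(others)) {
    Qx_red <- cca_basis(E[, others, drop = FALSE], qb$r)
    fit_red <- Qx_red %*% crossprod(Qx_red, qb$Qbar)
  } else {
    Qx_red <- NULL
    fit_red <- matrix(0, nrow(qb$Qbar), ncol(qb$Qbar))
  }
  res_red <- qb$Qbar - fit_red
  stat_obs <- cca_constrained_inertia(qb$Qbar, Qx_full) -
    sum(fit_red^2)
  n <- nrow(qb$Qbar)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    Ystar <- fit_red + res_red[sample.int(n), , drop = FALSE]
    stat <- cca_constrained_inertia(Ystar, Qx_full) -
      (if (is.null(Qx_red)) 0 else cca_constrained_inertia(Ystar, Qx_red))
    if (stat >= stat_obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA: %d constrained axes; constrained/total inertia = %.3f/%.3f (%.0f%%)\n",
              length(x$eigenvalues), x$constrained_inertia, x$total_inertia,
              100 * x$constrained_fraction))
  if (length(x$axis_fraction) >= 2)
    cat(sprintf("first two axes carry %.0f%% of the constrained inertia\n",
                100 * sum(x$axis_fraction[1:2])))
  invisible(x)
}

#' Stepwise AIC selection of CCA predictors
#'
#' Forward-backward search over the candidate predictors, scoring each
#' model by a deviance-style AIC on its residual inertia,
#' `n * log(residual_inertia / n) + 2k` with `k` the number of selected
#' predictors. The final model is refitted with per-variable permutation
#' tests.
#'
#' @param Y,E As in [cca_fit()].
#' @param n_perm Permutations for the final per-variable tests.
#' @param seed Optional RNG seed.
#' @return A `cca_result` for the selected model with extra fields
#'   `selected` (variable names, possibly empty) and `aic_trace`. With no
#'   selected variable the result is the intercept-only model (constrained
#'   inertia 0).
#' @export
cca_stepwise_aic <- function(Y, E, n_perm = 999, seed = NULL) {
  E <- as.matrix(E)
  qb <- cca_qbar(Y)
  total <- sum(qb$Qbar^2)
  n <- nrow(E)
  model_aic <- function(vars) {
    resid <- if (length(vars)) {
      total - cca_constrained_inertia(qb$Qbar, cca_basis(E[, vars, drop = FALSE], qb$r))
    } else total
    n * log(max(resid, 1e-12) / n) + 2 * length(vars)
  }
  current <- character()
  aic_cur <- model_aic(current)
  trace <- data.frame(step = "start", variables = "", aic = aic_cur)
  repeat {
    moves <- list()
    for (v in setdiff(colnames(E), current))
      moves[[paste0("+", v)]] <- c(current, v)
    for (v in current)
      moves[[paste0("-", v)]] <- setdiff(current, v)
    if (!length(moves)) break
    aics <- vapply(moves, model_aic, numeric(1))
    if (min(aics) >= aic_cur - 1e-9) break
    best <- which.min(aics)
    current <- moves[[best]]
    aic_cur <- aics[best]
    trace <- rbind(trace, data.frame(step = names(moves)[best],
                                     variables = paste(current, collapse = ","),
                                     aic = aic_cur))
  }
  if (!length(current)) {
    out <- structure(list(eigenvalues = numeric(0), total_inertia = total,
                          constrained_inertia = 0, constrained_fraction = 0,
                          axis_fraction = numeric(0), site_scores = NULL,
                          biplot_scores = NULL, variable_p = NULL,
                          variables = character(), n_perm = n_perm),
                     class = "cca_result")
  } else {
    out <- cca_fit(Y, E[, current, drop = FALSE], n_perm = n_perm, seed = seed)
  }
  out$selected <- current
  out$aic_trace <- trace
  out
}
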