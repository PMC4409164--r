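# Partial least squares regression (univariate response, NIPALS-style
# deflation) with variable-importance-in-projection (VIP) scores. Used to
# rank environmental drivers of per-phylum OTU richness; predictors with
# VIP > 1 are flagged as pertinent.

#' PLS regression with VIP variable ranking
#'
#' Fits a univariate-response PLS model by iterative latent-variable
#' extraction on the standardised predictor matrix and response. For
#' component `a` the weight vector is `w_a = X'y / |X'y|`, the score
#' `t_a = X w_a`, and `X`, `y` are deflated by the loadings before the next
#' component. The VIP score of predictor `j` over `A` components is
#'
#' `VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a )`
#'
#' with `SS_a` the response variance explained by component `a`, so the mean
#' squared VIP over predictors is exactly 1. The association sign of a
#' predictor is the sign of its first-component regression coefficient.
#' Per-predictor univariate `R^2` values and permutation p-values (response
#' permuted) accompany the table.
#'
#' @param X Observations x predictors matrix (e.g. stations x environmental
#'   drivers, optionally with macrofauna metrics).
#' @param y Response vector (e.g. per-station OTU richness of one phylum).
#' @param n_components Number of latent variables (default 2).
#' @param n_perm Permutations for the per-predictor univariate R^2 p-values
#'   (0 skips them).
#' @param seed Optional RNG seed for the permutations.
#' @return Object of class `pls_vip_result`: `table` (per predictor:
#'   `vip1` for the first latent variable, `vip` over all components,
#'   `sign`, `r_squared`, `p`, `pertinent` = vip1 > 1), `component_r2`,
#'   `cumulative_r2`, `n_components`, plus weights/scores for inspection.
#' @export
pls_vip <- function(X, y, n_components = 2, n_perm = 999, seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stopf("X rows and y length must match")
  if (anyNA(X) || anyNA(y)) stopf("missing values in X or y")
  if (sd(y) == 0) stopf("response has zero variance")
  p <- ncol(X)
  n <- nrow(X)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stopf("constant predictor(s): %s", paste(colnames(X)[sds == 0], collapse = ", "))
  A <- min(n_components, p, n - 1)
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  ss_y <- sum(ys^2)

  W <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  ss <- numeric(A)
  Xd <- Xs
  yd <- ys
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    pl <- crossprod(Xd, t_a) / tt
    q[a] <- sum(yd * t_a) / tt
    Xd <- Xd - t_a %*% t(pl)
    yd <- yd - q[a] * t_a
    W[, a] <- w
    Tm[, a] <- t_a
    ss[a] <- q[a]^2 * tt # response sum of squares explained by component a
  }
  if (A < 1) stopf("no usable PLS component (predictors orthogonal to response)")
  W <- W[, seq_len(A), drop = FALSE]
  ss <- ss[seq_len(A)]
  comp_r2 <- ss / ss_y

  vip_over <- function(a_use) {
    num <- colSums(t(W[, a_use, drop = FALSE]^2) * ss[a_use])
    sqrt(p * num / sum(ss[a_use]))
  }
  vip1 <- vip_over(1L)
  vip_all <- vip_over(seq_len(A))
  sign1 <- sign(W[, 1] * q[1])

  r2_uni <- apply(Xs, 2, function(x) cor(x, ys)^2)
  pvals <- rep(NA_real_, p)
  if (n_perm > 0) {
    pvals <- with_seed_(seed, {
      vapply(seq_len(p), function(j) {
        obs <- r2_uni[j]
        null <- vapply(seq_len(n_perm),
                       function(b) cor(Xs[, j], sample(ys))^2, numeric(1))
        (sum(null >= obs) + 1) / (n_perm + 1)
      }, numeric(1))
    })
  }
  vars <- colnames(X) %||% paste0("X", seq_len(p))
  tab <- data.frame(variable = vars, vip1 = vip1, vip = vip_all,
                    sign = sign1, r_squared = unname(r2_uni), p = pvals,
                    pertinent = vip1 > 1, row.names = NULL)
  structure(list(table = tab, component_r2 = comp_r2,
                 cumulative_r2 = cumsum(comp_r2), n_components = A,
                 weights = W, scores = Tm[, seq_len(A), drop = FALSE]),
            class = "pls_vip_result")
}

#' @export
print.pls_vip_result <- function(x, ...) {
  cat(sprintf("PLS-VIP: %d components, cumulative R2 = %s\n",
              x$n_components,
              paste(sprintf("%.2f", x$cumulative_r2), collapse = ", ")))
  print(x$table[order(-x$table$vip1), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' PLS-VIP tables for several responses
#'
#' Convenience wrapper running [pls_vip()] for each column of a response
#' matrix (e.g. per-phylum richness) against a common predictor matrix,
#' arranged predictors x responses as in a driver-importance table.
#'
#' @param X Predictor matrix.
#' @param Y Responses matrix (observations x responses); zero-variance or
#'   sparse responses (fewer than `min_otus` total) are skipped.
#' @param min_total Minimum column total for a response to be analysed.
#' @param ... Passed to [pls_vip()].
#' @return List with `vip1` (predictors x responses matrix of
#'   first-component VIPs), `sign`, `r_squared`, `p` matrices, and `fits`
#'   (the individual `pls_vip_result`s).
#' @export
pls_vip_table <- function(X, Y, min_total = 10, ...) {
  Y <- as.matrix(Y)
  usable <- colSums(Y) >= min_total & apply(Y, 2, sd) > 0
  fits <- lapply(colnames(Y)[usable], function(resp)
    pls_vip(X, Y[, resp], ...))
  names(fits) <- colnames(Y)[usable]
  grab <- function(field) {
    m <- vapply(fits, function(f) f$table[[field]], numeric(ncol(X)))
    rownames(m) <- colnames(X)
    m
  }
  list(vip1 = grab("vip1"), sign = grab("sign"),
       r_squared = grab("r_squared"), p = grab("p"), fits = fits)
}
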