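# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a local RNG state; seed = NULL leaves the global stream alone
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# derive a stage seed < 2^31 from a master seed and a stage label
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# symmetric dissimilarity matrix with labels -> validated "dist"-like matrix
check_distmat <- function(D, name = "D") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stopf("`%s` must be square", name)
  if (max(abs(D - t(D))) > 1e-12) stopf("`%s` must be symmetric", name)
  if (max(abs(diag(D))) > 1e-12) stopf("`%s` must have a zero diagonal", name)
  D
}

lower_tri <- function(D) D[lower.tri(D)]
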