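#' @keywords internal
"_PACKAGE"

## Natural logarithm used everywhere a size-density variable is transformed.
## Single shared definition so no fit can silently switch base.
ln <- function(x) {
  stopifnot(is.numeric(x))
  log(x)
}

## Numerically stable log(sum(exp(x))) along rows of a matrix (or a vector).
logsumexp <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    m + log(rowSums(exp(x - m)))
  } else {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
}

## Gauss-Hermite nodes/weights for integrals against a N(0, sd^2) density:
## int f(u) dnorm(u, 0, sd) du  ~=  sum_k w[k] * f(sqrt(2) * sd * x[k]).
gh_rule <- function(n_nodes = 15L) {
  gh <- pracma::gaussHermite(n_nodes)
  list(x = gh$x, w = gh$w / sqrt(pi))
}

## Format numerics at 17 significant digits so that CSV round-trips are
## lossless; non-numeric columns are passed through.
format_17g <- function(df) {
  stopifnot(is.data.frame(df))
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.17g", df[[j]])
    }
  }
  df
}

## Write a data.frame as CSV with lossless float formatting.
write_table_csv <- function(df, path) {
  utils::write.csv(format_17g(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Derive a child seed (< 2^31) from a master seed and a stream label.
child_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629) + 1L
}

## Run an expression with its own RNG stream, restoring the caller's
## .Random.seed afterwards (fitters use fixed internal seeds for jittered
## restarts without disturbing user-level reproducibility).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## Finite-difference Hessian of a scalar function (used for SEs where an
## analytic Hessian is not worth maintaining).
num_hessian <- function(fn, par, eps = 1e-5) {
  p <- length(par)
  H <- matrix(NA_real_, p, p)
  step <- pmax(abs(par), 1) * eps
  f0 <- fn(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      pp <- par; pp[i] <- pp[i] + step[i]; pp[j] <- pp[j] + step[j]
      pm <- par; pm[i] <- pm[i] + step[i]; pm[j] <- pm[j] - step[j]
      mp <- par; mp[i] <- mp[i] - step[i]; mp[j] <- mp[j] + step[j]
      mm <- par; mm[i] <- mm[i] - step[i]; mm[j] <- mm[j] - step[j]
      H[i, j] <- H[j, i] <- (fn(pp) - fn(pm) - fn(mp) + fn(mm)) /
        (4 * step[i] * step[j])
    }
  }
  H
}

## Outer-product-of-gradients (BHHH) covariance: `lli` maps a parameter
## vector to the per-unit log-likelihood contributions. Appropriate for
## piecewise-smooth likelihoods (check-loss kernels) where a
## finite-difference Hessian is unreliable.
opg_covariance <- function(lli, par, eps = 1e-4) {
  p <- length(par)
  n <- length(lli(par))
  G <- matrix(0, n, p)
  for (j in seq_len(p)) {
    tp <- par; tp[j] <- tp[j] + eps
    tm <- par; tm[j] <- tm[j] - eps
    G[, j] <- (lli(tp) - lli(tm)) / (2 * eps)
  }
  tryCatch(solve(crossprod(G)), error = function(e) matrix(NA_real_, p, p))
}

## Standard errors from a negative-log-likelihood Hessian; NA where the
## curvature is not positive definite.
se_from_hessian <- function(H) {
  p <- nrow(H)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, p))
  d <- diag(V)
  ifelse(d > 0, sqrt(d), NA_real_)
}
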