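# Internal numerical helpers shared across modules.

#' Derive a child seed from a base seed and an index
#'
#' Deterministic integer hash used to give every scenario and every
#' replicate its own random stream while keeping the whole study
#' reproducible from a single base seed.  The result always lies in
#' `[1, 2^31 - 2]` so it is a valid argument to [set.seed()].
#'
#' @param base_seed Integer base seed.
#' @param index Non-negative integer index (replicate or scenario number).
#' @return A single integer seed.
#' @export
derive_seed <- function(base_seed, index) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # multiplicative hash; all intermediates stay well below 2^53 so the
  # double arithmetic is exact
  m <- 2147483647            # 2^31 - 1 (prime)
  x <- (abs(base_seed) %% m) * 48271 %% m
  x <- (x + (index + 1) * 69621) %% m
  x <- (x * 16807) %% m
  as.integer(x %% (m - 1) + 1)
}

# log(sum(exp(x))) along rows of a matrix, guarded against overflow
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# phi_k(w) = int_0^1 t^(k-1) exp(w t) dt, k = 1..3, stable near w = 0.
# Shared by the closed-form piecewise-hazard integrals below.
phi1_f <- function(w) {
  r <- expm1(w) / w
  r[w == 0] <- 1
  r
}
phi2_f <- function(w) {
  r <- (w * exp(w) - expm1(w)) / w^2
  s <- abs(w) < 1e-4
  ws <- w[s]
  r[s] <- 1 / 2 + ws / 3 + ws^2 / 8 + ws^3 / 30 + ws^4 / 144
  r
}
phi3_f <- function(w) {
  r <- (exp(w) * (w^2 - 2 * w + 2) - 2) / w^3
  s <- abs(w) < 1e-3
  ws <- w[s]
  r[s] <- 1 / 3 + ws / 4 + ws^2 / 10 + ws^3 / 36 + ws^4 / 168
  r
}

# Sample n draws from N(mu, Sigma) for a 2x2 (or general) PSD Sigma.
# Uses an eigendecomposition so rank-deficient covariances (including the
# zero matrix) are handled without error.
rmvnorm_psd <- function(n, mu, Sigma) {
  d <- length(mu)
  eg <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1)) {
    stop("covariance matrix is not positive semi-definite")
  }
  A <- eg$vectors %*% diag(sqrt(ev), d)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% t(A), 2L, mu, "+")
}

# Closed-form integrals over (lo, hi) used by the piecewise-constant
# hazard: substituting s = lo + t*(hi - lo) gives
#   int exp(c s) ds          = e^{c lo} d phi1(w)
#   int s exp(c s) ds        = e^{c lo} d (lo phi1 + d phi2)
#   int s^2 exp(c s) ds      = e^{c lo} d (lo^2 phi1 + 2 lo d phi2 + d^2 phi3)
# with d = hi - lo and w = c d.  Elementwise; arguments recycle.

int_exp <- function(c_, lo, hi) {
  d <- hi - lo
  exp(c_ * lo) * d * phi1_f(c_ * d)
}

int_s_exp <- function(c_, lo, hi) {
  d <- hi - lo
  w <- c_ * d
  exp(c_ * lo) * d * (lo * phi1_f(w) + d * phi2_f(w))
}

int_s2_exp <- function(c_, lo, hi) {
  d <- hi - lo
  w <- c_ * d
  exp(c_ * lo) * d *
    (lo^2 * phi1_f(w) + 2 * lo * d * phi2_f(w) + d^2 * phi3_f(w))
}

# check a 2x2 matrix is symmetric positive semi-definite
is_psd2 <- function(S, tol = 1e-10) {
  is.matrix(S) && all(dim(S) == 2L) &&
    abs(S[1, 2] - S[2, 1]) <= tol * (1 + max(abs(S))) &&
    S[1, 1] >= -tol && S[2, 2] >= -tol &&
    (S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]) >= -tol * (1 + max(abs(S))^2)
}
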