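#' Simulate a stationary Gaussian process by circulant embedding
#'
#' Exact sampling of a zero-mean stationary Gaussian series from its
#' autocovariance sequence, by embedding the Toeplitz covariance into a
#' circulant matrix diagonalized by the FFT (Davies-Harte construction).
#'
#' @param acov numeric vector of autocovariances at lags `0:(n-1)`.
#' @param clip_negative if `TRUE`, small negative circulant eigenvalues are
#'   clipped to zero (needed for covariances whose minimal embedding is not
#'   quite nonnegative definite, e.g. truncated logarithmic kernels); if
#'   `FALSE` a negative eigenvalue is an error.
#' @return numeric vector of length `length(acov)` drawn from the process.
#' @keywords internal
circulant_gaussian <- function(acov, clip_negative = FALSE) {
  n <- length(acov)
  # first row of the 2(n-1)-circulant embedding
  row <- c(acov, acov[(n - 1):2])
  m <- length(row)
  lambda <- Re(stats::fft(row))
  if (any(lambda < 0)) {
    if (!clip_negative && min(lambda) < -1e-8 * max(lambda)) {
      stop("circulant embedding is not nonnegative definite")
    }
    lambda[lambda < 0] <- 0
  }
  z <- complex(
    real = stats::rnorm(m),
    imaginary = stats::rnorm(m)
  )
  # Re and Im of fft(sqrt(lambda/m) z) are two independent draws with
  # covariance C each (the complex pseudo-covariance vanishes); use Re
  w <- stats::fft(sqrt(lambda / m) * z)
  Re(w)[seq_len(n)]
}

#' Fractional Gaussian noise autocovariance
#' @keywords internal
fgn_acov <- function(n, hurst, sigma2 = 1) {
  k <- 0:(n - 1)
  sigma2 / 2 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
    abs(k - 1)^(2 * hurst))
}

#' Generate fractional Gaussian noise
#'
#' Exact simulation of increments of fractional Brownian motion with Hurst
#' exponent `hurst`, via circulant embedding of the fGn autocovariance.
#'
#' @param n number of samples.
#' @param hurst Hurst exponent, in (0, 1).
#' @param seed optional integer seed (local to this call).
#' @return numeric vector of length `n`, stationary Gaussian increments.
#' @export
generate_fgn <- function(n, hurst, seed = NULL) {
  if (!is.numeric(hurst) || length(hurst) != 1 || hurst <= 0 || hurst >= 1) {
    stop("`hurst` must be a single value in (0, 1)")
  }
  if (n < 2) stop("`n` must be at least 2")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  circulant_gaussian(fgn_acov(n, hurst))
}

#' Generate fractional Brownian motion
#'
#' Self-similar monofractal Gaussian process with Hurst exponent `hurst`;
#' the wavelet-leader scaling exponents of fBm are linear, `zeta(q) = q H`,
#' so it serves as the monofractal reference signal (`c1 = H`, `c2 = 0`).
#'
#' @inheritParams generate_fgn
#' @return numeric vector of length `n` (cumulated fGn, starting near 0).
#' @export
#' @examples
#' x <- generate_fbm(4096, hurst = 0.7, seed = 1)
generate_fbm <- function(n, hurst, seed = NULL) {
  if (n < 2^10) stop("`n` must be at least 2^10 for stable scaling analysis")
  cumsum(generate_fgn(n, hurst, seed = seed))
}

#' Generate a multifractal random walk
#'
#' Multifractal cascade process: fGn(`hurst`) increments modulated by the
#' exponential of an independent stationary Gaussian field `omega` with
#' logarithmic covariance `lambda2 * log(L / (k + 1))` up to the integral
#' scale `L` (taken equal to `n`). Its scaling exponents are quadratic,
#' `zeta(q) = c1 q + c2 q^2 / 2` with second log-cumulant `c2 = -lambda2`;
#' `lambda2 = 0` degenerates to plain fBm. Because the cascade itself tilts
#' the linear exponent by `+lambda2`, the fGn backbone uses exponent
#' `hurst - lambda2` so that the process's first log-cumulant is the
#' requested `hurst`.
#'
#' @inheritParams generate_fgn
#' @param lambda2 intermittency parameter `lambda^2 >= 0`.
#' @return numeric vector of length `n` (the walk, i.e. cumulated modulated
#'   increments).
#' @export
#' @examples
#' x <- generate_mrw(2^13, hurst = 0.7, lambda2 = 0.05, seed = 1)
generate_mrw <- function(n, hurst, lambda2, seed = NULL) {
  if (!is.numeric(lambda2) || length(lambda2) != 1 || lambda2 < 0) {
    stop("`lambda2` must be a single value >= 0")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  if (lambda2 == 0) {
    return(cumsum(circulant_gaussian(fgn_acov(n, hurst))))
  }
  h_eff <- hurst - lambda2
  if (h_eff <= 0) stop("`hurst` must exceed `lambda2` for a valid backbone")
  eps <- circulant_gaussian(fgn_acov(n, h_eff))
  L <- n
  k <- 0:(n - 1)
  acov_w <- lambda2 * log(pmax(L / (k + 1), 1))
  omega <- circulant_gaussian(acov_w, clip_negative = TRUE)
  # scale-independent mean keeps E[exp(omega)] = 1 without tilting zeta(q)
  omega <- omega - lambda2 * log(L) / 2
  cumsum(eps * exp(omega))
}

# RNG bookkeeping: run seeded generators without disturbing the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
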