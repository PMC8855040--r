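#' @useDynLib eegcomplexity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Orthonormal Daubechies scaling filters (sum = sqrt(2)); db2/db3/db4 cover
# 2-4 vanishing moments, enough for polynomial-trend immunity of leaders.
daubechies_filter <- function(wavelet = "db3") {
  filters <- list(
    db2 = c(
      0.482962913144690, 0.836516303737469,
      0.224143868041857, -0.129409522550921
    ),
    db3 = c(
      0.332670552950083, 0.806891509311092, 0.459877502118491,
      -0.135011020010255, -0.085441273882027, 0.035226291885710
    ),
    db4 = c(
      0.230377813308896, 0.714846570552915, 0.630880767929859,
      -0.027983769416860, -0.187034811719093, 0.030841381835561,
      0.032883011666885, -0.010597401785069
    )
  )
  h <- filters[[wavelet]]
  if (is.null(h)) {
    stop("unsupported wavelet '", wavelet, "'; use db2, db3 or db4")
  }
  h
}

#' Discrete wavelet transform (detail coefficients per dyadic scale)
#'
#' Mallat pyramid with a compactly supported Daubechies wavelet. Coefficients
#' are L1-normalized (multiplied by `2^(-j/2)` relative to the orthonormal
#' convention) so that for fractional Brownian motion with Hurst exponent H
#' the leader structure functions scale as `zeta(q) = q H`. Boundary policy:
#' the causal pyramid leaves `NA` at positions whose support is not fully
#' inside the signal; those positions are carried as `NA` and excluded
#' downstream, with surviving counts reported per scale.
#'
#' @param x numeric series.
#' @param wavelet one of `"db2"`, `"db3"` (default), `"db4"`.
#' @param n_levels number of dyadic scales; default `floor(log2(length(x))) - 2`.
#' @param gamint fractional-integration (pseudo-regularization) order: the
#'   scale-`j` coefficients are multiplied by `2^(j * gamint)`, equivalent to
#'   analyzing a fractionally integrated copy of the signal. This shifts the
#'   first log-cumulant by `+gamint` (corrected downstream) and leaves `c2`
#'   untouched; it counters the finite-size downward bias of leader suprema
#'   at low regularity.
#' @return object of class `wavelet_decomposition`: list with `coefficients`
#'   (list over scales `j = 1..n_levels`, `NA` at boundary-contaminated
#'   positions), `wavelet`, `n_levels`, `signal_length`, `gamint`.
#' @export
dwt_leaders_decompose <- function(x, wavelet = "db3", n_levels = NULL,
                                  gamint = 0) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(n_levels)) n_levels <- max(1L, floor(log2(n)) - 2L)
  if (n < 2^(n_levels + 2)) {
    stop("series too short (", n, ") for ", n_levels, " levels")
  }
  h <- daubechies_filter(wavelet)
  g <- rev(h) * (-1)^(seq_along(h) - 1) # quadrature mirror wavelet filter
  approx <- x
  coefficients <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    # causal convolution: first length(h)-1 outputs are NA (boundary)
    d <- as.numeric(stats::filter(approx, g, method = "convolution", sides = 1))
    a <- as.numeric(stats::filter(approx, h, method = "convolution", sides = 1))
    keep <- seq(2, length(d), by = 2)
    # L1 normalization: 2^(-j/2) times the orthonormal-pyramid coefficient;
    # gamint applies the fractional-integration scale weighting
    coefficients[[j]] <- d[keep] * 2^(j * (gamint - 0.5))
    approx <- a[keep]
    if (length(approx) < length(h)) {
      n_levels <- j
      coefficients <- coefficients[seq_len(j)]
      break
    }
  }
  structure(
    list(
      coefficients = coefficients, wavelet = wavelet,
      n_levels = n_levels, signal_length = n, gamint = gamint
    ),
    class = "wavelet_decomposition"
  )
}

#' Wavelet leaders
#'
#' The leader at scale `j`, position `k` is the supremum of absolute wavelet
#' coefficients over all dyadic intervals at scales `<= j` contained in the
#' union of the interval `lambda_{j,k}` and its two same-scale neighbours
#' (the standard 3-neighbourhood). Computed by the usual bottom-up recursion:
#' the within-interval supremum at `(j, k)` is the max of `|d(j,k)|` and the
#' suprema of its two children at scale `j - 1`; the leader then takes the
#' max over the 3-neighbourhood. Positions whose neighbourhood touches a
#' boundary-contaminated coefficient are `NA`.
#'
#' @param decomp a `wavelet_decomposition`.
#' @return object of class `leader_set`: list with `leaders` (list over
#'   scales; `NA` where undefined) and `n_valid` (finite leaders per scale).
#' @export
compute_leaders <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  nj <- decomp$n_levels
  sup_within <- vector("list", nj) # sup over lambda_{j,k} and finer
  leaders <- vector("list", nj)
  for (j in seq_len(nj)) {
    d <- abs(decomp$coefficients[[j]])
    if (j == 1) {
      sup_within[[j]] <- d
    } else {
      child <- sup_within[[j - 1]]
      nk <- length(d)
      left <- child[2 * seq_len(nk) - 1]
      right <- child[2 * seq_len(nk)]
      sup_within[[j]] <- pmax(d, left, right)
    }
    s <- sup_within[[j]]
    nk <- length(s)
    if (nk >= 3) {
      leaders[[j]] <- pmax(s[1:(nk - 2)], s[2:(nk - 1)], s[3:nk])
    } else {
      leaders[[j]] <- rep(NA_real_, 0)
    }
  }
  structure(
    list(
      leaders = leaders,
      n_valid = vapply(leaders, function(v) sum(is.finite(v)), integer(1))
    ),
    class = "leader_set"
  )
}

#' Default regression scale range for leader-based estimates
#'
#' `j1 = 3` up to `j2 = floor(log2(N)) - 3`, shortened if coarse scales keep
#' fewer than `min_count` usable leaders.
#' @keywords internal
default_fit_range <- function(leader_set, signal_length, min_count = 8L) {
  j2_cap <- floor(log2(signal_length)) - 3L
  usable <- which(leader_set$n_valid >= min_count)
  j2 <- min(j2_cap, if (length(usable)) max(usable) else 0L)
  j1 <- 3L
  if (j2 - j1 + 1L < 3L) {
    stop("fewer than 3 usable scales between j=", j1, " and j=", j2)
  }
  c(j1, j2)
}

#' Leader structure functions and scaling exponents
#'
#' `S_L(q, j)` is the mean of `|L(j,k)|^q` over valid leaders at scale `j`;
#' `zeta_L(q)` is the slope of `log2 S_L(q, j)` against `j`, by weighted
#' least squares with weights equal to the per-scale leader counts, over the
#' fitted scale range. The sign convention makes monofractal fBm(H) yield
#' `zeta_L(q) = q H`. `q = 0` is not admitted (the singularity spectrum is
#' defined through an infimum over `q != 0`).
#'
#' @param leader_set a `leader_set`.
#' @param q_grid moments; default symmetric grid `[-5, 5]` step 0.25 without 0.
#' @param fit_range integer `c(j1, j2)`; default [default_fit_range()].
#' @param signal_length original series length (used for the default range;
#'   taken from the decomposition when called through [mf_analyze()]).
#' @return object of class `structure_scaling`: `q_grid`, `S` (q x j matrix),
#'   `zeta`, `fit_range`, `n_j`.
#' @export
structure_functions <- function(leader_set, q_grid = default_q_grid(),
                                fit_range = NULL, signal_length = NULL) {
  stopifnot(inherits(leader_set, "leader_set"))
  if (any(q_grid == 0)) stop("q = 0 is not admitted in the moment grid")
  if (is.null(fit_range)) {
    if (is.null(signal_length)) {
      stop("either `fit_range` or `signal_length` must be given")
    }
    fit_range <- default_fit_range(leader_set, signal_length)
  }
  js <- fit_range[1]:fit_range[2]
  if (length(js) < 3) stop("fewer than 3 scales in fit range")
  if (max(js) > length(leader_set$leaders)) {
    stop("fit range exceeds available scales")
  }
  S <- matrix(NA_real_, nrow = length(q_grid), ncol = length(js),
              dimnames = list(NULL, paste0("j", js)))
  n_j <- integer(length(js))
  for (i in seq_along(js)) {
    L <- leader_set$leaders[[js[i]]]
    L <- L[is.finite(L) & L > 0]
    n_j[i] <- length(L)
    if (length(L) == 0) stop("no usable leaders at scale j=", js[i])
    logL <- log(L)
    S[, i] <- vapply(q_grid, function(q) mean(exp(q * logL)), numeric(1))
  }
  zeta <- apply(log2(S), 1, function(y) {
    stats::lm.wfit(cbind(1, js), y, w = n_j)$coefficients[2]
  })
  structure(
    list(q_grid = q_grid, S = S, zeta = unname(zeta),
         fit_range = fit_range, n_j = n_j),
    class = "structure_scaling"
  )
}

#' @rdname structure_functions
#' @export
default_q_grid <- function() {
  q <- seq(-5, 5, by = 0.25)
  q[q != 0]
}

#' Singularity spectrum by Legendre transform
#'
#' `D(h) = inf over q != 0 of (1 + q h - zeta_L(q))`, evaluated by exact
#' minimization over the discrete moment grid for each Holder exponent `h`.
#' `D(h) <= 1` always; for a monofractal signal the spectrum collapses onto
#' its peak at `h = c1`.
#'
#' @param scaling a `structure_scaling`.
#' @param h_grid Holder exponents at which to evaluate; default 0..1.5 step 0.01.
#' @return object of class `singularity_spectrum`: `h_grid`, `D`, `c1`, `c2`
#'   (`c1` here is the spectrum's argmax; cumulant-based estimates come from
#'   [log_cumulants()]).
#' @export
legendre_spectrum <- function(scaling, h_grid = seq(0, 1.5, by = 0.01)) {
  stopifnot(inherits(scaling, "structure_scaling"))
  ok <- is.finite(scaling$zeta)
  if (!any(ok)) stop("no finite scaling exponents")
  q <- scaling$q_grid[ok]
  zeta <- scaling$zeta[ok]
  D <- vapply(h_grid, function(h) min(1 + q * h - zeta), numeric(1))
  c1_hat <- h_grid[which.max(D)]
  structure(
    list(h_grid = h_grid, D = D, c1 = c1_hat, c2 = NA_real_,
         n_excluded = sum(!ok)),
    class = "singularity_spectrum"
  )
}

#' Log-cumulants c1 and c2 of the singularity spectrum
#'
#' Cumulant-based estimator: the p-th sample cumulant of `log L(j, .)` grows
#' linearly in `j ln 2`, with slope `c_p ln 2`; `c_p` is therefore
#' `log2(e)` times the weighted-least-squares slope of the cumulant against
#' `j` over the fitted scale range. `c1` indexes the overall smoothness of
#' the series (peak location of `D(h)`), the signed `c2 <= 0` its
#' multifractal width; `|c2|` is the feature used in group statistics.
#'
#' @inheritParams structure_functions
#' @return list with `c1`, `c2` (signed), `abs_c2`, `fit_range`, `n_j`.
#' @export
log_cumulants <- function(leader_set, fit_range = NULL, signal_length = NULL) {
  stopifnot(inherits(leader_set, "leader_set"))
  if (is.null(fit_range)) {
    if (is.null(signal_length)) {
      stop("either `fit_range` or `signal_length` must be given")
    }
    fit_range <- default_fit_range(leader_set, signal_length)
  }
  js <- fit_range[1]:fit_range[2]
  C1 <- C2 <- numeric(length(js))
  n_j <- integer(length(js))
  for (i in seq_along(js)) {
    L <- leader_set$leaders[[js[i]]]
    L <- L[is.finite(L) & L > 0]
    n_j[i] <- length(L)
    if (length(L) < 3) stop("too few leaders at scale j=", js[i])
    logL <- log(L)
    C1[i] <- mean(logL)
    v <- stats::var(logL)
    if (!is.finite(v) || v == 0) stop("degenerate leaders at scale j=", js[i])
    C2[i] <- v
  }
  slope <- function(y) stats::lm.wfit(cbind(1, js), y, w = n_j)$coefficients[2]
  list(
    c1 = unname(log2(exp(1)) * slope(C1)),
    c2 = unname(log2(exp(1)) * slope(C2)),
    abs_c2 = abs(unname(log2(exp(1)) * slope(C2))),
    fit_range = fit_range, n_j = n_j
  )
}

#' Full wavelet-leader multifractal analysis of one series
#'
#' Convenience wrapper: decompose, take leaders, estimate scaling exponents,
#' singularity spectrum and log-cumulants.
#'
#' @inheritParams dwt_leaders_decompose
#' @param q_grid moment grid (see [structure_functions()]).
#' @param fit_range optional `c(j1, j2)` scale range.
#' @param h_grid Holder grid for the spectrum dump.
#' @return list with `c1`, `c2`, `abs_c2`, `spectrum` (a
#'   `singularity_spectrum`), `scaling` (a `structure_scaling`; exponents on
#'   the fractionally integrated scale when `gamint > 0`).
#' @export
#' @examples
#' x <- generate_fbm(2^13, hurst = 0.7, seed = 2)
#' fit <- mf_analyze(x)
#' c(fit$c1, fit$c2)
mf_analyze <- function(x, wavelet = "db3", q_grid = default_q_grid(),
                       fit_range = NULL, h_grid = seq(0, 1.5, by = 0.01),
                       gamint = 0.5) {
  decomp <- dwt_leaders_decompose(x, wavelet = wavelet, gamint = gamint)
  leaders <- compute_leaders(decomp)
  if (is.null(fit_range)) {
    fit_range <- default_fit_range(leaders, decomp$signal_length)
  }
  scaling <- structure_functions(leaders, q_grid, fit_range = fit_range)
  # spectrum of the original signal: evaluate on the integrated scale, then
  # label by h = h_integrated - gamint
  spec <- legendre_spectrum(scaling, h_grid + gamint)
  spec$h_grid <- h_grid
  spec$c1 <- spec$c1 - gamint
  cum <- log_cumulants(leaders, fit_range = fit_range)
  cum$c1 <- cum$c1 - gamint
  spec$c2 <- cum$c2
  list(
    c1 = cum$c1, c2 = cum$c2, abs_c2 = cum$abs_c2,
    spectrum = spec, scaling = scaling, fit_range = fit_range,
    gamint = gamint
  )
}
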