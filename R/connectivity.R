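#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real numeric series.
#' @return complex vector `x + i * H(x)`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude of a band-limited series
#'
#' Hilbert analytic signal; phase wrapped to (-pi, pi]. A fraction of
#' samples at each end (`edge_fraction`, default 5%) is flagged as edge
#' region, where the analytic signal is distorted by the transform's
#' circularity, and excluded from phase-lag sums.
#'
#' @param x numeric band-limited series (one channel).
#' @param edge_fraction fraction of samples flagged at each end.
#' @return object of class `phase_series`: `phase`, `amplitude`, `keep`
#'   (logical mask of non-edge samples).
#' @export
instantaneous_phase <- function(x, edge_fraction = 0.05) {
  x <- as.numeric(x)
  if (all(x == 0)) stop("cannot extract phase from an all-zero series")
  z <- analytic_signal(x)
  n <- length(x)
  n_edge <- floor(edge_fraction * n)
  keep <- rep(TRUE, n)
  if (n_edge > 0) {
    keep[seq_len(n_edge)] <- FALSE
    keep[(n - n_edge + 1):n] <- FALSE
  }
  phase <- Arg(z) # already in (-pi, pi]
  structure(
    list(phase = phase, amplitude = Mod(z), keep = keep),
    class = "phase_series"
  )
}

# wrap angles into (-pi, pi]
wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Phase lag index between two phase series
#'
#' `|mean(sign(dphi))|` over retained (non-edge) samples, with the phase
#' difference wrapped to (-pi, pi] and `sign(0) = 0`. Zero-lag coupling
#' (identical or volume-conducted sources, and exact pi lags from dipole
#' geometry) yields 0; a consistent nonzero lag yields values up to 1.
#'
#' @param pa,pb `phase_series` of equal length for the same band.
#' @return scalar in `[0, 1]`.
#' @export
pli_pair <- function(pa, pb) {
  stopifnot(inherits(pa, "phase_series"), inherits(pb, "phase_series"))
  if (length(pa$phase) != length(pb$phase)) {
    stop("phase series lengths differ (", length(pa$phase), " vs ",
         length(pb$phase), ")")
  }
  keep <- pa$keep & pb$keep
  dphi <- wrap_phase(pa$phase[keep] - pb$phase[keep])
  s <- sign(dphi)
  # exactly-zero-lag samples contribute nothing; treat float-level phase
  # residue (e.g. from filtering amplitude-scaled copies) as zero lag
  s[abs(dphi) < 1e-8] <- 0
  abs(mean(s))
}

#' Band-wise PLI matrices averaged over connectivity epochs
#'
#' For each band: band-filter each 5-s epoch, extract Hilbert phases, compute
#' the pairwise PLI within each epoch, and average the 10 per-epoch matrices.
#'
#' @param epochs list of `"pli"` `analysis_epoch` objects from
#'   [segment_for_pli()].
#' @param bands data.frame as from [eeg_bands()]; may be a subset of rows.
#' @return object of class `pli_matrix`: `values` (named list of symmetric
#'   channel x channel matrices with zero diagonal, one per band),
#'   `n_epochs_averaged`, `T` (samples per epoch).
#' @export
pli_matrix <- function(epochs, bands = eeg_bands()) {
  if (length(epochs) == 0) stop("no epochs supplied")
  ok <- vapply(epochs, function(e) inherits(e, "analysis_epoch"), logical(1))
  if (!all(ok)) stop("epochs ", paste(which(!ok), collapse = ", "),
                     " are not analysis_epoch objects")
  n_ch <- nrow(epochs[[1]]$samples)
  labels <- rownames(epochs[[1]]$samples)
  values <- vector("list", nrow(bands))
  names(values) <- bands$name
  for (b in seq_len(nrow(bands))) {
    acc <- matrix(0, n_ch, n_ch)
    for (e in epochs) {
      be <- bandpass(e, bands$low[b], bands$high[b])
      phases <- lapply(seq_len(n_ch), function(ch) {
        instantaneous_phase(be$samples[ch, ])
      })
      for (i in seq_len(n_ch - 1)) {
        for (j in (i + 1):n_ch) {
          p <- pli_pair(phases[[i]], phases[[j]])
          acc[i, j] <- acc[i, j] + p
          acc[j, i] <- acc[j, i] + p
        }
      }
    }
    m <- acc / length(epochs)
    dimnames(m) <- list(labels, labels)
    values[[b]] <- m
  }
  structure(
    list(values = values, n_epochs_averaged = length(epochs),
         T = ncol(epochs[[1]]$samples)),
    class = "pli_matrix"
  )
}

#' Node strength from a PLI matrix
#'
#' Mean PLI of each electrode to the other `K - 1` electrodes, per band.
#'
#' @param m a `pli_matrix` (or a single symmetric matrix).
#' @return for a `pli_matrix`, a band x channel matrix; for a bare matrix, a
#'   named vector.
#' @export
node_strength <- function(m) {
  ns_one <- function(mat) {
    K <- nrow(mat)
    if (K < 2) stop("need at least 2 channels")
    (rowSums(mat) - diag(mat)) / (K - 1)
  }
  if (inherits(m, "pli_matrix")) {
    out <- t(vapply(m$values, ns_one, numeric(nrow(m$values[[1]]))))
    rownames(out) <- names(m$values)
    out
  } else {
    ns_one(as.matrix(m))
  }
}
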