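#' Multiscale-entropy parameters
#'
#' Container for the sample-entropy settings: embedding dimension `m = 2`,
#' tolerance `r = 0.2` (as a fraction of the SD of the scale-1 standardized
#' series, held fixed across scales), and maximum coarse-graining scale 30.
#'
#' @param m embedding dimension (>= 1).
#' @param r tolerance, fraction of SD (> 0).
#' @param max_scale largest coarse-graining factor (>= 1).
#' @return list of class `mse_params`.
#' @export
mse_params <- function(m = 2L, r = 0.2, max_scale = 30L) {
  stopifnot(m >= 1, r > 0, max_scale >= 1)
  structure(list(m = as.integer(m), r = r, max_scale = as.integer(max_scale)),
            class = "mse_params")
}

#' Coarse-grain a series by non-overlapping block means
#'
#' Scale-`tau` coarse-graining: consecutive non-overlapping blocks of `tau`
#' samples are averaged; a trailing partial block is dropped.
#'
#' @param x numeric series.
#' @param tau integer scale factor >= 1.
#' @return numeric vector of length `floor(length(x) / tau)`.
#' @export
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5, 6), 2) # 1.5 3.5 5.5
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1) stop("`tau` must be >= 1")
  n <- length(x)
  if (tau > n) stop("`tau` (", tau, ") exceeds series length (", n, ")")
  if (tau == 1L) return(as.numeric(x))
  nb <- n %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `-ln(A / B)` where `B` counts pairs of `m`-length templates within
#' Chebyshev distance `< r` (self-matches excluded, each unordered pair
#' counted once) and `A` counts those still matching when extended to length
#' `m + 1`. Returns `NA` with attribute `undefined = TRUE` when either count
#' is zero (no matches), never `Inf`.
#'
#' @param x numeric series (expected standardized; see [mse_curve()]).
#' @param params an [mse_params()] object (only `m` and `r` are used).
#' @return scalar entropy (nats), or flagged `NA` if undefined.
#' @export
sample_entropy <- function(x, params = mse_params()) {
  x <- as.numeric(x)
  if (length(x) < params$m + 2) {
    stop("series length ", length(x), " too short for m = ", params$m)
  }
  cnt <- sampen_counts(x, params$m, params$r)
  if (cnt$A == 0 || cnt$B == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  -log(cnt$A / cnt$B)
}

#' Multiscale entropy profile of a multichannel epoch
#'
#' Each channel is z-scored once, then sample entropy is computed on the
#' coarse-grained series at scales `1..max_scale` with the tolerance fixed at
#' `r` times the SD of the scale-1 standardized series (i.e. `r` itself), so
#' the entropy decrease across scales reflects loss of fast variance, not a
#' moving tolerance.
#'
#' @param epoch an `analysis_epoch` (see [trim_select()]) or a channels x
#'   time numeric matrix.
#' @param params an [mse_params()].
#' @param sampling_rate Hz; taken from the epoch when available.
#' @return object of class `mse_profile`: `entropy` (channels x scales
#'   matrix), `scales_seconds`, `params`, `n_undefined`.
#' @export
mse_curve <- function(epoch, params = mse_params(), sampling_rate = NULL) {
  if (inherits(epoch, "analysis_epoch")) {
    samples <- epoch$samples
    if (is.null(sampling_rate)) sampling_rate <- epoch$sampling_rate
  } else {
    samples <- as.matrix(epoch)
  }
  if (is.null(sampling_rate)) stop("`sampling_rate` required for scale timing")
  n_ch <- nrow(samples)
  scales <- seq_len(params$max_scale)
  entropy <- matrix(NA_real_, nrow = n_ch, ncol = length(scales),
                    dimnames = list(rownames(samples), paste0("scale", scales)))
  n_undefined <- 0L
  for (ch in seq_len(n_ch)) {
    z <- zscore(samples[ch, ])
    for (tau in scales) {
      cg <- coarse_grain(z, tau)
      h <- tryCatch(sample_entropy(cg, params), error = function(e) {
        stop("sample entropy failed at channel ", ch, ", scale ", tau, ": ",
             conditionMessage(e))
      })
      if (is.na(h)) n_undefined <- n_undefined + 1L
      entropy[ch, tau] <- h
    }
  }
  structure(
    list(entropy = entropy,
         scales_seconds = scales / sampling_rate,
         params = params, n_undefined = n_undefined),
    class = "mse_profile"
  )
}

#' Mean sample entropy over the fast scales
#'
#' Per-channel arithmetic mean of the entropy at coarse-graining scales
#' `scale_lo..scale_hi` (defaults 1-5, i.e. 0.005-0.025 s at 200 Hz), the
#' temporal region where aging elevates entropy; this average is the
#' entropy feature used for classification.
#'
#' @param profile an `mse_profile`.
#' @param scale_lo,scale_hi inclusive scale range.
#' @return named numeric vector, one value per channel (`NA` if any entropy
#'   inside the range is undefined for that channel).
#' @export
fast_scale_mean <- function(profile, scale_lo = 1L, scale_hi = 5L) {
  stopifnot(inherits(profile, "mse_profile"))
  if (scale_hi > ncol(profile$entropy)) {
    stop("profile only covers scales up to ", ncol(profile$entropy))
  }
  rowMeans(profile$entropy[, scale_lo:scale_hi, drop = FALSE])
}
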