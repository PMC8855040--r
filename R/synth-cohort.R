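#' Specification of a synthetic two-group EEG cohort
#'
#' Defaults emulate the study conditions the pipeline targets: 32 younger and
#' 18 older subjects, 16 channels at 200 Hz for 60 s. Group contrasts follow
#' the directions reported for aging: the older group has lower
#' self-similarity (H 0.70 vs 0.80, driving lower c1), lower intermittency
#' (lambda^2 0.03 vs 0.08, driving lower |c2|), and 1.5x the fast Gaussian
#' noise gain (driving higher fast-scale sample entropy). Effect magnitudes
#' are not calibrated to the study (no quantitative effect sizes are
#' available), only signs.
#'
#' @param n_young,n_old group sizes (>= 2 each).
#' @param n_channels number of channels (16 uses the standard montage).
#' @param sampling_rate Hz.
#' @param duration seconds per subject; `duration * sampling_rate` must be at
#'   least 12,000 samples so the 60-s trim arithmetic is possible.
#' @param hurst_by_group named list `younger`/`older`, Hurst H in (0, 1).
#' @param intermittency_by_group named list, lambda^2 >= 0.
#' @param fast_noise_gain_by_group named list, noise SD relative to the
#'   unit-SD multifractal backbone. The noise is high-passed above
#'   `fast_noise_cutoff` so it raises fast-scale (1-5) sample entropy
#'   without touching the coarser scales where c1 and c2 are estimated.
#' @param fast_noise_cutoff high-pass edge (Hz) of the fast noise.
#' @param coupling_edges list of lists with fields `a`, `b` (channel labels),
#'   `band` (name in [eeg_bands()]), `lag` (radians), `strength` in [0, 1]:
#'   the two channels share a narrowband drifting-phase oscillation with a
#'   constant phase offset `lag`.
#' @param common_source_gain gain in [0, 1] of a broadband source mixed into
#'   every channel at zero lag (emulated volume conduction; the phase-lag
#'   index is blind to it by construction).
#' @param osc_amplitude amplitude of each channel's independent alpha-band
#'   oscillation (kept small so narrowband phases decorrelate within epochs).
#' @param phase_jitter_sd per-sample SD (radians) of the random-walk phase
#'   drift of the oscillatory components; pure sinusoids would make PLI
#'   saturate at 1 regardless of coupling strength.
#' @param seed integer seed making the cohort reproducible.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_young = 32L, n_old = 18L, n_channels = 16L,
                       sampling_rate = 200, duration = 60,
                       hurst_by_group = list(younger = 0.80, older = 0.70),
                       intermittency_by_group = list(younger = 0.08, older = 0.03),
                       fast_noise_gain_by_group = list(younger = 0.2, older = 0.3),
                       fast_noise_cutoff = 30,
                       coupling_edges = default_coupling_edges(),
                       common_source_gain = 0.05,
                       osc_amplitude = 0.15,
                       phase_jitter_sd = 0.3,
                       seed = 1L) {
  if (n_young < 2 || n_old < 2) stop("need at least 2 subjects per group")
  if (duration * sampling_rate < 12000) {
    stop("duration x sampling_rate must be >= 12,000 samples ",
         "(60 s at 200 Hz) for the trimming arithmetic")
  }
  for (g in c("younger", "older")) {
    H <- hurst_by_group[[g]]
    if (is.null(H) || H <= 0 || H >= 1) stop("hurst for '", g, "' must be in (0,1)")
    l2 <- intermittency_by_group[[g]]
    if (is.null(l2) || l2 < 0) stop("intermittency for '", g, "' must be >= 0")
    if (fast_noise_gain_by_group[[g]] < 0) stop("noise gain must be >= 0")
  }
  if (common_source_gain < 0 || common_source_gain > 1) {
    stop("common_source_gain must be in [0, 1]")
  }
  for (e in coupling_edges) {
    if (e$strength < 0 || e$strength > 1) stop("coupling strength must be in [0, 1]")
  }
  structure(
    list(n_young = as.integer(n_young), n_old = as.integer(n_old),
         n_channels = as.integer(n_channels),
         sampling_rate = sampling_rate, duration = duration,
         hurst_by_group = hurst_by_group,
         intermittency_by_group = intermittency_by_group,
         fast_noise_gain_by_group = fast_noise_gain_by_group,
         fast_noise_cutoff = fast_noise_cutoff,
         coupling_edges = coupling_edges,
         common_source_gain = common_source_gain,
         osc_amplitude = osc_amplitude,
         phase_jitter_sd = phase_jitter_sd,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' @rdname synth_spec
#' @export
default_coupling_edges <- function() {
  list(
    list(a = "C3", b = "C4", band = "alpha", lag = pi / 4, strength = 0.8),
    list(a = "O1", b = "O2", band = "alpha", lag = pi / 4, strength = 0.6),
    list(a = "F3", b = "F4", band = "theta", lag = pi / 3, strength = 0.5)
  )
}

# drifting-phase narrowband oscillation: returns the phase track so coupled
# channels can share it with a constant offset
drifting_phase <- function(n, freq, sampling_rate, jitter_sd) {
  2 * pi * freq * seq_len(n) / sampling_rate +
    stats::runif(1, 0, 2 * pi) +
    cumsum(stats::rnorm(n, 0, jitter_sd))
}

#' Generate a synthetic cohort of recordings
#'
#' Each channel is built as: z-scored multifractal-random-walk backbone with
#' the group's H and lambda^2, plus group-scaled fast white Gaussian noise,
#' plus a small independent alpha-band drifting-phase oscillation, plus any
#' coupling-edge components (shared narrowband oscillation, constant phase
#' lag, amplitude `2 * strength`), plus the zero-lag broadband common
#' source. Deterministic given `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return list of `eeg_recording` objects (younger first, then older), with
#'   attribute `manifest` (data.frame subject_id, group, seed).
#' @export
#' @examples
#' cohort <- generate_cohort(synth_spec(n_young = 3, n_old = 2))
#' length(cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old_rng <- get_rng_state()
  on.exit(restore_rng_state(old_rng))
  set.seed(spec$seed)

  n <- round(spec$duration * spec$sampling_rate)
  n_gen <- 2^ceiling(log2(n)) # power-of-2 generation length, then truncate
  labels <- if (spec$n_channels == 16) montage_16() else
    paste0("ch", seq_len(spec$n_channels))
  bands <- eeg_bands()
  groups <- c(rep("younger", spec$n_young), rep("older", spec$n_old))
  ids <- sprintf("S%03d", seq_along(groups))

  hp_filter <- signal::butter(4, spec$fast_noise_cutoff /
                                   (spec$sampling_rate / 2), type = "high")
  cohort <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    g <- groups[s]
    H <- spec$hurst_by_group[[g]]
    l2 <- spec$intermittency_by_group[[g]]
    sig <- spec$fast_noise_gain_by_group[[g]]

    common <- stats::rnorm(n)

    # shared coupling oscillations, one phase track per edge
    edge_phase <- lapply(spec$coupling_edges, function(e) {
      f0 <- mean(unlist(bands[bands$name == e$band, c("low", "high")]))
      drifting_phase(n, f0, spec$sampling_rate, spec$phase_jitter_sd)
    })

    samples <- matrix(0, nrow = spec$n_channels, ncol = n)
    f_alpha <- mean(unlist(bands[bands$name == "alpha", c("low", "high")]))
    for (ch in seq_len(spec$n_channels)) {
      backbone <- generate_mrw(n_gen, H, l2)[seq_len(n)]
      # keep the fractal backbone inside the analysis band: the sub-2-Hz
      # random-walk drift would otherwise carry nearly all its variance and
      # the group-dependent scaling would vanish after broadband filtering
      backbone <- bandpass(matrix(backbone, 1), 2, 60,
                           sampling_rate = spec$sampling_rate)[1, ]
      # standardize to unit power over the scaling-analysis octaves
      # (fs/32 .. fs/8 Hz, dyadic scales 3-5) so both groups present equal
      # amplitude at the fitted scales and additive components perturb each
      # group's spectral slope symmetrically
      win <- bandpass(matrix(backbone, 1), spec$sampling_rate / 32,
                      spec$sampling_rate / 8,
                      sampling_rate = spec$sampling_rate)[1, ]
      backbone <- backbone / stats::sd(win)
      fast_noise <- signal::filtfilt(hp_filter, stats::rnorm(n))
      x <- backbone + sig * fast_noise
      x <- x + spec$osc_amplitude *
        sin(drifting_phase(n, f_alpha, spec$sampling_rate,
                           spec$phase_jitter_sd))
      for (ei in seq_along(spec$coupling_edges)) {
        e <- spec$coupling_edges[[ei]]
        amp <- 2 * e$strength
        if (labels[ch] == e$a) {
          x <- x + amp * sin(edge_phase[[ei]])
        } else if (labels[ch] == e$b) {
          x <- x + amp * sin(edge_phase[[ei]] - e$lag)
        }
      }
      # zero-lag mixing fraction: the common source is scaled to the
      # channel's own amplitude so `common_source_gain` is a true fraction
      mix <- spec$common_source_gain
      samples[ch, ] <- (1 - mix) * x + mix * stats::sd(x) * common
    }
    cohort[[s]] <- new_recording(samples, spec$sampling_rate, labels,
                                 group = g, subject_id = ids[s])
  }
  attr(cohort, "manifest") <- data.frame(
    subject_id = ids, group = groups, seed = spec$seed,
    stringsAsFactors = FALSE
  )
  cohort
}

#' Write / read a recording as a plain CSV matrix
#'
#' Dialect: rows are samples, columns are channels, header row of channel
#' labels; sampling rate and metadata travel in a sidecar comment-free
#' manifest (see [write_cohort_csv()]) or must be supplied on read.
#'
#' @param recording an `eeg_recording`.
#' @param path output file.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  utils::write.csv(
    as.data.frame(t(recording$samples)),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sampling_rate Hz of the stored data.
#' @param group,subject_id metadata to attach.
#' @export
read_recording_csv <- function(path, sampling_rate,
                               group = NA_character_, subject_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(subject_id)) subject_id <- sub("\\.csv$", "", basename(path))
  new_recording(t(as.matrix(df)), sampling_rate,
                channel_labels = colnames(df),
                group = group, subject_id = subject_id)
}

#' Write a cohort to disk
#'
#' One file per subject (`<subject_id>.csv` or `.edf`) plus `manifest.csv`
#' with columns subject_id, group, seed, sampling_rate.
#'
#' @param cohort list of recordings from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` (plain matrix dialect) or `"edf"`.
#' @return the directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort) {
    f <- file.path(dir, paste0(rec$subject_id, ".", format))
    if (format == "csv") write_recording_csv(rec, f) else write_edf(rec, f)
  }
  manifest <- attr(cohort, "manifest")
  if (is.null(manifest)) {
    manifest <- data.frame(
      subject_id = vapply(cohort, `[[`, "", "subject_id"),
      group = vapply(cohort, `[[`, "", "group"),
      seed = NA_integer_
    )
  }
  manifest$sampling_rate <- vapply(cohort, `[[`, 0, "sampling_rate")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort_csv()]
#'
#' @param dir directory containing `manifest.csv` and per-subject files.
#' @return list of `eeg_recording` with manifest attribute.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    base <- file.path(dir, manifest$subject_id[i])
    if (file.exists(paste0(base, ".csv"))) {
      read_recording_csv(paste0(base, ".csv"), manifest$sampling_rate[i],
                         group = manifest$group[i],
                         subject_id = manifest$subject_id[i])
    } else if (file.exists(paste0(base, ".edf"))) {
      rec <- read_edf(paste0(base, ".edf"))
      rec$group <- manifest$group[i]
      rec$subject_id <- manifest$subject_id[i]
      rec
    } else {
      stop("no data file for subject ", manifest$subject_id[i])
    }
  })
  attr(cohort, "manifest") <- manifest
  cohort
}
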