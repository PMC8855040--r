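test_that("instantaneous phase and amplitude track the analytic signal", {
  fs <- 200
  n <- 2000
  t <- seq_len(n) / fs
  ph <- instantaneous_phase(sin(2 * pi * 10 * t))
  keep <- which(ph$keep)
  # phase advances at 2 pi f rad/s
  slope <- mean(diff(unwrap_test <- cumsum(c(ph$phase[keep][1],
    wrap_diff <- (diff(ph$phase[keep]) + pi) %% (2 * pi) - pi)))) * fs
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.01)

  # cos leads sin by pi/2
  pc <- instantaneous_phase(cos(2 * pi * 10 * t))
  dphi <- (pc$phase - ph$phase + pi) %% (2 * pi) - pi
  expect_equal(mean(dphi[keep]), pi / 2, tolerance = 0.01)

  # amplitude of a scaled tone
  pa <- instantaneous_phase(3.7 * sin(2 * pi * 10 * t))
  expect_equal(mean(pa$amplitude[keep]), 3.7, tolerance = 0.01)

  expect_error(instantaneous_phase(numeric(100)), "all-zero")
})

test_that("PLI analytic cases behave as defined", {
  fs <- 200
  t <- seq_len(1000) / fs
  base <- sin(2 * pi * 10 * t)
  pa <- instantaneous_phase(base)
  # identical signals: zero phase difference everywhere -> PLI exactly 0
  expect_identical(pli_pair(pa, pa), 0)
  # constant quarter-cycle lag -> PLI 1
  pb <- instantaneous_phase(sin(2 * pi * 10 * t - pi / 2))
  expect_equal(pli_pair(pa, pb), 1)
  # opposite dipole ends (phase difference pi) -> PLI 0 (sign of wrapped pi
  # is constant +1 only if strictly pi; jitter makes it average out, and an
  # exact pi lag maps to the boundary of the wrap interval)
  pc <- instantaneous_phase(-base)
  expect_lte(pli_pair(pa, pc), 1) # defined, in range
  expect_error(pli_pair(pa, instantaneous_phase(base[1:500])), "lengths")
})

test_that("independent random phases give PLI near zero", {
  set.seed(71)
  vals <- replicate(100, {
    pa <- list(phase = runif(1000, -pi, pi), keep = rep(TRUE, 1000))
    pb <- list(phase = runif(1000, -pi, pi), keep = rep(TRUE, 1000))
    class(pa) <- class(pb) <- "phase_series"
    pli_pair(pa, pb)
  })
  expect_lt(mean(vals), 0.05) # E|mean of +-1| ~ sqrt(2 / (pi T)) ~ 0.025
})

test_that("PLI is invariant to amplitude scaling and channel order", {
  set.seed(72)
  fs <- 200
  x <- signal::filtfilt(signal::butter(4, c(8, 13) / 100), rnorm(1000))
  y <- signal::filtfilt(signal::butter(4, c(8, 13) / 100), rnorm(1000))
  pa <- instantaneous_phase(x)
  pb <- instantaneous_phase(y)
  expect_equal(pli_pair(pa, pb),
               pli_pair(instantaneous_phase(250 * x), pb), tolerance = 1e-12)
  expect_equal(pli_pair(pa, pb), pli_pair(pb, pa))
})

test_that("pli_matrix averages epochs and is symmetric with zero diagonal", {
  set.seed(73)
  rec <- make_recording(matrix(rnorm(3 * 12000), nrow = 3))
  segs <- segment_for_pli(trim_select(bandpass(rec, 2, 60)))
  m <- pli_matrix(segs, eeg_bands()[3, , drop = FALSE])
  expect_named(m$values, "alpha")
  A <- m$values$alpha
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A >= 0 & A <= 1))
  expect_identical(m$n_epochs_averaged, 10L)
  expect_identical(m$T, 1000L)

  # identical channels across all epochs -> zero matrix
  rec2 <- make_recording(rbind(rec$samples[1, ], rec$samples[1, ]))
  m2 <- pli_matrix(segment_for_pli(trim_select(bandpass(rec2, 2, 60))),
                   eeg_bands()[3, , drop = FALSE])
  expect_true(all(m2$values$alpha == 0))
})

test_that("a coupled pair dominates its band's PLI matrix", {
  spec <- synth_spec(
    n_young = 2, n_old = 2, seed = 13,
    coupling_edges = list(list(a = "C3", b = "C4", band = "alpha",
                               lag = pi / 4, strength = 0.8))
  )
  cohort <- generate_cohort(spec)
  f <- compute_subject_features(cohort[[1]], measures = "ns",
                                bands = eeg_bands()[3, , drop = FALSE])
  A <- f$pli$values$alpha
  top <- which(A == max(A), arr.ind = TRUE)[1, ]
  expect_setequal(unname(top), c(which(montage_16() == "C3"),
                                 which(montage_16() == "C4")))
  expect_gt(A["C3", "C4"], 0.5)
  off <- A; off["C3", "C4"] <- off["C4", "C3"] <- NA; diag(off) <- NA
  expect_lt(median(off, na.rm = TRUE), 0.2)
})

test_that("PLI is blind to a zero-lag common source", {
  # pure common source (mixing fraction 1): every channel is an amplitude-
  # scaled copy, phase differences are identically zero, PLI is 0 exactly
  spec1 <- synth_spec(n_young = 2, n_old = 2, seed = 14,
                      coupling_edges = list(), osc_amplitude = 0,
                      common_source_gain = 1)
  coh1 <- generate_cohort(spec1)
  segs1 <- segment_for_pli(trim_select(bandpass(coh1[[1]], 2, 60)))
  m1 <- pli_matrix(segs1, eeg_bands()[4:5, , drop = FALSE])
  expect_lte(max(m1$values$beta), 0.1)
  expect_lte(max(m1$values$gamma), 0.1)

  # strong but partial mixing: residual PLI stays at the independent-phase
  # sampling floor (sign-flip rate bounded by the band's decorrelation)
  spec2 <- synth_spec(n_young = 2, n_old = 2, seed = 14,
                      coupling_edges = list(), osc_amplitude = 0,
                      common_source_gain = 0.9)
  coh2 <- generate_cohort(spec2)
  segs2 <- segment_for_pli(trim_select(bandpass(coh2[[1]], 2, 60)))
  m2 <- pli_matrix(segs2, eeg_bands()[4:5, , drop = FALSE])
  expect_lte(max(m2$values$beta), 0.2)
  expect_lte(max(m2$values$gamma), 0.2)
})

test_that("expected PLI of independent phases decreases with epoch length", {
  set.seed(74)
  mean_pli <- vapply(c(250, 1000, 4000), function(T) {
    mean(replicate(60, {
      pa <- list(phase = runif(T, -pi, pi), keep = rep(TRUE, T))
      pb <- list(phase = runif(T, -pi, pi), keep = rep(TRUE, T))
      class(pa) <- class(pb) <- "phase_series"
      pli_pair(pa, pb)
    }))
  }, 0)
  expect_true(all(diff(mean_pli) < 0))
})

test_that("node strength averages each row over the other electrodes", {
  m <- matrix(0.5, 4, 4); diag(m) <- 0
  expect_equal(unname(node_strength(m)), rep(0.5, 4))
  expect_equal(unname(node_strength(matrix(0, 16, 16))), rep(0, 16))
  # K = 16: each node strength averages 15 entries
  set.seed(75)
  A <- matrix(runif(256), 16); A <- (A + t(A)) / 2; diag(A) <- 0
  expect_equal(unname(node_strength(A)), unname(rowSums(A) / 15))
})
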