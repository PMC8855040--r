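# Shared fixtures built in code.

# multichannel recording holding given channel signals (rows)
make_recording <- function(samples, fs = 200, group = NA_character_,
                           id = "test") {
  samples <- as.matrix(samples)
  new_recording(samples, fs,
                channel_labels = montage_16()[seq_len(nrow(samples))],
                group = group, subject_id = id)
}

sine_wave <- function(freq, n = 12000, fs = 200, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * seq_len(n) / fs + phase)
}

# naive O(N^2) sample-entropy oracle mirroring the definition directly
sampen_naive <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1
      }
    }
  }
  list(A = A, B = B, h = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# brute-force wavelet leader: exhaustive sup of |coefficients| over all
# dyadic intervals at scales <= j contained in the 3-neighbourhood of
# (j, k) (1-based k), mirroring the interval-inclusion definition
leaders_bruteforce <- function(coefficients, j, k) {
  vals <- c()
  for (kk in (k - 1):(k + 1)) {
    if (kk < 1 || kk > length(coefficients[[j]])) return(NA_real_)
    # interval at (j, kk) contains intervals (jp, m) with
    # m in [(kk-1)*2^(j-jp)+1, kk*2^(j-jp)]
    for (jp in 1:j) {
      span <- 2^(j - jp)
      ms <- ((kk - 1) * span + 1):(kk * span)
      if (max(ms) > length(coefficients[[jp]])) return(NA_real_)
      vals <- c(vals, abs(coefficients[[jp]][ms]))
    }
  }
  max(vals)
}

# BH step-up oracle straight from the definition
bh_stepup_oracle <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= (seq_len(n) / n) * q)
  sig <- rep(FALSE, n)
  if (length(k) > 0) sig[ord[seq_len(max(k))]] <- TRUE
  sig
}
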