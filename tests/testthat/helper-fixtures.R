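# Small fixtures built in code. Tests that exercise behaviour (not the
# stated world) run on short, low-rate recordings for speed; the acceptance
# suite is where full-scale settings live.

# A compressed five-phase protocol: same roles as the default, 4 s phases.
tiny_protocol <- function(phase_s = 4) default_protocol(phase_s = phase_s)

# Config that skips the start-up trim and pins a small kernel so short
# fixtures behave predictably.
tiny_config <- function(kernel = 5L, methods = c("ED-PCA", "MD", "CVID", "ED-KPCA"),
                        downsample_hz = 1, ...) {
  rsi_config(preprocess = preprocess_config(trim_seconds = 0, kernel_override = kernel,
                                            downsample_hz = downsample_hz),
             methods = methods, ...)
}

# Deterministic five-channel recording with phase-mean structure.
tiny_recording <- function(seed = 1L, fs = 32, protocol = tiny_protocol(),
                           rho = 0.7, shift_scale = 1, noise = NULL, ...) {
  args <- list(rho = rho, shift_scale = shift_scale, seed = seed,
               spike_rate = 0, ...)
  if (!is.null(noise)) args$noise_sd <- noise
  sp <- do.call(subject_spec, args)
  simulate_subject(sp, protocol, fs = fs, subject_id = paste0("T", seed))
}

# A labelled feature matrix from raw gaussian clusters (no pipeline), for
# distance-method unit tests: `shifts` gives the per-phase mean offset
# applied to every column.
gaussian_fm <- function(n_per_phase, p = 15L, shifts, seed = 1L, subject_id = "G") {
  set.seed(seed)
  k <- length(shifts)
  x <- matrix(rnorm(n_per_phase * k * p), n_per_phase * k, p)
  phase <- rep(seq_len(k), each = n_per_phase)
  for (i in seq_len(k)) x[phase == i, ] <- x[phase == i, ] + shifts[i]
  feature_matrix(x, phase, subject_id, fs = 1)
}

# Protocol with k contiguous phases of 1 s (baseline first) for gaussian_fm.
flat_protocol <- function(k) {
  phase_protocol(paste0("p", seq_len(k)), 0:(k - 1), 1:k,
                 c("baseline", rep("stressor", k - 1L)))
}

# Table of published seven-subject RSI columns and questionnaire totals
# (regression fixture for the validation module).
published_rsi_table <- function() {
  data.frame(
    resim = c(106, 138, 142, 148, 152, 159, 162),
    edpca = c(0.2175, 0.5728, -0.0133, 0.2853, 0.4129, 0.0998, 0.1633),
    md    = c(0.2420, 0.2562, 0.2024, 0.2249, -0.5933, 0.2200, -0.1718),
    cvid  = c(0.0137, 0.6317, 0.1203, 1.0000, -0.1771, -0.0230, 0.0081),
    kpca  = c(0.0813, 0.0075, -0.0090, 0.0232, -0.0151, 0.0490, 0.0318)
  )
}

# Published per-subject phase-1 vs phase-5 per-channel rank correlations,
# their row means, and questionnaire totals.
published_phase15_table <- function() {
  data.frame(
    subject = 1:7,
    EMG = c(-0.45, 0.00, -0.03, -0.31, -0.09, -0.10, -0.11),
    HR  = c(0.25, 0.27, -0.09, 0.08, 0.24, 0.15, 0.04),
    BR  = c(-0.27, 0.11, -0.02, 0.16, 0.14, 0.02, 0.03),
    SC  = c(0.92, 0.99, 0.88, 0.96, 0.99, 0.99, 0.99),
    PT  = c(-0.99, 0.87, 0.94, -0.35, -0.82, -1.00, -1.00),
    mean = c(-0.11, 0.45, 0.34, 0.11, 0.09, 0.01, -0.01),
    resim = c(159, 148, 138, 152, 106, 142, 162)
  )
}
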