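#' Median-filter kernel size rule
#'
#' The running-median window grows with recording length relative to the
#' sampling rate: `w = round(n / (4 * fs))`, incremented by one when even so
#' the window has a unique centre. For the canonical 10-minute recording at
#' 256 Hz (n = 153,600) this yields 151 samples.
#'
#' @param fs sampling rate in Hz.
#' @param n number of samples.
#' @return odd integer kernel size, at least 1.
#' @export
median_kernel_size <- function(fs, n) {
  if (!is.numeric(fs) || fs <= 0) rsi_stop("fs must be positive", "rsi_bad_input")
  if (!is.numeric(n) || n <= 0) rsi_stop("n must be positive", "rsi_bad_input")
  w <- round(n / (4 * fs))
  if (w < 1) w <- 1
  if (w %% 2 == 0) w <- w + 1
  as.integer(w)
}

#' Trim the sensor start-up offset from a recording
#'
#' Biofeedback hardware shows a transient at the start of acquisition; the
#' first `seconds` of every channel are dropped (default 0.5 s) and the
#' trim is recorded in `t0_offset` so phase segmentation stays anchored to
#' the original t = 0.
#'
#' @param rec a [recording()].
#' @param seconds seconds to drop from the start.
#' @return the trimmed [recording()].
#' @export
trim_offset <- function(rec, seconds = 0.5) {
  stopifnot(inherits(rec, "recording"))
  if (seconds < 0) rsi_stop("trim seconds must be >= 0", "rsi_bad_input")
  k <- floor(seconds * rec$fs)
  if (k >= rec$n_samples)
    rsi_stop("recording shorter than requested trim", "rsi_trim_too_long")
  if (k == 0L) return(rec)
  recording(rec$channels[-seq_len(k), , drop = FALSE], fs = rec$fs,
            subject_id = rec$subject_id, t0_offset = rec$t0_offset + k / rec$fs)
}

#' Running median filter with reflected edges
#'
#' Element k of the output is the median of the `w`-sample window centred at
#' k. Edges are handled by symmetric reflection (the first/last `(w-1)/2`
#' samples mirrored outward), which avoids the boundary transients that
#' zero-padding would inject into baseline statistics. The heavy lifting is
#' done by `stats::runmed`.
#'
#' @param x numeric series.
#' @param w odd window size, `w <= length(x)`.
#' @return filtered series, same length as `x`.
#' @export
median_filter <- function(x, w) {
  n <- length(x)
  if (w %% 2 == 0) rsi_stop("kernel size must be odd", "rsi_even_kernel")
  if (w > n) rsi_stop("kernel size exceeds series length", "rsi_kernel_too_long")
  if (w == 1L) return(x)
  h <- (w - 1L) / 2L
  padded <- c(x[h:1], x, x[n:(n - h + 1L)])
  out <- stats::runmed(padded, w, endrule = "keep")
  out[(h + 1L):(h + n)]
}

#' Standardize a series to zero mean and unit variance
#'
#' `z = (x - a) / s` with the population (divide-by-N) standard deviation,
#' the standard-scaler convention. Attributes `center` and `scale` carry the
#' fitted statistics.
#'
#' @param x numeric series, non-constant.
#' @return standardized series with attributes `center`, `scale`.
#' @export
standardize <- function(x) {
  a <- mean(x)
  s <- sqrt(mean((x - a)^2))
  if (s == 0) rsi_stop("cannot standardize a constant series", "rsi_constant_series")
  structure((x - a) / s, center = a, scale = s)
}

# Yeo-Johnson transform at a fixed lambda (strictly monotone for all lambda).
yj_transform <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos)) {
    out[pos] <- if (abs(lambda) < 1e-8) log1p(x[pos])
                else (exp(lambda * log1p(x[pos])) - 1) / lambda
  }
  if (any(!pos)) {
    out[!pos] <- if (abs(lambda - 2) < 1e-8) -log1p(-x[!pos])
                 else -(exp((2 - lambda) * log1p(-x[!pos])) - 1) / (2 - lambda)
  }
  out
}

#' Yeo-Johnson power transform with maximum-likelihood lambda
#'
#' Fits the transform parameter by profile maximum likelihood (Gaussian
#' model) over lambda in [-5, 5], applies it, and standardizes the result.
#' Used ahead of PCA to bring skewed channels closer to normality.
#'
#' @param x numeric series, non-constant.
#' @param standardize_output standardize after transforming (default TRUE).
#' @return transformed series with attribute `lambda` (plus `center`/`scale`
#'   when standardized).
#' @export
yeo_johnson <- function(x, standardize_output = TRUE) {
  n <- length(x)
  if (sqrt(mean((x - mean(x))^2)) == 0)
    rsi_stop("cannot transform a constant series", "rsi_constant_series")
  jac <- sum(sign(x) * log1p(abs(x)))  # lambda-independent part of log|J|
  loglik <- function(lambda) {
    y <- yj_transform(x, lambda)
    v <- mean((y - mean(y))^2)
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lambda - 1) * jac
  }
  lambda <- stats::optimize(loglik, c(-5, 5), maximum = TRUE, tol = 1e-4)$maximum
  y <- yj_transform(x, lambda)
  if (standardize_output) y <- standardize(y)
  attr(y, "lambda") <- lambda
  y
}

#' Downsample a matrix by per-second block aggregation
#'
#' Splits the rows into consecutive blocks of `fs / target_hz` samples and
#' replaces each block by its column-wise median (or mean). A trailing
#' partial block is aggregated over the samples available.
#'
#' @param x numeric matrix (or vector) at `fs` Hz.
#' @param fs input sampling rate.
#' @param target_hz output rate; `fs` must be divisible by it.
#' @param aggregator `"median"` (default) or `"mean"`.
#' @return aggregated matrix with one row per block.
#' @export
downsample_median <- function(x, fs, target_hz = 1, aggregator = c("median", "mean")) {
  aggregator <- match.arg(aggregator)
  if (fs %% target_hz != 0)
    rsi_stop("fs must be divisible by the target rate", "rsi_bad_rate")
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  block <- fs %/% target_hz
  n <- nrow(x)
  grp <- (seq_len(n) - 1L) %/% block
  agg <- if (aggregator == "median") stats::median else mean
  out <- vapply(split(seq_len(n), grp),
                function(idx) apply(x[idx, , drop = FALSE], 2L, agg),
                numeric(ncol(x)))
  out <- if (ncol(x) == 1L) matrix(out, ncol = 1L) else t(out)
  colnames(out) <- colnames(x)
  rownames(out) <- NULL
  out
}

#' Preprocessing configuration
#'
#' @param trim_seconds start-up trim in seconds (default 0.5).
#' @param kernel_override optional odd integer overriding the kernel rule.
#' @param downsample_hz target rate for the downsampled paths (default 1).
#' @param aggregator block aggregator, `"median"` or `"mean"`.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(trim_seconds = 0.5, kernel_override = NULL,
                              downsample_hz = 1, aggregator = "median") {
  if (trim_seconds < 0) rsi_stop("trim_seconds must be >= 0", "rsi_bad_input")
  if (!is.null(kernel_override) && kernel_override %% 2 == 0)
    rsi_stop("kernel_override must be odd", "rsi_even_kernel")
  structure(list(trim_seconds = trim_seconds, kernel_override = kernel_override,
                 downsample_hz = downsample_hz,
                 aggregator = match.arg(aggregator, c("median", "mean"))),
            class = "preprocess_config")
}

#' Condition a raw recording
#'
#' Applies the fixed order: start-up trim, per-channel running median in raw
#' units, per-channel standardization over the whole recording (all phases
#' pooled, so every phase shares one coordinate system).
#'
#' @param rec a raw [recording()].
#' @param config a [preprocess_config()].
#' @return the processed [recording()] with attribute `channel_stats`
#'   (per-channel mean, sd, kernel size used).
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  rec <- trim_offset(rec, config$trim_seconds)
  w <- if (!is.null(config$kernel_override)) as.integer(config$kernel_override)
       else median_kernel_size(rec$fs, rec$n_samples)
  stats_tab <- data.frame(channel = RSI_CHANNELS, mean = NA_real_,
                          sd = NA_real_, kernel = w)
  ch <- rec$channels
  for (j in seq_len(ncol(ch))) {
    f <- median_filter(ch[, j], w)
    z <- standardize(f)
    stats_tab$mean[j] <- attr(z, "center")
    stats_tab$sd[j] <- attr(z, "scale")
    ch[, j] <- as.numeric(z)
  }
  out <- recording(ch, fs = rec$fs, subject_id = rec$subject_id,
                   t0_offset = rec$t0_offset)
  attr(out, "channel_stats") <- stats_tab
  out
}
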