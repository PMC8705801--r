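#' First- and second-lag difference features
#'
#' Augments each of the five standardized channels with its lag-1 and lag-2
#' differences, `d1(t) = x(t) - x(t-1)` and `d2(t) = x(t) - x(t-2)`,
#' capturing short-range temporal dependence that per-sample clustering
#' would otherwise ignore. The first two rows, where the differences are
#' undefined, are dropped so the matrix stays rectangular.
#'
#' @param x numeric matrix of channel columns (>= 3 rows).
#' @return matrix with `3 * ncol(x)` columns: the originals, then the lag-1
#'   differences (suffix `_d1`), then the lag-2 differences (`_d2`); two
#'   fewer rows than the input.
#' @export
difference_features <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(n) || n < 3L)
    rsi_stop("differencing needs at least 3 rows", "rsi_too_few_rows")
  keep <- 3:n
  d1 <- x[keep, , drop = FALSE] - x[keep - 1L, , drop = FALSE]
  d2 <- x[keep, , drop = FALSE] - x[keep - 2L, , drop = FALSE]
  base <- x[keep, , drop = FALSE]
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("ch", seq_len(ncol(x)))
  out <- cbind(base, d1, d2)
  colnames(out) <- c(nms, paste0(nms, "_d1"), paste0(nms, "_d2"))
  out
}

#' Assign a phase label to every sample
#'
#' Phase windows are half-open in seconds, converted to sample indices by
#' `floor(start_s * fs)` on the original (untrimmed) timeline; samples
#' removed by the start-up trim are therefore deducted from phase 1 only.
#'
#' @param n_samples number of samples to label (after any trim).
#' @param protocol a [phase_protocol()].
#' @param fs sampling rate in Hz.
#' @param t0_offset seconds trimmed from the start of the recording.
#' @return integer vector of phase indices (1-based row of `protocol`).
#' @export
segment_phases <- function(n_samples, protocol, fs, t0_offset = 0) {
  start_idx <- floor(protocol$start_s * fs)
  end_idx <- floor(protocol$end_s * fs)
  offset <- floor(t0_offset * fs)
  global <- offset + seq_len(n_samples) - 1L  # 0-based original index
  if (any(global >= end_idx[length(end_idx)]))
    rsi_stop("samples extend beyond the protocol end", "rsi_protocol_too_short")
  labels <- findInterval(global, start_idx)
  if (any(labels < 1L))
    rsi_stop("samples precede the protocol start", "rsi_protocol_too_short")
  as.integer(labels)
}

#' Build the labelled 15-column feature matrix for one subject
#'
#' Combines [difference_features()] on the preprocessed channels with
#' per-sample phase labels from [segment_phases()]. The two rows dropped by
#' differencing are likewise dropped from the labels so rows stay aligned.
#'
#' @param rec a preprocessed [recording()] (see [preprocess_recording()]).
#' @param protocol a [phase_protocol()].
#' @return a `feature_matrix`: list with `x` (n x 15 matrix), `phase`
#'   (integer labels), `subject_id`, `fs`.
#' @export
build_feature_matrix <- function(rec, protocol) {
  stopifnot(inherits(rec, "recording"))
  labels <- segment_phases(rec$n_samples, protocol, rec$fs, rec$t0_offset)
  x <- difference_features(rec$channels)
  labels <- labels[-(1:2)]
  feature_matrix(x, labels, rec$subject_id, rec$fs)
}

#' @rdname build_feature_matrix
#' @param x feature matrix.
#' @param phase integer phase label per row.
#' @param subject_id subject identifier.
#' @param fs rate of the rows in Hz.
#' @export
feature_matrix <- function(x, phase, subject_id = "subject", fs = 256) {
  if (nrow(x) != length(phase))
    rsi_stop("labels and rows misaligned", "rsi_bad_input")
  if (anyNA(x)) rsi_stop("feature matrix contains missing cells", "rsi_non_numeric")
  structure(list(x = x, phase = as.integer(phase),
                 subject_id = as.character(subject_id), fs = fs),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d rows x %d features, phases: %s\n",
              x$subject_id, nrow(x$x), ncol(x$x),
              paste(rle(x$phase)$values, collapse = " ")))
  invisible(x)
}

# Downsample a labelled feature matrix phase by phase so no aggregation
# block straddles a phase boundary.
downsample_feature_matrix <- function(fm, target_hz = 1, aggregator = "median") {
  stopifnot(inherits(fm, "feature_matrix"))
  phases <- unique(fm$phase)
  parts <- lapply(phases, function(p) {
    rows <- fm$x[fm$phase == p, , drop = FALSE]
    ds <- downsample_median(rows, fm$fs, target_hz, aggregator)
    list(x = ds, phase = rep(p, nrow(ds)))
  })
  feature_matrix(do.call(rbind, lapply(parts, `[[`, "x")),
                 unlist(lapply(parts, `[[`, "phase")),
                 fm$subject_id, target_hz)
}

# Apply the Yeo-Johnson transform per channel ahead of the PCA paths.
# Fitted over the whole recording (phases pooled); differences recomputed on
# the transformed channels are NOT taken here -- the caller decides order.
yeo_johnson_matrix <- function(x) {
  lambdas <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    y <- yeo_johnson(x[, j])
    lambdas[j] <- attr(y, "lambda")
    x[, j] <- as.numeric(y)
  }
  attr(x, "lambdas") <- lambdas
  x
}
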