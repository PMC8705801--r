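#' Construct a multichannel recording
#'
#' A recording is one subject's uniformly sampled five-channel signal block:
#' electromyography (EMG, uV), blood volume pulse (BVP, relative %),
#' breathing (BR, relative %), skin conductance (SC, uS) and peripheral
#' temperature (PT, degrees C), all sampled at a common rate.
#'
#' @param channels a numeric matrix (or data.frame / named list of equal-length
#'   numeric vectors) with the five channel columns. Column names may use the
#'   case-insensitive aliases emg, bvp, br/resp, sc/gsr, pt/temp.
#' @param fs sampling rate in Hz (default 256).
#' @param subject_id opaque subject identifier.
#' @param t0_offset seconds already trimmed from the start of the recording.
#' @return An object of class `recording`: a list with elements `channels`
#'   (n x 5 matrix in canonical order EMG, BVP, BR, SC, PT), `fs`,
#'   `subject_id`, `t0_offset`, `n_samples`.
#' @export
recording <- function(channels, fs = 256, subject_id = "subject", t0_offset = 0) {
  if (is.data.frame(channels)) channels <- as.list(channels)
  if (is.list(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) != 1L)
      rsi_stop("all channels must have identical length", "rsi_ragged_channels")
    channels <- do.call(cbind, channels)
  }
  if (!is.matrix(channels)) rsi_stop("channels must be a matrix or list of vectors", "rsi_bad_input")
  colnames(channels) <- canonical_channel_names(colnames(channels))
  channels <- channels[, RSI_CHANNELS, drop = FALSE]
  if (!is.numeric(channels)) rsi_stop("channel data must be numeric", "rsi_non_numeric")
  if (anyNA(channels) || any(!is.finite(channels)))
    rsi_stop("channel data contains missing or non-finite values", "rsi_non_numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    rsi_stop("fs must be a positive scalar", "rsi_bad_input")
  if (t0_offset < 0) rsi_stop("t0_offset must be >= 0", "rsi_bad_input")
  structure(list(
    channels = channels, fs = fs, subject_id = as.character(subject_id),
    t0_offset = t0_offset, n_samples = nrow(channels)
  ), class = "recording")
}

# Map observed column names onto the canonical EMG/BVP/BR/SC/PT set.
canonical_channel_names <- function(nms) {
  if (is.null(nms)) rsi_stop("channel columns must be named", "rsi_missing_channel")
  out <- character(length(nms))
  low <- tolower(trimws(nms))
  for (canon in RSI_CHANNELS) {
    hit <- which(low %in% c(tolower(canon), RSI_CHANNEL_ALIASES[[canon]]))
    if (length(hit) == 0L)
      rsi_stop(paste0("required channel missing: ", canon), "rsi_missing_channel")
    if (length(hit) > 1L)
      rsi_stop(paste0("duplicate columns for channel: ", canon), "rsi_duplicate_channel")
    out[hit] <- canon
  }
  out[out == ""] <- nms[out == ""]  # passthrough extras (rejected later by subset)
  out
}

#' Read a recording from CSV
#'
#' Expects a header row naming the five channels (aliases accepted) and one
#' row per sample. Missing channels, non-numeric cells and ragged rows each
#' raise a distinct error class (`rsi_missing_channel`, `rsi_non_numeric`,
#' `rsi_ragged_rows`).
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz.
#' @param subject_id identifier; defaults to the file name without extension.
#' @return A [recording()].
#' @export
read_recording <- function(path, fs = 256,
                           subject_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) rsi_stop(paste0("file not found: ", path), "rsi_file_not_found")
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L)
    rsi_stop(sprintf("ragged CSV: rows carry %s fields",
                     paste(unique(nf), collapse = "/")), "rsi_ragged_rows")
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, colClasses = "character", fill = FALSE),
    error = function(e) rsi_stop(paste0("unreadable CSV: ", conditionMessage(e)),
                                 "rsi_ragged_rows")
  )
  nms <- canonical_channel_names(names(dt))
  cols <- lapply(RSI_CHANNELS, function(canon) {
    raw <- dt[[which(nms == canon)]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0L)
      rsi_stop(sprintf("non-numeric value in channel %s at row %d: '%s'",
                       canon, bad[1L], raw[bad[1L]]), "rsi_non_numeric")
    val
  })
  names(cols) <- RSI_CHANNELS
  recording(cols, fs = fs, subject_id = subject_id)
}

#' Write a recording to CSV
#'
#' Values are written at full precision so that
#' `read_recording(write_recording(rec))` round-trips exactly.
#'
#' @param rec a [recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(rec$channels)
  dt <- data.table::as.data.table(lapply(df, function(x) sprintf("%.17g", x)))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read RESI-M questionnaire totals
#'
#' Two-column CSV (`subject_id`, `score`); totals must lie in the
#' instrument's range 43-172.
#'
#' @param path CSV path.
#' @return named numeric vector of scores, names = subject ids.
#' @export
read_resim_scores <- function(path) {
  if (!file.exists(path)) rsi_stop(paste0("file not found: ", path), "rsi_file_not_found")
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 2L) rsi_stop("scores file needs subject_id and score columns", "rsi_bad_input")
  scores <- as.numeric(dt[[2L]])
  if (anyNA(scores)) rsi_stop("non-numeric score", "rsi_non_numeric")
  if (any(scores < 43 | scores > 172))
    rsi_stop("RESI-M totals must lie in [43, 172]", "rsi_out_of_range")
  stats::setNames(scores, as.character(dt[[1L]]))
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d samples x %d channels @ %g Hz (%.1f s%s)\n",
              x$subject_id, x$n_samples, ncol(x$channels), x$fs,
              x$n_samples / x$fs,
              if (x$t0_offset > 0) sprintf(", %.2f s trimmed", x$t0_offset) else ""))
  invisible(x)
}
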