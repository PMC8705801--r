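#' @keywords internal
"_PACKAGE"

# Condition helper: every user-facing failure carries a named class under
# "rsindex_error" so callers (and tests) can distinguish failure modes.
rsi_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "rsindex_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

rsi_warn <- function(msg, class = "rsindex_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Canonical channel order used throughout the package.
RSI_CHANNELS <- c("EMG", "BVP", "BR", "SC", "PT")

# Case-insensitive aliases accepted in CSV headers.
RSI_CHANNEL_ALIASES <- list(
  EMG = c("emg"),
  BVP = c("bvp"),
  BR  = c("br", "resp", "breathing", "respiration"),
  SC  = c("sc", "gsr", "eda"),
  PT  = c("pt", "temp", "temperature")
)
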