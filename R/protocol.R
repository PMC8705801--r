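#' Phase protocol for a stress-test recording
#'
#' A phase protocol is an ordered, contiguous set of half-open time windows
#' `[start_s, end_s)` with a role for each phase: exactly one `baseline`
#' (the calibration phase all distances are measured against), plus any
#' number of `stressor` and `recovery` phases.
#'
#' @param name character vector of phase names.
#' @param start_s,end_s numeric vectors of window boundaries in seconds.
#' @param role character vector; each element one of `"baseline"`,
#'   `"stressor"`, `"recovery"`.
#' @return An object of class `phase_protocol`: a data.frame with columns
#'   `name`, `start_s`, `end_s`, `role` and attribute `baseline` (the row
#'   index of the baseline phase).
#' @examples
#' phase_protocol(
#'   name = c("p1", "p2", "p3"),
#'   start_s = c(0, 60, 120), end_s = c(60, 120, 180),
#'   role = c("baseline", "stressor", "recovery")
#' )
#' @export
phase_protocol <- function(name, start_s, end_s, role) {
  n <- length(name)
  if (n == 0L) rsi_stop("protocol must contain at least one phase", "rsi_empty_protocol")
  if (length(start_s) != n || length(end_s) != n || length(role) != n)
    rsi_stop("protocol fields must have equal length", "rsi_bad_protocol")
  role <- match.arg(role, c("baseline", "stressor", "recovery"), several.ok = TRUE)
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
    rsi_stop("phase boundaries must be finite", "rsi_bad_protocol")
  if (any(end_s <= start_s))
    rsi_stop("each phase must have start_s < end_s", "rsi_bad_protocol")
  ord <- order(start_s)
  name <- name[ord]; start_s <- start_s[ord]; end_s <- end_s[ord]; role <- role[ord]
  if (n > 1L) {
    gap <- start_s[-1L] - end_s[-n]
    if (any(gap < 0)) rsi_stop("phases overlap", "rsi_overlapping_phases")
    if (any(gap > 0)) rsi_stop("phases leave a gap", "rsi_gapped_phases")
  }
  bl <- which(role == "baseline")
  if (length(bl) != 1L)
    rsi_stop("protocol must contain exactly one baseline phase", "rsi_bad_baseline")
  out <- data.frame(name = as.character(name), start_s = start_s,
                    end_s = end_s, role = role, stringsAsFactors = FALSE)
  structure(out, baseline = bl, class = c("phase_protocol", "data.frame"))
}

#' Default five-phase protocol
#'
#' Ten minutes in five two-minute phases: baseline, stressor (mental
#' arithmetic), recovery, stressor (emotional recall), recovery.
#'
#' @param phase_s duration of each phase in seconds (default 120).
#' @return A [phase_protocol()].
#' @export
default_protocol <- function(phase_s = 120) {
  phase_protocol(
    name    = paste0("phase", 1:5),
    start_s = phase_s * 0:4,
    end_s   = phase_s * 1:5,
    role    = c("baseline", "stressor", "recovery", "stressor", "recovery")
  )
}

#' Load a phase protocol from a JSON configuration file
#'
#' The file holds an array of phase objects with keys `name`, `start_s`,
#' `end_s`, `role` (either at top level or under a `"phases"` key). With
#' `path = NULL` the default five-phase protocol is returned.
#'
#' @param path path to a JSON file, or `NULL` for the default protocol.
#' @return A [phase_protocol()].
#' @export
load_protocol <- function(path = NULL) {
  if (is.null(path)) return(default_protocol())
  if (!file.exists(path)) rsi_stop(paste0("protocol file not found: ", path), "rsi_file_not_found")
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.list(cfg) && !is.data.frame(cfg) && !is.null(cfg$phases)) cfg <- cfg$phases
  if (!is.data.frame(cfg) || !all(c("name", "start_s", "end_s", "role") %in% names(cfg)))
    rsi_stop("protocol config must define phases with name/start_s/end_s/role", "rsi_bad_protocol")
  phase_protocol(cfg$name, cfg$start_s, cfg$end_s, cfg$role)
}

#' @export
print.phase_protocol <- function(x, ...) {
  cat(sprintf("<phase_protocol> %d phases, %g s total (baseline: %s)\n",
              nrow(x), max(x$end_s), x$name[attr(x, "baseline")]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

protocol_duration <- function(protocol) max(protocol$end_s)
baseline_index <- function(protocol) attr(protocol, "baseline")
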