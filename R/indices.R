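#' Signed recovery delta of a subject
#'
#' `delta_R = D(4) - D(5)`: the baseline-relative separation at the last
#' stressor phase minus the separation at the last recovery phase. Positive
#' means phase 5 ended nearer the baseline than phase 4 was (the subject
#' recovered); negative means the physiological state drifted further from
#' baseline after the last stressor.
#'
#' @param profile a [phase_distance_profile()].
#' @param stressor_phase,recovery_phase phase indices (defaults 4 and 5).
#' @return scalar delta_R (may be negative).
#' @export
recovery_delta <- function(profile, stressor_phase = 4L, recovery_phase = 5L) {
  D <- profile$D
  want <- as.character(c(stressor_phase, recovery_phase))
  if (!all(want %in% names(D)))
    rsi_stop("profile lacks the stressor or recovery phase", "rsi_missing_phase")
  unname(D[want[1L]] - D[want[2L]])
}

#' Maximum baseline-relative stretch of a subject
#'
#' The largest separation from baseline attained over the non-baseline
#' phases: how far the subject's physiology was pushed at its worst.
#'
#' @param profile a [phase_distance_profile()].
#' @return scalar `SubMaxS`.
#' @export
subject_max_stretch <- function(profile) {
  if (length(profile$D) == 0L) rsi_stop("empty distance profile", "rsi_missing_phase")
  max(profile$D)
}

#' Resilience to Stress Index across a cohort
#'
#' `RSI_k = delta_R_k / max_j delta_R_j`. The cohort's best recoverer scores
#' exactly 1; negative values mark subjects whose state was farther from
#' baseline after the last stressor than during it. Requires that at least
#' one subject recovered (max delta_R > 0), otherwise the normalizer is
#' meaningless.
#'
#' @param deltas numeric vector of per-subject delta_R values (length >= 2).
#' @return numeric vector of RSI values with attribute `delta_s` (the
#'   normalizer).
#' @export
compute_rsi <- function(deltas) {
  if (length(deltas) < 2L) rsi_stop("cohort must have at least 2 subjects", "rsi_cohort_too_small")
  ds <- max(deltas)
  if (ds <= 0) rsi_stop("no subject recovered (max delta_R <= 0)", "rsi_no_recovery")
  structure(deltas / ds, delta_s = ds)
}

#' Alteration Factor across a cohort
#'
#' `AF_k = (SubMaxS_k - SamMinS) / (SamMaxS - SamMinS)`: each subject's
#' maximum stretch rescaled to [0, 1] over the cohort. The least-altered
#' subject scores 0, the most-altered 1.
#'
#' @param stretches numeric vector of per-subject `SubMaxS` (length >= 2,
#'   not all equal).
#' @return numeric vector of AF values with attributes `sam_min_s` and
#'   `delta_sam_st`.
#' @export
compute_af <- function(stretches) {
  if (length(stretches) < 2L) rsi_stop("cohort must have at least 2 subjects", "rsi_cohort_too_small")
  lo <- min(stretches); hi <- max(stretches)
  if (hi - lo <= 0) rsi_stop("degenerate cohort: all stretches equal", "rsi_degenerate_cohort")
  structure((stretches - lo) / (hi - lo), sam_min_s = lo, delta_sam_st = hi - lo)
}

#' Cohort-relative indices from per-subject distance profiles
#'
#' Computes RSI and AF for every subject and method. Normalizers (`delta_s`,
#' `sam_min_s`, `delta_sam_st`) are per method, never pooled across methods,
#' since each method has its own distance scale.
#'
#' @param profiles list of [phase_distance_profile()] objects (all subjects,
#'   one or more methods).
#' @return a `cohort_indices` data.frame: one row per subject x method with
#'   columns `subject_id`, `method`, `D2`..`D5`, `delta_r`, `sub_max_s`,
#'   `rsi`, `af`; attribute `normalizers` holds the per-method normalizers.
#' @export
cohort_indices <- function(profiles) {
  if (length(profiles) == 0L) rsi_stop("no profiles given", "rsi_cohort_too_small")
  rows <- lapply(profiles, function(p) {
    d <- as.list(p$D)
    names(d) <- paste0("D", names(p$D))
    c(list(subject_id = p$subject_id, method = p$method), d,
      list(delta_r = recovery_delta(p), sub_max_s = subject_max_stretch(p)))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  norms <- list()
  df$rsi <- NA_real_; df$af <- NA_real_
  for (m in unique(df$method)) {
    sel <- df$method == m
    if (sum(sel) < 2L) rsi_stop("cohort must have at least 2 subjects per method",
                                "rsi_cohort_too_small")
    rsi <- compute_rsi(df$delta_r[sel])
    af <- compute_af(df$sub_max_s[sel])
    df$rsi[sel] <- as.numeric(rsi)
    df$af[sel] <- as.numeric(af)
    norms[[m]] <- list(delta_s = attr(rsi, "delta_s"),
                       sam_min_s = attr(af, "sam_min_s"),
                       delta_sam_st = attr(af, "delta_sam_st"),
                       n = sum(sel))
  }
  structure(df, normalizers = norms, class = c("cohort_indices", "data.frame"))
}
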