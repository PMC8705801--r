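#' Full analysis configuration
#'
#' Bundles the preprocessing settings with the method-specific knobs.
#'
#' @param preprocess a [preprocess_config()].
#' @param methods methods to run; subset of `"ED-PCA"`, `"MD"`, `"CVID"`,
#'   `"ED-KPCA"`.
#' @param md_instances Mahalanobis averaging set, `"target"` or `"pooled"`
#'   (see [mahalanobis_phase_distance()]).
#' @param kpca_kernel kernel for the kernel-PCA path.
#' @param kpca_gamma RBF bandwidth (default: median heuristic).
#' @param kpca_components components retained by kernel PCA.
#' @param cvid_all_pairs also compute all phase pairs for CVID.
#' @return an `rsi_config` list.
#' @export
rsi_config <- function(preprocess = preprocess_config(),
                       methods = c("ED-PCA", "MD", "CVID", "ED-KPCA"),
                       md_instances = "target",
                       kpca_kernel = "rbf", kpca_gamma = NULL,
                       kpca_components = 15L, cvid_all_pairs = FALSE) {
  methods <- match.arg(methods, c("ED-PCA", "MD", "CVID", "ED-KPCA"),
                       several.ok = TRUE)
  structure(list(preprocess = preprocess, methods = methods,
                 md_instances = md_instances, kpca_kernel = kpca_kernel,
                 kpca_gamma = kpca_gamma, kpca_components = kpca_components,
                 cvid_all_pairs = cvid_all_pairs),
            class = "rsi_config")
}

#' Distance profiles for one subject under the selected methods
#'
#' Runs the per-subject pipeline: preprocessing (trim, median filter,
#' standardize), differenced feature construction, then each method on its
#' prescribed representation -- MD on the full-rate standardized features;
#' ED-PCA on the Yeo-Johnson-transformed, re-standardized channels
#' (transformed before differencing, fitted over all phases pooled); CVID
#' and ED-KPCA on the per-second block-median downsampled features.
#'
#' @param rec a raw [recording()].
#' @param protocol a [phase_protocol()].
#' @param config an [rsi_config()].
#' @return named list of [phase_distance_profile()], one per method.
#' @export
subject_profiles <- function(rec, protocol, config = rsi_config()) {
  proc <- preprocess_recording(rec, config$preprocess)
  fm <- build_feature_matrix(proc, protocol)
  out <- list()
  if ("MD" %in% config$methods)
    out[["MD"]] <- md_distances(fm, protocol, instances = config$md_instances)
  if ("ED-PCA" %in% config$methods) {
    yj <- yeo_johnson_matrix(proc$channels)
    rec_yj <- recording(yj, fs = proc$fs, subject_id = proc$subject_id,
                        t0_offset = proc$t0_offset)
    fm_yj <- build_feature_matrix(rec_yj, protocol)
    out[["ED-PCA"]] <- edpca_distances(fm_yj, protocol)
  }
  if (any(c("CVID", "ED-KPCA") %in% config$methods)) {
    fm_ds <- downsample_feature_matrix(fm, config$preprocess$downsample_hz,
                                       config$preprocess$aggregator)
    if ("CVID" %in% config$methods)
      out[["CVID"]] <- cvid_distances(fm_ds, protocol,
                                      all_pairs = config$cvid_all_pairs)
    if ("ED-KPCA" %in% config$methods)
      out[["ED-KPCA"]] <- kpca_distances(fm_ds, protocol,
                                         kernel = config$kpca_kernel,
                                         gamma = config$kpca_gamma,
                                         n_components = config$kpca_components)
  }
  out
}

#' Cohort indices from raw recordings
#'
#' Applies [subject_profiles()] to every recording and derives the
#' cohort-relative RSI and AF per method.
#'
#' @param recordings list of raw [recording()] objects (>= 2).
#' @param protocol a [phase_protocol()].
#' @param config an [rsi_config()].
#' @return a [cohort_indices()] data.frame.
#' @export
compute_cohort <- function(recordings, protocol = default_protocol(),
                           config = rsi_config()) {
  if (length(recordings) < 2L)
    rsi_stop("cohort must have at least 2 subjects", "rsi_cohort_too_small")
  profiles <- unlist(lapply(recordings, subject_profiles, protocol = protocol,
                            config = config), recursive = FALSE)
  cohort_indices(profiles)
}

#' Write cohort indices and a run manifest
#'
#' @param indices a [cohort_indices()] data.frame.
#' @param dir output directory (created if needed).
#' @param config the [rsi_config()] used.
#' @param seeds named list/vector of seeds used, recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_results <- function(indices, dir, config = rsi_config(), seeds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(as.data.frame(indices), file.path(dir, "indices.csv"))
  manifest <- list(
    package = "rsindex",
    version = as.character(utils::packageVersion("rsindex")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass_deep(config),
    seeds = seeds,
    normalizers = attr(indices, "normalizers")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
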