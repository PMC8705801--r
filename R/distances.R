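#' Per-subject baseline-relative phase distance profile
#'
#' Container for the output of one distance method applied to one subject:
#' the separation `D(i)` between the baseline phase and every other phase
#' `i`, plus method diagnostics.
#'
#' @param subject_id subject identifier.
#' @param method one of `"ED-PCA"`, `"MD"`, `"CVID"`, `"ED-KPCA"`.
#' @param D named numeric vector, names = phase indices as character.
#' @param diagnostics list of method-specific diagnostics.
#' @return a `phase_distance_profile` object.
#' @export
phase_distance_profile <- function(subject_id, method, D, diagnostics = list()) {
  method <- match.arg(method, c("ED-PCA", "MD", "CVID", "ED-KPCA"))
  if (method %in% c("ED-PCA", "MD") && any(D < 0))
    rsi_stop("distances must be non-negative", "rsi_bad_profile")
  if (method == "CVID" && any(D < -1 | D > 1))
    rsi_stop("silhouette scores must lie in [-1, 1]", "rsi_bad_profile")
  structure(list(subject_id = subject_id, method = method, D = D,
                 diagnostics = diagnostics),
            class = "phase_distance_profile")
}

#' @export
print.phase_distance_profile <- function(x, ...) {
  cat(sprintf("<phase_distance_profile> %s [%s]: %s\n", x$subject_id, x$method,
              paste(sprintf("D(%s)=%.4g", names(x$D), x$D), collapse = ", ")))
  invisible(x)
}

phase_centroids <- function(x, phase) {
  rowsum(x, phase) / as.numeric(table(phase))
}

#' Euclidean centroid distances in principal-component space
#'
#' Fits a full-rank PCA (all 15 components, so no information is lost) on
#' the subject's pooled samples and measures the Euclidean distance from the
#' baseline-phase centroid to every other phase centroid in component
#' space. Because the full-rank PCA is an orthogonal map, these equal the
#' centroid distances in the input space; the PCA exists to decorrelate the
#' axes and to expose the explained-variance diagnostics.
#'
#' @param fm a `feature_matrix` (expected: Yeo-Johnson-transformed and
#'   standardized, full rate).
#' @param protocol a [phase_protocol()]; identifies the baseline phase.
#' @param n_components number of components retained (default: all).
#' @return a [phase_distance_profile()] with method `"ED-PCA"`.
#' @export
edpca_distances <- function(fm, protocol, n_components = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  p <- ncol(fm$x)
  if (nrow(fm$x) < p) rsi_stop("fewer rows than feature columns", "rsi_rank_deficient")
  if (length(unique(fm$phase)) < 2L) rsi_stop("need at least two phases", "rsi_bad_input")
  if (is.null(n_components)) n_components <- p
  fit <- stats::prcomp(fm$x, center = TRUE, scale. = FALSE)
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  cent <- phase_centroids(scores, fm$phase)
  bl <- baseline_index(protocol)
  others <- setdiff(rownames(cent), as.character(bl))
  D <- vapply(others, function(i)
    sqrt(sum((cent[as.character(bl), ] - cent[i, ])^2)), numeric(1))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  phase_distance_profile(fm$subject_id, "ED-PCA", D,
                         diagnostics = list(explained_variance = ev,
                                            n_components = n_components))
}

# Pooled-pair covariance with a diagnostal ridge when ill-conditioned.
regularized_cov <- function(rows, cond_limit = 1e10, ridge_scale = 1e-6) {
  S <- stats::cov(rows)
  ridge <- FALSE
  kap <- tryCatch(kappa(S, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap) || kap > cond_limit) {
    S <- S + diag(ridge_scale * sum(diag(S)) / ncol(S), ncol(S))
    ridge <- TRUE
  }
  list(cov = S, ridge = ridge, condition = kap)
}

#' Mean Mahalanobis distance of a phase to the baseline centroid
#'
#' Four steps: (1) covariance from the pooled rows of the baseline and
#' target phases (with a small diagonal ridge when near-singular);
#' (2) baseline centroid as the per-column mean of baseline rows;
#' (3) Mahalanobis distance of each target-phase row to that centroid under
#' the inverse covariance; (4) the mean of those distances.
#'
#' @param fm a `feature_matrix` (standardized, full rate).
#' @param protocol a [phase_protocol()].
#' @param phase target phase index.
#' @param instances `"target"` (default) averages distances over the target
#'   phase's rows only; `"pooled"` averages over both phases' rows.
#' @param cov_matrix optional covariance override (e.g. identity, for
#'   checks against a Euclidean oracle).
#' @return list with `D` (the mean distance) and `diagnostics`.
#' @export
mahalanobis_phase_distance <- function(fm, protocol, phase,
                                       instances = c("target", "pooled"),
                                       cov_matrix = NULL) {
  instances <- match.arg(instances)
  bl <- baseline_index(protocol)
  if (!phase %in% fm$phase) rsi_stop("undefined phase", "rsi_bad_input")
  rows_bl <- fm$x[fm$phase == bl, , drop = FALSE]
  rows_ph <- fm$x[fm$phase == phase, , drop = FALSE]
  pooled <- rbind(rows_bl, rows_ph)
  if (nrow(pooled) <= ncol(pooled))
    rsi_stop("phase pair has fewer rows than columns", "rsi_rank_deficient")
  if (is.null(cov_matrix)) {
    rc <- regularized_cov(pooled)
  } else {
    rc <- list(cov = cov_matrix, ridge = FALSE, condition = kappa(cov_matrix))
  }
  centroid <- colMeans(rows_bl)
  target <- if (instances == "target") rows_ph else pooled
  d2 <- tryCatch(stats::mahalanobis(target, centroid, rc$cov),
                 error = function(e) rsi_stop("singular covariance", "rsi_singular_cov"))
  list(D = mean(sqrt(pmax(d2, 0))),
       diagnostics = list(ridge = rc$ridge, condition = rc$condition))
}

#' Mahalanobis distance profile across phases
#'
#' @inheritParams mahalanobis_phase_distance
#' @return a [phase_distance_profile()] with method `"MD"`.
#' @export
md_distances <- function(fm, protocol, instances = "target") {
  bl <- baseline_index(protocol)
  others <- setdiff(sort(unique(fm$phase)), bl)
  res <- lapply(others, function(i)
    mahalanobis_phase_distance(fm, protocol, i, instances = instances))
  D <- vapply(res, `[[`, numeric(1), "D")
  names(D) <- as.character(others)
  phase_distance_profile(fm$subject_id, "MD", D,
                         diagnostics = list(per_phase = lapply(res, `[[`, "diagnostics")))
}

# Whiten points by the Cholesky factor of a covariance so that Euclidean
# distance in the whitened space is the Mahalanobis distance under it.
whiten <- function(x, S) {
  R <- tryCatch(chol(S), error = function(e)
    rsi_stop("singular covariance", "rsi_singular_cov"))
  t(backsolve(R, t(x), transpose = TRUE))
}

#' Silhouette score of a phase pair under the Mahalanobis metric
#'
#' Treats the two phases as a two-cluster labelling and returns the mean
#' per-point silhouette `s = (b - a) / max(a, b)` where `a` is the mean
#' distance to the point's own cluster and `b` the mean distance to the
#' other cluster, with distances Mahalanobis under the pooled-pair
#' covariance. Values near 1 mean well-separated phases, near 0 overlapping
#' phases.
#'
#' @param fm a `feature_matrix` (typically downsampled to 1 Hz; the
#'   silhouette is quadratic in the number of points).
#' @param pair integer vector of two phase indices.
#' @param cov_matrix optional metric covariance override (e.g. identity).
#' @return scalar silhouette score in [-1, 1].
#' @export
cvid_score <- function(fm, pair, cov_matrix = NULL) {
  stopifnot(length(pair) == 2L)
  rows1 <- fm$x[fm$phase == pair[1L], , drop = FALSE]
  rows2 <- fm$x[fm$phase == pair[2L], , drop = FALSE]
  n1 <- nrow(rows1); n2 <- nrow(rows2)
  if (n1 < 2L || n2 < 2L)
    rsi_stop("each cluster needs at least two points", "rsi_cluster_too_small")
  pooled <- rbind(rows1, rows2)
  S <- if (is.null(cov_matrix)) regularized_cov(pooled)$cov else cov_matrix
  wp <- whiten(pooled, S)
  dm <- as.matrix(stats::dist(wp))
  lab <- rep(c(1L, 2L), c(n1, n2))
  n <- n1 + n2
  s <- numeric(n)
  for (k in seq_len(n)) {
    own <- lab == lab[k]
    a <- sum(dm[k, own]) / (sum(own) - 1L)  # exclude self
    b <- mean(dm[k, !own])
    s[k] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Silhouette profile of the baseline against every other phase
#'
#' @param fm a `feature_matrix` (downsampled; see [cvid_score()]).
#' @param protocol a [phase_protocol()].
#' @param all_pairs also compute every phase pair (kept in diagnostics).
#' @return a [phase_distance_profile()] with method `"CVID"`; `D` holds the
#'   silhouette of (baseline, phase i).
#' @export
cvid_distances <- function(fm, protocol, all_pairs = FALSE) {
  bl <- baseline_index(protocol)
  others <- setdiff(sort(unique(fm$phase)), bl)
  D <- vapply(others, function(i) cvid_score(fm, c(bl, i)), numeric(1))
  names(D) <- as.character(others)
  diag <- list()
  if (all_pairs) {
    phases <- sort(unique(fm$phase))
    combs <- utils::combn(phases, 2L)
    pw <- apply(combs, 2L, function(pr) cvid_score(fm, pr))
    diag$pairwise <- data.frame(i = combs[1L, ], j = combs[2L, ], score = pw)
  }
  phase_distance_profile(fm$subject_id, "CVID", D, diagnostics = diag)
}

# Kernel matrices ------------------------------------------------------------

rbf_kernel <- function(x, gamma) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  exp(-gamma * pmax(d2, 0))
}

# Median heuristic: gamma = 1 / (2 * median(pairwise distance)^2).
median_heuristic_gamma <- function(x, max_points = 500L) {
  n <- nrow(x)
  if (n > max_points) x <- x[seq(1L, n, length.out = max_points), , drop = FALSE]
  med <- stats::median(stats::dist(x))
  if (med <= 0) rsi_stop("degenerate point cloud for bandwidth heuristic", "rsi_degenerate_kernel")
  1 / (2 * med^2)
}

#' Euclidean centroid distances in kernel principal-component space
#'
#' Fits kernel PCA on the subject's pooled (downsampled) rows: the centred
#' kernel matrix is eigendecomposed and points are projected onto the
#' leading components, where baseline-to-phase centroid distances are
#' measured. The default kernel is RBF with the median-heuristic bandwidth;
#' with a linear kernel and all components this reduces exactly to ordinary
#' PCA.
#'
#' @param fm a `feature_matrix`, downsampled to about 1 Hz (the kernel
#'   matrix is n x n).
#' @param protocol a [phase_protocol()].
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param gamma RBF bandwidth; default median heuristic.
#' @param n_components components retained (default 15, parity with ED-PCA).
#' @return a [phase_distance_profile()] with method `"ED-KPCA"`.
#' @export
kpca_distances <- function(fm, protocol, kernel = c("rbf", "linear"),
                           gamma = NULL, n_components = 15L) {
  kernel <- match.arg(kernel)
  x <- fm$x
  n <- nrow(x)
  if (n < 4L) rsi_stop("too few rows for kernel PCA", "rsi_too_few_rows")
  if (kernel == "rbf") {
    if (is.null(gamma)) gamma <- median_heuristic_gamma(x)
    K <- rbf_kernel(x, gamma)
  } else {
    K <- tcrossprod(x)
  }
  # Double-centre the kernel matrix.
  rm <- rowMeans(K); gm <- mean(K)
  Kc <- K - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm
  eig <- eigen(Kc, symmetric = TRUE)
  tol <- 1e-10 * max(eig$values, 1)
  keep <- which(eig$values > tol)
  if (length(keep) == 0L) rsi_stop("degenerate kernel matrix", "rsi_degenerate_kernel")
  keep <- keep[seq_len(min(n_components, length(keep)))]
  # Scores: V * sqrt(lambda) gives feature-space coordinates.
  scores <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), length(keep))
  cent <- phase_centroids(scores, fm$phase)
  bl <- baseline_index(protocol)
  others <- setdiff(rownames(cent), as.character(bl))
  D <- vapply(others, function(i)
    sqrt(sum((cent[as.character(bl), ] - cent[i, ])^2)), numeric(1))
  phase_distance_profile(fm$subject_id, "ED-KPCA", D,
                         diagnostics = list(kernel = kernel, gamma = gamma,
                                            n_components = length(keep),
                                            eigenvalues = eig$values[keep]))
}
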