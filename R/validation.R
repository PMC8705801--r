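#' Spearman rank correlation
#'
#' Average ranks on ties; exact permutation p-value for n <= 8 without ties,
#' the large-sample t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `estimate` (rho) and `p.value`.
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- length(x) <= 8L && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}

#' Pearson product-moment correlation
#'
#' p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `estimate` (r) and `p.value`.
#' @export
pearson_cor <- function(x, y) {
  check_cor_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) rsi_stop("x and y must have equal length", "rsi_bad_input")
  if (length(x) < 3L) rsi_stop("need at least 3 paired observations", "rsi_too_few_rows")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    rsi_stop("constant input vector", "rsi_constant_series")
  invisible(TRUE)
}

#' Anderson-Darling test of normality
#'
#' Case-3 statistic (mean and variance estimated from the sample). The
#' unadjusted A-squared is reported as the statistic; the p-value uses the
#' small-sample adjustment `A* = A^2 (1 + 0.75/n + 2.25/n^2)` with the
#' D'Agostino-Stephens interpolation formulas.
#'
#' @param x numeric vector, n >= 5, non-constant.
#' @param alpha significance level for the normality decision.
#' @return list with `statistic` (A^2), `adjusted` (A*), `p.value`,
#'   `normal` (logical decision at `alpha`).
#' @export
anderson_darling <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 5L) rsi_stop("Anderson-Darling needs n >= 5", "rsi_too_few_rows")
  if (stats::sd(x) == 0) rsi_stop("constant input vector", "rsi_constant_series")
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  A2 <- -n - mean((2 * seq_len(n) - 1) * (log(p) + log(1 - rev(p))))
  As <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  pv <- if (As >= 0.6) exp(1.2937 - 5.709 * As + 0.0186 * As^2)
        else if (As >= 0.34) exp(0.9177 - 4.279 * As - 1.38 * As^2)
        else if (As > 0.2) 1 - exp(-8.318 + 42.796 * As - 59.938 * As^2)
        else 1 - exp(-13.436 + 101.14 * As - 223.73 * As^2)
  pv <- min(max(pv, 0), 1)
  list(statistic = A2, adjusted = As, p.value = pv, normal = pv > alpha)
}

#' Friedman rank test across methods
#'
#' Within-subject average ranks (rank 1 = smallest value), the classic
#' Friedman chi-square with tie correction, and a per-method summary table
#' (median, median absolute deviation, mean rank).
#'
#' @param values numeric matrix, subjects in rows, methods in columns.
#' @return list with `statistic`, `p.value`, `mean_ranks`, and `summary`
#'   (data.frame with columns `method`, `MD`, `MAD`, `MR`).
#' @export
friedman_rank_test <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) rsi_stop("need >= 2 subjects and >= 2 methods", "rsi_too_few_rows")
  if (anyNA(values)) rsi_stop("missing method values", "rsi_non_numeric")
  R <- t(apply(values, 1L, rank))
  Rj <- colMeans(R)
  stat <- 12 * n / (k * (k + 1)) * sum((Rj - (k + 1) / 2)^2)
  # Tie correction: divide by 1 - sum(t^3 - t) / (n k (k^2 - 1)).
  tie_sum <- sum(apply(values, 1L, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (C > 0) stat <- stat / C else stat <- 0
  p <- stats::pchisq(stat, df = k - 1L, lower.tail = FALSE)
  nms <- colnames(values)
  if (is.null(nms)) nms <- paste0("method", seq_len(k))
  summary_tab <- data.frame(
    method = nms,
    MD = apply(values, 2L, stats::median),
    MAD = apply(values, 2L, function(v) stats::median(abs(v - stats::median(v)))),
    MR = Rj, row.names = NULL)
  list(statistic = stat, p.value = p, mean_ranks = stats::setNames(Rj, nms),
       summary = summary_tab)
}

#' Phase-1 vs phase-5 per-channel rank correlations
#'
#' For each of the five preprocessed channels, aggregates phase 1 and
#' phase 5 to one sample per second (mean per block) and computes the
#' Spearman correlation between the two series, paired by within-phase
#' position (second k of phase 1 against second k of phase 5). A strongly
#' positive mean suggests the recovery-phase trajectory mirrors the
#' baseline. Unequal lengths are truncated to the shorter with a warning.
#'
#' @param rec a preprocessed [recording()].
#' @param protocol a [phase_protocol()].
#' @param baseline_phase,recovery_phase phase indices (defaults 1 and 5).
#' @param aggregator per-second aggregator (default `"mean"`).
#' @return list with `per_channel` (named rho vector) and `mean`.
#' @export
phase15_feature_correlations <- function(rec, protocol, baseline_phase = 1L,
                                         recovery_phase = 5L, aggregator = "mean") {
  labels <- segment_phases(rec$n_samples, protocol, rec$fs, rec$t0_offset)
  if (!all(c(baseline_phase, recovery_phase) %in% labels))
    rsi_stop("requested phases not present in the recording", "rsi_missing_phase")
  agg <- function(phase) {
    downsample_median(rec$channels[labels == phase, , drop = FALSE],
                      rec$fs, 1, aggregator = aggregator)
  }
  a <- agg(baseline_phase); b <- agg(recovery_phase)
  if (nrow(a) != nrow(b)) {
    rsi_warn(sprintf("phase lengths differ after aggregation (%d vs %d); truncating",
                     nrow(a), nrow(b)), "rsi_truncated_pairing")
    n <- min(nrow(a), nrow(b))
    a <- a[seq_len(n), , drop = FALSE]; b <- b[seq_len(n), , drop = FALSE]
  }
  rho <- vapply(seq_len(ncol(a)), function(j) spearman_cor(a[, j], b[, j])$estimate,
                numeric(1))
  names(rho) <- colnames(rec$channels)
  list(per_channel = rho, mean = mean(rho))
}

#' Correlate per-method RSI vectors with RESI-M questionnaire totals
#'
#' Per method: an Anderson-Darling gate on both the RSI vector and the
#' RESI-M vector chooses the coefficient -- Pearson when both pass the
#' normality test at `alpha`, Spearman otherwise. With fewer than 5 subjects
#' the gate cannot run and Spearman is used with a warning. The `coefficient`
#' argument overrides the gate per method, which is needed to reproduce
#' published analyses whose gate was computed on unrounded data.
#'
#' @param rsi_by_method data.frame or matrix of RSI values, subjects in rows,
#'   methods in columns.
#' @param resim_scores numeric vector of RESI-M totals, aligned to rows.
#' @param alpha significance level for the normality gate.
#' @param coefficient optional named character vector (method ->
#'   `"pearson"`/`"spearman"`) overriding the gate.
#' @return a data.frame, one row per method: `method`, `rsi_normal`,
#'   `resim_normal`, `coefficient`, `estimate`, `p.value`; attribute
#'   `rank_table` holds the per-method within-cohort ranks (rank 1 =
#'   smallest).
#' @export
resim_validation <- function(rsi_by_method, resim_scores, alpha = 0.05,
                             coefficient = NULL) {
  m <- as.matrix(rsi_by_method)
  if (nrow(m) != length(resim_scores))
    rsi_stop("subject sets misaligned", "rsi_bad_input")
  nms <- colnames(m)
  if (is.null(nms)) nms <- paste0("method", seq_len(ncol(m)))
  small <- nrow(m) < 5L
  if (small) rsi_warn("fewer than 5 subjects: falling back to Spearman",
                      "rsi_small_sample")
  resim_ad <- if (small) NULL else anderson_darling(resim_scores, alpha)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    rsi_ad <- if (small) NULL else anderson_darling(m[, j], alpha)
    choice <- if (!is.null(coefficient) && nms[j] %in% names(coefficient)) {
      match.arg(coefficient[[nms[j]]], c("pearson", "spearman"))
    } else if (small) "spearman"
    else if (rsi_ad$normal && resim_ad$normal) "pearson" else "spearman"
    ct <- if (choice == "pearson") pearson_cor(m[, j], resim_scores)
          else spearman_cor(m[, j], resim_scores)
    data.frame(method = nms[j],
               rsi_normal = if (small) NA else rsi_ad$normal,
               resim_normal = if (small) NA else resim_ad$normal,
               coefficient = choice, estimate = ct$estimate,
               p.value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ranks <- apply(m, 2L, rank)
  attr(out, "rank_table") <- cbind(resim_rank = rank(resim_scores), ranks)
  out
}
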