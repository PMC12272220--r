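#' Test-retest pattern similarity
#'
#' One subject's measure map from two sessions, correlated across regions
#' (Pearson). Region pairs where either session is `NaN` are dropped
#' pairwise; at least 3 finite pairs are required.
#'
#' @param measure_s1,measure_s2 Per-region (per-pair) numeric vectors from
#'   session 1 and 2, same region set.
#' @return Pearson correlation across regions.
#' @export
pattern_similarity <- function(measure_s1, measure_s2) {
  if (length(measure_s1) != length(measure_s2))
    stop("session vectors must cover the same region set")
  ok <- is.finite(measure_s1) & is.finite(measure_s2)
  if (sum(ok) < 3)
    stop("fewer than 3 finite region pairs after pairwise deletion")
  if (stats::sd(measure_s1[ok]) == 0 || stats::sd(measure_s2[ok]) == 0) {
    warning("constant measure map in one session; similarity undefined")
    return(NA_real_)
  }
  stats::cor(measure_s1[ok], measure_s2[ok])
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation — the standard test-retest coefficient. From the two-way
#' ANOVA mean squares (rows = subjects, columns = sessions):
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' Session offsets count against agreement, so ICC(2,1) drops when a
#' constant shift separates the sessions; the coefficient can be negative.
#'
#' @param measurements subjects x sessions numeric matrix, complete, with at
#'   least 3 subjects and 2 sessions.
#' @return List: `icc`, and the mean squares `ms_rows`, `ms_cols`,
#'   `ms_error`. `icc` is `NaN` (with a warning) for constant input.
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("ICC requires a complete subjects x sessions matrix")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 sessions")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (denom <= .Machine$double.eps * abs(ms_r + ms_c + ms_e) ||
      ss_tot == 0) {
    warning("constant measurements; ICC undefined")
    val <- NaN
  } else {
    val <- (ms_r - ms_e) / denom
  }
  list(icc = val, ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e)
}

#' Reliability of a cohort's measure maps across two sessions
#'
#' @param s1,s2 subjects x regions matrices of one measure (e.g. HoFC) in
#'   sessions 1 and 2.
#' @return List: `pattern_similarity` (per-subject vector) and `icc`
#'   (per-region vector of ICC(2,1)).
#' @export
reliability_summary <- function(s1, s2) {
  stopifnot(identical(dim(s1), dim(s2)))
  ps <- vapply(seq_len(nrow(s1)), function(i)
    pattern_similarity(s1[i, ], s2[i, ]), numeric(1))
  iccs <- vapply(seq_len(ncol(s1)), function(j)
    icc(cbind(s1[, j], s2[, j]))$icc, numeric(1))
  names(iccs) <- colnames(s1)
  names(ps) <- rownames(s1)
  list(pattern_similarity = ps, icc = iccs)
}
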