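#' Parcellated BOLD time series
#'
#' Thin container for a frames x regions numeric matrix plus its sampling
#' interval. All post-processing operations take and return this class and
#' guarantee finite values on output.
#'
#' @param data Numeric matrix, frames x regions. Column names, when present,
#'   are region labels matched against a homotopic atlas downstream.
#' @param tr Sampling interval (repetition time) in seconds, > 0.
#' @param run_id Identifier for the run.
#' @param frame_keep_mask Optional logical vector marking frames retained
#'   after fixation-block removal; `NULL` means all frames kept.
#' @return A `parcel_ts` object.
#' @export
parcel_ts <- function(data, tr, run_id = "run", frame_keep_mask = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (!all(is.finite(data))) stop("time-series data contains non-finite values")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0) stop("tr must be > 0")
  if (!is.null(frame_keep_mask) && length(frame_keep_mask) != nrow(data))
    stop("frame_keep_mask length must equal the number of frames")
  structure(list(data = data, tr = tr, run_id = as.character(run_id),
                 frame_keep_mask = frame_keep_mask),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat("parcel_ts '", x$run_id, "': ", nrow(x$data), " frames x ",
      ncol(x$data), " regions, tr = ", x$tr, " s\n", sep = "")
  invisible(x)
}

as_parcel_data <- function(ts) {
  if (inherits(ts, "parcel_ts")) ts$data else as.matrix(ts)
}

# lm.fit residuals with the response's matrix shape and dimnames kept
resid_matrix <- function(X, y) {
  r <- stats::lm.fit(X, y)$residuals
  r <- matrix(r, nrow = nrow(y), ncol = ncol(y))
  dimnames(r) <- dimnames(y)
  r
}

replace_data <- function(ts, data) {
  stopifnot(inherits(ts, "parcel_ts"))
  ts$data <- data
  ts
}

#' Remove linear trends from each region
#'
#' Each column is replaced by its residual from an ordinary least-squares fit
#' on an intercept and a linear ramp, removing slow scanner drift. Column
#' means are exactly zero afterwards.
#'
#' @param ts A `parcel_ts` with at least 3 frames.
#' @return Detrended `parcel_ts`.
#' @export
linear_detrend <- function(ts) {
  x <- as_parcel_data(ts)
  n <- nrow(x)
  if (n < 3) stop("linear detrending needs at least 3 frames")
  X <- cbind(1, seq_len(n))
  replace_data(ts, resid_matrix(X, x))
}

#' Expand 6 rigid-body motion parameters to the Friston-24 set
#'
#' The 24-regressor head-motion model: the 6 parameters, their one-frame
#' lags (first frame zero-padded), and the squares of both.
#'
#' @param motion6 frames x 6 numeric matrix.
#' @return frames x 24 matrix, column blocks in the order
#'   \[p(t), p(t-1), p(t)^2, p(t-1)^2\].
#' @export
expand_friston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6)
    stop("motion matrix must have exactly 6 columns, got ", ncol(motion6))
  lag1 <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  out <- cbind(motion6, lag1, motion6^2, lag1^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_lag"),
                     paste0("p", 1:6, "_sq"), paste0("p", 1:6, "_lag_sq"))
  out
}

#' Regress nuisance confounds out of every region
#'
#' Residualizes each column on an intercept plus the supplied confound
#' columns (e.g. Friston-24 motion expansion, mean white-matter and CSF
#' signals). Residuals are exactly orthogonal to the confounds.
#'
#' @param ts A `parcel_ts`.
#' @param confounds frames x k numeric matrix; `k = 0` (or `NULL`) reduces to
#'   mean-centering.
#' @return Residual `parcel_ts`.
#' @export
nuisance_regress <- function(ts, confounds = NULL) {
  x <- as_parcel_data(ts)
  if (is.null(confounds) || NCOL(confounds) == 0 || length(confounds) == 0) {
    res <- scale(x, center = TRUE, scale = FALSE)
    attr(res, "scaled:center") <- NULL
    dimnames(res) <- dimnames(x)
    return(replace_data(ts, res))
  }
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(x))
    stop("confounds must have the same number of frames as the series")
  X <- cbind(intercept = 1, confounds)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    if (is.null(dropped)) dropped <- q$pivot[(q$rank + 1):ncol(X)]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  replace_data(ts, resid_matrix(X, x))
}

butter_check_band <- function(tr, freqs) {
  nyq <- 1 / (2 * tr)
  if (any(freqs <= 0) || any(freqs >= nyq))
    stop("filter band must lie strictly inside (0, ", signif(nyq, 4),
         ") Hz for tr = ", tr, " s")
}

#' Temporal band-pass / high-pass filtering
#'
#' Zero-phase (forward-backward) application of an order-2 Butterworth
#' design. `bandpass_filter()` is the resting-state default (0.01-0.1 Hz);
#' `highpass_filter()` is used for task runs (> 0.01 Hz).
#'
#' @param ts A `parcel_ts`.
#' @param low,high Band edges in Hz; must lie inside (0, Nyquist).
#' @param cutoff High-pass cutoff in Hz.
#' @return Filtered `parcel_ts`, same length as input.
#' @export
bandpass_filter <- function(ts, low = 0.01, high = 0.1) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (low >= high) stop("low edge must be below high edge")
  butter_check_band(ts$tr, c(low, high))
  w <- c(low, high) * 2 * ts$tr       # normalized to Nyquist
  flt <- signal::butter(2, w, type = "pass")
  apply_filtfilt(ts, flt)
}

#' @rdname bandpass_filter
#' @export
highpass_filter <- function(ts, cutoff = 0.01) {
  stopifnot(inherits(ts, "parcel_ts"))
  butter_check_band(ts$tr, cutoff)
  flt <- signal::butter(2, cutoff * 2 * ts$tr, type = "high")
  apply_filtfilt(ts, flt)
}

apply_filtfilt <- function(ts, flt) {
  x <- ts$data
  out <- apply(x, 2, function(col) signal::filtfilt(flt, col))
  dimnames(out) <- dimnames(x)
  replace_data(ts, out)
}

#' Build HRF-convolved task regressors
#'
#' One column per non-fixation condition: a boxcar that is 1 while an event
#' of that condition is on, convolved with the canonical double-gamma
#' hemodynamic response and truncated to the run length. Overlapping events
#' within one condition are merged with a warning.
#'
#' @param events Event data.frame (`onset`, `duration`, `condition`).
#' @param tr Sampling interval (s).
#' @param n_frames Number of frames in the run.
#' @return frames x conditions numeric matrix (zero columns if no task
#'   events).
#' @export
build_task_regressors <- function(events, tr, n_frames) {
  events <- validate_events(events)
  run_len <- n_frames * tr
  if (nrow(events) > 0 && any(events$onset + events$duration > run_len + 1e-9))
    stop("event extends beyond the run duration (", run_len, " s)")
  conds <- setdiff(unique(events$condition), fixation_condition())
  out <- matrix(0, n_frames, length(conds),
                dimnames = list(NULL, conds))
  if (length(conds) == 0) return(out)
  t_frames <- (seq_len(n_frames) - 1) * tr
  hrf <- double_gamma_hrf(tr)
  for (cn in conds) {
    ev <- events[events$condition == cn, , drop = FALSE]
    box <- rep(0, n_frames)
    covered <- rep(FALSE, n_frames)
    overlap <- FALSE
    for (i in seq_len(nrow(ev))) {
      on <- t_frames >= ev$onset[i] & t_frames < ev$onset[i] + ev$duration[i]
      if (any(on & covered)) overlap <- TRUE
      covered <- covered | on
    }
    if (overlap)
      warning("overlapping events merged within condition '", cn, "'")
    box[covered] <- 1
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_frames)]
    out[, cn] <- conv
  }
  out
}

#' Background-connectivity residuals of a task run
#'
#' Removes the across-trial mean task response by regressing every region on
#' an intercept plus the HRF-convolved task regressors, then discards frames
#' whose midpoint falls inside a fixation block. The regression is fit on all
#' frames; fixation frames are dropped from the residuals afterwards, so the
#' HRF tails stay estimable.
#'
#' @param ts A `parcel_ts`.
#' @param events Event data.frame; fixation blocks use the reserved
#'   condition name `"fixation"`.
#' @return `parcel_ts` of residuals restricted to non-fixation frames, with
#'   `frame_keep_mask` recording which original frames survived.
#' @export
task_background_residuals <- function(ts, events) {
  stopifnot(inherits(ts, "parcel_ts"))
  events <- validate_events(events)
  x <- ts$data
  n <- nrow(x)
  X <- build_task_regressors(events, ts$tr, n)
  res <- resid_matrix(cbind(1, X), x)

  mid <- (seq_len(n) - 1) * ts$tr + ts$tr / 2
  fix <- events[events$condition == fixation_condition(), , drop = FALSE]
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(fix)))
    keep <- keep & !(mid >= fix$onset[i] & mid < fix$onset[i] + fix$duration[i])
  if (!any(keep)) stop("all frames fall inside fixation blocks")
  out <- parcel_ts(res[keep, , drop = FALSE], ts$tr, ts$run_id)
  out$frame_keep_mask <- keep
  out
}

#' Concatenate runs after per-run standardization
#'
#' Each run's columns are standardized (mean 0, sd 1) before rows are
#' stacked, so run-specific offsets and scale differences cannot masquerade
#' as cross-run correlation.
#'
#' @param runs List of `parcel_ts` with identical region count and tr.
#' @return One concatenated `parcel_ts`.
#' @export
concatenate_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  p <- ncol(as_parcel_data(runs[[1]]))
  tr <- runs[[1]]$tr
  pieces <- lapply(runs, function(r) {
    x <- as_parcel_data(r)
    if (ncol(x) != p) stop("region count mismatch between runs")
    if (abs(r$tr - tr) > 1e-12) stop("tr mismatch between runs")
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stop("constant region in run '", r$run_id, "' cannot be standardized")
    scale(x)
  })
  out <- do.call(rbind, pieces)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  colnames(out) <- colnames(as_parcel_data(runs[[1]]))
  parcel_ts(out, tr, run_id = paste(vapply(runs, `[[`, "", "run_id"),
                                    collapse = "+"))
}

#' Standard resting-state post-processing chain
#'
#' detrend -> nuisance regression -> band-pass, the fixed order used for
#' resting runs.
#'
#' @param ts A `parcel_ts`.
#' @param confounds Optional frames x k confound matrix.
#' @param band Length-2 band edges in Hz.
#' @return Processed `parcel_ts`.
#' @export
prep_rest <- function(ts, confounds = NULL, band = c(0.01, 0.1)) {
  ts <- linear_detrend(ts)
  ts <- nuisance_regress(ts, confounds)
  bandpass_filter(ts, band[1], band[2])
}

#' Task-run post-processing chain
#'
#' nuisance regression -> high-pass -> task-event regression ->
#' fixation-frame removal. Combine several runs with [concatenate_runs()].
#'
#' @param ts A `parcel_ts`.
#' @param events Event table for the run.
#' @param confounds Optional confound matrix.
#' @param cutoff High-pass cutoff in Hz.
#' @return Residual `parcel_ts` on non-fixation frames.
#' @export
prep_task <- function(ts, events, confounds = NULL, cutoff = 0.01) {
  ts <- nuisance_regress(ts, confounds)
  ts <- highpass_filter(ts, cutoff)
  task_background_residuals(ts, events)
}
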