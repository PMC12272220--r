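#' Functional connectivity matrix from a time series
#'
#' Pearson correlation between the BOLD series of every pair of regions.
#'
#' @param ts A `parcel_ts` (or plain frames x regions matrix) with at least
#'   3 frames and no constant column.
#' @return An `fc_matrix` on the `r` scale: symmetric, unit diagonal, region
#'   labels carried as dimnames.
#' @export
fc_matrix <- function(ts) {
  x <- as_parcel_data(ts)
  if (nrow(x) < 3) stop("correlation needs at least 3 frames")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    lab <- colnames(x)[sds == 0]
    if (is.null(lab)) lab <- which(sds == 0)
    stop("constant region(s): ", paste(lab, collapse = ", "))
  }
  r <- stats::cor(x)
  new_fc(r, scale = "r")
}

#' Wrap an existing matrix as an FC matrix
#'
#' For precomputed connectivity matrices (e.g. population covariances or
#' matrices read from disk).
#'
#' @param values Symmetric numeric matrix.
#' @param scale `"r"` (correlations) or `"z"` (Fisher-transformed).
#' @return An `fc_matrix`.
#' @export
as_fc_matrix <- function(values, scale = c("r", "z")) {
  new_fc(values, match.arg(scale))
}

new_fc <- function(values, scale = c("r", "z")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("FC matrix must be square")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-10)
    stop("FC matrix must be symmetric")
  structure(values, scale = scale, class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("fc_matrix (", attr(x, "scale"), " scale), ", nrow(x), " regions\n",
      sep = "")
  print(unclass(x[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))]))
  invisible(x)
}

#' Fisher r-to-z transformation
#'
#' `atanh` applied elementwise to off-diagonal correlations, the standard
#' variance-stabilizing step before averaging or comparing FC values. The
#' diagonal (self-correlation) is undefined on the z scale and stored as
#' `NaN`.
#'
#' @param fc An `fc_matrix` on the `r` scale with all off-diagonal |r| < 1.
#' @return An `fc_matrix` on the `z` scale.
#' @export
fisher_z <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (attr(fc, "scale") != "r") stop("input is already on the z scale")
  r <- unclass(fc)
  off <- abs(r) >= 1
  diag(off) <- FALSE
  if (any(off))
    stop("off-diagonal |r| = 1 (degenerate, perfectly correlated regions)")
  z <- atanh(r)
  diag(z) <- NaN
  new_fc(z, scale = "z")
}

#' Average two FC matrices
#'
#' Elementwise mean, used to combine the two phase-encoding runs of a
#' session into one final z-scale matrix.
#'
#' @param z_a,z_b `fc_matrix` objects of identical shape and scale.
#' @return `fc_matrix` of the same scale.
#' @export
average_fc <- function(z_a, z_b) {
  stopifnot(inherits(z_a, "fc_matrix"), inherits(z_b, "fc_matrix"))
  if (!identical(dim(z_a), dim(z_b)))
    stop("FC matrices differ in shape")
  if (!identical(attr(z_a, "scale"), attr(z_b, "scale")))
    stop("FC matrices differ in scale")
  new_fc((unclass(z_a) + unclass(z_b)) / 2, scale = attr(z_a, "scale"))
}

fc_index <- function(z, atlas, labels) {
  if (!is.null(rownames(z))) {
    miss <- setdiff(labels, rownames(z))
    if (length(miss) > 0)
      stop("regions missing from FC matrix: ", paste(miss, collapse = ", "))
    match(labels, rownames(z))
  } else {
    if (nrow(z) != n_regions(atlas))
      stop("unlabelled FC matrix size does not match the atlas")
    atlas$region_index[labels]
  }
}

#' Homotopic functional connectivity
#'
#' HoFC of pair i is the z-scale FC between the pair's left region and its
#' mirror-position counterpart in the right hemisphere. Indexing is by
#' region label, so any column ordering of the underlying series gives the
#' same answer.
#'
#' @param z `fc_matrix` on the z scale.
#' @param atlas A `homotopic_atlas`.
#' @return Named numeric vector, one value per pair (z units).
#' @export
hofc <- function(z, atlas) {
  stopifnot(inherits(z, "fc_matrix"), attr(z, "scale") == "z")
  li <- fc_index(z, atlas, atlas$pairs$left)
  ri <- fc_index(z, atlas, atlas$pairs$right)
  stats::setNames(unclass(z)[cbind(li, ri)], atlas$pairs$pair_id)
}

#' Intrahemispheric functional integration
#'
#' For each pair, the signed sum of z-scale FC between the pair's left
#' region and every other left-hemisphere region (L), and likewise on the
#' right (R). Positive and negative correlations both count; the region
#' itself and all opposite-hemisphere regions are excluded.
#'
#' @param z `fc_matrix` on the z scale.
#' @param atlas A `homotopic_atlas`.
#' @return List with named per-pair vectors `L` and `R`.
#' @export
intra_integration <- function(z, atlas) {
  stopifnot(inherits(z, "fc_matrix"), attr(z, "scale") == "z")
  zz <- unclass(z)
  left_idx <- fc_index(z, atlas, atlas$pairs$left)
  right_idx <- fc_index(z, atlas, atlas$pairs$right)
  sum_within <- function(idx) {
    if (length(idx) < 2) {
      warning("hemisphere has a single region; integration sums are 0")
      return(stats::setNames(rep(0, length(idx)), atlas$pairs$pair_id))
    }
    block <- zz[idx, idx, drop = FALSE]
    diag(block) <- 0          # self excluded (diagonal is NaN on z scale)
    stats::setNames(rowSums(block), atlas$pairs$pair_id)
  }
  list(L = sum_within(left_idx), R = sum_within(right_idx))
}

#' Laterality index of intrahemispheric integration
#'
#' `LI_i = |L_i - R_i| / (|L_i| + |R_i|)`, in \[0, 1\]: 0 means perfectly
#' symmetric integration, 1 fully lateralized. When `|L| + |R| = 0` the
#' index is undefined and returned as `NaN` with a warning.
#'
#' @param L,R Numeric vectors of equal length (left / right integration).
#' @return Numeric vector of laterality indices.
#' @export
laterality_index <- function(L, R) {
  if (length(L) != length(R)) stop("L and R must have the same length")
  denom <- abs(L) + abs(R)
  out <- abs(L - R) / denom
  if (any(denom == 0, na.rm = TRUE)) {
    warning("zero total integration; LI undefined (NaN) for ",
            sum(denom == 0, na.rm = TRUE), " pair(s)")
    out[denom == 0] <- NaN
  }
  out
}

#' Whole-brain mean functional connectivity
#'
#' Mean of all region-pair z values (upper triangle, diagonal excluded);
#' the per-subject global FC covariate.
#'
#' @param z `fc_matrix` on the z scale.
#' @return Scalar.
#' @export
mean_fc <- function(z) {
  stopifnot(inherits(z, "fc_matrix"), attr(z, "scale") == "z")
  zz <- unclass(z)
  mean(zz[upper.tri(zz)])
}

#' All per-subject measures from one FC matrix
#'
#' Bundles HoFC, intrahemispheric integration (L, R), the laterality index
#' and the whole-brain mean FC.
#'
#' @param z `fc_matrix` on the z scale.
#' @param atlas A `homotopic_atlas`.
#' @return A `subject_measures` list: `hofc`, `L`, `R`, `li` (per-pair
#'   vectors, z units except `li`), `mean_fc` (scalar).
#' @export
subject_measures <- function(z, atlas) {
  h <- hofc(z, atlas)
  ii <- intra_integration(z, atlas)
  li <- laterality_index(ii$L, ii$R)
  names(li) <- atlas$pairs$pair_id
  structure(list(hofc = h, L = ii$L, R = ii$R, li = li,
                 mean_fc = mean_fc(z)),
            class = "subject_measures")
}

#' @export
print.subject_measures <- function(x, ...) {
  cat("subject_measures:", length(x$hofc), "pairs; mean FC =",
      signif(x$mean_fc, 4), "\n")
  print(utils::head(data.frame(hofc = x$hofc, L = x$L, R = x$R, li = x$li), 6))
  invisible(x)
}

#' Measures for every subject of a cohort
#'
#' Convenience wrapper: correlate, Fisher-transform and measure each
#' subject's prepped series.
#'
#' @param ts_list List of `parcel_ts`, one per subject.
#' @param atlas A `homotopic_atlas`.
#' @return List with matrices `hofc`, `L`, `R`, `li` (subjects x pairs) and
#'   vector `mean_fc`.
#' @export
cohort_measures <- function(ts_list, atlas) {
  ms <- lapply(ts_list, function(ts) subject_measures(fisher_z(fc_matrix(ts)),
                                                      atlas))
  pull <- function(f) do.call(rbind, lapply(ms, `[[`, f))
  out <- list(hofc = pull("hofc"), L = pull("L"), R = pull("R"),
              li = pull("li"),
              mean_fc = vapply(ms, `[[`, numeric(1), "mean_fc"))
  rownames(out$hofc) <- rownames(out$L) <- rownames(out$R) <-
    rownames(out$li) <- names(ts_list)
  out
}
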