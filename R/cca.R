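#' Residualize and standardize a variable table
#'
#' Column-wise OLS residuals on an intercept plus the covariate design,
#' followed by standardization to mean 0, sd 1 — the preprocessing applied
#' to both variable blocks before canonical correlation. Columns with no
#' residual variance are flagged in the `"constant"` attribute and left as
#' zeros.
#'
#' @param table subjects x variables numeric matrix/data.frame.
#' @param covariates Optional subjects x k covariate matrix.
#' @return Numeric matrix of standardized residuals.
#' @export
residualize_table <- function(table, covariates = NULL) {
  X <- as.matrix(table)
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates))
    X <- stats::lm.fit(Z, X)$residuals
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  const <- sds <= .Machine$double.eps^0.5
  X[, !const] <- scale(X[, !const, drop = FALSE])
  X[, const] <- 0
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  colnames(X) <- colnames(as.matrix(table))
  attr(X, "constant") <- colnames(X)[const]
  X
}

cca_core <- function(Xc, Yc) {
  qx <- qr(Xc)
  qy <- qr(Yc)
  dx <- qx$rank
  dy <- qy$rank
  Qx <- qr.Q(qx)[, seq_len(dx), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(dy), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy))
  d <- pmin(pmax(sv$d, 0), 1)
  list(qx = qx, qy = qy, dx = dx, dy = dy, sv = sv, d = d)
}

#' Canonical correlation analysis of two variable blocks
#'
#' Plain (unregularized) CCA via the QR/SVD factorization of the whitened
#' cross-covariance, the same algorithm as MATLAB's `canoncorr`. Modes are
#' ordered by decreasing canonical correlation; weights are scaled so every
#' canonical variate has unit variance; the sign of each mode is fixed so
#' that the X-side variate correlates positively with its highest-|loading|
#' X variable.
#'
#' @param X,Y subjects x p and subjects x q numeric matrices, columns
#'   already standardized (see [residualize_table()]). A warning is issued
#'   when n <= p + q; rank-deficient blocks give a reduced-rank fit with a
#'   warning.
#' @return A `cca_result` list: `cor` (canonical correlations), `xweights`,
#'   `yweights`, `xscores`, `yscores`, `xloadings`, `yloadings`, `n`, `p`,
#'   `q`.
#' @export
cca_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same subjects")
  p <- ncol(X); q <- ncol(Y)
  if (n <= p + q)
    warning("n <= p + q; canonical correlations will be inflated")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  core <- cca_core(Xc, Yc)
  if (core$dx < p || core$dy < q)
    warning("rank-deficient block; reduced-rank fit with ",
            min(core$dx, core$dy), " mode(s)")
  nmod <- min(core$dx, core$dy)
  d <- core$d[seq_len(nmod)]
  Rx <- qr.R(core$qx)[seq_len(core$dx), seq_len(core$dx), drop = FALSE]
  Ry <- qr.R(core$qy)[seq_len(core$dy), seq_len(core$dy), drop = FALSE]
  A <- backsolve(Rx, core$sv$u[, seq_len(nmod), drop = FALSE]) * sqrt(n - 1)
  B <- backsolve(Ry, core$sv$v[, seq_len(nmod), drop = FALSE]) * sqrt(n - 1)
  # map weights back to original column positions when pivoting occurred
  A <- unpivot(A, core$qx, p)
  B <- unpivot(B, core$qy, q)
  xs <- Xc %*% A
  ys <- Yc %*% B
  xload <- stats::cor(X, xs)
  for (mode in seq_len(nmod)) {
    top <- which.max(abs(xload[, mode]))
    if (xload[top, mode] < 0) {
      A[, mode] <- -A[, mode]; B[, mode] <- -B[, mode]
      xs[, mode] <- -xs[, mode]; ys[, mode] <- -ys[, mode]
      xload[, mode] <- -xload[, mode]
    }
  }
  structure(list(cor = d, xweights = A, yweights = B, xscores = xs,
                 yscores = ys, xloadings = xload,
                 yloadings = stats::cor(Y, ys), n = n, p = p, q = q),
            class = "cca_result")
}

unpivot <- function(W, qrobj, ncols) {
  rank <- qrobj$rank
  out <- matrix(0, ncols, ncol(W))
  out[qrobj$pivot[seq_len(rank)], ] <- W
  out
}

#' @export
print.cca_result <- function(x, ...) {
  cat("cca_result:", length(x$cor), "mode(s), n =", x$n, "\n")
  cat("canonical correlations:", paste(signif(x$cor, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Bartlett's approximate chi-squared statistic
#'
#' Sequential test of the canonical correlations from mode `k` on:
#' \deqn{\chi^2_k = -(n - 1 - (p + q + 1)/2) \sum_{i \ge k} \log(1 - r_i^2)}
#' with `(p - k + 1)(q - k + 1)` degrees of freedom.
#'
#' @param canonical_rs Vector of canonical correlations.
#' @param n Number of subjects.
#' @param p,q Block widths.
#' @param k First mode included (1 tests all modes jointly).
#' @return List: `chi2`, `df`, `p`.
#' @export
bartlett_chi2 <- function(canonical_rs, n, p, q, k = 1) {
  if (k < 1 || k > length(canonical_rs)) stop("k out of range")
  rs <- canonical_rs[k:length(canonical_rs)]
  chi2 <- -(n - 1 - (p + q + 1) / 2) * sum(log(1 - rs^2))
  df <- (p - k + 1) * (q - k + 1)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Permutation test of the canonical modes
#'
#' Rows of the Y block are permuted `n_perm` times; each mode's Bartlett
#' statistic is recomputed and the add-one permutation p-value
#' `p_k = (1 + #\{perm >= observed\}) / (n_perm + 1)` reported.
#'
#' @param X,Y Standardized blocks as in [cca_fit()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List: `p_perm` (per mode), `observed_chi2`, `n_perm`.
#' @export
cca_permutation_test <- function(X, Y, n_perm = 5000, seed) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  p <- ncol(X); q <- ncol(Y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  core <- cca_core(Xc, Yc)
  nmod <- min(core$dx, core$dy)
  chi_seq <- function(d) {
    vapply(seq_len(nmod), function(k)
      bartlett_chi2(d, n, p, q, k)$chi2, numeric(1))
  }
  obs <- chi_seq(core$d[seq_len(nmod)])
  # permuting rows of Y permutes rows of its Q factor, so the QR need not
  # be recomputed inside the loop
  Qx <- qr.Q(core$qx)[, seq_len(core$dx), drop = FALSE]
  Qy <- qr.Q(core$qy)[, seq_len(core$dy), drop = FALSE]
  set.seed(seed)
  exceed <- numeric(nmod)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Qyp <- Qy[perm, , drop = FALSE]
    Qyp <- scale(Qyp, center = TRUE, scale = FALSE)
    d <- svd(crossprod(Qx, Qyp), nu = 0, nv = 0)$d
    d <- pmin(pmax(d[seq_len(nmod)], 0), 1)
    exceed <- exceed + (chi_seq(d) >= obs - 1e-12)
  }
  list(p_perm = (1 + exceed) / (n_perm + 1), observed_chi2 = obs,
       n_perm = n_perm)
}

#' Loadings of original variables on the canonical variates
#'
#' A loading is the Pearson correlation of a variable with a canonical
#' variate; |loading| > 0.3 (strictly) marks the variable as meaningfully
#' contributive.
#'
#' @param table subjects x variables matrix of the original (residualized)
#'   variables.
#' @param scores subjects x modes canonical variate scores.
#' @param threshold Contribution threshold (exclusive).
#' @return List: `loadings` (variables x modes), `contributive` (logical
#'   matrix of the same shape).
#' @export
cca_loadings <- function(table, scores, threshold = 0.3) {
  L <- stats::cor(as.matrix(table), as.matrix(scores))
  list(loadings = L, contributive = abs(L) > threshold)
}

#' Correlation between the loadings of two measures
#'
#' Correlates the per-pair loadings of two measure blocks (e.g. HoFC and
#' LI) on the same canonical mode, revealing whether they contribute in the
#' same or opposite directions.
#'
#' @param hofc_loadings,li_loadings Per-pair loading vectors of one mode.
#' @return List: `r`, `p`.
#' @export
loading_correlation <- function(hofc_loadings, li_loadings) {
  if (length(hofc_loadings) != length(li_loadings))
    stop("loading vectors differ in length")
  ct <- stats::cor.test(hofc_loadings, li_loadings)
  list(r = unname(ct$estimate), p = ct$p.value)
}
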