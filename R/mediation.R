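#' Average a per-pair measure over a region mask
#'
#' Mediation is run on mask-averaged measures to limit multiple
#' comparisons. A mask is admissible only when every required path estimate
#' is significant with the same sign across all member pairs; supplying the
#' per-pair path table enforces that rule.
#'
#' @param values subjects x pairs matrix.
#' @param mask Pair ids (column names) or column indices of the mask.
#' @param paths Optional data.frame with columns `pair_id`, `path`,
#'   `estimate`, `p`; when given, the admission rule is checked for every
#'   distinct `path`.
#' @param alpha Significance level for the admission rule.
#' @return Per-subject vector of mask means.
#' @export
mask_average <- function(values, mask, paths = NULL, alpha = 0.05) {
  values <- as.matrix(values)
  cols <- if (is.character(mask)) match(mask, colnames(values)) else
    as.integer(mask)
  if (anyNA(cols)) stop("mask names not found among pair columns")
  if (!is.null(paths)) {
    ids <- if (is.character(mask)) mask else colnames(values)[cols]
    for (pth in unique(paths$path)) {
      sub <- paths[paths$path == pth & paths$pair_id %in% ids, ]
      if (nrow(sub) < length(ids))
        stop("path table is missing entries for path '", pth, "'")
      if (any(sub$p >= alpha))
        stop("mask rejected: path '", pth,
             "' not significant in every member region")
      if (length(unique(sign(sub$estimate))) > 1)
        stop("mask rejected: path '", pth,
             "' has mixed signs across member regions")
    }
  }
  rowMeans(values[, cols, drop = FALSE])
}

# weighted bootstrap of the product of coefficients: all bootstrap Gram
# matrices are obtained from one crossproduct of the pairwise-product basis
# with the resampling-count matrix, then solved mode by mode
boot_indirect_between <- function(x, m, y, C, n_boot, seed) {
  n <- length(x)
  Z <- cbind(1, x, m, C, y)
  K <- ncol(Z)
  ij <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  P <- Z[, ij[, 1], drop = FALSE] * Z[, ij[, 2], drop = FALSE]
  set.seed(seed)
  W <- matrix(0L, n, n_boot)
  for (b in seq_len(n_boot))
    W[, b] <- tabulate(sample.int(n, n, replace = TRUE), n)
  M <- crossprod(P, W)                     # entries x boots
  a_idx <- c(1, 2, seq_len(ncol(C)) + 3)   # intercept, x, covariates
  b_idx <- c(1, 2, 3, seq_len(ncol(C)) + 3)
  G <- matrix(0, K, K)
  ut <- upper.tri(G, diag = TRUE)
  ab <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    G[ut] <- M[, b]
    G[lower.tri(G)] <- t(G)[lower.tri(G)]
    ga <- try(solve(G[a_idx, a_idx, drop = FALSE], G[a_idx, 3]),
              silent = TRUE)
    gb <- try(solve(G[b_idx, b_idx, drop = FALSE], G[b_idx, K]),
              silent = TRUE)
    if (inherits(ga, "try-error") || inherits(gb, "try-error")) next
    ab[b] <- ga[2] * gb[3]
  }
  ab[is.finite(ab)]
}

ols_coef_p <- function(X, y, col) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  kk <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - kk)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[col, col])
  tstat <- fit$coefficients[col] / se
  list(beta = unname(fit$coefficients[col]),
       p = unname(2 * stats::pt(abs(tstat), n - kk, lower.tail = FALSE)))
}

new_mediation_result <- function(a, b, c_tot, c_prime, ab_boot, n_boot,
                                 step_ps, conf_level, n) {
  qs <- stats::quantile(ab_boot, c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2),
                        names = FALSE, type = 6)
  structure(list(path_a = a, path_b = b, path_c = c_tot,
                 path_c_prime = c_prime, indirect = a * b,
                 ci_low = qs[1], ci_high = qs[2],
                 n_boot = length(ab_boot),
                 significant = qs[1] > 0 || qs[2] < 0,
                 step_ps = step_ps, conf_level = conf_level, n = n),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("mediation: a =", signif(x$path_a, 3), " b =", signif(x$path_b, 3),
      " c =", signif(x$path_c, 3), " c' =", signif(x$path_c_prime, 3), "\n")
  cat("indirect (a x b) =", signif(x$indirect, 4), " ",
      100 * x$conf_level, "% CI [", signif(x$ci_low, 4), ",",
      signif(x$ci_high, 4), "]",
      if (x$significant) " *" else "", "\n", sep = "")
  invisible(x)
}

#' Between-subject step-wise mediation with bootstrap CI
#'
#' The four-step model (e.g. age -> HoFC -> LI): total effect c from
#' `y ~ x + covariates`, path a from `m ~ x + covariates`, paths b and c'
#' from `y ~ x + m + covariates`, all on standardized variables so the
#' coefficients are reported as betas. The indirect effect `a x b` gets a
#' percentile confidence interval over subject-resampled bootstrap
#' replicates; a CI excluding 0 marks significance. The OLS decomposition
#' `c = c' + a x b` holds exactly.
#'
#' @param x,m,y Predictor, mediator, outcome (per-subject vectors).
#' @param covariates Optional covariate matrix entered in every regression.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf_level Confidence level of the percentile interval.
#' @return A `mediation_result`.
#' @export
mediate_between <- function(x, m, y, covariates = NULL, n_boot = 10000,
                            seed, conf_level = 0.95) {
  C <- if (is.null(covariates)) matrix(0, length(x), 0) else
    as.matrix(covariates)
  ok <- is.finite(x) & is.finite(m) & is.finite(y)
  if (ncol(C) > 0) ok <- ok & apply(is.finite(C), 1, all)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  C <- C[ok, , drop = FALSE]
  n <- length(x)
  if (n <= ncol(C) + 10) stop("too few complete subjects")
  for (v in list(x, m, y)) if (stats::sd(v) == 0)
    stop("zero variance in a mediation variable")
  x <- as.numeric(scale(x)); m <- as.numeric(scale(m))
  y <- as.numeric(scale(y))
  if (ncol(C) > 0) C <- scale(C)

  Xc <- cbind(1, x, C)
  Xb <- cbind(1, x, m, C)
  c_fit <- ols_coef_p(Xc, y, 2)
  a_fit <- ols_coef_p(Xc, m, 2)
  b_fit <- ols_coef_p(Xb, y, 3)
  cp_fit <- ols_coef_p(Xb, y, 2)
  ab <- boot_indirect_between(x, m, y, C, n_boot, seed)
  new_mediation_result(a_fit$beta, b_fit$beta, c_fit$beta, cp_fit$beta,
                       ab, n_boot,
                       step_ps = c(c = c_fit$p, a = a_fit$p, b = b_fit$p),
                       conf_level, n)
}

within_paths <- function(dm_s, dy_s, mbar_c, Cc) {
  if (stats::sd(dm_s) == 0) {
    # degenerate contrast (identical conditions): no mediator path
    co <- stats::lm.fit(cbind(1, mbar_c, Cc), dy_s)$coefficients
    return(list(a = mean(dm_s), b = 0, c_prime = unname(co[1])))
  }
  co <- stats::lm.fit(cbind(1, dm_s, mbar_c, Cc), dy_s)$coefficients
  list(a = mean(dm_s), b = unname(co[2]), c_prime = unname(co[1]))
}

#' Two-condition within-participant mediation
#'
#' Path-analytic model for a repeated-measures contrast (e.g. rest vs task
#' state -> change in HoFC -> change in LI): the total effect c is the mean
#' condition difference of the outcome, path a the mean difference of the
#' mediator, and paths b and c' come from regressing the outcome difference
#' on the mediator difference plus the mean-centered mediator average and
#' covariates. Differences are standardized so paths are on the beta scale;
#' the indirect effect `a x b` gets a subject-resampled percentile
#' bootstrap CI.
#'
#' @param m1,m2 Mediator under condition 1 and 2.
#' @param y1,y2 Outcome under condition 1 and 2.
#' @param covariates Optional covariates (centered internally).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @return A `mediation_result` (`path_c` = mean standardized outcome
#'   difference; `step_ps` from paired t-tests for a and c and the
#'   regression for b).
#' @export
mediate_within <- function(m1, m2, y1, y2, covariates = NULL,
                           n_boot = 10000, seed, conf_level = 0.95) {
  n <- length(m1)
  if (length(m2) != n || length(y1) != n || length(y2) != n)
    stop("condition vectors must cover the same subjects")
  if (n < 10) stop("fewer than 10 subjects")
  dm <- m2 - m1
  dy <- y2 - y1
  sdm <- stats::sd(dm); if (sdm <= .Machine$double.eps^0.5) sdm <- 1
  sdy <- stats::sd(dy); if (sdy <= .Machine$double.eps^0.5) sdy <- 1
  dm_s <- dm / sdm
  dy_s <- dy / sdy
  mbar_c <- as.numeric(scale((m1 + m2) / 2, scale = FALSE))
  Cc <- if (is.null(covariates)) matrix(0, n, 0) else
    scale(as.matrix(covariates), scale = FALSE)

  pw <- within_paths(dm_s, dy_s, mbar_c, Cc)
  c_tot <- mean(dy_s)
  # step tests: paired differences for a and c, regression slope for b
  p_a <- if (stats::sd(dm_s) == 0) 1 else
    stats::t.test(dm_s)$p.value
  p_c <- if (stats::sd(dy_s) == 0) 1 else
    stats::t.test(dy_s)$p.value
  p_b <- if (stats::sd(dm_s) == 0) 1 else
    ols_coef_p(cbind(1, dm_s, mbar_c, Cc), dy_s, 2)$p

  set.seed(seed)
  ab <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- within_paths(dm_s[idx], dy_s[idx], mbar_c[idx],
                       Cc[idx, , drop = FALSE])
    ab[b] <- pb$a * pb$b
  }
  ab <- ab[is.finite(ab)]
  if (length(ab) == 0) ab <- 0
  new_mediation_result(pw$a, pw$b, c_tot, pw$c_prime, ab, n_boot,
                       step_ps = c(c = p_c, a = p_a, b = p_b),
                       conf_level, n)
}
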