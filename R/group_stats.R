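#' Partial correlation with covariate control
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' OLS, Pearson-correlates the residuals, and tests against zero with
#' `df = n - 2 - k` (k = number of covariates).
#'
#' @param x,y Per-subject numeric vectors.
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (no intercept column).
#' @return List: `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & apply(is.finite(covariates), 1, all)
  }
  x <- x[ok]; y <- y[ok]
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(x)
  if (n <= k + 3) stop("too few complete subjects (n must exceed k + 3)")
  if (k > 0) {
    Z <- cbind(1, covariates[ok, , drop = FALSE])
    q <- qr(Z)
    if (q$rank < ncol(Z)) stop("collinear covariates in partial correlation")
    x <- qr.resid(q, x)
    y <- qr.resid(q, y)
  } else {
    x <- x - mean(x); y <- y - mean(y)
  }
  r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       n = n, df = df)
}

#' Per-zone averages of a per-pair measure
#'
#' Averages the values of all pairs belonging to the same cortical
#' hierarchy zone, per subject; `NaN` entries are ignored.
#'
#' @param values subjects x pairs matrix (or a single per-pair vector).
#' @param atlas A `homotopic_atlas`; pair order must match the columns.
#' @return subjects x zones matrix (zones present in the atlas only).
#' @export
zone_average <- function(values, atlas) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (ncol(values) != n_pairs(atlas))
    stop("values must have one column per atlas pair")
  zones <- intersect(hierarchy_zones(), unique(atlas$pairs$zone))
  out <- sapply(zones, function(zn) {
    cols <- which(atlas$pairs$zone == zn)
    rowMeans(values[, cols, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, zones))
  out
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Variance-heterogeneity-robust F test for equal group means, with
#' Welch-Satterthwaite denominator degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2, nonzero
#'   variance).
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  if (any(vapply(groups, stats::var, 1) == 0))
    stop("zero variance within a group")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(vals ~ g, var.equal = FALSE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = fit$p.value)
}

#' Games-Howell post hoc comparisons
#'
#' All pairwise group comparisons under variance heterogeneity: Welch t
#' statistics with Welch-Satterthwaite degrees of freedom, referred to the
#' studentized range distribution (the Games-Howell adjustment).
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @return data.frame with columns `group_a`, `group_b`, `t`, `df`,
#'   `p_adjusted`.
#' @export
games_howell <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  n <- vapply(groups, length, 1L)
  m <- vapply(groups, mean, 1)
  v <- vapply(groups, stats::var, 1)
  idx <- utils::combn(k, 2)
  i <- idx[1, ]; j <- idx[2, ]
  se2 <- v[i] / n[i] + v[j] / n[j]
  tstat <- unname((m[i] - m[j]) / sqrt(se2))
  df <- unname(se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                          (v[j] / n[j])^2 / (n[j] - 1)))
  p <- stats::ptukey(abs(tstat) * sqrt(2), k, df, lower.tail = FALSE)
  data.frame(group_a = nm[i], group_b = nm[j],
             t = tstat, df = df, p_adjusted = p)
}

#' Standardized GLM effect of one predictor
#'
#' OLS of the standardized outcome on the standardized predictor plus
#' covariates; reports the predictor's standardized coefficient and its
#' two-sided p-value.
#'
#' @param y Per-subject outcome.
#' @param predictor Per-subject predictor (e.g. age).
#' @param covariates Optional covariate matrix.
#' @return List: `beta`, `p`, `n`.
#' @export
glm_effect <- function(y, predictor, covariates = NULL) {
  ys <- as.numeric(scale(y))
  xs <- as.numeric(scale(predictor))
  X <- if (is.null(covariates)) cbind(1, xs) else
    cbind(1, xs, as.matrix(covariates))
  fit <- stats::lm.fit(X, ys)
  n <- length(ys)
  kk <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - kk)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tstat <- fit$coefficients[2] / se
  list(beta = unname(fit$coefficients[2]),
       p = 2 * stats::pt(abs(tstat), n - kk, lower.tail = FALSE), n = n)
}

#' Bonferroni adjustment
#'
#' @param pvals Raw p-values.
#' @param m Number of comparisons; defaults to `length(pvals)`.
#' @return Adjusted p-values, `min(1, p * m)`.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  pmin(1, pvals * m)
}

#' Paired t-test across subjects
#'
#' @param a,b Paired per-subject vectors (e.g. a measure in two states).
#' @return List: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
    stop("constant nonzero difference; t statistic undefined")
  }
  fit <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, mean_diff = unname(fit$estimate))
}

#' Fisher z test for the difference of two correlations
#'
#' Compares two correlation coefficients from samples of size `n1`, `n2`
#' via the difference of their Fisher transforms:
#' `z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p.
#'
#' @param r1,r2 Correlations with |r| < 1.
#' @param n1,n2 Sample sizes, > 3.
#' @return List: `zstat`, `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be below 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(zstat = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Per-pair association between LI and HoFC across subjects
#'
#' The headline association: for every homotopic pair, the partial
#' correlation across subjects between the laterality index and HoFC,
#' controlling the supplied covariates (typically age, sex, handedness and
#' whole-brain mean FC), with Bonferroni adjustment over pairs.
#'
#' @param li,hofc subjects x pairs matrices.
#' @param covariates Covariate matrix (subjects x k).
#' @return data.frame per pair: `pair`, `r_partial`, `p`, `p_bonferroni`,
#'   `n`.
#' @export
li_hofc_association <- function(li, hofc, covariates = NULL) {
  stopifnot(identical(dim(li), dim(hofc)))
  res <- lapply(seq_len(ncol(li)), function(j)
    partial_correlation(li[, j], hofc[, j], covariates))
  pair <- colnames(li)
  if (is.null(pair)) pair <- paste0("pair", seq_len(ncol(li)))
  out <- data.frame(pair = pair,
                    r_partial = vapply(res, `[[`, 1, "r"),
                    p = vapply(res, `[[`, 1, "p"),
                    n = vapply(res, `[[`, 1, "n"))
  out$p_bonferroni <- bonferroni(out$p, ncol(li))
  out
}
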