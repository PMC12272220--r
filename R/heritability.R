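#' Kinship matrix from a pedigree
#'
#' Recursive (tabular-method) kinship coefficients: founders are unrelated
#' and non-inbred, `phi(i,i) = 0.5 (1 + phi(f_i, m_i))`,
#' `phi(i,j) = 0.5 (phi(f_i, j) + phi(m_i, j))` for j computed before i.
#' Monozygotic co-twins are then forced to `phi = 0.5` with identical
#' relationships to everyone else. `2 * phi` is the expected additive
#' genetic sharing used by the variance-component models.
#'
#' @param pedigree A validated `pedigree` data.frame (see
#'   [read_pedigree()]).
#' @return A `kinship_matrix`: symmetric matrix with individual ids as
#'   dimnames, diagonal 0.5 for non-inbred individuals.
#' @export
kinship_from_pedigree <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  # order so parents precede children
  order_ids <- character(0)
  remaining <- ped$id
  while (length(remaining) > 0) {
    idx <- match(remaining, ped$id)
    ok <- (is.na(ped$father[idx]) | ped$father[idx] %in% order_ids) &
      (is.na(ped$mother[idx]) | ped$mother[idx] %in% order_ids)
    order_ids <- c(order_ids, remaining[ok])
    remaining <- remaining[!ok]
  }
  pos <- match(order_ids, ped$id)
  fa <- match(ped$father[pos], order_ids)
  mo <- match(ped$mother[pos], order_ids)

  phi <- matrix(0, n, n, dimnames = list(order_ids, order_ids))
  for (i in seq_len(n)) {
    pf <- if (is.na(fa[i]) || is.na(mo[i]) || fa[i] >= i || mo[i] >= i)
      0 else phi[fa[i], mo[i]]
    phi[i, i] <- 0.5 * (1 + pf)
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        v <- 0
        if (!is.na(fa[i]) && fa[i] < i) v <- v + phi[fa[i], j]
        if (!is.na(mo[i]) && mo[i] < i) v <- v + phi[mo[i], j]
        phi[i, j] <- phi[j, i] <- 0.5 * v
      }
    }
  }
  mz <- ped$mz_group[pos]
  for (g in unique(mz[!is.na(mz)])) {
    tw <- which(!is.na(mz) & mz == g)
    phi[tw[1], ] <- phi[tw[2], ] <- pmax(phi[tw[1], ], phi[tw[2], ])
    phi[, tw[1]] <- phi[, tw[2]] <- phi[tw[1], ]
    phi[tw[1], tw[2]] <- phi[tw[2], tw[1]] <- 0.5
    phi[tw[1], tw[1]] <- phi[tw[2], tw[2]] <- 0.5
  }
  # restore the input order
  back <- match(ped$id, order_ids)
  phi <- phi[back, back]
  structure(phi, class = c("kinship_matrix", "matrix", "array"))
}

#' Residualize a phenotype on the standard covariate set
#'
#' OLS residuals on an intercept plus age, sex, age^2, age x sex,
#' age^2 x sex and handedness, then standardized to unit variance — the
#' preprocessing applied before variance-component fitting.
#'
#' @param y Per-individual phenotype vector.
#' @param covariates Covariate data.frame with `age`, `sex`, `handedness`.
#' @return Standardized residual vector.
#' @export
residualize_phenotype <- function(y, covariates) {
  Z <- cbind(1, covariate_design(covariates))
  r <- stats::lm.fit(Z, y)$residuals
  s <- stats::sd(r)
  if (s <= .Machine$double.eps^0.5 * max(1, stats::sd(y)))
    stop("no residual variance after covariate adjustment")
  as.numeric(r / s)
}

#' Eigendecomposition of the additive-genetic sharing matrix
#'
#' Decomposes `2 * Phi` once so that many phenotypes on the same pedigree
#' can be fitted cheaply (the variance-component likelihood is diagonal in
#' this basis). Errors when the kinship contains no related pairs, since
#' heritability is then unidentifiable.
#'
#' @param phi Kinship matrix.
#' @return `eigen()` result of `2 * phi`.
#' @export
kinship_eigen <- function(phi) {
  K <- 2 * as.matrix(unclass(phi))
  if (max(abs(K[upper.tri(K)])) < 1e-8)
    stop("heritability unidentifiable: kinship has no related pairs")
  eigen(K, symmetric = TRUE)
}

uni_profile_loglik <- function(h2, lam, ystar) {
  d <- h2 * lam + (1 - h2)
  vhat <- mean(ystar^2 / d)
  -0.5 * (length(ystar) * log(vhat) + sum(log(d)) + length(ystar))
}

#' Univariate variance-component heritability
#'
#' Maximum-likelihood AE model: phenotypic covariance
#' `sigma2_g * (2 Phi) + sigma2_e * I`, fitted through a one-time
#' eigendecomposition of `2 Phi` (which diagonalizes the likelihood) with
#' the total variance profiled out, multi-started over
#' `h2 in \{0.1, 0.5, 0.9\}`. The p-value for `h2 = 0` uses the
#' 50:50 mixture of a point mass and chi-squared(1), the boundary-respecting
#' reference for a variance component.
#'
#' @param y Residualized phenotype (see [residualize_phenotype()]).
#' @param phi Kinship matrix.
#' @param eig Optional precomputed `eigen(2 * phi)` to reuse across many
#'   phenotypes on the same pedigree.
#' @return A `heritability_result` list: `h2`, `sigma2_g`, `sigma2_e`,
#'   `loglik`, `lrt`, `lrt_p`.
#' @export
fit_univariate_vc <- function(y, phi, eig = NULL) {
  if (is.null(eig)) eig <- kinship_eigen(phi)
  lam <- eig$values
  ystar <- as.numeric(crossprod(eig$vectors, y))
  if (length(y) < 30)
    warning("fewer than 30 individuals; h2 is weakly identified")
  best <- NULL
  for (h0 in c(0.1, 0.5, 0.9)) {
    lo <- max(0, h0 - 0.45); hi <- min(1, h0 + 0.45)
    op <- stats::optimize(uni_profile_loglik, c(lo, hi), lam = lam,
                          ystar = ystar, maximum = TRUE, tol = 1e-8)
    if (is.null(best) || op$objective > best$objective) best <- op
  }
  for (hb in c(0, 1)) {     # boundary candidates
    ll <- uni_profile_loglik(hb, lam, ystar)
    if (ll > best$objective) best <- list(maximum = hb, objective = ll)
  }
  h2 <- best$maximum
  d <- h2 * lam + (1 - h2)
  vhat <- mean(ystar^2 / d)
  ll0 <- uni_profile_loglik(0, lam, ystar)
  lrt <- max(0, 2 * (best$objective - ll0))
  p <- if (lrt <= 0) 1 else
    0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  structure(list(h2 = h2, sigma2_g = vhat * h2, sigma2_e = vhat * (1 - h2),
                 loglik = best$objective, lrt = lrt, lrt_p = p),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat("h2 =", signif(x$h2, 4), " (sigma2_g =", signif(x$sigma2_g, 4),
      ", sigma2_e =", signif(x$sigma2_e, 4), "), LRT p =",
      signif(x$lrt_p, 4), "\n")
  if (!is.null(x$rho_g))
    cat("rho_g =", signif(x$rho_g, 4), " (p =", signif(x$rho_g_p, 4),
        "), rho_e =", signif(x$rho_e, 4), "\n")
  invisible(x)
}

bi_loglik <- function(par, lam, z1, z2, fix_rho_g = NULL) {
  g1 <- exp(par[1]); g2 <- exp(par[2])
  e1 <- exp(par[3]); e2 <- exp(par[4])
  rg <- if (is.null(fix_rho_g)) tanh(par[5]) else fix_rho_g
  re <- tanh(par[length(par)])
  cg <- rg * sqrt(g1 * g2)
  ce <- re * sqrt(e1 * e2)
  a <- lam * g1 + e1
  b <- lam * cg + ce
  c <- lam * g2 + e2
  det <- a * c - b^2
  if (any(det <= 0) || any(a <= 0)) return(-1e10)
  quad <- (c * z1^2 - 2 * b * z1 * z2 + a * z2^2) / det
  -0.5 * sum(log(det) + quad)
}

#' Bivariate variance-component model: genetic correlation
#'
#' Two-trait ML fit decomposing the cross-trait covariance into a genetic
#' part `rho_g * sqrt(sigma2_g1 sigma2_g2) * (2 Phi)` and an environmental
#' part `rho_e * sqrt(sigma2_e1 sigma2_e2) * I`. The p-value for
#' `rho_g = 0` is a 1-df likelihood-ratio test against the constrained
#' refit.
#'
#' @param y1,y2 Residualized phenotypes on the same individuals.
#' @param phi Kinship matrix.
#' @param eig Optional precomputed `eigen(2 * phi)`.
#' @return A `heritability_result` with the univariate fields for trait 1
#'   plus `h2_2`, `rho_g`, `rho_e`, `rho_g_p`. `rho_g` is `NaN` with a
#'   warning when either trait has (near-)zero heritability.
#' @export
fit_bivariate_vc <- function(y1, y2, phi, eig = NULL) {
  if (is.null(eig)) eig <- kinship_eigen(phi)
  lam <- eig$values
  z1 <- as.numeric(crossprod(eig$vectors, y1))
  z2 <- as.numeric(crossprod(eig$vectors, y2))
  u1 <- fit_univariate_vc(y1, phi, eig)
  u2 <- fit_univariate_vc(y2, phi, eig)
  clamp_log <- function(x) log(max(x, 1e-4))
  base <- c(clamp_log(u1$sigma2_g), clamp_log(u2$sigma2_g),
            clamp_log(u1$sigma2_e), clamp_log(u2$sigma2_e))
  fit_once <- function(fix_rg) {
    starts <- if (is.null(fix_rg)) list(c(base, atanh(-0.5), 0),
                                        c(base, 0, 0),
                                        c(base, atanh(0.5), 0))
              else list(c(base, 0), c(base, atanh(-0.5)), c(base, atanh(0.5)))
    best <- NULL
    for (st in starts) {
      for (meth in c("BFGS", "Nelder-Mead")) {
        op <- try(stats::optim(st, bi_loglik, lam = lam, z1 = z1, z2 = z2,
                               fix_rho_g = fix_rg, method = meth,
                               control = list(fnscale = -1, maxit = 1000)),
                  silent = TRUE)
        if (inherits(op, "try-error")) next
        if (is.null(best) || op$value > best$value) best <- op
      }
    }
    if (is.null(best)) stop("bivariate variance-component fit failed")
    best
  }
  full <- fit_once(NULL)
  null <- fit_once(0)
  par <- full$par
  res <- list(h2 = exp(par[1]) / (exp(par[1]) + exp(par[3])),
              h2_2 = exp(par[2]) / (exp(par[2]) + exp(par[4])),
              sigma2_g = exp(par[1]), sigma2_e = exp(par[3]),
              loglik = full$value,
              rho_g = tanh(par[5]), rho_e = tanh(par[6]),
              lrt = NA_real_, lrt_p = NA_real_)
  lrt <- max(0, 2 * (full$value - null$value))
  res$rho_g_p <- stats::pchisq(lrt, 1, lower.tail = FALSE)
  if (u1$h2 < 0.02 || u2$h2 < 0.02) {
    warning("near-zero heritability in one trait; rho_g undefined")
    res$rho_g <- NaN
    res$rho_g_p <- NaN
  }
  class(res) <- "heritability_result"
  res
}
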