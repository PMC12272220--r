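test_that("pedigree kinship gives the classical coefficients", {
  ped <- data.frame(
    id = c("F", "M", "s1", "s2", "F2", "h1"),
    father = c(NA, NA, "F", "F", NA, "F2"),
    mother = c(NA, NA, "M", "M", NA, "M"),
    mz_group = NA)
  phi <- kinship_from_pedigree(ped)
  expect_equal(phi["s1", "s2"], 0.25)     # full siblings
  expect_equal(phi["s1", "h1"], 0.125)    # half siblings (shared mother)
  expect_equal(phi["s1", "F"], 0.25)      # parent-offspring
  expect_equal(unname(diag(phi)), rep(0.5, 6))
  expect_equal(phi["F", "M"], 0)

  mz <- data.frame(id = c("F", "M", "a", "b"),
                   father = c(NA, NA, "F", "F"),
                   mother = c(NA, NA, "M", "M"),
                   mz_group = c(NA, NA, "g", "g"))
  phimz <- kinship_from_pedigree(mz)
  expect_equal(phimz["a", "b"], 0.5)
  expect_equal(phimz["a", "F"], phimz["b", "F"])
  expect_true(all(phi[upper.tri(phi)] >= 0 & phi[upper.tri(phi)] <= 0.5))
})

test_that("phenotype residualization removes the covariate terms", {
  set.seed(30)
  n <- 200
  cov <- data.frame(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5),
                    handedness = runif(n, -100, 100))
  y <- 0.02 * cov$age + 0.5 * cov$sex + rnorm(n)
  r <- residualize_phenotype(y, cov)
  expect_equal(sd(r), 1, tolerance = 1e-12)
  expect_lt(abs(cor(r, cov$age)), 1e-8)
  expect_lt(abs(cor(r, cov$age^2 * cov$sex)), 1e-8)

  ybad <- 1 + 0.1 * cov$age - 0.3 * cov$sex
  expect_error(residualize_phenotype(ybad, cov), "no residual variance")
})

test_that("eigen fast path equals the dense multivariate likelihood", {
  ped <- make_twin_pedigree(13, 12)
  twins <- attr(ped, "twin_ids")
  phi <- kinship_from_pedigree(ped)[twins, twins]   # 50 individuals
  K <- 2 * phi
  set.seed(31)
  y <- simulate_family_phenotypes(phi, 0.5, seed = 32)[, 1]
  eig <- eigen(K, symmetric = TRUE)
  ystar <- as.numeric(crossprod(eig$vectors, y))
  for (pars in list(c(0.6, 0.7), c(0.1, 1.2), c(1.5, 0.2))) {
    sg <- pars[1]; se <- pars[2]
    d <- sg * eig$values + se
    ll_fast <- -0.5 * (sum(log(d)) + sum(ystar^2 / d))
    S <- sg * K + se * diag(50)
    ll_dense <- -0.5 * (determinant(S)$modulus + drop(y %*% solve(S, y)))
    expect_equal(ll_fast, as.numeric(ll_dense), tolerance = 1e-6)
  }
})

test_that("univariate fit recovers h2 and respects its invariances", {
  ped <- make_twin_pedigree(150, 150)
  twins <- attr(ped, "twin_ids")
  phi <- kinship_from_pedigree(ped)[twins, twins]
  y <- simulate_family_phenotypes(phi, 0.6, seed = 33)[, 1]
  fit <- fit_univariate_vc(y, phi)
  expect_lt(abs(fit$h2 - 0.6), 0.1)
  expect_lt(fit$lrt_p, 0.001)
  expect_gte(fit$sigma2_g, 0)
  expect_gte(fit$sigma2_e, 0)

  # invariant to phenotype rescaling
  fit3 <- fit_univariate_vc(3 * y, phi)
  expect_equal(fit3$h2, fit$h2, tolerance = 1e-5)
  expect_equal(fit3$lrt, fit$lrt, tolerance = 1e-5)

  # optimum beats both boundary models
  eig <- eigen(2 * phi, symmetric = TRUE)
  ystar <- as.numeric(crossprod(eig$vectors, y))
  ll_at <- function(h2) {
    d <- h2 * eig$values + (1 - h2)
    v <- mean(ystar^2 / d)
    -0.5 * (length(y) * log(v) + sum(log(d)) + length(y))
  }
  expect_gte(fit$loglik, ll_at(0) - 1e-8)
  expect_gte(fit$loglik, ll_at(1 - 1e-12) - 1e-8)

  # MZ pairs identical within pair: h2 at the upper limit
  mzped <- make_twin_pedigree(50, 0)
  mzt <- attr(mzped, "twin_ids")
  mzphi <- kinship_from_pedigree(mzped)[mzt, mzt]
  set.seed(34)
  ymz <- rep(rnorm(50), each = 2)
  fmz <- fit_univariate_vc(ymz, mzphi)
  expect_gte(fmz$h2, 0.95)

  expect_error(fit_univariate_vc(rnorm(40), diag(0.5, 40)),
               "unidentifiable")
})

test_that("bivariate fit recovers genetic correlations of either sign", {
  ped <- make_twin_pedigree(150, 150)
  twins <- attr(ped, "twin_ids")
  phi <- kinship_from_pedigree(ped)[twins, twins]
  eig <- kinship_eigen(phi)

  y <- simulate_family_phenotypes(phi, h2 = 0.5, n_traits = 2,
                                  rho_g = -0.5, seed = 35)
  fit <- fit_bivariate_vc(y[, 1], y[, 2], phi, eig)
  expect_lt(abs(fit$rho_g - (-0.5)), 0.2)
  expect_lt(fit$rho_g_p, 0.05)

  y0 <- simulate_family_phenotypes(phi, h2 = 0.5, n_traits = 2,
                                   rho_g = 0, seed = 36)
  fit0 <- fit_bivariate_vc(y0[, 1], y0[, 2], phi, eig)
  expect_lt(abs(fit0$rho_g), 0.2)

  # identical traits: both correlations at the ceiling
  y1 <- simulate_family_phenotypes(phi, h2 = 0.5, seed = 37)[, 1]
  fid <- fit_bivariate_vc(y1, y1, phi, eig)
  expect_gt(fid$rho_g, 0.98)
  expect_gt(fid$rho_e, 0.98)
})
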