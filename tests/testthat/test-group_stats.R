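test_that("partial correlation reduces to Pearson and matches closed form", {
  set.seed(17)
  x <- rnorm(60); y <- rnorm(60)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)

  z <- rnorm(50)
  x2 <- 0.5 * z + rnorm(50); y2 <- -0.4 * z + rnorm(50)
  pc <- partial_correlation(x2, y2, cbind(z))
  rxy <- cor(x2, y2); rxz <- cor(x2, z); ryz <- cor(y2, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$r, closed, tolerance = 1e-10)
  expect_equal(pc$df, 50 - 3)

  pc0 <- partial_correlation(z + rnorm(50, sd = 1e-8), y2, cbind(z))
  expect_lt(abs(pc0$r), 0.05)
  expect_error(partial_correlation(x2, y2, cbind(z, z)), "collinear")
})

test_that("zone averages are NaN-aware means within hierarchy zones", {
  atlas <- make_synthetic_atlas(6)   # one pair per zone
  v <- matrix(1:6, nrow = 1)
  za <- zone_average(v, atlas)
  expect_equal(as.numeric(za), 1:6)

  atlas2 <- make_synthetic_atlas(4, zones = "primary")
  m <- rbind(c(1, 2, 3, NaN), c(4, 4, 4, 4))
  za2 <- zone_average(m, atlas2)
  expect_equal(as.numeric(za2), c(2, 4))

  # planted zone offsets recovered
  atlas3 <- make_synthetic_atlas(12)
  offs <- stats::setNames(seq(0, 50, by = 10), hierarchy_zones())
  vals <- matrix(rep(offs[atlas3$pairs$zone], each = 5), 5) +
    matrix(rnorm(60, sd = 0.1), 5)
  za3 <- zone_average(vals, atlas3)
  expect_equal(unname(colMeans(za3)), unname(offs[colnames(za3)]),
               tolerance = 0.2)
})

test_that("Welch ANOVA reproduces the hand-computed worked example", {
  w <- welch_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(w$F, 18 / 7, tolerance = 1e-6)
  expect_equal(w$df1, 2)
  expect_equal(w$df2, 4, tolerance = 1e-6)

  same <- welch_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_error(welch_anova(list(1, c(1, 2))), "n >= 2")
  expect_error(welch_anova(list(c(1, 1), c(1, 2))), "zero variance")
})

test_that("Games-Howell flags only genuinely shifted groups", {
  set.seed(18)
  g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30) + 5)
  gh <- games_howell(g)
  expect_equal(nrow(gh), 3)
  involves_c <- gh$group_a == "c" | gh$group_b == "c"
  expect_true(all(gh$p_adjusted[involves_c] < 0.001))
  expect_true(all(gh$p_adjusted[!involves_c] > 0.05))

  # order of groups does not change the p-values
  gh2 <- games_howell(g[c("c", "b", "a")])
  key <- function(d) {
    k <- apply(cbind(d$group_a, d$group_b), 1,
               function(r) paste(sort(r), collapse = "-"))
    stats::setNames(d$p_adjusted, k)[sort(k)]
  }
  expect_equal(key(gh2), key(gh), tolerance = 1e-12)
})

test_that("GLM effects are standardized betas with valid nulls", {
  age <- seq(20, 80, length.out = 100)
  g <- glm_effect(2 * age, age)
  expect_equal(g$beta, 1, tolerance = 1e-12)

  set.seed(19)
  gp <- glm_effect(2 * age, sample(age))
  expect_lt(abs(gp$beta), 0.2)

  n <- 2000
  agez <- rnorm(n)
  y <- 0.3 * agez + rnorm(n, sd = sqrt(1 - 0.09))
  gr <- glm_effect(y, agez)
  expect_lt(abs(gr$beta - 0.3), 0.05)  # planted slope recovered
})

test_that("Bonferroni adjustment caps at one and never lowers p", {
  expect_equal(bonferroni(0.01, 190), 1)
  expect_equal(bonferroni(c(0.2, 0.04), m = 1), c(0.2, 0.04))
  set.seed(20)
  p <- runif(50)
  expect_true(all(bonferroni(p) >= p))
})

test_that("paired t-test matches the textbook formula", {
  a <- c(10, 12, 9, 14, 11)
  b <- c(8, 11, 9, 12, 10)
  res <- paired_ttest(a, b)
  d <- a - b
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$df, 4)

  eq <- paired_ttest(a, a)
  expect_equal(eq$t, 0)
  expect_error(paired_ttest(a, a - 2), "undefined")
})

test_that("Fisher z comparison of correlations is antisymmetric", {
  fz <- fisher_z_compare(0.5, 100, 0.3, 100)
  expect_equal(fz$zstat, 1.670, tolerance = 1e-3)
  expect_equal(fisher_z_compare(0.4, 80, 0.4, 120)$zstat, 0)
  sw <- fisher_z_compare(0.3, 100, 0.5, 100)
  expect_equal(sw$zstat, -fz$zstat)
  expect_equal(sw$p, fz$p)
  expect_error(fisher_z_compare(1, 10, 0.5, 10), "below 1")
})

test_that("per-pair LI~HoFC association table recovers planted coupling", {
  set.seed(21)
  n <- 150; npair <- 5
  u <- matrix(rnorm(n * npair), n)
  hofc <- 0.5 + 0.1 * u + matrix(rnorm(n * npair, sd = 0.02), n)
  li <- 0.3 - 0.08 * u + matrix(rnorm(n * npair, sd = 0.02), n)
  covs <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  tab <- li_hofc_association(li, hofc, covs)
  expect_equal(nrow(tab), npair)
  expect_true(all(tab$r_partial < 0))
  expect_true(all(tab$p_bonferroni < 0.05))
  expect_true(all(tab$p_bonferroni >= tab$p))
})
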