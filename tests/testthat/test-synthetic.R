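test_that("target covariance realizes the stated correlation structure", {
  atlas <- toy_atlas(2)
  m0 <- build_region_covariance(atlas, rho_homotopic = 0, intra_base = 0,
                                asym = 0, cross_bg = 0)
  expect_equal(unclass(m0), diag(4), ignore_attr = TRUE)

  a1 <- make_synthetic_atlas(1)
  m1 <- build_region_covariance(a1, rho_homotopic = 0.7)
  expect_equal(unclass(m1), matrix(c(1, .7, .7, 1), 2), ignore_attr = TRUE)

  # asymmetric intrahemispheric coupling: left raised, right lowered
  m2 <- build_region_covariance(toy_atlas(3, "primary"), 0.3,
                                intra_base = 0.2, asym = 0.1,
                                cross_bg = 0.05)
  expect_equal(m2["L001", "L002"], 0.25)
  expect_equal(m2["R001", "R002"], 0.15)
  expect_equal(m2["L001", "R001"], 0.3)
  expect_equal(m2["L001", "R002"], 0.05)
})

test_that("large-sample correlations match the (post-projection) targets", {
  atlas <- make_synthetic_atlas(190)
  set.seed(99)
  rho <- runif(190, 0.2, 0.8)
  asym <- rnorm(190, 0.1, 0.05)
  covm <- build_region_covariance(atlas, rho, intra_base = 0.2,
                                  asym = asym, cross_bg = 0.05)
  ts <- simulate_subject_timeseries(covm, n_frames = 100000, seed = 11)
  emp <- cor(ts$data)
  expect_lt(max(abs(emp - covm)), 0.02)
})

test_that("time-series simulation is seeded and respects AR(1) structure", {
  a <- simulate_subject_timeseries(diag(6), 5000, seed = 5)
  b <- simulate_subject_timeseries(diag(6), 5000, seed = 5)
  expect_identical(a$data, b$data)
  r <- cor(a$data)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  ar <- simulate_subject_timeseries(diag(3), 5000, ar1 = 0.9, seed = 6)
  lag1 <- vapply(1:3, function(j)
    cor(ar$data[-1, j], ar$data[-5000, j]), numeric(1))
  expect_true(all(abs(lag1 - 0.9) < 0.05))
  # AR recursion leaves the zero-lag covariance at its target
  expect_lt(max(abs(cor(ar$data) - diag(3))), 0.07)

  expect_error(simulate_subject_timeseries(matrix(c(1, 2, 2, 1), 2), 10,
                                           seed = 1),
               "positive semidefinite")
})

test_that("cohort ground truth carries the planted coupling and age nulls", {
  atlas <- make_synthetic_atlas(6)
  cfg <- simulation_config(atlas, n_subjects = 200, n_frames = 60,
                           coupling = -0.8, seed = 21)
  co <- suppressWarnings(simulate_cohort(cfg))
  tw <- reshape(co$truth, idvar = "subject_id", timevar = "pair_id",
                direction = "wide")
  cors <- vapply(seq_len(6), function(i)
    cor(tw[[paste0("hofc.P", sprintf("%03d", i))]],
        tw[[paste0("li.P", sprintf("%03d", i))]]), numeric(1))
  expect_gte(mean(cors < -0.4), 0.75)

  cfg0 <- simulation_config(atlas, n_subjects = 150, n_frames = 60,
                            age_range = c(20, 80), seed = 22)
  co0 <- suppressWarnings(simulate_cohort(cfg0))
  hof1 <- co0$truth$hofc[co0$truth$pair_id == "P001"]
  sl <- coef(lm(hof1 ~ co0$covariates$age))[2]
  expect_lt(abs(sl), 0.005)
})

test_that("the HRF has the canonical double-gamma shape", {
  h <- double_gamma_hrf(0.72)
  t <- seq(0, 32, by = 0.72)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak <- t[which.max(h)]
  expect_gte(peak, 4); expect_lte(peak, 6)
  expect_true(is.finite(sum(h) * 0.72) && sum(h) * 0.72 > 0)
  # undershoot minimum in the 12-20 s window
  trough <- t[which.min(h)]
  expect_gte(trough, 12); expect_lte(trough, 20)
})

test_that("task runs add recoverable activation on top of the background", {
  atlas <- toy_atlas(2)
  covm <- build_region_covariance(atlas, 0.4, 0.1, 0, 0.05)
  ev <- data.frame(onset = c(10, 60, 110, 160), duration = 30,
                   condition = c("A", "fixation", "A", "fixation"))
  n <- 280; tr <- 0.72
  rest <- simulate_subject_timeseries(covm, n, tr, seed = 31)
  null_task <- simulate_task_run(covm, ev, betas = 0, n, tr, seed = 31)
  expect_identical(null_task$ts$data, rest$data)

  betas <- matrix(0, 4, 1); betas[2, 1] <- 5
  act <- simulate_task_run(covm, ev, betas, n, tr, seed = 31)
  X <- build_task_regressors(ev, tr, n)
  bhat <- coef(lm(act$ts$data[, 2] ~ X))[2]
  expect_lt(abs(bhat - 5), 0.5)

  late <- data.frame(onset = 1000, duration = 30, condition = "A")
  expect_error(simulate_task_run(covm, late, 1, n, tr, seed = 1),
               "beyond the run duration")
})

test_that("family phenotypes realize the requested genetic structure", {
  ped <- make_twin_pedigree(150, 150)
  twins <- attr(ped, "twin_ids")
  phi <- kinship_from_pedigree(ped)[twins, twins]

  y0 <- simulate_family_phenotypes(phi, h2 = 0, n_traits = 3, seed = 41)
  expect_lt(max(abs(cor(y0)[upper.tri(diag(3))])), 0.07)
  mz1 <- seq(1, 300, by = 2)   # first 150 families are the MZ pairs
  expect_lt(abs(cor(y0[mz1, 1], y0[mz1 + 1, 1])), 0.15)

  y1 <- simulate_family_phenotypes(phi, h2 = 1, n_traits = 1, seed = 42)
  expect_gt(cor(y1[mz1, 1], y1[mz1 + 1, 1]), 0.99)

  y6 <- simulate_family_phenotypes(phi, h2 = 0.6, n_traits = 1, seed = 43)
  fit <- fit_univariate_vc(y6[, 1], phi)
  expect_lt(abs(fit$h2 - 0.6), 0.1)
})

test_that("a small smoke cohort simulates quickly and deterministically", {
  atlas <- make_synthetic_atlas(4)
  cfg <- simulation_config(atlas, n_subjects = 10, n_frames = 300, seed = 3)
  t0 <- Sys.time()
  co <- simulate_cohort(cfg)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$timeseries[[5]]$data, co2$timeseries[[5]]$data)
  expect_identical(co$truth, co2$truth)
  expect_equal(nrow(co$covariates), 10)
})
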