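test_that("Pearson FC matrix matches hand computation and flags degeneracy", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  fc <- fc_matrix(parcel_ts(cbind(a = x, b = y), tr = 1))
  expect_equal(fc["a", "b"], 0.8)
  expect_equal(diag(unclass(fc)), c(a = 1, b = 1))

  same <- fc_matrix(parcel_ts(cbind(x, x + 0), tr = 1))
  expect_equal(same[1, 2], 1)
  neg <- fc_matrix(parcel_ts(cbind(x, -x), tr = 1))
  expect_equal(neg[1, 2], -1)

  expect_error(fc_matrix(parcel_ts(cbind(x, rep(2, 4)), tr = 1)),
               "constant region")
  expect_error(fc_matrix(parcel_ts(cbind(x[1:2], y[1:2]), tr = 1)),
               "3 frames")
})

test_that("Fisher transform is atanh with NaN diagonal and exact inverse", {
  r <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3)
  z <- fisher_z(as_fc_matrix(r, "r"))
  expect_equal(z[1, 2], atanh(0.5))
  expect_equal(round(z[1, 2], 4), 0.5493)
  expect_equal(z[1, 3], 0)
  expect_true(all(is.nan(diag(unclass(z)))))
  back <- tanh(unclass(z)); diag(back) <- 1
  expect_lt(max(abs(back - r)), 1e-12)

  r1 <- matrix(c(1, 1, 1, 1), 2)
  expect_error(fisher_z(as_fc_matrix(r1, "r")), "degenerate")
})

test_that("FC averaging is the elementwise mean on matching scales", {
  a <- as_fc_matrix(matrix(c(NaN, .2, .2, NaN), 2), "z")
  b <- as_fc_matrix(matrix(c(NaN, .4, .4, NaN), 2), "z")
  expect_equal(average_fc(a, b)[1, 2], 0.3)
  expect_equal(average_fc(a, a)[1, 2], 0.2)
  neg <- as_fc_matrix(-unclass(a), "z")
  expect_equal(average_fc(a, neg)[1, 2], 0)
})

test_that("HoFC is the homotopic cell, found by label in any order", {
  atlas <- toy_atlas(2)
  z <- toy_z_matrix(atlas)
  z["L001", "R001"] <- z["R001", "L001"] <- 0.8
  z["L002", "R002"] <- z["R002", "L002"] <- 0.3
  h <- hofc(as_z(z), atlas)
  expect_equal(unname(h), c(0.8, 0.3))
  expect_equal(names(h), c("P001", "P002"))

  perm <- sample(colnames(z))
  h2 <- hofc(as_z(z[perm, perm]), atlas)
  expect_equal(h2, h)
})

test_that("intrahemispheric integration sums signed same-hemisphere FC", {
  atlas <- toy_atlas(2)
  z <- toy_z_matrix(atlas)
  z["L001", "L002"] <- z["L002", "L001"] <- 0.3
  ii <- intra_integration(as_z(z), atlas)
  expect_equal(unname(ii$L), c(0.3, 0.3))
  expect_equal(unname(ii$R), c(0, 0))

  big <- make_synthetic_atlas(190)
  zb <- toy_z_matrix(big, fill = 0)
  left <- big$pairs$left
  zb[left, left] <- 0.1
  diag(zb) <- NaN
  iib <- intra_integration(as_z(zb), big)
  expect_equal(unname(iib$L), rep(0.1 * 189, 190))

  # mirror-symmetric matrix gives L = R
  set.seed(8)
  atlas4 <- make_synthetic_atlas(4)
  blk <- matrix(rnorm(16), 4); blk <- (blk + t(blk)) / 2
  zm <- toy_z_matrix(atlas4, fill = 0.05)
  zm[atlas4$pairs$left, atlas4$pairs$left] <- blk
  zm[atlas4$pairs$right, atlas4$pairs$right] <- blk
  diag(zm) <- NaN
  iim <- intra_integration(as_z(zm), atlas4)
  expect_equal(iim$L, iim$R)
})

test_that("laterality index follows |L-R|/(|L|+|R|) with NaN contract", {
  expect_equal(laterality_index(0.5, 0.5), 0)
  expect_equal(laterality_index(1, 0), 1)
  expect_equal(round(laterality_index(0.8, 0.4), 4), 0.3333)
  expect_equal(laterality_index(1, -1), 1)
  expect_warning(out <- laterality_index(c(0, 1), c(0, 1)),
                 "undefined")
  expect_true(is.nan(out[1]) && out[2] == 0)
  # invariant to global rescaling
  set.seed(9)
  L <- rnorm(50); R <- rnorm(50)
  expect_equal(laterality_index(3 * L, 3 * R), laterality_index(L, R))
  expect_equal(laterality_index(-2 * L, -2 * R), laterality_index(L, R))
  li <- laterality_index(L, R)
  expect_true(all(li >= 0 & li <= 1))
})

test_that("mean FC averages the off-diagonal upper triangle", {
  z <- matrix(0.2, 3, 3); diag(z) <- NaN
  expect_equal(mean_fc(as_fc_matrix(z, "z")), 0.2)
  z2 <- matrix(NaN, 3, 3)
  z2[1, 2] <- z2[2, 1] <- 0.1
  z2[1, 3] <- z2[3, 1] <- 0.2
  z2[2, 3] <- z2[3, 2] <- 0.3
  expect_equal(mean_fc(as_fc_matrix(z2, "z")), 0.2)
  zz <- unclass(as_fc_matrix(z2, "z"))
  expect_equal(mean(zz[lower.tri(zz)]), 0.2)   # symmetric: same either way
})

test_that("subject_measures bundles exactly its components", {
  atlas <- make_synthetic_atlas(3)
  set.seed(10)
  ts <- simulate_subject_timeseries(
    build_region_covariance(atlas, 0.5, 0.2, 0.1, 0.05), 400, seed = 12)
  z <- fisher_z(fc_matrix(ts))
  sm <- subject_measures(z, atlas)
  expect_equal(sm$hofc, hofc(z, atlas))
  ii <- intra_integration(z, atlas)
  expect_equal(sm$L, ii$L)
  expect_equal(unname(sm$li), laterality_index(ii$L, ii$R),
               ignore_attr = TRUE)
  expect_equal(sm$mean_fc, mean_fc(z))
})
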