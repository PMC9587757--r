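test_that("2D directional variance hits its landmark values", {
  expect_equal(directional_variance_2d(c(45, 45, 45)), 0)
  expect_equal(directional_variance_2d(c(0, 90)), 1)
  expect_equal(directional_variance_2d(c(10, 10, NA, 10)), 0)
  expect_error(directional_variance_2d(45), "at least 2")
})

test_that("3D directional variance hits its landmark values", {
  expect_equal(directional_variance_3d(c(0, 0, 0), c(0, 0, 0)), 0)
  # equal thirds along x, y, z: isotropic tensor, lambda1 = 1/3
  expect_equal(directional_variance_3d(c(0, 90, 0), c(90, 90, 0)), 1)
  expect_error(directional_variance_3d(1, 1), "at least 2")
})

test_that("uniform random axes give variance near 1 (Monte Carlo)", {
  set.seed(42)
  n <- 1e5
  expect_equal(directional_variance_2d(runif(n, 0, 180)), 1, tolerance = 0.01)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  flip <- u[, 2] < 0
  u[flip, ] <- -u[flip, ]
  theta <- (atan2(u[, 2], u[, 1]) * 180 / pi) %% 180
  phi <- acos(pmin(1, pmax(-1, u[, 3]))) * 180 / pi
  expect_equal(directional_variance_3d(theta, phi), 1, tolerance = 0.01)
})

test_that("variance is invariant under global rotation of the axes", {
  set.seed(7)
  th <- runif(200, 0, 180)
  v0 <- directional_variance_2d(th)
  for (rho in c(15, 60, 117)) {
    expect_equal(directional_variance_2d((th + rho) %% 180), v0,
                 tolerance = 1e-9)
  }
  # 3D: rotate about z with proper axial re-canonicalization
  # (theta crossing 180 flips the axis: theta - 180 pairs with 180 - phi)
  ph <- runif(200, 0, 180)
  v3 <- directional_variance_3d(th, ph)
  th2 <- th + 40
  wrap <- th2 >= 180
  ph2 <- ifelse(wrap, 180 - ph, ph)
  th2 <- ifelse(wrap, th2 - 180, th2)
  expect_equal(directional_variance_3d(th2, ph2), v3, tolerance = 1e-9)
})

test_that("coplanar 3D axes rank like their 2D projections", {
  set.seed(11)
  draws <- replicate(20, runif(50, 0, sample(c(10, 40, 90, 180), 1)),
                     simplify = FALSE)
  v2 <- vapply(draws, directional_variance_2d, 0)
  v3 <- vapply(draws, function(th)
    directional_variance_3d(th, rep(90, length(th))), 0)
  expect_equal(order(v2), order(v3))
})

test_that("local variance map is low inside an aligned cylinder", {
  ph <- generate_fibers_3d(phantom_spec(c(64, 64, 64), 16, seed = 3,
                                        length_range = c(40, 50)))
  # exact aligned field: variance is identically ~0 on the fiber
  truth_fld <- structure(list(theta = ifelse(ph$truth$mask, ph$truth$theta, NA),
                              phi = ifelse(ph$truth$mask, ph$truth$phi, NA),
                              valid = ph$truth$mask),
                         class = "orientation_field")
  vm0 <- local_variance_map(truth_fld, neighborhood = 7, min_count = 5)
  expect_true(all(vm0[is.finite(vm0)] < 1e-9))

  # estimated field: interior stays well aligned
  fld <- orient3d(ph$image, ph$truth$mask, local_thickness(ph$truth$mask))
  vm <- local_variance_map(fld, neighborhood = 7, min_count = 5)
  deep <- distance_transform(ph$truth$mask, border = "ignore") >= 6
  sel <- deep & is.finite(vm)
  expect_gt(sum(sel), 50)
  expect_lt(median(vm[sel]), 0.05)
  expect_true(all(vm[is.finite(vm)] >= 0 & vm[is.finite(vm)] <= 1))
})

test_that("all-invalid fields give an all-NaN variance map", {
  fld <- structure(list(theta = array(NA_real_, c(6, 6, 6)),
                        phi = array(NA_real_, c(6, 6, 6)),
                        valid = array(FALSE, c(6, 6, 6))),
                   class = "orientation_field")
  vm <- local_variance_map(fld, neighborhood = 3, min_count = 2)
  expect_true(all(!is.finite(vm)))
})

test_that("depth profile averages slices and flags empty ones", {
  v <- array(NA_real_, c(4, 4, 6))
  v[, , 2] <- 0.3
  v[1:2, 1:2, 5] <- 0.8
  dp <- depth_profile(v, spacing_z = 2.5)
  expect_equal(dp$depth, (0:5) * 2.5)
  expect_equal(dp$variance_mean[2], 0.3)
  expect_equal(dp$variance_mean[5], 0.8)
  expect_true(is.na(dp$variance_mean[1]))
  expect_equal(dp$n_valid[1], 0L)
  expect_equal(dp$n_valid[2], 16L)
  expect_true(!is.unsorted(dp$depth, strictly = TRUE))
})

test_that("thickness stratification converts physical units", {
  th <- matrix(NA_real_, 10, 10)
  th[1:5, ] <- 30
  th[6:10, ] <- 10
  fld <- structure(list(theta = th, phi = NULL, valid = is.finite(th)),
                   class = "orientation_field")
  thick <- matrix(0, 10, 10)
  thick[1:5, ] <- 30; thick[6:10, ] <- 10  # px
  vm <- matrix(0.5, 10, 10)
  class(vm) <- c("variance_map", class(vm))
  # 12 um edge at 0.5 um/px = 24 px: 10 px fibers fall below, 30 above
  s <- stratify_by_thickness(fld, thick, edges = 12, spacing = 0.5, vmap = vm)
  expect_equal(levels(s$stratum), c("<12", ">=12"))
  expect_equal(sort(unique(s$thickness[s$stratum == "<12"])), 5)
  expect_equal(sort(unique(s$thickness[s$stratum == ">=12"])), 15)
})
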