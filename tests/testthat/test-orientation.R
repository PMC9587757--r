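test_that("window size follows 2d+1 with round-half-up and clamping", {
  expect_equal(window_size(5), 11L)
  expect_equal(window_size(5.4), 11L)
  expect_equal(window_size(5.5), 13L)
  expect_equal(window_size(1, range = c(3L, 201L)), 3L)
  expect_equal(window_size(150), 201L)
  expect_equal(window_size(2, range = c(9L, 201L)), 9L)
  expect_true(all(window_size(seq(0.5, 80, by = 0.37)) %% 2 == 1))
  expect_error(window_size(0), "> 0")
})

test_that("windowed summation matches the naive double loop", {
  for (seed in 1:3) {
    m <- random_blob_mask(20, 18, p = 0.5, seed = seed)
    img <- matrix(runif(length(m), 0.5, 1), nrow(m))
    win <- matrix(sample(c(5L, 9L, 15L), length(m), TRUE), nrow(m))
    for (circ in c(TRUE, FALSE)) for (expo in c(0, 1, 2)) {
      ref <- brute_orient2d(img, m, win, expo, circ)
      got <- fiberwo:::cpp_orient2d(as.vector(m), as.numeric(img),
                                    as.integer(win), dim(m), expo, circ, 4L)
      expect_equal(array(got$theta, dim(m)), ref, tolerance = 1e-9)
    }
  }
})

test_that("axis-aligned and diagonal bands are estimated exactly", {
  m <- band_mask(60, 80, 28:33)
  thick <- local_thickness(m)
  fld <- orient2d(NULL, m, thick)
  interior <- m
  interior[, c(1:10, 71:80)] <- FALSE
  expect_lt(max(angular_error_axial(fld$theta[interior & fld$valid], 0)), 1)

  # diagonal fiber along rows = columns: direction (+x, +y), theta = 45
  n <- 80
  m45 <- matrix(FALSE, n, n)
  for (i in 1:n) for (w in -3:3) {
    j <- i + w
    if (j >= 1 && j <= n) m45[j, i] <- TRUE
  }
  th45 <- local_thickness(m45)
  f45 <- orient2d(NULL, m45, th45)
  core <- m45 & f45$valid
  core[c(1:12, (n - 11):n), ] <- FALSE
  expect_lt(mean(angular_error_axial(f45$theta[core], 45)), 1.5)
})

test_that("isolated pixels and sparse neighbourhoods are invalid", {
  m <- matrix(FALSE, 21, 21)
  m[11, 11] <- TRUE
  fld <- orient2d(NULL, m, local_thickness(m))
  expect_false(any(fld$valid))
  expect_true(all(is.na(fld$theta)))
})

test_that("estimates are axial: point reflection leaves theta unchanged", {
  for (seed in 1:3) {
    m <- random_blob_mask(31, 31, p = 0.45, seed = seed + 20)
    m[16, 16] <- TRUE
    img <- matrix(1, 31, 31)
    w <- matrix(31L, 31, 31)
    res <- fiberwo:::cpp_orient2d(as.vector(m), as.numeric(img),
                                  as.integer(w), dim(m), 1, TRUE, 4L)
    th <- array(res$theta, dim(m))
    # reflect the mask through the centre pixel; centre estimate unchanged
    mr <- m[31:1, 31:1]
    resr <- fiberwo:::cpp_orient2d(as.vector(mr), as.numeric(img),
                                   as.integer(w), dim(m), 1, TRUE, 4L)
    thr <- array(resr$theta, dim(m))
    expect_equal(th[16, 16], thr[16, 16], tolerance = 1e-9)
  }
})

test_that("2D estimates are rotation-equivariant within 2 degrees", {
  base <- 10
  for (rho in c(15, 30, 60)) {
    errs <- c()
    for (ang in base + c(0, rho)) {
      n <- 140
      yy <- matrix(seq_len(n), n, n)
      xx <- t(yy)
      a <- ang * pi / 180
      perp <- abs(-(xx - n / 2) * sin(a) + (yy - n / 2) * cos(a))
      m <- perp <= 5
      fld <- orient2d(NULL, m, local_thickness(m))
      interior <- m & fld$valid & perp <= 3
      # keep away from image borders
      interior[c(1:20, (n - 19):n), ] <- FALSE
      interior[, c(1:20, (n - 19):n)] <- FALSE
      errs <- c(errs, mean(angular_error_axial(fld$theta[interior], ang)))
    }
    expect_lt(max(errs), 2)
  }
})

test_that("3D cylinders along canonical axes give the expected angles", {
  dm <- c(40, 40, 40)
  yy <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm)
  xx <- aperm(yy, c(2, 1, 3))
  # cylinder along z through the centre; interior voxels (the outermost
  # shell of a thick cylinder sees an inward-biased neighbourhood and is a
  # known limitation of windowed dyadic summation)
  mz <- (yy - 20)^2 + (xx - 20)^2 <= 36
  fz <- orient3d(NULL, mz, local_thickness(mz))
  sel <- (yy - 20)^2 + (xx - 20)^2 <= 16 & fz$valid
  sel[, , c(1:8, 33:40)] <- FALSE
  expect_lt(mean(angular_error_axial(fz$phi[sel], 0)), 2)

  # in-plane cylinder at azimuth 30 degrees
  a <- 30 * pi / 180
  zz <- aperm(array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm), c(1, 2, 3))
  zz <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  px <- xx - 20; py <- yy - 20; pz <- zz - 20
  along <- px * cos(a) + py * sin(a)
  d2 <- (px - along * cos(a))^2 + (py - along * sin(a))^2 + pz^2
  m30 <- d2 <= 25
  f30 <- orient3d(NULL, m30, local_thickness(m30))
  sel <- d2 <= 9 & f30$valid & abs(along) < 12
  expect_lt(mean(angular_error_axial(f30$theta[sel], 30)), 2.5)
  expect_lt(mean(angular_error_axial(f30$phi[sel], 90)), 2.5)
})

test_that("isotropic neighbourhoods are flagged invalid in 3D", {
  dm <- c(25, 25, 25)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  ball <- array(colSums((t(idx) - 13)^2) <= 100, dm)
  # centre voxel of a solid ball: leading eigenvalue tie
  fld <- orient3d(NULL, ball, NULL,
                  orientation_params(mode = "fixed", fixed_window = 15L),
                  tie_tol = 1e-2)
  expect_false(fld$valid[13, 13, 13])
})

test_that("finite angles stay in range and windows stay odd", {
  ph <- generate_straight_fibers_2d(
    phantom_spec(c(128, 128), c(2, 7, 13), seed = 21))
  thick <- local_thickness(ph$truth$mask)
  fld <- orient2d(ph$image, ph$truth$mask, thick)
  th <- fld$theta[fld$valid]
  expect_true(all(th >= 0 & th < 180))
  expect_true(all(fld$window_used[fld$valid] %% 2 == 1))
})

test_that("3D centre subsampling matches the full evaluation where evaluated", {
  sp <- phantom_spec(c(40, 40, 40), 6, seed = 2, length_range = c(25, 30))
  ph <- generate_fibers_3d(sp)
  thick <- local_thickness(ph$truth$mask)
  full <- orient3d(ph$image, ph$truth$mask, thick)
  idx <- which(ph$truth$mask)[c(3, 10, 50)]
  ctr <- arrayInd(idx, dim(ph$truth$mask))
  sub <- orient3d(ph$image, ph$truth$mask, thick, centers = ctr)
  expect_equal(sub$theta[idx], full$theta[idx])
  expect_equal(sub$phi[idx], full$phi[idx])
  expect_true(all(is.na(sub$theta[setdiff(which(ph$truth$mask), idx)])))
})
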