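test_that("extinction matrix straddles the isosbestic point correctly", {
  A <- extinction_matrix()
  expect_gt(A["750", "HbR"], A["750", "HbO2"])
  expect_gt(A["850", "HbO2"], A["850", "HbR"])
  expect_true(all(A > 0))
  expect_error(extinction_matrix(c(500, 850)), "outside")
})

test_that("least squares recovers random concentration pairs from b = A c", {
  A <- extinction_matrix()
  set.seed(11)
  n <- 50
  c_true <- cbind(hbr = stats::runif(n, 0.01, 2), hbo2 = stats::runif(n, 0.01, 2))
  b <- c_true %*% t(A)           # b[i, ] = A %*% c_true[i, ]
  mk <- function(v, wl) structure(matrix(v, 5, 10),
                                  class = c("compensated_image", "matrix", "array"),
                                  valid = matrix(TRUE, 5, 10), wavelength = wl)
  conc <- linear_unmix(mk(b[, 1], 750), mk(b[, 2], 850), A)
  expect_equal(as.vector(conc$c_hbr), c_true[, 1], tolerance = 1e-10)
  expect_equal(as.vector(conc$c_hbo2), c_true[, 2], tolerance = 1e-10)

  # pure-chromophore columns and linearity in b
  k <- 3.7
  bo <- mk(k * A[, "HbO2"][1], 750)
  bo2 <- mk(k * A[, "HbO2"][2], 850)
  pure <- linear_unmix(bo, bo2, A)
  expect_equal(as.vector(pure$c_hbr), rep(0, 50), tolerance = 1e-12)
  expect_equal(as.vector(pure$c_hbo2), rep(k, 50), tolerance = 1e-12)
  tripled <- linear_unmix(mk(3 * b[, 1], 750), mk(3 * b[, 2], 850), A)
  expect_equal(tripled$c_hbr, 3 * conc$c_hbr, tolerance = 1e-12)
})

test_that("sO2 is scale invariant in both the data and the extinction matrix", {
  A <- extinction_matrix()
  mk <- function(v, wl) structure(matrix(v, 2, 2),
                                  class = c("compensated_image", "matrix", "array"),
                                  valid = matrix(TRUE, 2, 2), wavelength = wl)
  b <- A %*% c(0.3, 0.7)
  s0 <- so2_map(linear_unmix(mk(b[1], 750), mk(b[2], 850), A))
  # global rescale of both images
  s1 <- so2_map(linear_unmix(mk(5 * b[1], 750), mk(5 * b[2], 850), A))
  expect_equal(unclass(s1), unclass(s0), tolerance = 1e-12)
  # global rescale of A (Grueneisen / log-convention freedom)
  A2 <- A * log(10)
  rownames(A2) <- rownames(A)
  s2 <- so2_map(linear_unmix(mk(b[1], 750), mk(b[2], 850), A2))
  expect_equal(unclass(s2), unclass(s0), tolerance = 1e-12)
  expect_equal(s0[1, 1], 70)
})

test_that("sO2 map handles pure, balanced and degenerate concentrations", {
  mkc <- function(hbr, hbo2, valid = TRUE) {
    structure(list(c_hbr = matrix(hbr, 1, 4), c_hbo2 = matrix(hbo2, 1, 4),
                   valid = matrix(valid, 1, 4),
                   negative = matrix(FALSE, 1, 4)),
              class = "concentration_maps")
  }
  expect_equal(so2_map(mkc(0, 1))[1, 1], 100)
  expect_equal(so2_map(mkc(0.5, 0.5))[1, 1], 50)
  expect_equal(so2_map(mkc(0.25, 0.75))[1, 1], 75)    # (c, 3c)
  expect_equal(so2_map(mkc(2, 6))[1, 1], 75)          # scale invariance
  # negative total -> invalid; clipping to [0, 100]
  expect_true(is.na(so2_map(mkc(-1, 0.5))[1, 1]))
  expect_equal(so2_map(mkc(-0.2, 1))[1, 1], 100)
})

test_that("fluence compensation divides by energy and fluence with a floor", {
  set.seed(2)
  p <- matrix(stats::runif(600, 0.5, 2), 20, 30)
  pa <- pa_image(p, wavelength = 750, pulse_energy = 100, pitch = 0.1)
  # constant fluence: a global rescale
  flc <- structure(list(values = matrix(2, 20, 30), pitch = 0.1,
                        wavelength = 750),
                   class = c("fluence_map_2d", "fluence_map"))
  b <- compensate_fluence(pa, flc)
  expect_equal(unclass(b), p / 100 / 2, tolerance = 1e-12, ignore_attr = TRUE)
  # deep corner below the floor: flagged, no infinities
  phi <- matrix(1, 20, 30)
  phi[18:20, 28:30] <- 1e-7
  fl <- structure(list(values = phi, pitch = 0.1, wavelength = 750),
                  class = c("fluence_map_2d", "fluence_map"))
  b2 <- compensate_fluence(pa, fl, floor_fraction = 1e-3)
  expect_true(all(attr(b2, "floor_applied")[18:20, 28:30]))
  expect_true(all(is.na(unclass(b2)[18:20, 28:30])))
  expect_true(all(is.finite(unclass(b2)[1:17, ])))
  # energy normalization can be skipped
  b3 <- compensate_fluence(pa, flc, normalize_energy = FALSE)
  expect_equal(unclass(b3), p / 2, tolerance = 1e-12, ignore_attr = TRUE)
  # raster mismatch
  bad <- structure(list(values = matrix(1, 10, 30), pitch = 0.1,
                        wavelength = 750),
                   class = c("fluence_map_2d", "fluence_map"))
  expect_error(compensate_fluence(pa, bad), "rasters differ")
})

test_that("non-negative unmixing projects infeasible pixels onto the boundary", {
  A <- extinction_matrix()
  mk <- function(v, wl) structure(matrix(v, 1, 2),
                                  class = c("compensated_image", "matrix", "array"),
                                  valid = matrix(TRUE, 1, 2), wavelength = wl)
  # a ratio 'more oxygenated than pure HbO2' forces c_hbr < 0 unconstrained
  b <- c(0.9 * A["750", "HbO2"], 1.1 * A["850", "HbO2"])
  un <- linear_unmix(mk(b[1], 750), mk(b[2], 850), A)
  expect_true(all(un$negative))
  expect_lt(un$c_hbr[1, 1], 0)
  nn <- linear_unmix(mk(b[1], 750), mk(b[2], 850), A, nonneg = TRUE)
  expect_gte(min(nn$c_hbr, nn$c_hbo2), 0)
  expect_equal(nn$c_hbr[1, 1], 0)
  # feasible pixels are untouched by the constraint
  b_ok <- A %*% c(0.4, 0.6)
  u0 <- linear_unmix(mk(b_ok[1], 750), mk(b_ok[2], 850), A)
  u1 <- linear_unmix(mk(b_ok[1], 750), mk(b_ok[2], 850), A, nonneg = TRUE)
  expect_equal(u1$c_hbr, u0$c_hbr, tolerance = 1e-12)
})

test_that("ROI means average valid pixels and fail cleanly otherwise", {
  m <- structure(matrix(80, 40, 40), class = c("so2_map", "matrix", "array"),
                 valid = matrix(TRUE, 40, 40))
  r <- roi_mean_so2(m, c(-0.5, 0.5, 0.5, 1.5), pitch = 0.1)
  expect_equal(r$mean, 80)
  half <- matrix(c(60, 100), 40, 40)
  m2 <- structure(half, class = c("so2_map", "matrix", "array"),
                  valid = matrix(TRUE, 40, 40))
  expect_equal(roi_mean_so2(m2, c(-1, 1, 1, 2), pitch = 0.1)$mean, 80)
  m3 <- m
  m3[5:15, ] <- NA
  expect_error(roi_mean_so2(m3, c(-0.5, 0.5, 0.6, 1.4), pitch = 0.1),
               "no valid")
  expect_error(roi_mean_so2(m, c(50, 60, 50, 60), pitch = 0.1),
               "does not intersect")
})

test_that("frame averaging reduces noise and keeps metadata", {
  set.seed(9)
  base <- matrix(5, 30, 30)
  frames <- lapply(1:20, function(i)
    pa_image(base + matrix(stats::rnorm(900), 30, 30), 750, 100))
  avg <- average_frames(frames)
  expect_s3_class(avg, "pa_image")
  expect_equal(attr(avg, "pulse_energy"), 100)
  expect_lt(stats::sd(avg - base), 1.5 / sqrt(20))
})

test_that("swapping the wavelength channels corrupts the estimate", {
  A <- extinction_matrix()
  mk <- function(v, wl) structure(matrix(v, 3, 3),
                                  class = c("compensated_image", "matrix", "array"),
                                  valid = matrix(TRUE, 3, 3), wavelength = wl)
  b <- A %*% c(0.04, 0.96)    # 96% saturation
  ok <- so2_map(linear_unmix(mk(b[1], 750), mk(b[2], 850), A))
  expect_equal(ok[1, 1], 96, tolerance = 1e-9)
  A_noname <- unname(A)
  swapped <- so2_map(linear_unmix(mk(b[2], 850), mk(b[1], 750), A_noname))
  expect_gt(abs(swapped[1, 1] - 96), 5)
  # and the wavelength metadata check catches the mistake when names exist
  expect_error(linear_unmix(mk(b[2], 850), mk(b[1], 750), A), "do not match")
})
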