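test_that("seeded runs are bit-identical and energy is conserved", {
  g <- tiny_grid()
  med <- absorber_medium(g, mua = 1, musp = 5, g = 0.9)
  f1 <- simulate_fluence(med, pencil_source(half_angle = 30), 750, 5e3, seed = 9)
  f2 <- simulate_fluence(med, pencil_source(half_angle = 30), 750, 5e3, seed = 9)
  expect_identical(f1$values, f2$values)
  f3 <- simulate_fluence(med, pencil_source(half_angle = 30), 750, 5e3, seed = 10)
  expect_false(identical(f1$values, f3$values))
  expect_lt(energy_imbalance(f1), 1e-6)
  expect_true(all(f1$values >= 0))
})

test_that("absorption-only transport reproduces Beer-Lambert decay", {
  g <- grid3d(c(21, 21, 200), spacing = 0.1)
  mua <- 5 # 1/cm
  med <- absorber_medium(g, mua = mua, musp = 0, g = 0)
  f <- simulate_fluence(med, pencil_source(), 750, 2e5, seed = 42)
  prof <- f$values[11, 11, ]
  z_cm <- grid_depths(g) / 10
  sel <- which(prof > 0 & z_cm < 1.0)[-(1:2)]
  fit <- stats::lm(log(prof[sel]) ~ z_cm[sel])
  slope <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  # fitted attenuation within 3 sigma of the true absorption coefficient
  expect_lt(abs(slope + mua), 3 * se + 0.05 * mua)
})

test_that("fluence scales linearly with source power and obeys 1/sqrt(n) error scaling", {
  g <- tiny_grid(c(15, 15, 30), spacing = 0.3)
  med <- absorber_medium(g, mua = 0.5, musp = 10, g = 0.9)
  src <- pencil_source(half_angle = 60)
  f1 <- simulate_fluence(med, src, 750, 2e4, seed = 3)
  src2 <- src
  src2$relative_power <- 2 * src2$relative_power
  f2 <- simulate_fluence(med, src2, 750, 2e4, seed = 3)
  # normalization is per unit delivered energy: same map either way
  expect_equal(f2$values, f1$values, tolerance = 1e-12)

  # voxelwise relative SE drops ~1/sqrt(2) when photons double
  rel_se <- function(n, seeds) {
    maps <- sapply(seeds, function(s)
      simulate_fluence(med, src, 750, n, seed = s)$values[6:10, 6:10, 5:15])
    mean(apply(maps, 1, stats::sd) / pmax(apply(maps, 1, mean), 1e-12))
  }
  r1 <- rel_se(4e3, 1:8)
  r2 <- rel_se(8e3, 11:18)
  expect_equal(r2 / r1, 1 / sqrt(2), tolerance = 0.25)
})

test_that("Henyey-Greenstein sampler has the correct mean cosine", {
  n <- 1e6
  for (g in c(0, 0.5, 0.9)) {
    ct <- paflux:::.hg_sample(n, g, seed = 77)
    se <- stats::sd(ct) / sqrt(n)
    expect_lt(abs(mean(ct) - g), 3 * se + 1e-4)
    if (g == 0) {
      # isotropic limit: uniform cosine
      expect_lt(suppressWarnings(
        stats::ks.test(ct, "punif", -1, 1)$statistic), 0.005)
    }
  }
})

test_that("cone emission stays inside the cone and matches the axis", {
  axis <- c(0, -sin(41.4 * pi / 180), cos(41.4 * pi / 180))
  d <- paflux:::.cone_sample(2e4, axis, cos(60 * pi / 180), FALSE, seed = 5)
  cosang <- d %*% axis
  expect_true(all(cosang >= cos(60 * pi / 180) - 1e-9))
  expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-9))
  # mean direction along the axis for a symmetric cone
  m <- colMeans(d)
  expect_equal(m / sqrt(sum(m^2)), axis, tolerance = 0.02)
})

test_that("isotropic point source matches diffusion theory at mid range", {
  g3 <- grid3d(c(81, 81, 81), spacing = 0.3, origin = c(-12.15, -12.15, -12.15))
  med <- absorber_medium(g3, mua = 0.1, musp = 10, g = 0.9)
  f <- simulate_fluence(med, isotropic_point_source(), 750, 1.2e5, seed = 31)
  ax <- (seq_len(81) - 0.5) * 0.3 - 12.15
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  mueff <- sqrt(3 * 0.01 * (0.01 + 1))   # 1/mm
  mfp_tr <- 1 / 1.01                     # mm
  bins <- seq(2, 8, by = 0.75) * mfp_tr
  mid <- (utils::head(bins, -1) + utils::tail(bins, -1)) / 2
  mc <- vapply(seq_along(mid), function(i)
    mean(f$values[r >= bins[i] & r < bins[i + 1]]), numeric(1))
  th <- exp(-mueff * mid) / mid
  k <- sum(mc * th) / sum(th * th)
  expect_lt(max(abs(mc / (k * th) - 1)), 0.10)
})

test_that("imaging-plane extraction crops, centers and averages correctly", {
  g <- grid3d(c(40, 9, 20), spacing = 0.5)
  med <- absorber_medium(g, mua = 1, musp = 2, g = 0.5)
  f <- simulate_fluence(med, pencil_source(half_angle = 60), 750, 2e4, seed = 2)
  f2 <- extract_imaging_plane(f, footprint = c(30, 20))
  expect_equal(dim(f2$values), c(20, 30))
  # crop is centered: column j of the slice maps to grid x-index j+5
  expect_equal(f2$values[3, 7], f$values[12, 5, 3])
  expect_error(extract_imaging_plane(f, footprint = c(64, 20)), "smaller")

  # elevation-invariant medium and source: center slice agrees with the
  # average of its neighbors (line source much wider than the averaged band)
  gw <- grid3d(c(40, 21, 20), spacing = 0.5)
  medw <- absorber_medium(gw, mua = 1, musp = 2, g = 0.5)
  line_src <- data.frame(x = 0, y = (seq_len(21) - 11) * 0.5, z = 1e-3,
                         ax = 0, ay = 0, az = 1, half_angle = 60,
                         wavelength = 750, relative_power = 1 / 21)
  fl <- simulate_fluence(medw, line_src, 750, 1.5e5, seed = 8)
  c0 <- extract_imaging_plane(fl, footprint = c(30, 20))
  cavg <- extract_imaging_plane(fl, footprint = c(30, 20), average_slices = 3)
  band <- function(v) mean(v[3:14, 10:21])
  expect_equal(band(cavg$values), band(c0$values), tolerance = 0.05)

  # left-right symmetry of a symmetric scene, after mirror averaging
  fs <- symmetrize_fluence(f2)
  expect_equal(fs$values, fs$values[, rev(seq_len(ncol(fs$values)))])
})

test_that("one_over_e_depth recovers the decay constant of an exponential profile", {
  delta <- 4.2
  pitch <- 0.074
  z <- (seq_len(500) - 0.5) * pitch
  prof <- exp(-z / delta)
  f2d <- structure(list(values = matrix(rep(prof, 11), ncol = 11),
                        pitch = pitch, wavelength = 750),
                   class = c("fluence_map_2d", "fluence_map"))
  expect_equal(one_over_e_depth(f2d, roi_start_depth = 9.2), delta,
               tolerance = pitch / 2 / delta)
  # profile that never decays to 1/e within the grid
  shallow <- structure(list(values = matrix(rep(exp(-z / 500), 11), ncol = 11),
                            pitch = pitch, wavelength = 750),
                       class = c("fluence_map_2d", "fluence_map"))
  expect_error(one_over_e_depth(shallow, 9.2), "never drops")
})

test_that("transport rejects impossible inputs", {
  g <- tiny_grid()
  med <- absorber_medium(g, wl = 750)
  expect_error(simulate_fluence(med, pencil_source(wl = 750), 850, 1e3, 1),
               "no source elements")
  away <- data.frame(x = 100, y = 100, z = -50, ax = 0, ay = 0, az = -1,
                     half_angle = 0, wavelength = 750, relative_power = 1)
  expect_error(simulate_fluence(med, away, 750, 1e3, 1), "outside the grid")
  med2 <- medium_grid(g, array(1L, g$shape), list(`1` = list()))
  expect_error(simulate_fluence(med2, pencil_source(), 750, 1e3, 1),
               "no optical properties")
})
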