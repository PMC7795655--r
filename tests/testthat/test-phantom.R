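test_that("tube phantoms build disjoint disks at the requested depths", {
  spec <- make_tube_phantom(depths = c(5, 10, 15, 20), so2 = 96)
  tm <- tube_masks(spec)
  expect_length(tm, 4)
  areas <- vapply(tm, sum, numeric(1))
  # 0.5 mm diameter disk at 74 um pitch: ~36 px
  expect_true(all(areas >= 24 & areas <= 44))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(sum(tm[[i]] & tm[[j]]), 0)
  }
  empty <- make_tube_phantom(depths = numeric(0))
  expect_equal(nrow(empty$tubes), 0)
  expect_true(all(phantom_mask(empty) == 1L))

  slab <- make_tube_phantom(depths = 12, medium_kind = "two_slab",
                            interface_depth = 8)
  m <- phantom_mask(slab)
  zc <- (seq_len(nrow(m)) - 0.5) * slab$pitch
  expect_true(all(m[zc < 8, ] == 0L))
  expect_true(all(m[zc > 8.1, ] == 1L))
  med <- phantom_medium(slab, grid3d(c(186, 8, 128), spacing = 0.296))
  expect_setequal(unique(as.vector(med$labels)), c(0L, 1L))

  expect_error(make_tube_phantom(depths = c(10, 10.2)), "overlap")
  expect_error(make_tube_phantom(depths = 50), "within the imaged depth")
})

test_that("forward model obeys the initial-pressure relation", {
  spec <- small_phantom(depths = c(6, 12), so2 = 100)
  phi <- matrix(rep(exp(-(seq_len(128) - 0.5) * 0.296 / 5), 136), 128, 136)
  fl <- function(wl) structure(list(values = phi, pitch = 0.296, wavelength = wl),
                               class = c("fluence_map_2d", "fluence_map"))
  p750 <- forward_pa_image(spec, fl(750), 750, noise_sigma = 0)
  p850 <- forward_pa_image(spec, fl(850), 850, noise_sigma = 0)
  tm <- tube_masks(spec)[[1]]
  A <- extinction_matrix()
  # inside a fully oxygenated tube the channel ratio is the HbO2 extinction
  # ratio times the energy-weighted fluence ratio (here E = 100 vs 200)
  ratio <- unclass(p750)[tm] / unclass(p850)[tm]
  expect_equal(ratio, rep((A["750", "HbO2"] * 100) / (A["850", "HbO2"] * 200),
                          sum(tm)), tolerance = 1e-12)
  # Gamma linearity
  spec2 <- spec
  spec2$grueneisen <- 2
  p2 <- forward_pa_image(spec2, fl(750), 750, noise_sigma = 0)
  expect_equal(unclass(p2), 2 * unclass(p750), tolerance = 1e-12)
  # zero absorption -> zero signal
  spec0 <- small_phantom(depths = numeric(0), medium_kind = "two_slab")
  spec0$interface_depth <- 1e6   # all water
  p0 <- forward_pa_image(spec0, fl(750), 750, noise_sigma = 0)
  water_level <- water_properties(750)$mua * 100 * max(phi)
  expect_lte(max(unclass(p0)), water_level + 1e-12)
  expect_error(forward_pa_image(spec, fl(920), 920), "pulse_energy")
})

test_that("synthetic ultrasound is reproducible, dark in water and Rayleigh in tissue", {
  spec <- make_tube_phantom(depths = numeric(0), medium_kind = "two_slab",
                            interface_depth = 8,
                            img_shape = c(256, 256), pitch = 0.148)
  us1 <- synth_us_image(spec, seed = 12)
  us2 <- synth_us_image(spec, seed = 12)
  expect_identical(unclass(us1), unclass(us2))
  water <- unclass(us1)[1:40, ]
  tissue <- unclass(us1)[80:250, ]
  expect_lt(mean(water), 0.02 * mean(tissue))

  # fully developed speckle: envelope is Rayleigh distributed
  spec_h <- make_tube_phantom(depths = numeric(0),
                              img_shape = c(320, 320), pitch = 0.148)
  ush <- synth_us_image(spec_h, seed = 3, noise_floor = 0)
  x <- as.vector(unclass(ush)[30:310, 30:310])
  sigma <- sqrt(mean(x^2) / 2)
  ks <- suppressWarnings(stats::ks.test(
    x, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_lt(unname(ks$statistic), 0.05)

  # water-only spec gives a near-zero image
  allw <- make_tube_phantom(depths = numeric(0), medium_kind = "two_slab",
                            interface_depth = 37, img_shape = c(128, 136),
                            pitch = 0.296)
  usw <- synth_us_image(allw, seed = 5)
  expect_lt(mean(unclass(usw)[1:100, ]), 0.02 * max(unclass(usw)))
})

test_that("noise-free closed loop with matching fluence maps is exact", {
  spec <- small_phantom(depths = c(5, 10), so2 = 96)
  frame <- synthetic_frame(spec, n_photons = 4e4, seed = 6,
                           noise_sigma = 0, envelope = FALSE)
  b1 <- compensate_fluence(frame$pa[["750"]][[1]], frame$fluence[["750"]])
  b2 <- compensate_fluence(frame$pa[["850"]][[1]], frame$fluence[["850"]])
  m <- so2_map(linear_unmix(b1, b2))
  for (i in seq_len(nrow(spec$tubes))) {
    r <- roi_mean_so2(m, tube_roi(spec, i), pitch = spec$pitch)
    expect_equal(r$mean, 96, tolerance = 1e-6)
  }
  # same seed regenerates the identical frame
  frame2 <- synthetic_frame(spec, n_photons = 4e4, seed = 6,
                            noise_sigma = 0, envelope = FALSE)
  expect_identical(frame$pa[["750"]][[1]], frame2$pa[["750"]][[1]])
  expect_identical(unclass(frame$us), unclass(frame2$us))
})

test_that("noise calibration places the detection limit at the requested depth", {
  spec <- small_phantom(depths = c(5, 10), so2 = 96)
  phi <- matrix(rep(exp(-(seq_len(128) - 0.5) * 0.296 / 4), 136), 128, 136)
  fl750 <- structure(list(values = phi, pitch = 0.296, wavelength = 750),
                     class = c("fluence_map_2d", "fluence_map"))
  sig <- calibrate_noise_sigma(spec, fl750, detection_depth = 6,
                               detection_ratio = 2.5)
  mua_b <- blood_mua(96, 150, 750)
  s6 <- mua_b * 100 * exp(-6 / 4)
  expect_equal(s6 / (sig * sqrt(2 / pi)), 2.5, tolerance = 1e-2)

  # SNR-targeted noise: dimmest tube/channel hits the requested SNR
  fl850 <- structure(list(values = phi, pitch = 0.296, wavelength = 850),
                     class = c("fluence_map_2d", "fluence_map"))
  sig10 <- snr_noise_sigma(spec, list(`750` = fl750, `850` = fl850),
                           snr_db = 10)
  tm <- tube_masks(spec)[[2]]                  # deepest tube
  amp750 <- mua_b * 100 * mean(phi[tm])
  expect_equal(amp750 / sig10, 10^(10 / 20), tolerance = 1e-6)
})
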