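#' Synthetic tube phantom specification
#'
#' Describes the bench experiments used to validate fluence-compensated sO2
#' imaging: blood-filled polythene tubes (0.5 mm inner diameter, optically
#' transparent walls) crossing the imaging plane at chosen depths, embedded
#' either in a homogeneous soft-tissue-mimicking medium or in a two-slab
#' medium (water coupling layer over the tissue slab).
#'
#' @param depths tube center depths, mm.
#' @param so2 blood oxygen saturation in the tubes, percent (scalar or one
#'   value per tube).
#' @param medium_kind `"homogeneous"` or `"two_slab"`.
#' @param interface_depth water/tissue interface depth for two-slab media,
#'   mm.
#' @param lateral_offsets tube center lateral offsets from the image axis,
#'   mm (scalar or one per tube).
#' @param tube_diameter inner diameter, mm.
#' @param thb total hemoglobin in the tubes, g/L-equivalent (only ratios
#'   matter for sO2).
#' @param grueneisen thermoelastic conversion efficiency Gamma
#'   (dimensionless, arbitrary scale).
#' @param medium_preset tissue preset name for the background medium
#'   (see [medium_presets()]).
#' @param img_shape image raster `c(depth_px, width_px)`.
#' @param pitch image pixel pitch, mm.
#' @return list of class `phantom_spec`; `$tubes` is a data frame with one
#'   row per tube (`x`, `z`, `diameter`, `so2`, `thb`).
#' @export
make_tube_phantom <- function(depths,
                              so2 = 96,
                              medium_kind = c("homogeneous", "two_slab"),
                              interface_depth = 8,
                              lateral_offsets = 0,
                              tube_diameter = 0.5,
                              thb = 150,
                              grueneisen = 1,
                              medium_preset = "soft_tissue_phantom",
                              img_shape = c(512, 545),
                              pitch = 0.074) {
  medium_kind <- match.arg(medium_kind)
  n <- length(depths)
  so2 <- rep_len(so2, max(n, 1))
  lateral_offsets <- rep_len(lateral_offsets, max(n, 1))
  stopifnot(all(so2 >= 0), all(so2 <= 100), tube_diameter > 0, thb > 0,
            grueneisen > 0, pitch > 0)
  depth_max <- img_shape[1] * pitch
  half_w <- img_shape[2] * pitch / 2
  if (n > 0) {
    r <- tube_diameter / 2
    if (any(depths - r < 0 | depths + r > depth_max)) {
      stop("tube depths must lie within the imaged depth range (0, ",
           signif(depth_max, 4), ") mm")
    }
    if (any(abs(lateral_offsets) + r > half_w)) {
      stop("tube lateral offsets place tubes outside the image")
    }
    if (n > 1) {
      centers <- cbind(lateral_offsets[seq_len(n)], depths)
      dmat <- as.matrix(stats::dist(centers))
      diag(dmat) <- Inf
      if (any(dmat < tube_diameter)) stop("tubes overlap")
    }
  }
  tubes <- if (n > 0) {
    data.frame(x = lateral_offsets[seq_len(n)], z = depths,
               diameter = tube_diameter, so2 = so2[seq_len(n)], thb = thb)
  } else {
    data.frame(x = numeric(0), z = numeric(0), diameter = numeric(0),
               so2 = numeric(0), thb = numeric(0))
  }
  structure(list(
    tubes = tubes, medium_kind = medium_kind,
    interface_depth = interface_depth,
    grueneisen = grueneisen, medium_preset = medium_preset,
    img_shape = as.integer(img_shape), pitch = pitch
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s medium, %d tube(s), raster %d x %d @ %g mm\n",
              x$medium_kind, nrow(x$tubes), x$img_shape[1], x$img_shape[2],
              x$pitch))
  invisible(x)
}

#' Ground-truth tissue mask of a phantom on the image raster
#'
#' 1 = tissue (the whole image for homogeneous media, everything below the
#' interface for two-slab media). Tubes are not part of the mask: their
#' walls are optically transparent and they are excluded from the light
#' model.
#'
#' @param spec a `phantom_spec`.
#' @return 0/1 integer matrix `[depth, lateral]`.
#' @export
phantom_mask <- function(spec) {
  nz <- spec$img_shape[1]; nx <- spec$img_shape[2]
  m <- matrix(1L, nz, nx)
  if (spec$medium_kind == "two_slab") {
    zc <- (seq_len(nz) - 0.5) * spec$pitch
    m[zc < spec$interface_depth, ] <- 0L
  }
  m
}

#' Per-tube pixel masks on the image raster
#'
#' @param spec a `phantom_spec`.
#' @return list of logical matrices, one per tube (disk cross-sections).
#' @export
tube_masks <- function(spec) {
  nz <- spec$img_shape[1]; nx <- spec$img_shape[2]
  zc <- (seq_len(nz) - 0.5) * spec$pitch
  xc <- (seq_len(nx) - 0.5) * spec$pitch
  xc <- xc - mean(xc)
  lapply(seq_len(nrow(spec$tubes)), function(i) {
    t <- spec$tubes[i, ]
    outer(zc, xc, function(z, x) (z - t$z)^2 + (x - t$x)^2 <= (t$diameter / 2)^2)
  })
}

#' Build the 3-D simulation medium of a phantom
#'
#' Extrudes the phantom's ground-truth tissue mask into a [medium_grid()]
#' using the phantom's tissue preset and water as background, at the grid's
#' pitch (the mask is block-downsampled when the grid is coarser than the
#' image raster).
#'
#' @param spec a `phantom_spec`.
#' @param grid a [grid3d()]; its spacing must be an integer multiple of the
#'   image pitch.
#' @param wavelengths wavelengths that will be simulated, nm.
#' @return a [medium_grid()].
#' @export
phantom_medium <- function(spec, grid, wavelengths = c(750, 850)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "grid3d"))
  fac <- grid$spacing / spec$pitch
  if (abs(fac - round(fac)) > 1e-9) {
    stop("grid spacing must be an integer multiple of the image pitch")
  }
  mask <- phantom_mask(spec)
  mask <- downsample_mask(mask, round(fac))
  # pad or crop depth to the grid
  nz <- grid$shape[3]
  if (nrow(mask) > nz) mask <- mask[seq_len(nz), , drop = FALSE]
  if (nrow(mask) < nz) {
    mask <- rbind(mask, matrix(mask[nrow(mask), ], nz - nrow(mask),
                               ncol(mask), byrow = TRUE))
  }
  if (ncol(mask) > grid$shape[1]) {
    x0 <- floor((ncol(mask) - grid$shape[1]) / 2)
    mask <- mask[, (x0 + 1):(x0 + grid$shape[1]), drop = FALSE]
  }
  tissue <- stats::setNames(
    lapply(wavelengths, function(w) preset_properties(spec$medium_preset, w)),
    as.character(wavelengths))
  mask_to_medium(mask, tissue_props = tissue, background_props = NULL,
                 grid = grid)
}

#' Absorption-coefficient map of a phantom on the image raster
#'
#' Background pixels take the tissue preset's (or water's) absorption; tube
#' pixels take whole-blood absorption implied by the tube's sO2 and total
#' hemoglobin through the bundled extinction spectra.
#'
#' @param spec a `phantom_spec`.
#' @param wavelength nm.
#' @param spectra extinction table, see [hb_spectra()].
#' @return matrix of absorption coefficients, 1/cm.
#' @export
phantom_mua_map <- function(spec, wavelength, spectra = hb_spectra()) {
  tissue <- preset_properties(spec$medium_preset, wavelength)
  water <- water_properties(wavelength)
  mask <- phantom_mask(spec)
  mua <- matrix(water$mua, spec$img_shape[1], spec$img_shape[2])
  mua[mask == 1L] <- tissue$mua
  tm <- tube_masks(spec)
  for (i in seq_along(tm)) {
    t <- spec$tubes[i, ]
    mua[tm[[i]]] <- blood_mua(t$so2, t$thb, wavelength, spectra)
  }
  mua
}

#' Forward PA image of a phantom under a given fluence map
#'
#' Initial-pressure forward model: `p = Gamma * mua * E * Phi` plus additive
#' Gaussian amplitude noise, optionally envelope-detected (absolute value),
#' emulating a reconstructed PA amplitude frame. Acoustic propagation and
#' band-limited detection are deliberately not modeled: the sO2 estimation
#' chain operates on reconstructed amplitude proportional to initial
#' pressure.
#'
#' @param spec a `phantom_spec`.
#' @param fl 2-D `fluence_map` on the image raster (per unit delivered
#'   energy).
#' @param wavelength nm.
#' @param spectra extinction table.
#' @param seed RNG seed for the noise draw.
#' @param noise_sigma additive Gaussian noise standard deviation in image
#'   units (0 = noise free).
#' @param envelope take the absolute value after adding noise, as envelope
#'   images do (`TRUE` by default).
#' @param pulse_energy pulse energy E at this wavelength, uJ; defaults to
#'   the standard probe values (100 uJ at 750 nm, 200 uJ at 850 nm).
#' @return a [pa_image()].
#' @export
forward_pa_image <- function(spec, fl, wavelength, spectra = hb_spectra(),
                             seed = 1, noise_sigma = 0, envelope = TRUE,
                             pulse_energy = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(fl, "fluence_map_2d"))
  if (!is.null(fl$wavelength) && fl$wavelength != wavelength) {
    stop("fluence map wavelength (", fl$wavelength,
         ") does not match requested wavelength (", wavelength, ")")
  }
  if (is.null(pulse_energy)) {
    pe <- c(`750` = 100, `850` = 200)
    if (!as.character(wavelength) %in% names(pe)) {
      stop("supply pulse_energy for wavelength ", wavelength, " nm")
    }
    pulse_energy <- pe[[as.character(wavelength)]]
  }
  phi <- fl$values
  if (!all(dim(phi) == spec$img_shape)) {
    stop("fluence map raster does not match the phantom image raster; ",
         "use resample_fluence()")
  }
  mua <- phantom_mua_map(spec, wavelength, spectra)
  p <- spec$grueneisen * mua * pulse_energy * phi
  if (noise_sigma > 0) {
    set.seed(seed)
    p <- p + matrix(stats::rnorm(length(p), sd = noise_sigma),
                    nrow(p), ncol(p))
  }
  if (envelope) p <- abs(p)
  pa_image(p, wavelength = wavelength, pulse_energy = pulse_energy,
           pitch = spec$pitch)
}

#' Calibrate the synthetic noise level to a detection depth
#'
#' Chooses the additive noise standard deviation so that the 750 nm tube
#' signal at `detection_depth` sits at `detection_ratio` times the mean
#' envelope noise floor (`sigma * sqrt(2/pi)` for a zero-mean Gaussian):
#' tubes deeper than the detection depth disappear into the noise, as they
#' do in practice for LED-based systems at these pulse energies.
#'
#' @param spec a `phantom_spec`.
#' @param fl750 2-D fluence map at 750 nm on the image raster.
#' @param detection_depth depth at which a tube is marginally detectable,
#'   mm.
#' @param detection_ratio tube amplitude over mean noise floor at the
#'   detection depth.
#' @param spectra extinction table.
#' @return noise standard deviation in the forward model's image units.
#' @export
calibrate_noise_sigma <- function(spec, fl750, detection_depth = 6,
                                  detection_ratio = 2.5,
                                  spectra = hb_spectra()) {
  stopifnot(inherits(fl750, "fluence_map_2d"))
  so2_ref <- if (nrow(spec$tubes)) spec$tubes$so2[1] else 96
  thb <- if (nrow(spec$tubes)) spec$tubes$thb[1] else 150
  mua_b <- blood_mua(so2_ref, thb, 750, spectra)
  # central-axis fluence at the detection depth
  prof <- rowMeans(fl750$values[, pmax(1, ncol(fl750$values) %/% 2 + (-2:2)),
                                drop = FALSE])
  depths <- (seq_len(nrow(fl750$values)) - 0.5) * fl750$pitch
  phi_d <- stats::approx(depths, prof, xout = detection_depth)$y
  s_tube <- spec$grueneisen * mua_b * 100 * phi_d     # E(750 nm) = 100 uJ
  s_tube / (detection_ratio * sqrt(2 / pi))
}

#' Noise level for a target tube signal-to-noise ratio
#'
#' Returns the additive noise standard deviation such that the weakest
#' tube/channel combination has the requested amplitude SNR, with SNR
#' defined on the tube-mean amplitude:
#' `snr_db = 20 log10(mean tube amplitude / sigma)`.
#'
#' @param spec a `phantom_spec`.
#' @param fl list of 2-D fluence maps on the image raster, named by
#'   wavelength (`"750"`, `"850"`).
#' @param snr_db target SNR in dB for the dimmest tube/channel.
#' @param spectra extinction table.
#' @return noise standard deviation in forward-model image units.
#' @export
snr_noise_sigma <- function(spec, fl, snr_db = 10, spectra = hb_spectra()) {
  stopifnot(nrow(spec$tubes) >= 1)
  pe <- c(`750` = 100, `850` = 200)
  tm <- tube_masks(spec)
  amp <- Inf
  for (wl in names(fl)) {
    mua_b <- vapply(seq_len(nrow(spec$tubes)), function(i)
      blood_mua(spec$tubes$so2[i], spec$tubes$thb[i], as.numeric(wl), spectra),
      numeric(1))
    for (i in seq_along(tm)) {
      a <- spec$grueneisen * mua_b[i] * pe[[wl]] *
        mean(fl[[wl]]$values[tm[[i]]])
      amp <- min(amp, a)
    }
  }
  amp / 10^(snr_db / 20)
}

#' Synthetic speckled B-mode ultrasound image of a phantom
#'
#' Fully developed speckle: two independent Gaussian scatterer fields
#' (in-phase/quadrature) restricted to the tissue region are convolved with
#' an anisotropic Gaussian point-spread kernel and envelope-detected, so
#' tissue intensities are Rayleigh distributed by construction. Water is
#' rendered dark except for a small sensor noise floor, and the water/tissue
#' interface of two-slab media carries a bright specular line, as a film
#' separator does in B-mode.
#'
#' @param spec a `phantom_spec`.
#' @param psf_sigma Gaussian PSF standard deviations in pixels,
#'   `c(axial, lateral)`.
#' @param seed RNG seed.
#' @param interface_gain brightness of the specular interface line relative
#'   to the mean tissue speckle.
#' @param noise_floor sensor noise amplitude relative to the mean tissue
#'   speckle.
#' @return matrix of class `us_image` with attributes `pitch` and
#'   `boundary_rows` (ground-truth first tissue row per column).
#' @export
synth_us_image <- function(spec, psf_sigma = c(1.2, 2.4), seed = 1,
                           interface_gain = 3, noise_floor = 0.005) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$img_shape[1]; nx <- spec$img_shape[2]
  mask <- phantom_mask(spec)
  set.seed(seed)
  re <- matrix(stats::rnorm(nz * nx), nz, nx) * mask
  im <- matrix(stats::rnorm(nz * nx), nz, nx) * mask
  ker <- .gauss_kernel(psf_sigma[1], psf_sigma[2])
  env <- sqrt(EBImage::filter2(re, ker, boundary = 0)^2 +
                EBImage::filter2(im, ker, boundary = 0)^2)
  tissue_mean <- mean(env[mask == 1L])
  if (spec$medium_kind == "two_slab") {
    # specular echo of the separating film
    irow <- round(spec$interface_depth / spec$pitch + 0.5)
    line <- matrix(0, nz, nx)
    if (irow >= 1 && irow <= nz) line[irow, ] <- 1
    line <- EBImage::filter2(line, ker, boundary = 0)
    line <- line / max(line)
    env <- env + interface_gain * tissue_mean * line
  }
  if (noise_floor > 0) {
    env <- env + noise_floor * tissue_mean *
      abs(matrix(stats::rnorm(nz * nx), nz, nx))
  }
  truth <- boundary_rows(mask)
  structure(env, class = c("us_image", "matrix", "array"),
            pitch = spec$pitch, boundary_rows = truth)
}

.gauss_kernel <- function(sz, sx) {
  rz <- max(1, ceiling(3 * sz)); rx <- max(1, ceiling(3 * sx))
  z <- (-rz):rz; x <- (-rx):rx
  k <- outer(exp(-z^2 / (2 * sz^2)), exp(-x^2 / (2 * sx^2)))
  k / sum(k)
}

#' Generate a complete synthetic frame (US + dual-wavelength PA + truth)
#'
#' Convenience wrapper for end-to-end runs: simulates the fluence maps on
#' the phantom's true medium, renders forward PA images at both wavelengths
#' and a speckled US image, and returns everything together with the ground
#' truth.
#'
#' @param spec a `phantom_spec`.
#' @param probe a [probe_config()].
#' @param grid a [grid3d()] for the transport simulation.
#' @param n_photons photons per wavelength.
#' @param seed base seed; wavelengths and noise use fixed offsets from it.
#' @param noise_sigma forward-model noise level (see [forward_pa_image()]);
#'   `"calibrated"` uses [calibrate_noise_sigma()].
#' @param envelope envelope-detect the PA frames.
#' @param n_frames number of noisy PA frames to generate per wavelength.
#' @param smooth_sigma Gaussian smoothing of the fluence maps, mm (see
#'   [smooth_fluence()]).
#' @param average_slices elevational slice averaging in
#'   [extract_imaging_plane()].
#' @param mirror lateral mirror averaging of the fluence maps
#'   ([symmetrize_fluence()]); valid here because phantom media are
#'   laterally symmetric and tubes are excluded from the light model.
#' @return list of class `synthetic_frame`: `us`, `pa` (list
#'   `"750"`/`"850"`, each a list of frames), `fluence` (list of 2-D maps on
#'   the image raster), `truth` (tube table, sO2 map parameters, boundary
#'   rows), `spec`, `noise_sigma`.
#' @export
synthetic_frame <- function(spec, probe = probe_config(),
                            grid = grid3d(c(186, 186, 128), spacing = 0.296),
                            n_photons = 2e5, seed = 1,
                            noise_sigma = 0, envelope = TRUE, n_frames = 1,
                            smooth_sigma = 0.3, average_slices = 3,
                            mirror = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  src <- build_led_sources(probe)
  medium <- phantom_medium(spec, grid)
  fl <- lapply(c(750, 850), function(wl) {
    f3 <- simulate_fluence(medium, src, wl, n_photons,
                           seed = seed + match(wl, c(750, 850)))
    f2 <- extract_imaging_plane(f3, footprint = c(grid$shape[1], grid$shape[3]),
                                average_slices = average_slices)
    if (mirror) f2 <- symmetrize_fluence(f2)
    smooth_fluence(resample_fluence(f2, shape = spec$img_shape,
                                    pitch = spec$pitch),
                   smooth_sigma)
  })
  names(fl) <- c("750", "850")
  if (identical(noise_sigma, "calibrated")) {
    noise_sigma <- calibrate_noise_sigma(spec, fl[["750"]])
  }
  pa <- lapply(c("750", "850"), function(wl) {
    lapply(seq_len(n_frames), function(k) {
      forward_pa_image(spec, fl[[wl]], as.numeric(wl),
                       seed = seed + 100 * as.numeric(wl) + k,
                       noise_sigma = noise_sigma, envelope = envelope)
    })
  })
  names(pa) <- c("750", "850")
  us <- synth_us_image(spec, seed = seed + 7)
  structure(list(
    us = us, pa = pa, fluence = fl,
    truth = list(tubes = spec$tubes, boundary_rows = attr(us, "boundary_rows"),
                 tube_masks = tube_masks(spec)),
    spec = spec, noise_sigma = noise_sigma, seed = seed
  ), class = "synthetic_frame")
}
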