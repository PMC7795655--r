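#' Simulate light fluence in a voxel medium by Monte Carlo photon transport
#'
#' Weighted-photon random walk with Henyey-Greenstein scattering, implicit
#' capture and Russian roulette, on the labeled voxel medium. Photon free
#' paths are sampled from the local total interaction coefficient; fluence is
#' accumulated with a track-length estimator, so voxels with zero absorption
#' (or zero scattering) are tallied correctly. Boundaries are matched
#' (no Fresnel reflection); photons leaving the grid are terminated.
#' The result is normalized per unit delivered energy: multiplying every
#' element's `relative_power` by a constant does not change the map returned
#' here (scaling by pulse energy is the unmixing stage's job).
#'
#' Results are bit-reproducible for a given `(seed, inputs)` pair: every
#' photon index derives its own random stream from the run seed.
#'
#' @param medium a [medium_grid()].
#' @param sources a `led_sources` data frame ([build_led_sources()]) or any
#'   data frame with columns `x,y,z,ax,ay,az,half_angle,wavelength,relative_power`.
#' @param wavelength nm; only elements at this wavelength emit.
#' @param n_photons number of photons to launch (>= 1).
#' @param seed integer RNG seed.
#' @param cosine_weighted if `TRUE`, emission within each cone is
#'   cosine-weighted instead of uniform over solid angle.
#' @param rr_threshold,rr_factor Russian roulette weight threshold and
#'   survival factor.
#' @param max_steps per-photon step cap (safety net).
#' @return An object of class `fluence_map` (3-D): list with `values`
#'   (array, 1/cm^2 per unit delivered energy), `grid`, `wavelength`,
#'   `photons`, `seed`, and `tallies` (energy accounting).
#' @export
simulate_fluence <- function(medium, sources, wavelength, n_photons, seed,
                             cosine_weighted = FALSE,
                             rr_threshold = 1e-4, rr_factor = 10,
                             max_steps = 1000000L) {
  stopifnot(inherits(medium, "medium_grid"), n_photons >= 1)
  el <- sources[sources$wavelength == wavelength, , drop = FALSE]
  if (nrow(el) == 0) stop("no source elements at ", wavelength, " nm")
  pv <- .property_vectors(medium, wavelength)

  g <- medium$grid
  lo <- g$origin
  hi <- g$origin + g$shape * g$spacing
  # at least one element must be able to illuminate the grid
  inside <- el$x >= lo[1] & el$x < hi[1] &
            el$y >= lo[2] & el$y < hi[2] &
            el$z >= lo[3] & el$z < hi[3]
  if (!any(inside)) {
    towards <- .ray_hits_box(cbind(el$x, el$y, el$z), cbind(el$ax, el$ay, el$az), lo, hi)
    if (!any(towards)) stop("sources lie entirely outside the grid and none aims at it")
  }

  p <- el$relative_power
  cum <- cumsum(p / sum(p))
  res <- .mc_transport(
    dims = g$shape, spacing = g$spacing, origin = g$origin,
    labels = medium$labels,
    mua = pv$mua, mus = pv$mus, gpar = pv$g,
    src_pos = cbind(el$x, el$y, el$z),
    src_axis = cbind(el$ax, el$ay, el$az),
    src_cos_half = cos(el$half_angle * pi / 180),
    src_cumprob = cum,
    cosine_weighted = cosine_weighted,
    n_photons = as.double(n_photons), seed = as.integer(seed),
    rr_threshold = rr_threshold, rr_factor = rr_factor,
    max_steps = as.integer(max_steps))

  vox_cm3 <- (g$spacing / 10)^3
  values <- array(res$fluence * (0.1 / (vox_cm3 * n_photons)), dim = g$shape)
  structure(list(
    values = values, grid = g, wavelength = wavelength,
    photons = n_photons, seed = seed,
    tallies = res[c("launched", "absorbed", "escaped",
                    "roulette_loss", "roulette_gain", "residual")]
  ), class = "fluence_map")
}

# rows of pos/dir that intersect the axis-aligned box [lo, hi]
.ray_hits_box <- function(pos, dir, lo, hi) {
  apply(cbind(pos, dir), 1, function(r) {
    p <- r[1:3]; d <- r[4:6]
    t0 <- 0; t1 <- Inf
    for (k in 1:3) {
      if (abs(d[k]) < 1e-15) {
        if (p[k] < lo[k] || p[k] > hi[k]) return(FALSE)
      } else {
        tt <- sort(c((lo[k] - p[k]) / d[k], (hi[k] - p[k]) / d[k]))
        t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
        if (t0 > t1) return(FALSE)
      }
    }
    TRUE
  })
}

#' @export
print.fluence_map <- function(x, ...) {
  d <- if (is.matrix(x$values)) dim(x$values) else dim(x$values)
  cat(sprintf("<fluence_map> %s nm, %s, %s photons, seed %s\n",
              x$wavelength, paste(d, collapse = " x "),
              format(x$photons, big.mark = ","), x$seed))
  invisible(x)
}

#' Energy balance of a finished transport run
#'
#' Launched weight must equal absorbed + escaped + residual weight once the
#' net Russian-roulette weight exchange is accounted for; the relative
#' imbalance should be at floating-point level.
#'
#' @param f a 3-D `fluence_map`.
#' @return relative energy imbalance (dimensionless).
#' @export
energy_imbalance <- function(f) {
  t <- f$tallies
  bal <- t$absorbed + t$escaped + t$residual + t$roulette_loss - t$roulette_gain
  abs(bal - t$launched) / t$launched
}

#' Extract the imaging-plane slice from a 3-D fluence map
#'
#' Returns the center elevational (y) slice, cropped laterally to the PA/US
#' image footprint and left at the grid's native pixel pitch. With the
#' full-scale reference grid (744 x 744 x 512 at 74 um) and the default
#' footprint this yields the 545 x 512 image raster.
#'
#' @param f a 3-D `fluence_map`.
#' @param footprint integer `c(width_px, depth_px)` of the image raster at
#'   the grid's spacing.
#' @param average_slices average the center slice with this many neighbor
#'   slices on each side (0 = center slice only). The probe geometry is
#'   elevationally symmetric about the imaging plane and extruded media are
#'   elevation-invariant, so the fluence field is stationary at the center
#'   and a narrow average reduces Monte-Carlo noise without bias.
#' @return A 2-D `fluence_map`: `values` is a matrix `[depth, lateral]`
#'   (row 1 = shallowest), with attributes `pitch` (mm) and `wavelength`.
#' @export
extract_imaging_plane <- function(f, footprint = c(545, 512),
                                  average_slices = 0) {
  stopifnot(inherits(f, "fluence_map"), length(dim(f$values)) == 3)
  sh <- f$grid$shape
  if (sh[1] < footprint[1] || sh[3] < footprint[2]) {
    stop("grid (", sh[1], " x ", sh[3], ") is smaller than the requested ",
         "image footprint (", footprint[1], " x ", footprint[2], ")")
  }
  iy <- ceiling(sh[2] / 2)
  slices <- max(iy - average_slices, 1):min(iy + average_slices, sh[2])
  sl <- f$values[, slices[1], ]              # [x, z]
  if (length(slices) > 1) {
    for (s in slices[-1]) sl <- sl + f$values[, s, ]
    sl <- sl / length(slices)
  }
  x0 <- floor((sh[1] - footprint[1]) / 2)
  sl <- sl[(x0 + 1):(x0 + footprint[1]), seq_len(footprint[2]), drop = FALSE]
  vals <- t(sl)                              # [z, x]: image convention
  structure(list(
    values = vals, grid = f$grid, wavelength = f$wavelength,
    photons = f$photons, seed = f$seed,
    pitch = f$grid$spacing,
    depth0 = f$grid$origin[3]
  ), class = c("fluence_map_2d", "fluence_map"))
}

#' Resample a 2-D fluence map onto an image raster
#'
#' Bilinear interpolation from the simulation pitch to the PA/US image pitch,
#' used when the Monte-Carlo grid is coarser than the image raster.
#'
#' @param f2d a 2-D `fluence_map`.
#' @param shape target `c(depth_px, width_px)`.
#' @param pitch target pixel pitch, mm.
#' @return a 2-D `fluence_map` on the new raster.
#' @export
resample_fluence <- function(f2d, shape, pitch) {
  stopifnot(inherits(f2d, "fluence_map_2d"))
  v <- f2d$values
  src_pitch <- f2d$pitch
  # physical coordinates of source and target pixel centers, sharing the
  # same lateral center and depth origin
  zs <- (seq_len(nrow(v)) - 0.5) * src_pitch
  xs <- (seq_len(ncol(v)) - 0.5) * src_pitch
  xs <- xs - mean(xs)
  zt <- (seq_len(shape[1]) - 0.5) * pitch
  xt <- (seq_len(shape[2]) - 0.5) * pitch
  xt <- xt - mean(xt)
  out <- .bilinear(v, zs, xs, zt, xt)
  f2d$values <- out
  f2d$pitch <- pitch
  f2d
}

# bilinear interpolation of matrix v sampled at (rows zs, cols xs) onto
# the outer grid (zt, xt); clamped at the borders
.bilinear <- function(v, zs, xs, zt, xt) {
  iz <- findInterval(zt, zs, all.inside = TRUE)
  ix <- findInterval(xt, xs, all.inside = TRUE)
  fz <- (zt - zs[iz]) / (zs[iz + 1] - zs[iz])
  fx <- (xt - xs[ix]) / (xs[ix + 1] - xs[ix])
  fz <- pmin(1, pmax(0, fz))
  fx <- pmin(1, pmax(0, fx))
  v00 <- v[iz, ix, drop = FALSE]
  v10 <- v[iz + 1, ix, drop = FALSE]
  v01 <- v[iz, ix + 1, drop = FALSE]
  v11 <- v[iz + 1, ix + 1, drop = FALSE]
  wz <- matrix(fz, nrow = length(zt), ncol = length(xt))
  wx <- matrix(fx, nrow = length(zt), ncol = length(xt), byrow = TRUE)
  v00 * (1 - wz) * (1 - wx) + v10 * wz * (1 - wx) +
    v01 * (1 - wz) * wx + v11 * wz * wx
}

#' Mirror-average a 2-D fluence map across the lateral axis
#'
#' The LED source set is mirror-symmetric about the image center line, so
#' for laterally symmetric media the true fluence field is symmetric too
#' and averaging the map with its mirror image halves the Monte-Carlo
#' variance. Only meaningful for (near-)symmetric scenes.
#'
#' @param f2d a 2-D `fluence_map`.
#' @return the symmetrized 2-D `fluence_map`.
#' @export
symmetrize_fluence <- function(f2d) {
  stopifnot(inherits(f2d, "fluence_map_2d"))
  f2d$values <- (f2d$values + f2d$values[, rev(seq_len(ncol(f2d$values)))]) / 2
  f2d
}

#' Smooth a 2-D fluence map
#'
#' Gaussian smoothing of the imaging-plane fluence. The diffuse fluence field
#' varies on the scale of the transport mean free path (about 1 mm in soft
#' tissue), so a kernel a few tenths of a millimetre wide suppresses
#' Monte-Carlo estimator noise without biasing the decay profile.
#'
#' @param f2d a 2-D `fluence_map`.
#' @param sigma_mm Gaussian standard deviation, mm; 0 returns the map
#'   unchanged.
#' @return the smoothed 2-D `fluence_map`.
#' @export
smooth_fluence <- function(f2d, sigma_mm = 0.3) {
  stopifnot(inherits(f2d, "fluence_map_2d"))
  if (sigma_mm <= 0) return(f2d)
  s <- sigma_mm / f2d$pitch
  k <- .gauss_kernel(s, s)
  f2d$values <- EBImage::filter2(f2d$values, k)
  f2d
}

#' Depth at which the fluence falls to 1/e of its ROI-start value
#'
#' Averages the fluence laterally over a band centered on the image axis,
#' takes the resulting depth profile, and returns the depth increment below
#' `roi_start_depth` at which the profile first falls to 1/e of its value at
#' `roi_start_depth` (linear interpolation between samples). The ROI-start
#' reference is a convention choice: the usable imaging region begins below
#' the advanced LED tips, and the profile reference is taken there.
#'
#' @param f2d a 2-D `fluence_map`.
#' @param roi_start_depth reference depth, mm.
#' @param band_mm width of the central lateral averaging band, mm.
#' @return depth increment in mm below `roi_start_depth`.
#' @export
one_over_e_depth <- function(f2d, roi_start_depth = 9.2, band_mm = 3) {
  stopifnot(inherits(f2d, "fluence_map_2d"))
  v <- f2d$values
  pitch <- f2d$pitch
  nxp <- ncol(v)
  half <- max(1, round(band_mm / 2 / pitch))
  c0 <- ceiling(nxp / 2)
  cols <- max(1, c0 - half):min(nxp, c0 + half)
  prof <- rowMeans(v[, cols, drop = FALSE])
  depths <- (seq_len(nrow(v)) - 0.5) * pitch
  if (roi_start_depth < depths[1] || roi_start_depth > depths[length(depths)]) {
    stop("roi_start_depth outside the imaged depth range")
  }
  ref <- stats::approx(depths, prof, xout = roi_start_depth)$y
  if (!is.finite(ref) || ref <= 0) stop("fluence not positive at roi_start_depth")
  target <- ref / exp(1)
  below <- which(depths > roi_start_depth & prof <= target)
  if (length(below) == 0) {
    stop("fluence never drops to 1/e of its reference within the grid; ",
         "increase the simulated depth")
  }
  i2 <- below[1]
  i1 <- i2 - 1
  # interpolate the crossing between samples i1 and i2
  z1 <- max(depths[i1], roi_start_depth)
  p1 <- if (depths[i1] >= roi_start_depth) prof[i1] else ref
  frac <- (p1 - target) / (p1 - prof[i2])
  z_cross <- z1 + frac * (depths[i2] - z1)
  z_cross - roi_start_depth
}
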