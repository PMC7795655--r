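# Shared fixtures: tiny grids and media so unit tests stay fast.

tiny_grid <- function(n = c(21, 21, 60), spacing = 0.2) {
  grid3d(n, spacing = spacing)
}

absorber_medium <- function(grid, mua = 5, musp = 0, g = 0, wl = 750) {
  homogeneous_medium(grid, stats::setNames(
    list(optical_properties(mua, musp, g)), as.character(wl)))
}

# collimated pencil beam entering at the grid center, pointing down
pencil_source <- function(wl = 750, half_angle = 0) {
  data.frame(x = 0, y = 0, z = 1e-3, ax = 0, ay = 0, az = 1,
             half_angle = half_angle, wavelength = wl, relative_power = 1)
}

isotropic_point_source <- function(wl = 750) {
  data.frame(x = 0, y = 0, z = 0, ax = 0, ay = 0, az = 1,
             half_angle = 180, wavelength = wl, relative_power = 1)
}

# small-raster tube phantom for fast end-to-end runs
small_phantom <- function(depths = c(4, 8), so2 = 96,
                          medium_kind = "homogeneous", ...) {
  make_tube_phantom(depths = depths, so2 = so2, medium_kind = medium_kind,
                    img_shape = c(128, 136), pitch = 0.296, ...)
}

# rectangular ROI fully inside tube i of a phantom
tube_roi <- function(spec, i, half = 0.15) {
  t <- spec$tubes[i, ]
  c(t$x - half, t$x + half, t$z - half, t$z + half)
}
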