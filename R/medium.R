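#' Regular 3-D simulation grid
#'
#' Isotropic voxel grid for the light-transport simulation. By default the
#' lateral (x) and elevational (y) axes are centered on zero and depth (z)
#' starts at the transducer face, matching the probe frame of
#' [build_led_sources()].
#'
#' @param shape integer vector `c(nx, ny, nz)` in voxels. The full-scale
#'   reference geometry is `c(744, 744, 512)` spanning 55 x 55 x 37.9 mm.
#' @param spacing isotropic voxel edge, mm (default 0.074).
#' @param origin mm coordinates of the low corner; default centers x and y
#'   and puts z = 0 at the first voxel face.
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(shape = c(744, 744, 512), spacing = 0.074, origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), spacing > 0)
  if (is.null(origin)) {
    origin <- c(-shape[1] * spacing / 2, -shape[2] * spacing / 2, 0)
  }
  stopifnot(length(origin) == 3)
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin)),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  ext <- x$shape * x$spacing
  cat(sprintf("<grid3d> %d x %d x %d voxels @ %g mm (%.1f x %.1f x %.1f mm)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              ext[1], ext[2], ext[3]))
  invisible(x)
}

#' Voxel center depths of a grid (z axis), mm
#' @param grid a `grid3d`.
#' @export
grid_depths <- function(grid) {
  grid$origin[3] + (seq_len(grid$shape[3]) - 0.5) * grid$spacing
}

#' Optical properties of one medium at one wavelength
#'
#' @param mua absorption coefficient, 1/cm.
#' @param musp reduced scattering coefficient, 1/cm.
#' @param g scattering anisotropy in (-1, 1); the transport simulation uses
#'   the full scattering coefficient `mus = musp / (1 - g)`.
#' @return A list of class `optical_properties` with fields `mua`, `musp`,
#'   `g` and the derived `mus`.
#' @export
optical_properties <- function(mua, musp, g = 0.9) {
  stopifnot(mua >= 0, musp >= 0, g > -1, g < 1)
  structure(list(mua = mua, musp = musp, g = g, mus = musp / (1 - g)),
            class = "optical_properties")
}

#' Bundled water absorption table
#'
#' Absorption coefficient of pure water at near-infrared wavelengths from a
#' standard published compilation, used for the background (label 0) medium.
#' Scattering in water is negligible at these wavelengths.
#'
#' @return data frame with `wavelength` (nm) and `mua` (1/cm).
#' @export
water_absorption <- function() {
  utils::read.table(system.file("extdata", "water_absorption.tsv",
                                package = "paflux"),
                    header = TRUE, sep = "\t")
}

#' Water optical properties at a wavelength
#'
#' Linear interpolation of the bundled absorption table; reduced scattering
#' is set to a near-zero nominal value.
#'
#' @param wavelength nm.
#' @param musp nominal reduced scattering, 1/cm.
#' @export
water_properties <- function(wavelength, musp = 0.001) {
  tab <- water_absorption()
  if (wavelength < min(tab$wavelength) || wavelength > max(tab$wavelength)) {
    stop("wavelength outside the bundled water absorption table")
  }
  mua <- stats::approx(tab$wavelength, tab$mua, xout = wavelength)$y
  optical_properties(mua = mua, musp = musp, g = 0)
}

#' Bundled tissue optical property presets
#'
#' Absorption and reduced scattering coefficients (1/cm, anisotropy g = 0.9)
#' for the three media used in the reference experiments: an
#' intralipid/ink soft-tissue phantom, mouse thigh muscle and human forearm.
#' The mouse-thigh rows are stored exactly as printed in the source table,
#' which lists 850 nm twice; most likely the first row is meant to be 750 nm.
#' A warning is raised when this preset is used at 750 nm and the first row
#' is substituted (see `Details`).
#'
#' @details `medium_presets()` returns the full table. `preset_properties()`
#'   resolves one `(preset, wavelength)` pair to an [optical_properties()]
#'   object. For `"mouse_thigh"` at 750 nm the duplicated 850 nm row is used
#'   with a warning, surfacing the ambiguity rather than hiding it.
#'
#' @return data frame with columns `preset`, `wavelength`, `mua`, `musp`, `g`.
#' @export
medium_presets <- function() {
  data.frame(
    preset = c("soft_tissue_phantom", "soft_tissue_phantom",
               "mouse_thigh", "mouse_thigh",
               "human_forearm", "human_forearm"),
    wavelength = c(750, 850, 850, 850, 750, 850),
    mua  = c(0.101, 0.089, 0.76, 0.64, 0.41, 0.30),
    musp = c(10.5,  9.0,   5.3,  4.8,  7.2,  6.5),
    g = 0.9
  )
}

#' @rdname medium_presets
#' @param preset preset name.
#' @param wavelength nm.
#' @export
preset_properties <- function(preset, wavelength) {
  tab <- medium_presets()
  rows <- tab[tab$preset == preset, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("unknown medium preset '", preset, "'; available: ",
         paste(unique(tab$preset), collapse = ", "))
  }
  hit <- rows[rows$wavelength == wavelength, , drop = FALSE]
  if (nrow(hit) == 0) {
    if (preset == "mouse_thigh" && wavelength == 750) {
      warning("mouse_thigh preset lists 850 nm twice as printed in its ",
              "source; using the first row for 750 nm")
      hit <- rows[1, , drop = FALSE]
    } else {
      stop("preset '", preset, "' has no properties at ", wavelength, " nm")
    }
  }
  hit <- hit[1, ]
  optical_properties(hit$mua, hit$musp, hit$g)
}

#' Labeled voxel medium with per-wavelength optical properties
#'
#' @param grid a [grid3d()].
#' @param labels integer array with `dim == grid$shape`; 0 is background
#'   (water by convention), 1..K are tissue types.
#' @param properties named list: `properties[[as.character(label)]][[as.character(wavelength)]]`
#'   is an [optical_properties()] object. Every label present in `labels`
#'   must have properties for every wavelength that will be simulated.
#' @return An object of class `medium_grid`.
#' @export
medium_grid <- function(grid, labels, properties) {
  stopifnot(inherits(grid, "grid3d"))
  if (is.null(dim(labels)) || !all(dim(labels) == grid$shape)) {
    stop("labels must be an array with dim equal to grid$shape")
  }
  storage.mode(labels) <- "integer"
  structure(list(grid = grid, labels = labels, properties = properties),
            class = "medium_grid")
}

#' Homogeneous medium filling the whole grid
#'
#' @param grid a [grid3d()].
#' @param props named list wavelength -> [optical_properties()] for label 1.
#' @export
homogeneous_medium <- function(grid, props) {
  labels <- array(1L, dim = grid$shape)
  medium_grid(grid, labels, list(`1` = props))
}

# per-label property vectors (1/mm) for one wavelength, or NULL if missing
.property_vectors <- function(medium, wavelength) {
  present <- sort(unique(as.integer(medium$labels)))
  nlab <- max(present) + 1L
  mua <- mus <- g <- rep(NA_real_, nlab)
  wl <- as.character(wavelength)
  for (l in present) {
    key <- as.character(l)
    p <- medium$properties[[key]][[wl]]
    if (is.null(p) && l == 0L) {
      # background defaults to water when not specified
      p <- water_properties(wavelength)
    }
    if (is.null(p)) {
      stop("no optical properties for label ", l, " at ", wavelength, " nm")
    }
    mua[l + 1] <- p$mua / 10     # 1/cm -> 1/mm
    mus[l + 1] <- p$mus / 10
    g[l + 1] <- p$g
  }
  # unreferenced intermediate labels: make them impossible to miss
  if (anyNA(mua[present + 1])) stop("incomplete property table")
  mua[is.na(mua)] <- 0; mus[is.na(mus)] <- 0; g[is.na(g)] <- 0
  list(mua = mua, mus = mus, g = g)
}
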