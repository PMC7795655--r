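#' Read and write float rasters as TIFF
#'
#' 32-bit float TIFF I/O for PA/US images, masks and 2-D fluence maps.
#' The TIFF backend stores samples in `[0, 1]`, so rasters are written
#' affinely rescaled, with the offset/scale recorded in a small JSON sidecar
#' (`<path>.json`); `read_raster()` undoes the transform transparently and
#' reads plain TIFFs from other tools as-is when no sidecar is present.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @return `read_raster()` returns a numeric matrix; `write_raster()`
#'   returns `path` invisibly.
#' @export
write_raster <- function(x, path) {
  x <- unclass(x)
  stopifnot(is.matrix(x), all(is.finite(x)))
  lo <- min(x)
  rng <- max(x) - lo
  scaled <- if (rng > 0) (x - lo) / rng else x * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = lo, scale = rng),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  img <- unclass(tiff::readTIFF(path, as.is = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    img <- img * meta$scale + meta$offset
  }
  img
}

#' Write a binary mask as PNG-compatible 0/255 TIFF and as 0/1 float TIFF
#' @noRd
write_mask <- function(mask, path) {
  write_raster(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
}

#' Write an sO2 color overlay on a B-mode image as PNG
#'
#' Renders the ultrasound image in grayscale and blends a blue-to-red sO2
#' color map (0-100%) over the valid sO2 pixels, the standard presentation
#' for fluence-compensated oxygenation maps.
#'
#' @param so2 an `so2_map`.
#' @param us numeric matrix, same raster.
#' @param path output PNG path.
#' @param alpha overlay opacity in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_so2_overlay <- function(so2, us, path, alpha = 0.7) {
  stopifnot(all(dim(so2) == dim(us)))
  g <- us / max(us, 1e-12)
  rgb <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  v <- is.finite(unclass(so2))
  frac <- unclass(so2)[v] / 100
  # blue (deoxygenated) -> red (oxygenated)
  r <- frac; b <- 1 - frac; gg <- 0.2 * (1 - abs(2 * frac - 1))
  ch <- function(k, col) {
    plane <- rgb[, , k]
    plane[v] <- (1 - alpha) * plane[v] + alpha * col
    plane
  }
  rgb[, , 1] <- ch(1, r); rgb[, , 2] <- ch(2, gg); rgb[, , 3] <- ch(3, b)
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' Persist pipeline intermediates and provenance
#'
#' Writes the mask, fluence maps, compensated images and sO2 maps as 32-bit
#' float TIFFs and a `provenance.json` record containing every configuration
#' value, the package version, seeds and content hashes of the outputs.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
save_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(mask = "mask.tif",
             so2 = "so2.tif", so2_uncomp = "so2_uncompensated.tif")
  write_mask(result$mask, file.path(dir, files["mask"]))
  so2 <- unclass(result$so2); so2[!is.finite(so2)] <- -1
  write_raster(so2, file.path(dir, files["so2"]))
  so2u <- unclass(result$so2_uncompensated); so2u[!is.finite(so2u)] <- -1
  write_raster(so2u, file.path(dir, files["so2_uncomp"]))
  for (wl in names(result$fluence)) {
    f <- file.path(dir, sprintf("fluence_%s.tif", wl))
    write_raster(result$fluence[[wl]]$values, f)
    files[paste0("fluence_", wl)] <- basename(f)
  }
  for (i in seq_along(result$compensated)) {
    b <- unclass(result$compensated[[i]])
    b[!is.finite(b)] <- 0
    f <- file.path(dir, sprintf("compensated_%d.tif", i))
    write_raster(b, f)
    files[paste0("compensated_", i)] <- basename(f)
  }
  cfg <- result$config
  prov <- list(
    package = "paflux",
    version = as.character(utils::packageVersion("paflux")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    n_photons = cfg$n_photons,
    wavelengths = cfg$wavelengths,
    medium_preset = cfg$medium_preset,
    threshold = cfg$threshold,
    median_kernel = cfg$median_kernel,
    two_slab = cfg$two_slab,
    grid_scale = cfg$grid_scale,
    grid_elevation = cfg$grid_elevation,
    grid_lateral_pad = cfg$grid_lateral_pad,
    floor_fraction = cfg$floor_fraction,
    amplitude_gate_k = cfg$amplitude_gate_k,
    probe = unclass(cfg$probe),
    elapsed_seconds = result$elapsed,
    files = as.list(files),
    md5 = as.list(tools::md5sum(file.path(dir, unname(files))))
  )
  names(prov$md5) <- unname(files)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
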