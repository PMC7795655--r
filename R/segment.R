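#' Segment the tissue region of a B-mode ultrasound image
#'
#' Converts a grayscale B-mode image into a binary tissue mask with a fixed
#' operator pipeline: median filter, global threshold, Sobel edge detection
#' of the boundary (kept as a diagnostic), morphological hole filling, and
#' selection of the largest connected component. The returned mask is the
#' filled largest component of the thresholded image.
#'
#' Images follow the raster convention used throughout the package:
#' matrices are `[depth_row, lateral_col]` with pixel `[1, 1]` the
#' shallowest, leftmost sample.
#'
#' The threshold is a required input: in practice it is chosen per tissue
#' type. An Otsu-based suggestion is reported via `message()` for guidance
#' but never applied silently.
#'
#' @param us numeric matrix of non-negative intensities.
#' @param threshold global intensity threshold; must lie within the image's
#'   intensity range.
#' @param median_kernel odd side length (pixels) of the median filter window;
#'   `1` disables smoothing.
#' @param quiet suppress the Otsu suggestion message.
#' @return An integer 0/1 matrix of class `binary_mask` (1 = tissue) with
#'   attributes `thresholded` (pre-fill foreground), `edges` (Sobel gradient
#'   magnitude of the thresholded image) and `otsu` (suggested threshold).
#' @export
segment_tissue <- function(us, threshold, median_kernel = 5, quiet = FALSE) {
  stopifnot(is.matrix(us), all(is.finite(us)), all(us >= 0))
  rng <- range(us)
  if (threshold < rng[1] || threshold > rng[2]) {
    stop("threshold ", threshold, " outside the image intensity range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  if (median_kernel < 1 || median_kernel %% 2 == 0) {
    stop("median_kernel must be an odd positive integer")
  }

  sm <- us
  if (median_kernel > 1) {
    # EBImage's constant-time median filter expects intensities in [0, 1]
    mx <- max(us)
    scaled <- if (mx > 0) us / mx else us
    sm <- EBImage::medianFilter(scaled, size = (median_kernel - 1) / 2) *
      (if (mx > 0) mx else 1)
  }

  bw <- (sm >= threshold) * 1L
  if (!any(bw == 1L)) {
    stop("empty mask after thresholding; lower the threshold ",
         "(Otsu suggestion: ", signif(.otsu_threshold(us), 4), ")")
  }

  # Sobel gradient of the binary image localizes the tissue boundary;
  # retained as a diagnostic layer
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(bw, kx)
  gy <- EBImage::filter2(bw, t(kx))
  edges <- sqrt(gx^2 + gy^2)

  filled <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(filled)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- (lab == keep) * 1L

  otsu <- .otsu_threshold(us)
  if (!quiet) {
    message(sprintf("segment_tissue: threshold = %.4g (Otsu suggestion: %.4g)",
                    threshold, otsu))
  }
  structure(mask, class = c("binary_mask", class(mask)),
            thresholded = bw, edges = edges, otsu = otsu)
}

# Otsu threshold on a 256-bin histogram of the raw intensities
.otsu_threshold <- function(img) {
  r <- range(img)
  if (diff(r) == 0) return(r[1])
  x <- (img - r[1]) / diff(r)
  h <- tabulate(pmin(256L, 1L + floor(as.vector(x) * 256)), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + diff(r) * k / 256
}

#' Force the region above a water/tissue interface to background
#'
#' For two-slab media (water coupling layer over tissue) the mask above the
#' detected interface is set to zero, pixel column by pixel column.
#'
#' @param mask a `binary_mask`.
#' @param interface_rows integer vector, one row index per column, or a
#'   single row index applied to all columns.
#' @return the modified `binary_mask`.
#' @export
zero_above_interface <- function(mask, interface_rows) {
  stopifnot(is.matrix(mask))
  if (length(interface_rows) == 1) {
    interface_rows <- rep(interface_rows, ncol(mask))
  }
  stopifnot(length(interface_rows) == ncol(mask))
  for (j in seq_len(ncol(mask))) {
    r <- interface_rows[j]
    if (r > 1) mask[seq_len(r - 1), j] <- 0L
  }
  mask
}

#' First tissue row per image column
#'
#' Utility for boundary-recovery checks: the shallowest row at which the
#' mask is 1 in each column (NA where the column is empty).
#'
#' @param mask a `binary_mask`.
#' @export
boundary_rows <- function(mask) {
  apply(mask, 2, function(col) {
    w <- which(col > 0)
    if (length(w)) w[1] else NA_integer_
  })
}

#' Extrude a 2-D tissue mask into the 3-D simulation medium
#'
#' Centers the mask laterally in the grid, replicates its first and last
#' columns to fill the grid's lateral extent, and stacks identical copies
#' along the elevational axis. In-footprint pixels are transferred exactly
#' (no resampling): the mask raster pitch must equal the grid spacing and
#' the mask depth must equal the grid depth.
#'
#' @param mask a `binary_mask` (or 0/1 matrix), `[depth, lateral]`.
#' @param tissue_props named list wavelength -> [optical_properties()] for
#'   mask label 1.
#' @param background_props named list wavelength -> [optical_properties()]
#'   for label 0; `NULL` selects water via [water_properties()].
#' @param grid a [grid3d()]; `grid$spacing` must equal the mask pitch.
#' @return a [medium_grid()] with labels 1 inside the mask, 0 outside.
#' @export
mask_to_medium <- function(mask, tissue_props, background_props = NULL, grid) {
  stopifnot(is.matrix(mask), inherits(grid, "grid3d"))
  nxm <- ncol(mask)              # lateral
  nzm <- nrow(mask)              # depth
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  if (nxm > nx || nzm > nz) {
    stop("mask (", nxm, " x ", nzm, ") is larger than the grid (",
         nx, " x ", nz, ")")
  }
  if (nzm != nz) {
    stop("mask depth (", nzm, ") must equal grid depth (", nz,
         "); crop or regenerate the grid")
  }
  m <- matrix(as.integer(mask > 0), nzm, nxm)
  # center laterally, then replicate edge columns outward
  x0 <- floor((nx - nxm) / 2)
  padded <- matrix(0L, nz, nx)
  padded[, (x0 + 1):(x0 + nxm)] <- m
  if (x0 > 0) padded[, seq_len(x0)] <- m[, 1]
  right <- x0 + nxm
  if (right < nx) padded[, (right + 1):nx] <- m[, nxm]

  labels <- array(0L, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) {
    labels[, , z] <- matrix(padded[z, ], nx, ny)
  }
  props <- list(`1` = tissue_props)
  if (!is.null(background_props)) props[["0"]] <- background_props
  medium_grid(grid, labels, props)
}

#' Block-downsample a binary mask by an integer factor
#'
#' Majority vote within `factor x factor` blocks; used when the Monte-Carlo
#' grid is run at a coarser pitch than the image raster.
#'
#' @param mask 0/1 matrix.
#' @param factor integer >= 1.
#' @export
downsample_mask <- function(mask, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(mask)
  nr <- floor(nrow(mask) / factor) * factor
  nc <- floor(ncol(mask) / factor) * factor
  m <- mask[seq_len(nr), seq_len(nc)]
  arr <- array(m, dim = c(factor, nr / factor, factor, nc / factor))
  out <- apply(arr, c(2, 4), mean)
  (out >= 0.5) * 1L
}
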