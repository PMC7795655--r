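#' Construct a PA image object
#'
#' Thin wrapper attaching acquisition metadata to a reconstructed
#' photoacoustic amplitude raster. Matrices are `[depth_row, lateral_col]`.
#'
#' @param pixels numeric matrix of reconstructed PA amplitude (arbitrary
#'   units).
#' @param wavelength nm.
#' @param pulse_energy per-pulse optical energy at this wavelength, uJ.
#' @param pitch pixel pitch, mm.
#' @return matrix of class `pa_image` with attributes `wavelength`,
#'   `pulse_energy`, `pitch`.
#' @export
pa_image <- function(pixels, wavelength, pulse_energy, pitch = 0.074) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            wavelength > 0, pulse_energy > 0, pitch > 0)
  structure(pixels, class = c("pa_image", class(pixels)),
            wavelength = wavelength, pulse_energy = pulse_energy,
            pitch = pitch)
}

#' Average a list of PA frames
#'
#' Pixelwise mean of repeated frames of the same scene, the standard
#' noise-reduction convention (e.g. a 20-frame average) for tube phantom
#' measurements.
#'
#' @param frames list of matrices (or `pa_image`s) of identical shape.
#' @return matrix (a `pa_image` if the inputs were).
#' @export
average_frames <- function(frames) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  for (f in frames) stopifnot(all(dim(f) == d))
  out <- Reduce(`+`, lapply(frames, unclass)) / length(frames)
  a <- frames[[1]]
  if (inherits(a, "pa_image")) {
    out <- pa_image(out, attr(a, "wavelength"), attr(a, "pulse_energy"),
                    attr(a, "pitch"))
  }
  out
}

#' Fluence-compensate a PA image
#'
#' Divides the PA image by the simulated fluence map pixelwise,
#' `b = p / (E * Phi)`: the pulse energy `E` puts both wavelengths on a
#' common energy scale and `Phi` (fluence per unit delivered energy) removes
#' the spatial illumination pattern. Pixels where the fluence falls below
#' `floor_fraction` times its maximum are flagged invalid instead of being
#' amplified into noise.
#'
#' @param pa a [pa_image()].
#' @param fl a 2-D `fluence_map` on the same raster (see
#'   [resample_fluence()]), or `NULL` for the energy-normalization-only
#'   (uncompensated) analysis path, which is equivalent to `Phi == 1`.
#' @param floor_fraction fluence validity floor as a fraction of the map
#'   maximum, in (0, 1).
#' @param normalize_energy divide by the pulse energy (disable if the
#'   acquisition system already exports energy-normalized frames).
#' @return matrix of class `compensated_image` with attributes `valid`
#'   (logical matrix), `floor_applied` (logical matrix of floored pixels)
#'   and `wavelength`.
#' @export
compensate_fluence <- function(pa, fl, floor_fraction = 1e-3,
                               normalize_energy = TRUE) {
  stopifnot(inherits(pa, "pa_image"))
  p <- unclass(pa)
  if (normalize_energy) p <- p / attr(pa, "pulse_energy")
  if (is.null(fl)) {
    b <- p
    floor_applied <- matrix(FALSE, nrow(p), ncol(p))
  } else {
    stopifnot(inherits(fl, "fluence_map_2d"))
    phi <- fl$values
    if (!all(dim(phi) == dim(p))) {
      stop("PA image (", paste(dim(p), collapse = " x "),
           ") and fluence map (", paste(dim(phi), collapse = " x "),
           ") rasters differ; resample the fluence map first")
    }
    if (!is.null(fl$wavelength) && fl$wavelength != attr(pa, "wavelength")) {
      stop("wavelength mismatch between PA image and fluence map")
    }
    stopifnot(floor_fraction > 0, floor_fraction < 1)
    floor_val <- floor_fraction * max(phi)
    floor_applied <- phi < floor_val
    b <- p / pmax(phi, floor_val)
    b[floor_applied] <- NA_real_
  }
  structure(b, class = c("compensated_image", "matrix", "array"),
            valid = !floor_applied, floor_applied = floor_applied,
            wavelength = attr(pa, "wavelength"))
}

#' Per-pixel linear unmixing of two compensated wavelength images
#'
#' Solves `A x = b` per pixel for the chromophore concentrations, where `A`
#' is the 2 x 2 extinction matrix (rows = wavelengths, columns = HbR, HbO2)
#' and `b` stacks the two fluence-compensated images. With two wavelengths
#' and two chromophores the least-squares solution `(A'A)^-1 A' b` is the
#' exact solve; it is computed in closed form.
#'
#' @param b1,b2 `compensated_image`s at the first and second row wavelength
#'   of `A` (default 750 then 850 nm).
#' @param A extinction matrix from [extinction_matrix()].
#' @param nonneg constrain concentrations to be non-negative: pixels whose
#'   unconstrained solution has a negative component are re-solved on the
#'   boundary of the feasible region (the better of the two single-
#'   chromophore fits by residual).
#' @return list of class `concentration_maps`: `c_hbr`, `c_hbo2` (relative
#'   molar units), `valid` (logical matrix), `negative` (logical matrix of
#'   pixels whose unconstrained solution was negative, kept for
#'   diagnostics).
#' @export
linear_unmix <- function(b1, b2, A = extinction_matrix(), nonneg = FALSE) {
  stopifnot(all(dim(b1) == dim(b2)), nrow(A) == 2, ncol(A) == 2)
  kappa <- kappa(A, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e6) {
    stop("extinction matrix is ill-conditioned (condition number ",
         format(kappa, digits = 3), ")")
  }
  w1 <- attr(b1, "wavelength"); w2 <- attr(b2, "wavelength")
  if (!is.null(w1) && !is.null(w2) && !is.null(rownames(A))) {
    if (!identical(as.character(c(w1, w2)), rownames(A))) {
      stop("image wavelengths (", w1, ", ", w2,
           ") do not match the extinction matrix rows (",
           paste(rownames(A), collapse = ", "), ")")
    }
  }
  det_a <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  x1 <- unclass(b1); x2 <- unclass(b2)
  c_hbr <- (A[2, 2] * x1 - A[1, 2] * x2) / det_a
  c_hbo2 <- (A[1, 1] * x2 - A[2, 1] * x1) / det_a
  v1 <- attr(b1, "valid"); v2 <- attr(b2, "valid")
  valid <- (if (is.null(v1)) is.finite(x1) else v1) &
           (if (is.null(v2)) is.finite(x2) else v2)
  negative <- (c_hbr < 0 | c_hbo2 < 0) & valid
  if (nonneg && any(negative, na.rm = TRUE)) {
    # boundary solutions of the constrained problem: one chromophore at 0,
    # the other fitted by 1-D least squares (clamped at 0)
    fit1 <- function(col) pmax(0, (A[1, col] * x1 + A[2, col] * x2) /
                                    sum(A[, col]^2))
    resid <- function(c1, c2) (A[1, 1] * c1 + A[1, 2] * c2 - x1)^2 +
      (A[2, 1] * c1 + A[2, 2] * c2 - x2)^2
    hbr_only <- fit1(1)
    hbo2_only <- fit1(2)
    use_hbr <- resid(hbr_only, 0) <= resid(0, hbo2_only)
    idx <- which(negative)
    c_hbr[idx] <- ifelse(use_hbr[idx], hbr_only[idx], 0)
    c_hbo2[idx] <- ifelse(use_hbr[idx], 0, hbo2_only[idx])
  }
  structure(list(c_hbr = c_hbr, c_hbo2 = c_hbo2, valid = valid,
                 negative = negative),
            class = "concentration_maps")
}

#' Oxygen-saturation map from concentration maps
#'
#' `sO2 = 100 * cHbO2 / (cHbO2 + cHbR)`, clipped to `[0, 100]`. Pixels with
#' non-positive total hemoglobin, outside the amplitude mask, or invalid in
#' the concentration maps are marked invalid (NA).
#'
#' @param conc a `concentration_maps` object from [linear_unmix()].
#' @param amplitude_mask optional logical matrix gating display to pixels
#'   with sufficient PA amplitude (see [amplitude_mask()]).
#' @return matrix of class `so2_map` (percent) with attribute `valid`.
#' @export
so2_map <- function(conc, amplitude_mask = NULL) {
  stopifnot(inherits(conc, "concentration_maps"))
  tot <- conc$c_hbr + conc$c_hbo2
  valid <- conc$valid & is.finite(tot) & tot > 0
  if (!is.null(amplitude_mask)) {
    stopifnot(all(dim(amplitude_mask) == dim(tot)))
    valid <- valid & amplitude_mask
  }
  so2 <- 100 * conc$c_hbo2 / tot
  so2 <- pmin(pmax(so2, 0), 100)
  so2[!valid] <- NA_real_
  structure(so2, class = c("so2_map", "matrix", "array"), valid = valid)
}

#' Amplitude display gate from a robust noise estimate
#'
#' Marks pixels whose mean energy-normalized PA amplitude across the two
#' wavelengths exceeds `k` times a robust noise scale (median absolute
#' deviation of the background region, or of the whole image when no
#' background is identified).
#'
#' @param p1,p2 energy-normalized PA amplitude matrices (e.g. `pa / E`).
#' @param k gate multiple (default 2).
#' @param background optional logical matrix selecting noise-only pixels.
#' @return logical matrix.
#' @export
amplitude_mask <- function(p1, p2, k = 2, background = NULL) {
  stopifnot(all(dim(p1) == dim(p2)))
  amp <- (abs(unclass(p1)) + abs(unclass(p2))) / 2
  ref <- if (is.null(background)) amp else amp[background]
  noise <- stats::mad(ref, center = stats::median(ref))
  if (noise == 0) noise <- stats::sd(ref)
  amp > k * noise
}

#' Mean oxygen saturation over a rectangular region of interest
#'
#' @param m an `so2_map`.
#' @param roi region in mm: `c(x_min, x_max, z_min, z_max)` with x measured
#'   laterally from the image center and z as depth below the transducer.
#' @param pitch pixel pitch, mm.
#' @return list with `mean` (percent), `n_valid` and `n_total` pixel counts.
#' @export
roi_mean_so2 <- function(m, roi, pitch = 0.074) {
  stopifnot(inherits(m, "so2_map"), length(roi) == 4)
  idx <- roi_indices(dim(m), roi, pitch)
  if (length(idx$rows) == 0 || length(idx$cols) == 0) {
    stop("ROI does not intersect the image")
  }
  vals <- m[idx$rows, idx$cols]
  n_total <- length(vals)
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("no valid sO2 pixels inside the ROI")
  list(mean = mean(vals), n_valid = length(vals), n_total = n_total)
}

# rectangle in mm -> row/col index ranges on the image raster
roi_indices <- function(dm, roi, pitch) {
  nz <- dm[1]; nx <- dm[2]
  xc <- (seq_len(nx) - 0.5) * pitch
  xc <- xc - mean(xc)
  zc <- (seq_len(nz) - 0.5) * pitch
  list(rows = which(zc >= roi[3] & zc <= roi[4]),
       cols = which(xc >= roi[1] & xc <= roi[2]))
}
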