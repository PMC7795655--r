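#' Probe configuration for a dual-wavelength LED photoacoustic probe
#'
#' Describes an AcousticX-style probe: a linear-array ultrasound transducer
#' flanked by two LED units tilted toward the imaging plane, each unit holding
#' alternating rows of 850 nm and 750 nm elements. Defaults encode the probe
#' used throughout the package: two units of four rows
#' (850/750/850/750, 36/24/36/24 elements), tilted 41.4 degrees, with a
#' 120 degree emission cone per element and a 2:1 pulse-energy ratio
#' (850 nm : 750 nm).
#'
#' @param unit_length LED unit length along the lateral (x) axis, mm.
#' @param unit_width LED unit width across the tilted face, mm.
#' @param tilt_angle tilt of the unit face relative to the transducer face,
#'   degrees; must lie in (0, 90]. 0 is accepted only via `allow_flat = TRUE`
#'   internally for testing degenerate geometry.
#' @param unit_standoff depth of the unit's near edge in front of the
#'   transducer face, mm.
#' @param inter_unit_gap elevational gap between the two units' near edges, mm.
#' @param element_pitch element spacing within a row, mm.
#' @param row_pitch spacing between rows across the unit width, mm.
#' @param rows_per_unit list of `c(wavelength_nm, n_elements)` in order from
#'   the transducer outward across the unit width.
#' @param cone_full_angle full opening angle of each element's emission cone,
#'   degrees.
#' @param pulse_energy named numeric vector, wavelength (nm) to pulse energy
#'   in microjoules, e.g. `c("750" = 100, "850" = 200)`.
#' @param roi_start_depth depth below which the imaging plane is usable as a
#'   region of interest (below the advanced LED tips), mm. Kept as a
#'   configuration value rather than derived from the tilt geometry.
#'
#' @return An object of class `probe_config`.
#' @export
probe_config <- function(unit_length = 50,
                         unit_width = 10,
                         tilt_angle = 41.4,
                         unit_standoff = 0.15,
                         inter_unit_gap = 9.56,
                         element_pitch = 1.4,
                         row_pitch = 1.72,
                         rows_per_unit = list(c(850, 36), c(750, 24),
                                              c(850, 36), c(750, 24)),
                         cone_full_angle = 120,
                         pulse_energy = c("750" = 100, "850" = 200),
                         roi_start_depth = 9.2) {
  stopifnot(unit_length > 0, unit_width > 0, unit_standoff >= 0,
            inter_unit_gap >= 0, element_pitch > 0, row_pitch > 0,
            cone_full_angle > 0, cone_full_angle <= 360)
  if (!(tilt_angle >= 0 && tilt_angle < 90)) {
    stop("tilt_angle must lie in [0, 90) degrees")
  }
  rows <- lapply(rows_per_unit, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2 || r[2] < 1) stop("each row must be c(wavelength, count) with count >= 1")
    r
  })
  counts <- vapply(rows, `[`, numeric(1), 2)
  if (any(counts != round(counts))) stop("element counts must be integers")
  if (is.null(names(pulse_energy)) || any(!is.finite(pulse_energy)) ||
      any(pulse_energy <= 0)) {
    stop("pulse_energy must be a named positive vector (wavelength nm -> uJ)")
  }
  wl_rows <- unique(vapply(rows, `[`, numeric(1), 1))
  missing_e <- setdiff(as.character(wl_rows), names(pulse_energy))
  if (length(missing_e)) {
    stop("pulse_energy missing for wavelength(s): ", paste(missing_e, collapse = ", "))
  }
  # rows must fit within the unit footprint at the stated pitches
  spans <- (counts - 1) * element_pitch
  if (any(spans > unit_length + 1e-9)) {
    stop("row of ", max(counts), " elements at pitch ", element_pitch,
         " mm does not fit within unit_length = ", unit_length, " mm")
  }
  if ((length(rows) - 1) * row_pitch > unit_width + 1e-9) {
    stop("rows do not fit within unit_width at the stated row_pitch")
  }
  structure(list(
    unit_length = unit_length, unit_width = unit_width,
    tilt_angle = tilt_angle, unit_standoff = unit_standoff,
    inter_unit_gap = inter_unit_gap, element_pitch = element_pitch,
    row_pitch = row_pitch, rows_per_unit = rows,
    cone_full_angle = cone_full_angle,
    pulse_energy = pulse_energy,
    roi_start_depth = roi_start_depth
  ), class = "probe_config")
}

#' @export
print.probe_config <- function(x, ...) {
  n_el <- sum(vapply(x$rows_per_unit, `[`, numeric(1), 2))
  cat("<probe_config>\n")
  cat(sprintf("  2 LED units, %d elements each, tilt %.1f deg, gap %.2f mm\n",
              as.integer(n_el), x$tilt_angle, x$inter_unit_gap))
  cat(sprintf("  cone %g deg full angle; pulse energy [uJ]: %s\n",
              x$cone_full_angle,
              paste(names(x$pulse_energy), x$pulse_energy, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read or write a probe configuration as YAML
#'
#' The YAML document mirrors [probe_config()] field for field. A bundled file
#' with the default probe is available at
#' `system.file("extdata", "probe_acousticx.yaml", package = "paflux")`.
#'
#' @param path file path.
#' @return `read_probe_config()` returns a `probe_config`;
#'   `write_probe_config()` returns `path` invisibly.
#' @export
read_probe_config <- function(path) {
  doc <- yaml::read_yaml(path)
  doc$rows_per_unit <- lapply(doc$rows_per_unit, function(r) c(r$wavelength, r$elements))
  pe <- vapply(doc$pulse_energy, as.numeric, numeric(1))
  doc$pulse_energy <- stats::setNames(as.numeric(pe), names(pe))
  do.call(probe_config, doc)
}

#' @rdname read_probe_config
#' @param cfg a `probe_config`.
#' @export
write_probe_config <- function(cfg, path) {
  doc <- unclass(cfg)
  doc$rows_per_unit <- lapply(doc$rows_per_unit, function(r)
    list(wavelength = r[1], elements = as.integer(r[2])))
  doc$pulse_energy <- as.list(doc$pulse_energy)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Construct the LED source set in simulation coordinates
#'
#' Places every LED element of both units in the simulation frame and assigns
#' emission axes and relative powers. Coordinates: x lateral (along the
#' transducer array, 0 at the image center), y elevational (0 on the imaging
#' plane), z depth (0 at the transducer face, increasing into the medium).
#'
#' Each unit's near edge sits at `y = +/- inter_unit_gap / 2`,
#' `z = unit_standoff`; the face extends across its width tilted by
#' `tilt_angle` away from the imaging plane and into the medium. Emission
#' axes are the tilted face normals, pointing into the medium and toward the
#' imaging plane, so the two units' cones converge under the transducer.
#' Energy is split equally among elements of the same wavelength; the
#' per-wavelength pulse energies carry the (default 2:1) power ratio.
#'
#' @param cfg a [probe_config()].
#' @return A data frame of class `led_sources` with one row per element:
#'   `x`, `y`, `z` (mm), emission axis `ax`, `ay`, `az` (unit vector),
#'   `half_angle` (degrees), `wavelength` (nm), `relative_power` (sums to 1
#'   within each wavelength) and `energy` (uJ).
#' @export
build_led_sources <- function(cfg) {
  stopifnot(inherits(cfg, "probe_config"))
  th <- cfg$tilt_angle * pi / 180
  n_rows <- length(cfg$rows_per_unit)
  # row offsets across the width, centered on the face
  w_off <- (seq_len(n_rows) - 1) * cfg$row_pitch
  w_off <- w_off - mean(w_off) + cfg$unit_width / 2

  rows <- list()
  for (side in c(+1, -1)) {
    for (j in seq_len(n_rows)) {
      wl <- cfg$rows_per_unit[[j]][1]
      n <- cfg$rows_per_unit[[j]][2]
      xs <- (seq_len(n) - 1) * cfg$element_pitch
      xs <- xs - mean(xs)                      # rows centered along unit length
      y0 <- cfg$inter_unit_gap / 2
      rows[[length(rows) + 1L]] <- data.frame(
        x = xs,
        y = side * (y0 + w_off[j] * cos(th)),
        z = cfg$unit_standoff + w_off[j] * sin(th),
        ax = 0,
        ay = -side * sin(th),
        az = cos(th),
        half_angle = cfg$cone_full_angle / 2,
        wavelength = wl,
        unit = side
      )
    }
  }
  el <- do.call(rbind, rows)
  # equal split within a wavelength; relative_power sums to 1 per wavelength
  n_wl <- table(el$wavelength)
  el$relative_power <- 1 / as.numeric(n_wl[as.character(el$wavelength)])
  el$energy <- cfg$pulse_energy[as.character(el$wavelength)] * el$relative_power
  rownames(el) <- NULL
  class(el) <- c("led_sources", "data.frame")
  attr(el, "pulse_energy") <- cfg$pulse_energy
  el
}

#' Total source energy share of one wavelength
#'
#' Returns the fraction of the probe's total pulse energy carried by all
#' elements of `wavelength`. With the default probe the 850 nm share is twice
#' the 750 nm share.
#'
#' @param elements a `led_sources` data frame from [build_led_sources()].
#' @param wavelength wavelength in nm.
#' @return The dimensionless energy share in (0, 1).
#' @export
total_source_weight <- function(elements, wavelength) {
  stopifnot(nrow(elements) > 0)
  sel <- elements$wavelength == wavelength
  if (!any(sel)) {
    stop("no elements at wavelength ", wavelength, " nm in this source set")
  }
  sum(elements$energy[sel]) / sum(elements$energy)
}

#' Subset a source set to one wavelength
#' @param elements a `led_sources` data frame.
#' @param wavelength wavelength in nm.
#' @return the matching rows, still a `led_sources` data frame.
#' @export
sources_at <- function(elements, wavelength) {
  sel <- elements$wavelength == wavelength
  if (!any(sel)) stop("no elements at wavelength ", wavelength, " nm")
  out <- elements[sel, , drop = FALSE]
  class(out) <- c("led_sources", "data.frame")
  attr(out, "pulse_energy") <- attr(elements, "pulse_energy")
  out
}
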