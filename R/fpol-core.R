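# Core polarization-image processing: validity masking, frame averaging,
# emission images, G-factor calibration, and per-pixel / per-cell Fpol.

#' Construct a polarized field
#'
#' Bundles the co-polarized and cross-polarized frame stacks acquired over one
#' field of view together with the instrument calibration factor G and the
#' pixel pitch. Stacks are `H x W x F` arrays (F frames); a plain matrix is
#' treated as a single frame. Pixel values are 8-bit counts in [0, 255].
#'
#' @param co_frames,cross_frames numeric arrays `H x W x F` (or `H x W`).
#' @param g_factor instrument calibration factor G (> 0); corrects the unequal
#'   sensitivity of the two detection arms. Default 0.75.
#' @param pixel_pitch_um physical pixel size in micrometres.
#' @param field_id identifier carried through to outputs.
#' @return A `polarized_field` object.
#' @export
polarized_field <- function(co_frames, cross_frames, g_factor = 0.75,
                            pixel_pitch_um, field_id = "field") {
  co <- .as_stack(co_frames)
  cross <- .as_stack(cross_frames)
  if (!identical(dim(co), dim(cross))) {
    stop("co and cross stacks must have identical dimensions", call. = FALSE)
  }
  if (dim(co)[3L] < 1L) stop("at least one frame is required", call. = FALSE)
  if (!is.numeric(g_factor) || length(g_factor) != 1L || g_factor <= 0) {
    stop("g_factor must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch_um) || pixel_pitch_um <= 0) {
    stop("pixel_pitch_um must be positive", call. = FALSE)
  }
  structure(list(co_frames = co, cross_frames = cross, g_factor = g_factor,
                 pixel_pitch_um = pixel_pitch_um, field_id = field_id),
            class = "polarized_field")
}

.as_stack <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("frames must be a matrix or an H x W x F array", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.polarized_field <- function(x, ...) {
  d <- dim(x$co_frames)
  cat(sprintf("Polarized field '%s': %d x %d px, %d frame(s)/channel, G = %g, pitch = %g um/px\n",
              x$field_id, d[1], d[2], d[3], x$g_factor, x$pixel_pitch_um))
  invisible(x)
}

#' Build the pixel validity mask
#'
#' A pixel is invalid if, in any frame of either channel, its value falls
#' below `low` (background) or above `high` (saturation). With the 8-bit
#' defaults this removes background pixels with values below 3 and saturated
#' pixels with values greater than 254. A pixel failing both rules is counted
#' once, under the background rule.
#'
#' @param co_frames,cross_frames stacks as in [polarized_field()].
#' @param low background threshold: values `< low` are excluded (default 3).
#' @param high saturation threshold: values `> high` are excluded (default 254).
#' @return A `validity_mask`: list with logical matrix `valid`,
#'   `n_background_excluded` and `n_saturated_excluded`.
#' @export
make_validity_mask <- function(co_frames, cross_frames, low = 3, high = 254) {
  co <- .as_stack(co_frames)
  cross <- .as_stack(cross_frames)
  if (!identical(dim(co), dim(cross))) {
    stop("co and cross stacks must have identical dimensions", call. = FALSE)
  }
  if (low < 0 || high > 255 || low > high) {
    stop("thresholds must satisfy 0 <= low <= high <= 255", call. = FALSE)
  }
  any_frame <- function(stack, test) {
    apply(test(stack), c(1L, 2L), any)
  }
  bg <- any_frame(co, function(s) s < low) | any_frame(cross, function(s) s < low)
  sat <- (any_frame(co, function(s) s > high) |
            any_frame(cross, function(s) s > high)) & !bg
  structure(list(valid = !(bg | sat),
                 n_background_excluded = sum(bg),
                 n_saturated_excluded = sum(sat)),
            class = "validity_mask")
}

#' Average a frame stack under a validity mask
#'
#' Per-pixel arithmetic mean over frames. Invalid pixels carry `NA`, the
#' package-wide sentinel for censored pixels, and are excluded from all
#' downstream sums.
#'
#' @param frames an `H x W x F` stack (or matrix).
#' @param validity optional [make_validity_mask()] result.
#' @return A numeric `H x W` matrix.
#' @export
average_frames <- function(frames, validity = NULL) {
  stack <- .as_stack(frames)
  avg <- rowMeans(stack, dims = 2L)
  if (!is.null(validity)) {
    if (!identical(dim(validity$valid), dim(avg))) {
      stop("validity mask dimensions do not match the frames", call. = FALSE)
    }
    avg[!validity$valid] <- NA_real_
  }
  avg
}

#' Threshold and average both channels of a field
#'
#' Applies [make_validity_mask()] jointly to both channels, then averages
#' each channel's frames, returning the matched pair used by every
#' quantitative operation downstream.
#'
#' @param field a [polarized_field()].
#' @param low,high validity thresholds, see [make_validity_mask()].
#' @return An `averaged_pair`: `fco_avg`, `fcross_avg`, `validity`,
#'   `g_factor`, `pixel_pitch_um`, `field_id`.
#' @export
average_channels <- function(field, low = 3, high = 254) {
  stopifnot(inherits(field, "polarized_field"))
  validity <- make_validity_mask(field$co_frames, field$cross_frames,
                                 low = low, high = high)
  structure(list(fco_avg = average_frames(field$co_frames, validity),
                 fcross_avg = average_frames(field$cross_frames, validity),
                 validity = validity,
                 g_factor = field$g_factor,
                 pixel_pitch_um = field$pixel_pitch_um,
                 field_id = field$field_id),
            class = "averaged_pair")
}

#' Fluorescence polarization from channel intensities
#'
#' Computes `Fpol = (Fco - G * Fcross) / (Fco + G * Fcross)`, the
#' G-corrected polarization ratio. Vectorized; `NA` inputs yield `NA`.
#'
#' @param fco,fcross non-negative fluorescence intensities (counts).
#' @param g calibration factor G (> 0).
#' @param na_undefined if `TRUE`, pixels with a non-positive denominator
#'   return `NA` instead of raising an error (used for per-pixel maps, where
#'   the caller skips such pixels).
#' @return Fpol values in [-1, 1] (the endpoints correspond to purely
#'   cross- and purely co-polarized emission).
#' @export
compute_fpol <- function(fco, fcross, g, na_undefined = FALSE) {
  if (!is.numeric(g) || length(g) != 1L || g <= 0) {
    stop("g must be a positive scalar", call. = FALSE)
  }
  if (any(fco < 0, na.rm = TRUE) || any(fcross < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  den <- fco + g * fcross
  bad <- !is.na(den) & den <= 0
  if (any(bad)) {
    if (!na_undefined) {
      stop("Fpol undefined: denominator Fco + G*Fcross is zero", call. = FALSE)
    }
    den[bad] <- NA_real_
  }
  (fco - g * fcross) / den
}

#' Fluorescence emission image
#'
#' Total detected signal after G calibration. The default convention is
#' `Fco + G * Fcross`, i.e. the denominator of the polarization ratio;
#' the uncorrected sum and the cuvette-fluorimetry total `Fco + 2 G Fcross`
#' are available as alternatives.
#'
#' @param pair an [average_channels()] result.
#' @param convention emission formula to use.
#' @return Numeric matrix; invalid pixels stay `NA`.
#' @export
compute_emission <- function(pair,
                             convention = c("co_plus_g_cross", "co_plus_cross",
                                            "co_plus_2g_cross")) {
  stopifnot(inherits(pair, "averaged_pair"))
  convention <- match.arg(convention)
  switch(convention,
         co_plus_g_cross = pair$fco_avg + pair$g_factor * pair$fcross_avg,
         co_plus_cross = pair$fco_avg + pair$fcross_avg,
         co_plus_2g_cross = pair$fco_avg + 2 * pair$g_factor * pair$fcross_avg)
}

#' Per-pixel Fpol map
#'
#' Applies the polarization ratio pixelwise on valid pixels; invalid pixels
#' and pixels with a zero denominator carry `NA`.
#'
#' @param pair an [average_channels()] result.
#' @return Numeric matrix of per-pixel Fpol.
#' @export
fpol_map <- function(pair) {
  stopifnot(inherits(pair, "averaged_pair"))
  compute_fpol(pair$fco_avg, pair$fcross_avg, pair$g_factor,
               na_undefined = TRUE)
}

#' Estimate the instrument G factor from a reference specimen
#'
#' For a specimen of known polarization `reference_fpol` (default 0: an
#' isotropic fluorophore solution), the calibration factor is the ratio of
#' mean valid-pixel intensities scaled by
#' `(1 - reference_fpol) / (1 + reference_fpol)`.
#'
#' @param co_frames,cross_frames reference-specimen stacks.
#' @param reference_fpol known Fpol of the reference (default 0).
#' @param low,high validity thresholds, see [make_validity_mask()].
#' @return Estimated G.
#' @export
estimate_g <- function(co_frames, cross_frames, reference_fpol = 0,
                       low = 3, high = 254) {
  if (reference_fpol <= -1 || reference_fpol >= 1) {
    stop("reference_fpol must lie in (-1, 1)", call. = FALSE)
  }
  validity <- make_validity_mask(co_frames, cross_frames, low = low, high = high)
  co_avg <- average_frames(co_frames, validity)
  cross_avg <- average_frames(cross_frames, validity)
  m_co <- mean(co_avg, na.rm = TRUE)
  m_cross <- mean(cross_avg, na.rm = TRUE)
  if (!is.finite(m_cross) || m_cross == 0) {
    stop("calibration failed: no cross-polarized signal in valid pixels",
         call. = FALSE)
  }
  (m_co / m_cross) * (1 - reference_fpol) / (1 + reference_fpol)
}

#' Per-cell Fpol from a label map
#'
#' For each labelled cell, sums the valid-pixel intensities of each averaged
#' channel over the cell and applies the polarization ratio once to the
#' aggregates: an intensity-weighted cell Fpol, not the mean of pixelwise
#' Fpol values. Cells with no valid pixels are dropped with a warning. The
#' mean-of-pixelwise-Fpol estimate is optionally reported alongside for
#' sensitivity analysis.
#'
#' @param labels integer label matrix (0 = background), same size as the field.
#' @param pair an [average_channels()] result.
#' @param pixelwise_mean also report the unweighted mean of per-pixel Fpol.
#' @return Data frame: `field_id`, `label`, `n_pixels` (valid pixels used),
#'   `area_um2`, `equivalent_diameter_um`, `fco_sum`, `fcross_sum`, `fpol`
#'   (and `fpol_pixelwise_mean` if requested).
#' @export
cell_fpol <- function(labels, pair, pixelwise_mean = FALSE) {
  stopifnot(inherits(pair, "averaged_pair"))
  if (!identical(dim(labels), dim(pair$fco_avg))) {
    stop("label map dimensions do not match the field", call. = FALSE)
  }
  ids <- sort(unique(labels[labels > 0]))
  out <- vector("list", length(ids))
  dropped <- character(0)
  pw <- if (pixelwise_mean) fpol_map(pair) else NULL
  for (i in seq_along(ids)) {
    sel <- labels == ids[i]
    fco <- pair$fco_avg[sel]
    fcross <- pair$fcross_avg[sel]
    ok <- !is.na(fco) & !is.na(fcross)
    if (!any(ok)) {
      dropped <- c(dropped, as.character(ids[i]))
      next
    }
    geom <- cell_geometry(sum(ok), pair$pixel_pitch_um)
    row <- data.frame(field_id = pair$field_id, label = ids[i],
                      n_pixels = sum(ok),
                      area_um2 = geom$area_um2,
                      equivalent_diameter_um = geom$equivalent_diameter_um,
                      fco_sum = sum(fco[ok]), fcross_sum = sum(fcross[ok]),
                      fpol = compute_fpol(sum(fco[ok]), sum(fcross[ok]),
                                          pair$g_factor),
                      stringsAsFactors = FALSE)
    if (pixelwise_mean) row$fpol_pixelwise_mean <- mean(pw[sel], na.rm = TRUE)
    out[[i]] <- row
  }
  if (length(dropped)) {
    warning("cells with no valid pixels excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(field_id = character(0), label = integer(0),
                      n_pixels = integer(0), area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      fco_sum = numeric(0), fcross_sum = numeric(0),
                      fpol = numeric(0), stringsAsFactors = FALSE))
  }
  rownames_reset(do.call(rbind, out))
}

rownames_reset <- function(df) { rownames(df) <- NULL; df }

#' Process one field end to end
#'
#' Convenience wrapper: threshold, average, and quantify every labelled cell
#' of a field.
#'
#' @param field a [polarized_field()].
#' @param labels integer label matrix.
#' @param low,high validity thresholds.
#' @return Per-cell data frame as in [cell_fpol()].
#' @export
process_field <- function(field, labels, low = 3, high = 254) {
  cell_fpol(labels, average_channels(field, low = low, high = high))
}
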