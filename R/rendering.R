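# Visual products: digitally stained emission images (pseudo-Papanicolaou)
# and pseudo-colored Fpol maps on a fixed scale. Pure view layer: nothing
# here feeds back into quantitative outputs.

#' Digital staining palette
#'
#' Colors used to mimic a Papanicolaou-stained appearance: bright (nuclear)
#' pixels map onto a blue-purple ramp, the remaining foreground onto a
#' blue-green ramp, split at a per-field intensity quantile.
#'
#' @param nucleus_color,cytoplasm_color,background_color 8-bit RGB triples.
#' @param nucleus_intensity_quantile foreground-intensity quantile above
#'   which pixels are colored as nuclei (default 0.65).
#' @return A `stain_palette` list.
#' @export
stain_palette <- function(nucleus_color = c(96, 64, 168),
                          cytoplasm_color = c(96, 176, 160),
                          background_color = c(236, 236, 240),
                          nucleus_intensity_quantile = 0.65) {
  chk <- function(x, what) {
    if (length(x) != 3L || any(x < 0) || any(x > 255)) {
      stop(what, " must be an RGB triple in [0, 255]", call. = FALSE)
    }
    x
  }
  if (nucleus_intensity_quantile <= 0 || nucleus_intensity_quantile >= 1) {
    stop("nucleus_intensity_quantile must lie in (0, 1)", call. = FALSE)
  }
  structure(list(nucleus_color = chk(nucleus_color, "nucleus_color"),
                 cytoplasm_color = chk(cytoplasm_color, "cytoplasm_color"),
                 background_color = chk(background_color, "background_color"),
                 nucleus_intensity_quantile = nucleus_intensity_quantile),
            class = "stain_palette")
}

#' Digitally stain an emission image
#'
#' Foreground pixels above the palette's intensity quantile are rendered on
#' the nuclear (blue-purple) ramp, the remaining foreground on the
#' cytoplasmic (blue-green) ramp; ramp luminance follows emission intensity.
#' Background and invalid pixels take the background color. Deterministic.
#'
#' @param emission emission image matrix (`NA` = invalid).
#' @param palette a [stain_palette()].
#' @return `H x W x 3` numeric array of 8-bit RGB values.
#' @export
digital_stain <- function(emission, palette = stain_palette()) {
  stopifnot(inherits(palette, "stain_palette"))
  fg <- !is.na(emission) & emission > 0
  out <- array(0, dim = c(dim(emission), 3L))
  for (k in 1:3) out[, , k] <- palette$background_color[k]
  if (!any(fg)) return(out)
  vals <- emission[fg]
  if (max(vals) == min(vals)) {
    warning("degenerate intensity distribution; staining all foreground as ",
            "cytoplasm", call. = FALSE)
    cut <- Inf
  } else {
    cut <- stats::quantile(vals, palette$nucleus_intensity_quantile,
                           names = FALSE)
  }
  # luminance ramp: 0.45..1 of the base color across intensity
  lum <- 0.45 + 0.55 * (vals - min(vals)) /
    max(max(vals) - min(vals), .Machine$double.eps)
  nuc <- vals >= cut
  for (k in 1:3) {
    plane <- out[, , k]
    col <- ifelse(nuc, palette$nucleus_color[k], palette$cytoplasm_color[k])
    plane[fg] <- col * lum
    out[, , k] <- plane
  }
  out
}

#' Pseudo-color an Fpol map on a fixed scale
#'
#' Linear black-to-red ramp: `lo` maps to black, `hi` to full red, values
#' outside the range clamp to the endpoints. Invalid (`NA`) pixels take the
#' background color. A color-scale table accompanies the image.
#'
#' @param fpol numeric Fpol matrix (`NA` = invalid).
#' @param lo,hi scale endpoints (defaults 0.0 and 0.40).
#' @param background_color RGB triple for invalid pixels (default black).
#' @return List: `rgb` (`H x W x 3` 8-bit array) and `scale` (data frame
#'   mapping Fpol values to ramp colors).
#' @export
pseudo_color_fpol <- function(fpol, lo = 0.0, hi = 0.40,
                              background_color = c(0, 0, 0)) {
  if (lo >= hi) stop("lo must be smaller than hi", call. = FALSE)
  t <- (fpol - lo) / (hi - lo)
  t[t < 0] <- 0
  t[t > 1] <- 1
  out <- array(0, dim = c(dim(fpol), 3L))
  red <- 255 * t
  red[is.na(red)] <- background_color[1L]
  out[, , 1L] <- red
  g <- array(background_color[2L], dim(fpol)); g[!is.na(t)] <- 0
  b <- array(background_color[3L], dim(fpol)); b[!is.na(t)] <- 0
  out[, , 2L] <- g
  out[, , 3L] <- b
  ticks <- seq(lo, hi, length.out = 9L)
  list(rgb = out,
       scale = data.frame(fpol = ticks,
                          red = 255 * (ticks - lo) / (hi - lo),
                          green = 0, blue = 0))
}

#' Burn a scale bar into a rendered RGB image
#'
#' Draws a horizontal bar of physical length `length_um` (default 50 um) in
#' the lower-right corner.
#'
#' @param rgb `H x W x 3` 8-bit RGB array.
#' @param pitch pixel pitch, um/px.
#' @param length_um bar length in micrometres.
#' @param color RGB triple (default white).
#' @return The RGB array with the bar drawn.
#' @export
add_scale_bar <- function(rgb, pitch, length_um = 50, color = c(255, 255, 255)) {
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  len <- min(w - 2L, max(1L, round(length_um / pitch)))
  rows <- (h - 14L):(h - 10L)
  cols <- (w - 8L - len):(w - 8L)
  rows <- rows[rows >= 1L]; cols <- cols[cols >= 1L]
  for (k in 1:3) rgb[rows, cols, k] <- color[k]
  rgb
}

#' Write an 8-bit RGB array as PNG
#' @param rgb `H x W x 3` array with values in [0, 255].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_render_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}
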