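# File interfaces: multi-page grayscale TIFF stacks with JSON sidecars,
# float TIFF maps, label masks, and per-cell CSV exports.

#' Write a polarized field to paired TIFF files
#'
#' Each channel is written as a multi-page 8-bit grayscale TIFF (one page per
#' frame) next to a JSON sidecar carrying `g_factor`, `fov_um` and
#' `field_id`.
#'
#' @param field a [polarized_field()].
#' @param co_path,cross_path output TIFF paths.
#' @param sidecar_path output JSON path (default: `co_path` with `.json`).
#' @return Invisibly, the sidecar path.
#' @export
write_polarized_field <- function(field, co_path, cross_path,
                                  sidecar_path = sub("\\.tiff?$", ".json",
                                                     co_path)) {
  stopifnot(inherits(field, "polarized_field"))
  to_pages <- function(stack) {
    lapply(seq_len(dim(stack)[3L]), function(f) stack[, , f] / 255)
  }
  tiff::writeTIFF(to_pages(field$co_frames), co_path, bits.per.sample = 8L)
  tiff::writeTIFF(to_pages(field$cross_frames), cross_path,
                  bits.per.sample = 8L)
  d <- dim(field$co_frames)
  jsonlite::write_json(list(field_id = field$field_id,
                            g_factor = field$g_factor,
                            fov_um = field$pixel_pitch_um * d[2L],
                            n_frames = d[3L]),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}

#' Read a polarized field from paired TIFF files
#'
#' @param co_path,cross_path multi-page 8-bit grayscale TIFFs (pages =
#'   frames).
#' @param sidecar_path JSON sidecar with `g_factor`, `fov_um`, `field_id`;
#'   defaults to `co_path` with a `.json` extension.
#' @return A [polarized_field()].
#' @export
read_polarized_field <- function(co_path, cross_path,
                                 sidecar_path = sub("\\.tiff?$", ".json",
                                                    co_path)) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  from_pages <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    stack <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
    for (f in seq_along(pages)) stack[, , f] <- round(pages[[f]] * 255)
    stack
  }
  co <- from_pages(co_path)
  polarized_field(co, from_pages(cross_path), g_factor = meta$g_factor,
                  pixel_pitch_um = meta$fov_um / dim(co)[2L],
                  field_id = meta$field_id)
}

#' Write an Fpol (or emission) map as a 32-bit float TIFF
#'
#' TIFF float storage in this toolchain is defined on [0, 1], so values are
#' stored affinely as `(value - lo) / (hi - lo)`; invalid (`NA`) pixels are
#' stored as 0, one representable step below the smallest admissible Fpol.
#' [read_float_map()] inverts the encoding. The encoding bounds travel in a
#' JSON sidecar.
#'
#' @param map numeric matrix (e.g. [fpol_map()] output), `NA` = invalid.
#' @param path output TIFF path.
#' @param lo,hi encoding bounds; defaults cover the Fpol range (-1, 1].
#' @return Invisibly, `path`.
#' @export
write_float_map <- function(map, path, lo = -1, hi = 1) {
  enc <- (map - lo) / (hi - lo)
  enc[is.na(enc)] <- 0
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(lo = lo, hi = hi, invalid = 0),
                       sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a float map written by [write_float_map()]
#' @param path TIFF path.
#' @return Numeric matrix with `NA` for invalid pixels.
#' @export
read_float_map <- function(path) {
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  enc <- tiff::readTIFF(path)
  out <- enc * (meta$hi - meta$lo) + meta$lo
  out[enc == meta$invalid] <- NA_real_
  out
}

#' Write per-cell records to CSV
#' @param cells per-cell data frame ([cell_fpol()] or [simulate_cells()]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cell_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
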