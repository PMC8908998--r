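# Cell regions: label-mask ingestion, an automated fallback segmentation,
# and cell geometry.

# Relabel positive labels to consecutive integers preserving order.
relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- labels
  for (i in seq_along(ids)) out[labels == ids[i]] <- i
  storage.mode(out) <- "integer"
  list(labels = out,
       mapping = data.frame(original = ids, relabeled = seq_along(ids)))
}

#' Load a cell label mask from a single-page integer TIFF
#'
#' Labels are validated and relabeled to consecutive positive integers
#' preserving their original order; the mapping is attached.
#'
#' @param path single-page 16-bit (or 8-bit) label TIFF; 0 = background.
#' @param expected_dim optional `c(H, W)` to enforce the field dimensions.
#' @return A `cell_label_map`: list with integer matrix `labels`,
#'   `provenance = "manual_import"`, `n_cells` and the relabel `mapping`.
#' @export
load_label_mask <- function(path, expected_dim = NULL) {
  raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.list(raw)) {
    if (length(raw) != 1L) stop("label mask must be a single-page TIFF",
                                call. = FALSE)
    raw <- raw[[1L]]
  }
  if (length(dim(raw)) != 2L) {
    stop("label mask must be a single grayscale plane", call. = FALSE)
  }
  if (any(raw != round(raw)) || any(raw < 0) || max(raw) > 65535) {
    stop("label mask must be integer-typed (8- or 16-bit), not floating-point",
         call. = FALSE)
  }
  if (!is.null(expected_dim) && !identical(dim(raw), as.integer(expected_dim))) {
    stop(sprintf("label mask is %d x %d but the field is %d x %d",
                 dim(raw)[1L], dim(raw)[2L], expected_dim[1L],
                 expected_dim[2L]), call. = FALSE)
  }
  rl <- relabel_consecutive(raw)
  structure(list(labels = rl$labels, provenance = "manual_import",
                 n_cells = nrow(rl$mapping), mapping = rl$mapping),
            class = "cell_label_map")
}

#' Write a label matrix as a 16-bit single-page TIFF
#' @param labels integer matrix, values in 0..65535.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Automated cell segmentation of an emission image
#'
#' Convenience fallback for unlabelled fields: global Otsu threshold on the
#' emission image, hole filling, distance-transform watershed to split
#' touching cells, and removal of components outside the admissible area
#' range. Deterministic for a fixed input. Quantitative analyses emulating
#' manually segmented data should use ground-truth or imported masks instead.
#'
#' @param emission emission image matrix (`NA` = invalid, treated as
#'   background).
#' @param pitch pixel pitch, um/px.
#' @param min_area_um2,max_area_um2 admissible cell area range (defaults
#'   20-2000 um^2).
#' @param watershed_tolerance minimum object-separation depth passed to the
#'   watershed (in distance-map units).
#' @return A `cell_label_map` with `provenance = "auto"`.
#' @export
auto_segment <- function(emission, pitch, min_area_um2 = 20,
                         max_area_um2 = 2000, watershed_tolerance = 1) {
  img <- emission
  img[is.na(img)] <- 0
  if (max(img) > 0) img <- img / max(img)
  if (all(img == 0)) {
    warning("no foreground found; returning empty label map", call. = FALSE)
    return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          provenance = "auto", n_cells = 0L,
                          mapping = data.frame(original = integer(0),
                                               relabeled = integer(0))),
                     class = "cell_label_map"))
  }
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  fg <- EBImage::fillHull(img > thr)
  if (sum(fg) == 0) {
    warning("no foreground found; returning empty label map", call. = FALSE)
    return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          provenance = "auto", n_cells = 0L,
                          mapping = data.frame(original = integer(0),
                                               relabeled = integer(0))),
                     class = "cell_label_map"))
  }
  dm <- EBImage::distmap(fg)
  labs <- EBImage::imageData(EBImage::watershed(dm,
                                                tolerance = watershed_tolerance))
  # area filter
  tab <- table(labs[labs > 0])
  areas <- as.numeric(tab) * pitch^2
  keep <- as.integer(names(tab))[areas >= min_area_um2 & areas <= max_area_um2]
  labs[!(labs %in% keep)] <- 0
  rl <- relabel_consecutive(labs)
  structure(list(labels = rl$labels, provenance = "auto",
                 n_cells = nrow(rl$mapping), mapping = rl$mapping),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("Cell label map (%s): %d cell(s), %d x %d px\n", x$provenance,
              x$n_cells, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Cell geometry from a pixel count
#'
#' @param n_pixels number of pixels in the cell (> 0).
#' @param pitch pixel pitch, um/px.
#' @return List with `area_um2` (`n_pixels * pitch^2`) and
#'   `equivalent_diameter_um` (`2 * sqrt(area / pi)`).
#' @export
cell_geometry <- function(n_pixels, pitch) {
  if (any(n_pixels <= 0)) stop("cell pixel set must be nonempty", call. = FALSE)
  area <- n_pixels * pitch^2
  list(area_um2 = area, equivalent_diameter_um = 2 * sqrt(area / pi))
}
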