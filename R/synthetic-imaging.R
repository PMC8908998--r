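# Synthetic polarization-resolved confocal imaging with known ground truth.
#
# The generator emulates the acquisition geometry of the quantitative
# pipeline's intended instrument: 8-bit co-/cross-polarized frame stacks over
# a 205 um x 205 um field of view, three frames per channel, with Poisson
# photon noise plus Gaussian read noise, and per-cell Fpol ground truth.

#' Imaging configuration for the synthetic generator
#'
#' @param image_size_px pixels per image side (default 512, i.e. 0.4 um/px
#'   over the default field of view).
#' @param fov_um field-of-view width in micrometres (default 205).
#' @param n_frames frames per channel (default 3).
#' @param g_factor instrument calibration factor G (default 0.75).
#' @param background_level mean background counts added everywhere (default 1,
#'   below the background-exclusion threshold of 3).
#' @param read_noise_sd Gaussian read noise SD in counts (default 1).
#' @param photon_scale photons per count for the Poisson noise model
#'   (default 1).
#' @param saturation_fraction target fraction of cell pixels pushed into
#'   saturation by rescaling the co-polarized signal (default 0: no rescale).
#' @param noise logical; `FALSE` disables Poisson and read noise (quantization
#'   and background remain).
#' @param cytoplasm_signal total (co + G*cross) signal per cytoplasm pixel,
#'   in counts (default 160).
#' @param nucleus_brightness nucleus/cytoplasm brightness ratio (default 1.8).
#' @param nucleus_area_fraction fraction of the cell area occupied by the
#'   nucleus (default 0.35).
#' @param cell_diameter_um range of equivalent cell diameters, um
#'   (default 8-25).
#' @param axis_ratio range of ellipse axis ratios (default 1-1.8).
#' @param max_coverage maximum fraction of a field's area covered by cells
#'   before spilling into a further field (default 0.2).
#' @return An `imaging_config` list; pixel pitch is `fov_um / image_size_px`.
#' @export
imaging_config <- function(image_size_px = 512L, fov_um = 205, n_frames = 3L,
                           g_factor = 0.75, background_level = 1,
                           read_noise_sd = 1, photon_scale = 1,
                           saturation_fraction = 0, noise = TRUE,
                           cytoplasm_signal = 160, nucleus_brightness = 1.8,
                           nucleus_area_fraction = 0.35,
                           cell_diameter_um = c(8, 25),
                           axis_ratio = c(1, 1.8), max_coverage = 0.2) {
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (g_factor <= 0) stop("g_factor must be positive", call. = FALSE)
  if (image_size_px < 16L) stop("image_size_px too small", call. = FALSE)
  structure(list(image_size_px = as.integer(image_size_px), fov_um = fov_um,
                 n_frames = as.integer(n_frames), bit_depth = 8L,
                 g_factor = g_factor, background_level = background_level,
                 read_noise_sd = read_noise_sd, photon_scale = photon_scale,
                 saturation_fraction = saturation_fraction, noise = noise,
                 cytoplasm_signal = cytoplasm_signal,
                 nucleus_brightness = nucleus_brightness,
                 nucleus_area_fraction = nucleus_area_fraction,
                 cell_diameter_um = cell_diameter_um, axis_ratio = axis_ratio,
                 max_coverage = max_coverage,
                 pixel_pitch_um = fov_um / image_size_px),
            class = "imaging_config")
}

#' Channel intensities realizing a target polarization
#'
#' Inverts the polarization ratio: given a target Fpol `p`, a total signal
#' `S = Fco + G * Fcross` (the ratio's denominator) and the calibration
#' factor `g`, returns the unique channel pair
#' `Fco = S (1 + p) / 2`, `Fcross = S (1 - p) / (2 g)`.
#' Feeding the outputs back through [compute_fpol()] returns `p` to machine
#' precision.
#'
#' @param target_fpol target polarization in (-1, 1]; vectorized.
#' @param total_signal total signal S > 0 (counts); vectorized.
#' @param g calibration factor (> 0).
#' @return List with components `fco` and `fcross`.
#' @examples
#' solve_intensities(0.25, 280, 0.75) # fco = 175, fcross = 140
#' @export
solve_intensities <- function(target_fpol, total_signal, g) {
  if (!is.numeric(g) || length(g) != 1L || g <= 0) {
    stop("g must be a positive scalar", call. = FALSE)
  }
  if (any(total_signal <= 0)) stop("total_signal must be positive", call. = FALSE)
  if (any(target_fpol <= -1 | target_fpol > 1)) {
    stop("target_fpol must lie in (-1, 1]", call. = FALSE)
  }
  list(fco = total_signal * (1 + target_fpol) / 2,
       fcross = total_signal * (1 - target_fpol) / (2 * g))
}

# Evaluate code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-sample child seed below 2^31.
child_seed <- function(seed, index) {
  (as.double(seed %% 65011) * 33013 + index * 7919) %% 2147483647 + 1
}

# Normal(mean, sd) truncated to (0, 1) by resampling; sd = 0 returns the mean.
rtrunc01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > 0 & x < 1])
  }
  out[seq_len(n)]
}

#' Simulate viable / non-viable counts for a sample
#'
#' Binomial draw emulating a dye-exclusion viability count after imaging.
#'
#' @param n_cells number of cells counted (>= 0).
#' @param viable_fraction probability a cell is viable, in [0, 1].
#' @param seed integer seed.
#' @return List with `n_viable` and `n_nonviable`; the two always sum to
#'   `n_cells`.
#' @export
generate_viability_counts <- function(n_cells, viable_fraction, seed = 1L) {
  if (n_cells < 0) stop("n_cells must be non-negative", call. = FALSE)
  if (viable_fraction < 0 || viable_fraction > 1) {
    stop("viable_fraction must lie in [0, 1]", call. = FALSE)
  }
  v <- with_seed(seed, stats::rbinom(1L, n_cells, viable_fraction))
  list(n_viable = v, n_nonviable = n_cells - v)
}

# --- image synthesis ---------------------------------------------------------

# Pixel set of an ellipse (centre cr/cc, semi-axes a/b px, angle theta).
.ellipse_mask <- function(size, cr, cc, a, b, theta) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(size, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(size, ceiling(cc + a))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  x <- dr * cos(theta) + dc * sin(theta)
  y <- -dr * sin(theta) + dc * cos(theta)
  inside <- (x / a)^2 + (y / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1L]], col = cols[idx[, 2L]])
}

# One noisy (or noiseless) 8-bit frame from a mean-signal image.
.realize_frame <- function(signal, cfg) {
  img <- signal
  if (cfg$noise) {
    img <- stats::rpois(length(signal), cfg$photon_scale * signal) /
      cfg$photon_scale
    img <- img + stats::rnorm(length(signal), 0, cfg$read_noise_sd)
    dim(img) <- dim(signal)
  }
  img <- img + cfg$background_level
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

#' Render one sample of a cohort plan as polarized image fields
#'
#' Draws each cell's true Fpol from a Normal(`fpol_mean`, `fpol_sd`)
#' truncated to (0, 1); lays cells out as non-overlapping ellipses with a
#' brighter concentric nuclear region; converts each pixel's total signal and
#' the cell's Fpol into co-/cross-polarized intensities via
#' [solve_intensities()]; and realizes `n_frames` independent noisy 8-bit
#' frames per channel. Cells spill into as many fields as needed to respect
#' the configured coverage limit. Deterministic given `(sample, imaging,
#' seed)`.
#'
#' @param sample one row of a [plan_cohort()] plan (data frame or list with
#'   `sample_id`, `n_cells`, `fpol_mean`, `fpol_sd`).
#' @param imaging an [imaging_config()].
#' @param seed integer seed.
#' @return A `rendered_sample` list: `fields` (list of
#'   [polarized_field()]), `label_maps` (matching integer label matrices,
#'   labels consecutive within each field), and `truth` (per-cell data frame
#'   with `field`, `label`, `true_fpol`, `true_total_signal`,
#'   `nucleus_pixels`, `cytoplasm_pixels`, `centroid_row`, `centroid_col`).
#' @export
render_sample <- function(sample, imaging = imaging_config(), seed = 1L) {
  sample <- as.list(sample)
  n <- as.integer(sample$n_cells)
  sid <- if (is.null(sample$sample_id)) "sample" else sample$sample_id
  size <- imaging$image_size_px
  pitch <- imaging$pixel_pitch_um

  empty_truth <- data.frame(sample_id = character(0), field = integer(0),
                            label = integer(0), true_fpol = numeric(0),
                            true_total_signal = numeric(0),
                            nucleus_pixels = integer(0),
                            cytoplasm_pixels = integer(0),
                            centroid_row = numeric(0),
                            centroid_col = numeric(0),
                            stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(fields = list(), label_maps = list(),
                          truth = empty_truth, sample_id = sid),
                     class = "rendered_sample"))
  }

  with_seed(seed, {
    true_fpol <- rtrunc01(n, sample$fpol_mean, sample$fpol_sd)
    diam_um <- stats::runif(n, imaging$cell_diameter_um[1],
                            imaging$cell_diameter_um[2])
    ratio <- stats::runif(n, imaging$axis_ratio[1], imaging$axis_ratio[2])
    theta <- stats::runif(n, 0, pi)

    # greedy packing of cells into fields under the coverage limit
    area_px <- pi * (diam_um / 2 / pitch)^2
    budget <- imaging$max_coverage * size^2
    field_of <- integer(n); acc <- 0; f <- 1L
    for (i in seq_len(n)) {
      if (acc + area_px[i] > budget && acc > 0) { f <- f + 1L; acc <- 0 }
      field_of[i] <- f; acc <- acc + area_px[i]
    }

    fields <- list(); label_maps <- list(); truth <- list()
    for (fi in seq_len(max(field_of))) {
      cells <- which(field_of == fi)
      labels <- matrix(0L, size, size)
      signal <- matrix(0, size, size)
      fco_img <- matrix(0, size, size)
      fcross_img <- matrix(0, size, size)
      occupied <- matrix(FALSE, size, size)
      for (k in seq_along(cells)) {
        i <- cells[k]
        a <- diam_um[i] / 2 * sqrt(ratio[i]) / pitch
        b <- diam_um[i] / 2 / sqrt(ratio[i]) / pitch
        placed <- FALSE
        for (try in 1:300) {
          cr <- stats::runif(1, a + 2, size - a - 1)
          cc <- stats::runif(1, a + 2, size - a - 1)
          px <- .ellipse_mask(size, cr, cc, a + 1.5, a + 1.5, 0) # margin disc
          if (any(occupied[px])) next
          cell_px <- .ellipse_mask(size, cr, cc, a, b, theta[i])
          occupied[px] <- TRUE
          nuc_px <- .ellipse_mask(size, cr, cc,
                                  a * sqrt(imaging$nucleus_area_fraction),
                                  b * sqrt(imaging$nucleus_area_fraction),
                                  theta[i])
          labels[cell_px] <- k
          s <- imaging$cytoplasm_signal
          signal[cell_px] <- s
          signal[nuc_px] <- s * imaging$nucleus_brightness
          ch <- solve_intensities(true_fpol[i], signal[cell_px],
                                  imaging$g_factor)
          fco_img[cell_px] <- ch$fco
          fcross_img[cell_px] <- ch$fcross
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sid, field = fi, label = k,
            true_fpol = true_fpol[i],
            true_total_signal = sum(signal[cell_px]),
            nucleus_pixels = nrow(nuc_px),
            cytoplasm_pixels = nrow(cell_px) - nrow(nuc_px),
            centroid_row = mean(cell_px[, "row"]),
            centroid_col = mean(cell_px[, "col"]),
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place cell without overlap; lower max_coverage so ",
               "cells spread over more fields", call. = FALSE)
        }
      }
      if (imaging$saturation_fraction > 0) {
        cell_sel <- labels > 0
        sc <- 255 / stats::quantile(fco_img[cell_sel],
                                    1 - imaging$saturation_fraction,
                                    names = FALSE)
        fco_img <- fco_img * sc
        fcross_img <- fcross_img * sc
      }
      co <- array(0, dim = c(size, size, imaging$n_frames))
      cross <- array(0, dim = c(size, size, imaging$n_frames))
      for (fr in seq_len(imaging$n_frames)) {
        co[, , fr] <- .realize_frame(fco_img, imaging)
        cross[, , fr] <- .realize_frame(fcross_img, imaging)
      }
      fields[[fi]] <- polarized_field(co, cross, g_factor = imaging$g_factor,
                                      pixel_pitch_um = pitch,
                                      field_id = sprintf("%s_f%d", sid, fi))
      label_maps[[fi]] <- labels
    }
    structure(list(fields = fields, label_maps = label_maps,
                   truth = if (length(truth)) rownames_reset(do.call(rbind, truth))
                           else empty_truth,
                   sample_id = sid),
              class = "rendered_sample")
  })
}

#' @export
print.rendered_sample <- function(x, ...) {
  cat(sprintf("Rendered sample '%s': %d cell(s) across %d field(s)\n",
              x$sample_id, nrow(x$truth), length(x$fields)))
  invisible(x)
}

#' Draw per-cell records directly from a cohort plan
#'
#' Fast statistical path used for cohort-level simulation studies: draws each
#' cell's Fpol from the sample's truncated Normal distribution and a cell
#' size from the configured diameter range, without synthesizing images. The
#' image path ([render_sample()] + [process_field()]) is the full-fidelity
#' route; this one preserves exactly the cell-level distributions.
#'
#' @param plan a [plan_cohort()] plan.
#' @param seed master seed; per-sample child seeds are derived
#'   deterministically so cohorts are reproducible piecewise.
#' @param cell_diameter_um range for the simulated cell diameters (um).
#' @return A per-cell data frame with plan metadata, `cell_id`, `area_um2`
#'   and `fpol`.
#' @export
simulate_cells <- function(plan, seed = 1L, cell_diameter_um = c(8, 25)) {
  plan <- validate_cohort_plan(plan)
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    n <- plan$n_cells[i]
    cs <- child_seed(seed, i)
    vals <- with_seed(cs, {
      f <- rtrunc01(n, plan$fpol_mean[i], plan$fpol_sd[i])
      d <- stats::runif(n, cell_diameter_um[1], cell_diameter_um[2])
      list(f = f, d = d)
    })
    out[[i]] <- data.frame(subject_id = plan$subject_id[i],
                           sample_id = plan$sample_id[i],
                           site = plan$site[i], diagnosis = plan$diagnosis[i],
                           tbsrtc = plan$tbsrtc[i], tissue = plan$tissue[i],
                           cell_id = sprintf("%s_c%d", plan$sample_id[i],
                                             seq_len(n)),
                           area_um2 = pi * (vals$d / 2)^2,
                           fpol = vals$f, stringsAsFactors = FALSE)
  }
  rownames_reset(do.call(rbind, out))
}
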