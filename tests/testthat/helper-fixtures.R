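# Shared fixtures: tiny fields and plans built in code.

# An averaged pair built from constant single-frame channels; low = 0 keeps
# zero-intensity channels valid for algebraic fixtures.
make_uniform_pair <- function(fco, fcross, g = 0.75, n = 4L, pitch = 0.4,
                              low = 0) {
  field <- polarized_field(matrix(fco, n, n), matrix(fcross, n, n),
                           g_factor = g, pixel_pitch_um = pitch,
                           field_id = "fix")
  average_channels(field, low = low)
}

# Small imaging config for fast rendering tests.
fast_imaging <- function(...) {
  imaging_config(image_size_px = 160L, ...)
}

# A two-group plan with identical Fpol distributions (null cohort scaffold).
null_plan <- function(n_subjects = 8L, n_cells = 30L, mean = 0.22, sd = 0.02,
                      sample_means = NULL) {
  rows <- list()
  for (grp in c("PTC", "FTA")) {
    for (s in seq_len(n_subjects)) {
      i <- length(rows) + 1L
      rows[[i]] <- data.frame(
        sample_id = sprintf("%s-%d", grp, s),
        subject_id = sprintf("%s-subj%d", grp, s),
        site = "UMMC", diagnosis = grp, tbsrtc = "III", tissue = "tumor",
        n_cells = n_cells,
        fpol_mean = if (is.null(sample_means)) mean else sample_means[i],
        fpol_sd = sd, stringsAsFactors = FALSE)
    }
  }
  validate_cohort_plan(do.call(rbind, rows))
}

# Brute-force Eq-oracle: double loop, no vectorized path shared with the
# implementation.
naive_fpol_map <- function(fco, fcross, g) {
  out <- matrix(NA_real_, nrow(fco), ncol(fco))
  for (i in seq_len(nrow(fco))) {
    for (j in seq_len(ncol(fco))) {
      a <- fco[i, j]; b <- fcross[i, j]
      if (is.na(a) || is.na(b)) next
      den <- a + g * b
      if (den > 0) out[i, j] <- (a - g * b) / den
    }
  }
  out
}

# Null-cohort sample means: identical distribution for both groups, with
# between-sample (subject) variability.
with_seed_means <- function(seed, n, mean = 0.22, sd = 0.008) {
  set.seed(seed + 50000L)
  rnorm(n, mean, sd)
}

# Jaccard index between two pixel sets given as logical matrices.
jaccard <- function(a, b) sum(a & b) / sum(a | b)
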