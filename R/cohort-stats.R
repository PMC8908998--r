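# Sample- and group-level aggregation, grouping schemes, threshold
# classification, and viability arithmetic.

#' Diagnostic class of a cell or sample
#'
#' Maps (diagnosis, tissue) to the three-way diagnostic classification:
#' normal tissue is `"normal"`; tumor-tissue MTC/PTC/FTC are `"malignant"`;
#' tumor-tissue FTA/MNG are `"benign"`.
#'
#' @param diagnosis,tissue character vectors.
#' @return Character vector of classes (`NA` where unmappable).
#' @export
diagnostic3_class <- function(diagnosis, tissue) {
  out <- rep(NA_character_, length(diagnosis))
  out[tissue == "normal"] <- "normal"
  out[tissue == "tumor" & diagnosis %in% .fpol_malignant] <- "malignant"
  out[tissue == "tumor" & diagnosis %in% .fpol_benign] <- "benign"
  out
}

#' Summarize one sample's cells
#'
#' Per-sample Fpol is the unweighted average of the per-cell Fpol values;
#' spread is the sample standard deviation (n - 1 denominator; 0 for a
#' single cell).
#'
#' @param cells per-cell data frame for exactly one sample, with an `fpol`
#'   column (metadata columns, if present, are carried through).
#' @return One-row data frame with `n_cells`, `fpol_mean`, `fpol_sd`.
#' @export
summarize_sample <- function(cells) {
  if (nrow(cells) == 0L) stop("cannot summarize an empty sample", call. = FALSE)
  n <- nrow(cells)
  meta <- intersect(c("subject_id", "sample_id", "site", "diagnosis",
                      "tbsrtc", "tissue"), names(cells))
  out <- if (length(meta)) unique(cells[, meta, drop = FALSE]) else
    data.frame(row.names = 1L)
  if (nrow(out) != 1L) {
    stop("cells belong to more than one sample; use summarize_samples()",
         call. = FALSE)
  }
  out$n_cells <- n
  out$fpol_mean <- mean(cells$fpol)
  out$fpol_sd <- if (n > 1L) stats::sd(cells$fpol) else 0
  rownames_reset(out)
}

#' Summarize every sample of a per-cell table
#'
#' @param cells per-cell data frame with `sample_id` and `fpol`.
#' @return Data frame of sample records, one row per sample.
#' @export
summarize_samples <- function(cells) {
  pieces <- lapply(split(cells, cells$sample_id), summarize_sample)
  out <- rownames_reset(do.call(rbind, pieces))
  out[order(match(out$sample_id, unique(cells$sample_id))), , drop = FALSE]
}

#' Assign samples to a grouping scheme
#'
#' Three schemes mirror the study's statistical organization:
#' \describe{
#'   \item{diagnostic3}{malignant (MTC/PTC/FTC tumor), benign (FTA/MNG
#'     tumor), normal (normal-tissue samples).}
#'   \item{histo5}{PTC, FTC, FTA, MNG tumor samples and normal-tissue
#'     samples; the MTC singleton is excluded (a group needs at least two
#'     samples for model-based comparison).}
#'   \item{indeterminate4}{cytologically indeterminate (TBSRTC III-V) tumor
#'     samples, split into III-benign, III-malignant, IV-malignant and
#'     V-malignant by category and histology-confirmed class.}
#' }
#' Samples matching no group are dropped; their ids and the reason are
#' reported via `message()` and in the `excluded` attribute.
#'
#' @param samples sample records with `diagnosis`, `tbsrtc`, `tissue`.
#' @param scheme grouping scheme.
#' @return The retained samples with a `group` column; excluded samples in
#'   `attr(, "excluded")`.
#' @export
assign_groups <- function(samples,
                          scheme = c("diagnostic3", "histo5", "indeterminate4")) {
  scheme <- match.arg(scheme)
  g <- switch(scheme,
    diagnostic3 = diagnostic3_class(samples$diagnosis, samples$tissue),
    histo5 = {
      out <- rep(NA_character_, nrow(samples))
      out[samples$tissue == "normal"] <- "normal"
      tum <- samples$tissue == "tumor" &
        samples$diagnosis %in% c("PTC", "FTC", "FTA", "MNG")
      out[tum] <- samples$diagnosis[tum]
      out
    },
    indeterminate4 = {
      out <- rep(NA_character_, nrow(samples))
      ind <- samples$tissue == "tumor" & samples$tbsrtc %in% c("III", "IV", "V")
      mal <- samples$diagnosis %in% .fpol_malignant
      ben <- samples$diagnosis %in% .fpol_benign
      out[ind & samples$tbsrtc == "III" & ben] <- "III-benign"
      out[ind & samples$tbsrtc == "III" & mal] <- "III-malignant"
      out[ind & samples$tbsrtc == "IV" & mal] <- "IV-malignant"
      out[ind & samples$tbsrtc == "V" & mal] <- "V-malignant"
      out
    })
  drop <- is.na(g)
  if (any(drop)) {
    message(sum(drop), " sample(s) outside scheme '", scheme, "' excluded: ",
            paste(samples$sample_id[drop], collapse = ", "))
  }
  out <- samples[!drop, , drop = FALSE]
  out$group <- g[!drop]
  attr(out, "excluded") <- samples$sample_id[drop]
  attr(out, "scheme") <- scheme
  rownames_reset(out)
}

#' Group-level mean Fpol
#'
#' Default reporting estimator: the unweighted mean of per-sample mean Fpol
#' with SE the standard deviation of sample means over the square root of
#' the number of samples. Model-based least-squares means are available via
#' [fpol_lmm()]. `mean_fpol_rounded` applies the reporting convention
#' (3 decimals, round-half-even); singleton groups carry `NA` SE.
#'
#' @param samples output of [assign_groups()] (needs `group`, `fpol_mean`,
#'   `n_cells`).
#' @return Data frame: `scheme`, `group`, `n_samples`, `n_cells`,
#'   `mean_fpol`, `se_fpol`, `mean_fpol_rounded`.
#' @export
group_mean <- function(samples) {
  if (is.null(samples$group)) stop("samples must carry a 'group' column",
                                   call. = FALSE)
  scheme <- attr(samples, "scheme")
  if (is.null(scheme)) scheme <- "custom"
  pieces <- lapply(split(samples, samples$group), function(s) {
    m <- mean(s$fpol_mean)
    data.frame(scheme = scheme, group = s$group[1L], n_samples = nrow(s),
               n_cells = sum(s$n_cells), mean_fpol = m,
               se_fpol = if (nrow(s) > 1L)
                 stats::sd(s$fpol_mean) / sqrt(nrow(s)) else NA_real_,
               mean_fpol_rounded = round(m, 3L), stringsAsFactors = FALSE)
  })
  rownames_reset(do.call(rbind, pieces))
}

#' Classify cells and samples against an Fpol threshold
#'
#' A cell is called malignant when its Fpol strictly exceeds the threshold
#' (the boundary value itself is non-malignant); a sample is called
#' malignant when its mean cell Fpol strictly exceeds the threshold. For
#' each sample the fraction of sub-threshold cells is reported.
#'
#' @param cells per-cell data frame with `sample_id` and `fpol` (optionally
#'   `diagnosis`/`tissue` for truth columns).
#' @param threshold Fpol discrimination threshold (default 0.245).
#' @return List of class `fpol_classification`: `cells` (input plus
#'   `cell_call`), `samples` (per-sample mean, call, fraction of cells at or
#'   below threshold) and `threshold`.
#' @export
classify_cells <- function(cells, threshold = 0.245) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  cells$cell_call <- ifelse(cells$fpol > threshold, "malignant",
                            "non-malignant")
  pieces <- lapply(split(cells, cells$sample_id), function(s) {
    data.frame(sample_id = s$sample_id[1L], n_cells = nrow(s),
               mean_fpol = mean(s$fpol),
               sample_call = ifelse(mean(s$fpol) > threshold, "malignant",
                                    "non-malignant"),
               frac_cells_at_or_below = mean(s$fpol <= threshold),
               stringsAsFactors = FALSE)
  })
  samples <- rownames_reset(do.call(rbind, pieces))
  samples <- samples[order(match(samples$sample_id, unique(cells$sample_id))), ,
                     drop = FALSE]
  structure(list(cells = cells, samples = rownames_reset(samples),
                 threshold = threshold),
            class = "fpol_classification")
}

#' Classify sample records against an Fpol threshold
#'
#' Sample-level variant of [classify_cells()] for tables that already carry
#' per-sample mean Fpol.
#'
#' @param samples data frame with `sample_id` and `fpol_mean`.
#' @param threshold Fpol threshold (default 0.245); strict inequality.
#' @return The input with a `sample_call` column.
#' @export
classify_samples <- function(samples, threshold = 0.245) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  samples$sample_call <- ifelse(samples$fpol_mean > threshold, "malignant",
                                "non-malignant")
  samples
}

#' @export
print.fpol_classification <- function(x, ...) {
  cat("Fpol threshold classification at", x$threshold, "\n")
  cat("  cells:", nrow(x$cells), "(",
      sum(x$cells$cell_call == "malignant"), "called malignant )\n")
  cat("  samples:", nrow(x$samples), "(",
      sum(x$samples$sample_call == "malignant"), "called malignant )\n")
  invisible(x)
}

#' Post-imaging viability
#'
#' Two readings of a viable / non-viable cell count are reported and
#' labelled. `value_printed_formula` is the ratio form
#' `(n_viable / n_nonviable) * 100`, which is undefined (flagged infinite)
#' when no non-viable cells were counted; `value_fraction_of_total` is the
#' conventional percentage `n_viable / (n_viable + n_nonviable) * 100`.
#' Neither is silently substituted for the other.
#'
#' @param n_viable,n_nonviable non-negative counts; at least one positive.
#' @return A `viability_result` list with both values and an
#'   `printed_formula_defined` flag.
#' @export
compute_viability <- function(n_viable, n_nonviable) {
  if (n_viable < 0 || n_nonviable < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (n_viable + n_nonviable < 1) {
    stop("at least one cell must be counted", call. = FALSE)
  }
  structure(list(n_viable = n_viable, n_nonviable = n_nonviable,
                 value_printed_formula = if (n_nonviable == 0) Inf else
                   n_viable / n_nonviable * 100,
                 printed_formula_defined = n_nonviable > 0,
                 value_fraction_of_total =
                   n_viable / (n_viable + n_nonviable) * 100),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("Viability: %d viable / %d non-viable\n", x$n_viable,
              x$n_nonviable))
  cat(sprintf("  ratio form (viable/non-viable x 100): %s\n",
              if (x$printed_formula_defined)
                sprintf("%.1f", x$value_printed_formula) else
                "undefined (no non-viable cells)"))
  cat(sprintf("  fraction of total: %.1f%%\n", x$value_fraction_of_total))
  invisible(x)
}

#' Cell-level scatter export (Fpol versus cell size)
#'
#' One row per cell with its size, Fpol and three-way diagnostic class,
#' plus a per-class summary of cell counts and Fpol ranges.
#'
#' @param cells per-cell data frame with `area_um2`, `fpol`, `diagnosis`,
#'   `tissue` (id columns carried through when present).
#' @return List: `cells` (scatter rows) and `ranges` (per-class n, min, max
#'   Fpol).
#' @export
scatter_table <- function(cells) {
  if (nrow(cells) == 0L) {
    return(list(cells = cells,
                ranges = data.frame(class = character(0), n_cells = integer(0),
                                    min_fpol = numeric(0),
                                    max_fpol = numeric(0))))
  }
  cls <- diagnostic3_class(cells$diagnosis, cells$tissue)
  keep <- intersect(c("subject_id", "sample_id", "cell_id", "area_um2",
                      "equivalent_diameter_um", "fpol"), names(cells))
  out <- cells[, keep, drop = FALSE]
  out$class <- cls
  ranges <- do.call(rbind, lapply(split(out, out$class), function(s) {
    data.frame(class = s$class[1L], n_cells = nrow(s),
               min_fpol = min(s$fpol), max_fpol = max(s$fpol),
               stringsAsFactors = FALSE)
  }))
  list(cells = rownames_reset(out), ranges = rownames_reset(ranges))
}
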