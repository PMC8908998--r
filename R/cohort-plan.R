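# Cohort planning: study designs for the synthetic imaging generator.

.fpol_sites <- c("UMMC", "LGH")
.fpol_diagnoses <- c("MTC", "PTC", "FTC", "FTA", "MNG", "Normal")
.fpol_tbsrtc <- c("II", "III", "IV", "V", "VI", "none")
.fpol_malignant <- c("MTC", "PTC", "FTC")
.fpol_benign <- c("FTA", "MNG")

#' Enumerate a synthetic cohort plan
#'
#' A cohort plan lists every sample to be simulated: its subject, collection
#' site, histological diagnosis, cytology (TBSRTC) category, tissue type
#' (tumor or adjacent normal), number of cells, and the mean and standard
#' deviation of the per-cell fluorescence polarization (Fpol) distribution.
#'
#' With `config = "default"` the packaged reference cohort is returned:
#' 32 thyroid samples from 21 subjects totalling 3521 cells, spanning
#' malignant (MTC, PTC, FTC), benign (FTA, MNG) and normal thyroid tissue,
#' including 12 cytologically indeterminate (TBSRTC III-V) nodules. The
#' default plan is fully deterministic and identical regardless of `seed`.
#'
#' Alternatively `config` may be a data frame with the plan columns
#' (`sample_id`, `subject_id`, `site`, `diagnosis`, `tbsrtc`, `tissue`,
#' `n_cells`, `fpol_mean`, `fpol_sd`), or a list of per-group
#' specifications, each a list with elements `diagnosis`, `n_subjects`,
#' `samples_per_subject` (default 1), `n_cells`, `fpol_mean`, `fpol_sd`
#' and optionally `tbsrtc`, `site`, `tissue`.
#'
#' @param config `"default"`, a plan data frame, or a list of group specs.
#' @param seed integer; accepted for interface symmetry. Plan enumeration is
#'   deterministic, so the seed does not alter the returned plan.
#' @return A `cohort_plan` data frame, one row per sample.
#' @examples
#' plan <- plan_cohort("default")
#' nrow(plan)        # 32 samples
#' sum(plan$n_cells) # 3521 cells
#' @export
plan_cohort <- function(config = "default", seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!config %in% c("default")) {
      stop("unknown cohort config '", config, "'", call. = FALSE)
    }
    path <- system.file("extdata", "default_cohort.csv", package = "fpolcyto",
                        mustWork = TRUE)
    plan <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(
                              sample_id = "character",
                              subject_id = "character",
                              site = "character", diagnosis = "character",
                              tbsrtc = "character", tissue = "character",
                              n_cells = "integer", fpol_mean = "numeric",
                              fpol_sd = "numeric"))
  } else if (is.data.frame(config)) {
    plan <- as.data.frame(config, stringsAsFactors = FALSE)
  } else if (is.list(config)) {
    plan <- .expand_group_specs(config)
  } else {
    stop("config must be \"default\", a data frame, or a list of group specs",
         call. = FALSE)
  }
  validate_cohort_plan(plan)
}

# Turn a list of per-diagnosis group specs into an enumerated plan.
.expand_group_specs <- function(specs) {
  rows <- list()
  subj <- 0L
  for (gi in seq_along(specs)) {
    g <- specs[[gi]]
    need <- c("diagnosis", "n_subjects", "n_cells", "fpol_mean", "fpol_sd")
    miss <- setdiff(need, names(g))
    if (length(miss)) {
      stop("group spec ", gi, " is missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    sps <- if (is.null(g$samples_per_subject)) 1L else as.integer(g$samples_per_subject)
    for (s in seq_len(g$n_subjects)) {
      subj <- subj + 1L
      for (k in seq_len(sps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("S%d-%d", subj, k),
          subject_id = sprintf("S%d", subj),
          site = if (is.null(g$site)) "UMMC" else g$site,
          diagnosis = g$diagnosis,
          tbsrtc = if (is.null(g$tbsrtc)) {
            if (g$diagnosis == "Normal") "none" else "VI"
          } else g$tbsrtc,
          tissue = if (is.null(g$tissue)) {
            if (g$diagnosis == "Normal") "normal" else "tumor"
          } else g$tissue,
          n_cells = as.integer(g$n_cells),
          fpol_mean = g$fpol_mean,
          fpol_sd = g$fpol_sd,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Validate a cohort plan
#'
#' Checks column presence, site/diagnosis/TBSRTC vocabulary, and the numeric
#' invariants (at least one cell per sample, Fpol mean strictly inside (0, 1),
#' non-negative Fpol SD). Errors name the first offending sample.
#'
#' @param plan a data frame of samples.
#' @return The plan, classed `cohort_plan`, invisibly usable downstream.
#' @export
validate_cohort_plan <- function(plan) {
  need <- c("sample_id", "subject_id", "site", "diagnosis", "tbsrtc",
            "tissue", "n_cells", "fpol_mean", "fpol_sd")
  miss <- setdiff(need, names(plan))
  if (length(miss)) {
    stop("cohort plan is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(plan$sample_id)) {
    stop("duplicated sample_id: ",
         plan$sample_id[duplicated(plan$sample_id)][1L], call. = FALSE)
  }
  check_tok <- function(col, vocab, what) {
    bad <- which(!plan[[col]] %in% vocab)
    if (length(bad)) {
      stop("sample '", plan$sample_id[bad[1L]], "': unknown ", what, " '",
           plan[[col]][bad[1L]], "'", call. = FALSE)
    }
  }
  check_tok("site", .fpol_sites, "site")
  check_tok("diagnosis", .fpol_diagnoses, "diagnosis")
  check_tok("tbsrtc", .fpol_tbsrtc, "TBSRTC category")
  check_tok("tissue", c("tumor", "normal"), "tissue type")
  bad <- which(plan$n_cells < 1L)
  if (length(bad)) {
    stop("sample '", plan$sample_id[bad[1L]], "': n_cells must be >= 1",
         call. = FALSE)
  }
  bad <- which(plan$fpol_mean <= 0 | plan$fpol_mean >= 1)
  if (length(bad)) {
    stop("sample '", plan$sample_id[bad[1L]],
         "': fpol_mean must lie strictly in (0, 1)", call. = FALSE)
  }
  bad <- which(plan$fpol_sd < 0)
  if (length(bad)) {
    stop("sample '", plan$sample_id[bad[1L]], "': fpol_sd must be >= 0",
         call. = FALSE)
  }
  class(plan) <- c("cohort_plan", "data.frame")
  plan
}

#' @export
print.cohort_plan <- function(x, ...) {
  cat("Cohort plan:", nrow(x), "samples,",
      length(unique(x$subject_id)), "subjects,",
      sum(x$n_cells), "cells\n")
  cat("Diagnoses:",
      paste(sprintf("%s=%d", names(table(x$diagnosis)), table(x$diagnosis)),
            collapse = ", "), "\n")
  invisible(x)
}
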