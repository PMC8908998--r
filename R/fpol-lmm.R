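# Mixed-effects comparison of Fpol across diagnostic groups: a classic
# fitted-model object wrapping a cell-level linear mixed model with group as
# the fixed effect and subject as a random intercept.

#' Fit the group-comparison mixed model
#'
#' Fits per-cell Fpol against the grouping scheme as a fixed effect with a
#' random intercept per subject (subjects contributing several samples, e.g.
#' tumor plus adjacent normal tissue, share one random-effect level). Group
#' least-squares means with standard errors and all pairwise contrasts
#' (unadjusted p-values, with a Holm-adjusted column alongside) are computed
#' from the fit; degrees of freedom use the Satterthwaite approximation.
#'
#' When the random-intercept variance is estimated as exactly zero (singular
#' fit), the model falls back to a sample-level one-way linear model on the
#' per-sample means, with a warning.
#'
#' @param cells per-cell data frame: `fpol`, `subject_id`, `sample_id`,
#'   `diagnosis`, `tbsrtc`, `tissue`.
#' @param scheme grouping scheme, see [assign_groups()].
#' @param threshold Fpol threshold carried along for [plot.fpol_lmm()].
#' @return An object of class `fpol_lmm` with `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `fitted`, `plot` and `simulate` methods.
#' @examples
#' cells <- simulate_cells(plan_cohort("default"), seed = 1)
#' fit <- fpol_lmm(cells, scheme = "diagnostic3")
#' coef(fit)
#' @export
fpol_lmm <- function(cells,
                     scheme = c("diagnostic3", "histo5", "indeterminate4"),
                     threshold = 0.245) {
  scheme <- match.arg(scheme)
  samples <- summarize_samples(cells)
  grouped <- assign_groups(samples, scheme)
  sizes <- table(grouped$group)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("the mixed model needs at least 2 groups with at least 2 samples ",
         "each; got: ", paste(names(sizes), sizes, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  df <- merge(cells, grouped[, c("sample_id", "group")], by = "sample_id")
  df$group <- factor(df$group)
  df$subject_id <- factor(df$subject_id)

  fit <- suppressMessages(lmerTest::lmer(fpol ~ group + (1 | subject_id),
                                         data = df, REML = TRUE))
  engine <- "cell_lmm"
  if (lme4::isSingular(fit, tol = 1e-5) || stats::sigma(fit) < 1e-8) {
    warning("singular or degenerate mixed-model fit (a variance component ",
            "is effectively zero); falling back to a sample-level one-way ",
            "linear model", call. = FALSE)
    sdat <- grouped
    sdat$group <- factor(sdat$group)
    fit <- stats::lm(fpol_mean ~ group, data = sdat)
    engine <- "sample_lm"
  }
  em <- emmeans::emmeans(fit, "group", lmer.df = "satterthwaite",
                         lmerTest.limit = 1e5)
  ls <- as.data.frame(summary(em))
  names(ls)[names(ls) == "emmean"] <- "lsmean"
  ctr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise"),
                               adjust = "none"))
  ctr$p_holm <- stats::p.adjust(ctr$p.value, method = "holm")
  structure(list(fit = fit, engine = engine, scheme = scheme,
                 lsmeans = ls, pairwise = ctr, samples = grouped,
                 data = df, threshold = threshold,
                 n_cells = nrow(df)),
            class = "fpol_lmm")
}

#' Look up a pairwise contrast p-value
#'
#' @param object an [fpol_lmm()] fit.
#' @param a,b group names (order-free).
#' @param adjusted use the Holm-adjusted column.
#' @return The contrast's p-value.
#' @export
pairwise_p <- function(object, a, b, adjusted = FALSE) {
  stopifnot(inherits(object, "fpol_lmm"))
  lab <- object$pairwise$contrast
  hit <- lab %in% c(paste(a, "-", b), paste(b, "-", a),
                    paste0("(", a, ") - (", b, ")"),
                    paste0("(", b, ") - (", a, ")"))
  if (!any(hit)) stop("no contrast between '", a, "' and '", b, "'",
                      call. = FALSE)
  if (adjusted) object$pairwise$p_holm[hit][1L] else
    object$pairwise$p.value[hit][1L]
}

#' @export
print.fpol_lmm <- function(x, ...) {
  cat("Fpol mixed-effects group comparison (scheme:", x$scheme, ")\n")
  cat("  engine:",
      if (x$engine == "cell_lmm")
        "per-cell LMM, fpol ~ group + (1 | subject)" else
        "sample-level one-way LM (singular-fit fallback)", "\n")
  cat("  ", nrow(x$samples), "samples /", x$n_cells, "cells\n")
  cat("  group LS means:\n")
  print(data.frame(group = x$lsmeans$group,
                   lsmean = round(x$lsmeans$lsmean, 3L),
                   SE = signif(x$lsmeans$SE, 2L)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fpol_lmm <- function(object, ...) {
  structure(list(scheme = object$scheme, engine = object$engine,
                 lsmeans = object$lsmeans, pairwise = object$pairwise,
                 n_samples = nrow(object$samples),
                 n_cells = object$n_cells),
            class = "summary.fpol_lmm")
}

#' @export
print.summary.fpol_lmm <- function(x, ...) {
  cat("Fpol group comparison —", x$scheme, "(", x$engine, ")\n")
  cat(x$n_samples, "samples,", x$n_cells, "cells\n\nLS means:\n")
  print(x$lsmeans, row.names = FALSE)
  cat("\nPairwise contrasts (unadjusted p, Holm alongside):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fpol_lmm <- function(object, ...) {
  stats::setNames(object$lsmeans$lsmean, as.character(object$lsmeans$group))
}

#' @export
predict.fpol_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  cf <- coef(object)
  if (is.null(newdata$group)) stop("newdata needs a 'group' column",
                                   call. = FALSE)
  unknown <- setdiff(unique(as.character(newdata$group)), names(cf))
  if (length(unknown)) stop("unknown group(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  unname(cf[as.character(newdata$group)])
}

#' @export
residuals.fpol_lmm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
fitted.fpol_lmm <- function(object, ...) stats::fitted(object$fit, ...)

#' @export
simulate.fpol_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Scatter plot of cell Fpol versus size
#'
#' Base-graphics rendition of the cohort scatter: each cell's area against
#' its Fpol, colored by diagnostic class, with the discrimination threshold
#' drawn as a horizontal line.
#'
#' @param x an [fpol_lmm()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fpol_lmm <- function(x, ...) {
  df <- x$data
  if (!is.null(df$area_um2)) {
    cls <- diagnostic3_class(df$diagnosis, df$tissue)
    pal <- c(malignant = "#CC2222", benign = "#223399", normal = "#55AADD")
    pch <- c(malignant = 17, benign = 16, normal = 15)
    graphics::plot(df$area_um2, df$fpol, col = pal[cls], pch = pch[cls],
                   cex = 0.6, xlab = expression("Cell area (" * mu * m^2 * ")"),
                   ylab = "Fpol", ...)
    graphics::abline(h = x$threshold, lwd = 1.5)
    graphics::legend("topright", legend = names(pal), col = pal, pch = pch,
                     bty = "n", cex = 0.8)
  } else {
    graphics::boxplot(fpol ~ group, data = df, ylab = "Fpol", ...)
    graphics::abline(h = x$threshold, lwd = 1.5)
  }
  invisible(x)
}
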