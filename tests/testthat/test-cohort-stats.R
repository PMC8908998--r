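test_that("sample summaries use the n-1 standard deviation", {
  cells <- data.frame(sample_id = "s1", subject_id = "p1",
                      fpol = c(0.20, 0.25, 0.30))
  s <- summarize_sample(cells)
  expect_equal(s$fpol_mean, 0.25)
  expect_equal(s$fpol_sd, 0.05)
  expect_equal(s$n_cells, 3L)

  one <- summarize_sample(data.frame(sample_id = "s1", fpol = 0.26))
  expect_equal(one$fpol_mean, 0.26)
  expect_equal(one$fpol_sd, 0)

  expect_error(summarize_sample(cells[0, ]), "empty")
  two <- data.frame(sample_id = c("a", "b"), fpol = c(0.2, 0.3))
  expect_error(summarize_sample(two), "more than one sample")

  # mean invariant to ordering and bounded by member cells
  shuf <- cells[c(3, 1, 2), ]
  expect_equal(summarize_sample(shuf)$fpol_mean, s$fpol_mean)
  expect_true(s$fpol_mean >= min(cells$fpol) && s$fpol_mean <= max(cells$fpol))
})

test_that("synthetic sample means fall within sampling error of the plan", {
  plan <- plan_cohort("default")
  mtc <- plan[plan$diagnosis == "MTC", ]
  cells <- simulate_cells(mtc, seed = 6)
  s <- summarize_sample(cells)
  expect_equal(s$n_cells, 247L)
  expect_lt(abs(s$fpol_mean - 0.270), 3 * 0.028 / sqrt(247))
})

test_that("grouping schemes partition the packaged cohort as reported", {
  plan <- plan_cohort("default")
  d3 <- suppressMessages(assign_groups(plan, "diagnostic3"))
  expect_equal(as.vector(table(d3$group)[c("malignant", "benign", "normal")]),
               c(13L, 7L, 12L))
  expect_equal(sum(d3$n_cells[d3$group == "malignant"]), 1877L)
  expect_equal(sum(d3$n_cells[d3$group == "benign"]), 724L)
  expect_equal(sum(d3$n_cells[d3$group == "normal"]), 920L)

  ind <- suppressMessages(assign_groups(plan, "indeterminate4"))
  expect_equal(nrow(ind), 12L)
  expect_equal(sum(ind$n_cells), 1719L)
  expect_equal(sum(ind$tbsrtc == "III"), 8L)
  expect_equal(sum(ind$tbsrtc == "IV"), 2L)
  expect_equal(sum(ind$tbsrtc == "V"), 2L)
  expect_equal(sum(ind$n_cells[ind$tbsrtc == "III" & ind$diagnosis == "PTC"]),
               592L)

  h5 <- suppressMessages(assign_groups(plan, "histo5"))
  expect_false(any(h5$diagnosis == "MTC"))
  expect_setequal(unique(h5$group), c("PTC", "FTC", "FTA", "MNG", "normal"))
  expect_equal(attr(h5, "excluded"), "1-T")

  empty <- suppressMessages(assign_groups(plan[0, ], "diagnostic3"))
  expect_equal(nrow(empty), 0L)
})

test_that("every cell belongs to exactly one diagnostic group", {
  cells <- simulate_cells(plan_cohort("default"), seed = 3)
  cls <- diagnostic3_class(cells$diagnosis, cells$tissue)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), nrow(cells))
})

test_that("group means reproduce the reported deterministic values", {
  plan <- plan_cohort("default")
  d3 <- suppressMessages(assign_groups(plan, "diagnostic3"))
  g3 <- group_mean(d3)
  expect_equal(g3$mean_fpol_rounded[g3$group == "malignant"], 0.261)

  h5 <- suppressMessages(assign_groups(plan, "histo5"))
  g5 <- group_mean(h5)
  expect_equal(g5$mean_fpol_rounded[g5$group == "FTC"], 0.253)

  ind <- suppressMessages(assign_groups(plan, "indeterminate4"))
  gi <- group_mean(ind)
  expect_equal(gi$mean_fpol_rounded[gi$group == "V-malignant"], 0.270)
  expect_equal(gi$mean_fpol_rounded[gi$group == "IV-malignant"], 0.261)
  expect_equal(gi$mean_fpol_rounded[gi$group == "III-malignant"], 0.257)

  # singleton group: the sample's own mean, flagged SE
  single <- plan[plan$diagnosis == "MTC", ]
  single$group <- "MTC"
  gs <- group_mean(single)
  expect_equal(gs$mean_fpol, 0.270)
  expect_true(is.na(gs$se_fpol))
})

test_that("threshold classification is strict and separates the cohort", {
  cells <- data.frame(sample_id = rep("s", 3),
                      fpol = c(0.246, 0.245, 0.200))
  cl <- classify_cells(cells)
  expect_equal(cl$cells$cell_call,
               c("malignant", "non-malignant", "non-malignant"))

  plan <- plan_cohort("default")
  called <- classify_samples(plan)
  truth <- diagnostic3_class(plan$diagnosis, plan$tissue)
  expect_equal(sum(called$sample_call == "malignant" & truth == "malignant"),
               13L)
  expect_equal(sum(called$sample_call == "non-malignant" &
                     truth != "malignant"), 19L)

  # a malignant sample near the threshold leaves tail mass below it
  mal <- simulate_cells(null_plan(n_subjects = 1L, n_cells = 500L,
                                  mean = 0.261, sd = 0.02)[1, ], seed = 8)
  clm <- classify_cells(mal)
  expect_gt(clm$samples$frac_cells_at_or_below[1], 0)
  expect_lt(clm$samples$frac_cells_at_or_below[1], 0.5)

  expect_error(classify_cells(cells, threshold = 0), "threshold")
})

test_that("viability reports both the ratio form and the fraction of total", {
  v <- compute_viability(91L, 9L)
  expect_equal(v$value_printed_formula, 91 / 9 * 100, tolerance = 1e-12)
  expect_equal(v$value_fraction_of_total, 91)

  v <- compute_viability(50L, 50L)
  expect_equal(v$value_printed_formula, 100)
  expect_equal(v$value_fraction_of_total, 50)

  v <- compute_viability(10L, 0L)
  expect_false(v$printed_formula_defined)
  expect_equal(v$value_fraction_of_total, 100)

  expect_error(compute_viability(0L, 0L), "at least one cell")
  expect_error(compute_viability(-1L, 5L), "non-negative")
})

test_that("the scatter export carries per-class rows and Fpol ranges", {
  cells <- simulate_cells(plan_cohort("default"), seed = 5)
  st <- scatter_table(cells)
  expect_equal(nrow(st$cells), 3521L)
  counts <- st$ranges$n_cells[match(c("malignant", "benign", "normal"),
                                    st$ranges$class)]
  expect_equal(counts, c(1877L, 724L, 920L))
  expect_true(all(st$ranges$min_fpol <= st$ranges$max_fpol))

  empty <- scatter_table(cells[0, ])
  expect_equal(nrow(empty$cells), 0L)

  one <- scatter_table(cells[cells$sample_id == "1-T", ])
  expect_equal(unique(one$cells$class), "malignant")
})
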