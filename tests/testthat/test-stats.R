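test_that("crosstab rates reproduce the published assessment tables", {
  # all drainage regions: software vs expert-corrected software
  cc <- confusion_counts(a = 127, b = 88, c = 16, d = 572)
  r <- rates(cc)
  expect_equal(r$sensitivity, 127 / 143)
  expect_equal(r$specificity, 572 / 660)
  expect_equal(r$fp_rate, 88 / 660)
  expect_equal(r$fn_rate, 16 / 143)
  fr <- format_rates(r)
  expect_equal(fr[["sensitivity"]], "88.8 %")
  expect_equal(fr[["specificity"]], "86.7 %")
  expect_equal(fr[["fp_rate"]], "0.133")
  expect_equal(fr[["fn_rate"]], "0.112")
  expect_equal(correction_rate(cc), 104 / 803)

  # inguinal only: true negatives unavailable
  cc2 <- confusion_counts(a = 77, b = 51, c = 6, d = NA)
  r2 <- rates(cc2)
  expect_equal(r2$sensitivity, 77 / 83)
  expect_equal(r2$fn_rate, 6 / 83)
  expect_true(is.na(r2$specificity))
  expect_true(is.na(r2$fp_rate))
  expect_equal(format_rates(r2)[["specificity"]], "undefined")
  expect_error(correction_rate(cc2), "all four")

  # perfect classifier
  r3 <- rates(confusion_counts(1, 0, 0, 1))
  expect_equal(unlist(r3), c(sensitivity = 1, specificity = 1,
                             fp_rate = 0, fn_rate = 0))

  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("complementary rate identities hold for random counts", {
  set.seed(21)
  for (rep in 1:50) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    r <- rates(cc)
    expect_equal(r$sensitivity + r$fn_rate, 1)
    expect_equal(r$specificity + r$fp_rate, 1)
  }
  # zero denominators give undefined, never a number
  r0 <- rates(confusion_counts(0, 5, 0, 7))
  expect_true(is.na(r0$sensitivity))
  expect_true(is.na(r0$fn_rate))
})

test_that("list crosstabs count moves and ignore labelling", {
  prog <- list(true = c(1, 2, 3), false = c(4, 5, 6))
  same <- crosstab_from_lists(prog, prog)
  expect_equal(c(same$a, same$b, same$c, same$d), c(3, 0, 0, 3))

  corr <- list(true = c(1, 2, 6), false = c(3, 4, 5))
  cc <- crosstab_from_lists(prog, corr)
  expect_equal(c(cc$a, cc$b, cc$c, cc$d), c(2, 1, 1, 2))

  # invariant under relabelling
  remap <- c("1" = "a", "2" = "b", "3" = "c", "4" = "d", "5" = "e",
             "6" = "f")
  prog2 <- lapply(prog, function(x) remap[as.character(x)])
  corr2 <- lapply(corr, function(x) remap[as.character(x)])
  cc2 <- crosstab_from_lists(prog2, corr2)
  expect_equal(c(cc2$a, cc2$b, cc2$c, cc2$d), c(cc$a, cc$b, cc$c, cc$d))

  # single finding moved true -> false
  one <- crosstab_from_lists(list(true = 1, false = integer()),
                             list(true = integer(), false = 1))
  expect_equal(c(one$a, one$b, one$c, one$d), c(0, 1, 0, 0))

  expect_error(crosstab_from_lists(prog, list(true = 1:2, false = 4:6)),
               "differ")

  # a partition with the published cell sizes reproduces the published
  # correction burden
  prog3 <- list(true = 1:215, false = 216:803)
  corr3 <- list(true = c(1:127, 216:231), false = c(128:215, 232:803))
  cc3 <- crosstab_from_lists(prog3, corr3)
  expect_equal(c(cc3$a, cc3$b, cc3$c, cc3$d), c(127, 88, 16, 572))
  expect_equal(correction_rate(cc3), 0.1295143, tolerance = 1e-6)
})

test_that("greedy truth matching follows probability order and the bound", {
  truth <- data.frame(x_mm = c(10, 30), y_mm = c(10, 10), z_mm = c(10, 10),
                      is_decoy = c(FALSE, FALSE))
  mk <- function(df_true, df_false = NULL) {
    empty <- data.frame(label = integer(), probability = numeric(),
                        centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                        centroid_z_mm = numeric())
    structure(list(true = if (is.null(df_true)) empty else df_true,
                   false = if (is.null(df_false)) empty else df_false),
              class = "sln_ranked")
  }
  # perfect run
  tr <- data.frame(label = 1:2, probability = c(0.9, 0.8),
                   centroid_x_mm = c(10.5, 29), centroid_y_mm = c(10, 11),
                   centroid_z_mm = c(10, 10))
  m <- match_to_truth(mk(tr), truth)
  expect_equal(c(m$counts$a, m$counts$b, m$counts$c, m$counts$d),
               c(2, 0, 0, 0))

  # one node missed entirely
  m2 <- match_to_truth(mk(tr[1, ]), truth)
  expect_equal(m2$counts$c, 1)

  # two findings contend for one node: higher probability wins
  tr3 <- data.frame(label = 1:2, probability = c(0.6, 0.9),
                    centroid_x_mm = c(12, 9), centroid_y_mm = c(10, 10),
                    centroid_z_mm = c(10, 10))
  m3 <- match_to_truth(mk(tr3), data.frame(x_mm = 10, y_mm = 10, z_mm = 10,
                                           is_decoy = FALSE))
  expect_equal(m3$matched$label, 2L)
  expect_equal(m3$counts$b, 1)

  # beyond the bound: no match
  far <- data.frame(label = 1, probability = 0.9, centroid_x_mm = 50,
                    centroid_y_mm = 50, centroid_z_mm = 50)
  m4 <- match_to_truth(mk(far), truth)
  expect_equal(m4$counts$a, 0)
  expect_equal(m4$counts$b, 1)
  expect_equal(m4$counts$c, 2)
})

test_that("per-unit rollups separate crosstab rates from event proportions", {
  patients <- data.frame(unit = 1:25,
                         outcome = c(rep("TP", 3), rep("FN", 1),
                                     rep("TN", 21)),
                         complication = c(rep(TRUE, 1), rep(FALSE, 24)))
  rp <- per_unit_rollup(patients)
  expect_equal(rp$rates$sensitivity, 0.75)
  expect_equal(rp$rates$specificity, 1.0)
  expect_equal(rp$proportions$fn_proportion, 1 / 25)
  expect_equal(rp$proportions$complication_proportion, 1 / 25)

  groins <- data.frame(unit = 1:44,
                       outcome = c(rep("TP", 3), rep("FN", 2),
                                   rep("TN", 39)),
                       complication = c(TRUE, rep(FALSE, 43)))
  rg <- per_unit_rollup(groins)
  expect_equal(rg$rates$sensitivity, 0.6)
  expect_equal(rg$rates$specificity, 1.0)
  expect_equal(rg$rates$fn_rate, 0.4)
  expect_equal(rg$proportions$fn_proportion, 2 / 44)
  expect_equal(rg$proportions$complication_proportion, 1 / 44)

  expect_error(per_unit_rollup(data.frame(unit = c(1, 1),
                                          outcome = c("TP", "TN"))),
               "duplicate")
  expect_error(per_unit_rollup(data.frame(unit = 1, outcome = "yes")),
               "TP/FP/FN/TN")
})

test_that("crosstab rendering shows undefined cells as dashes", {
  lines <- render_crosstab(confusion_counts(77, 51, 6, NA), "Inguinal")
  expect_true(any(grepl("undefined", lines)))
  expect_true(any(grepl("92.8", lines)))
})
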