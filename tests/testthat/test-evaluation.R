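make_ann <- function(walking, cadence = NULL) {
  if (is.null(cadence)) cadence <- ifelse(walking, 2, 0)
  ann <- data.frame(second = seq_along(walking) - 1L, walking = walking,
                    cadence = cadence)
  class(ann) <- c("walking_annotation", "data.frame")
  ann
}

test_that("alignment applies the majority-overlap rule per second", {
  labels <- label_track(0, 10, "walking")
  pairs <- align_annotation(make_ann(rep(TRUE, 10)), labels)
  expect_equal(nrow(pairs), 10)
  expect_true(all(pairs$truth) && all(pairs$prediction))

  # 60% of second 0 is walking -> truth walking
  lab2 <- label_track(c(0.4, 1), c(1, 2), c("walking", "eating"))
  p2 <- align_annotation(make_ann(c(FALSE, FALSE)), lab2)
  expect_equal(p2$truth, c(TRUE, FALSE))
  # 40% coverage -> second dropped entirely (outside labeled time)
  lab3 <- label_track(0.6, 1, "walking")
  expect_equal(nrow(suppressWarnings(
    align_annotation(make_ann(c(FALSE, FALSE)), lab3))), 0)

  # only the labeled prefix of a long annotation is scored
  lab4 <- label_track(0, 5, "eating")
  expect_equal(nrow(align_annotation(make_ann(rep(FALSE, 60)), lab4)), 5)

  # disjoint label track warns and yields nothing
  expect_warning(
    out <- align_annotation(make_ann(rep(TRUE, 5)),
                            label_track(100, 110, "walking")),
    "do not overlap")
  expect_equal(nrow(out), 0)
})

test_that("confusion counts partition the pairs exhaustively", {
  pairs <- data.frame(truth = c(TRUE, TRUE, FALSE, FALSE),
                      prediction = c(TRUE, FALSE, FALSE, TRUE))
  cc <- confusion(pairs)
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))

  allgood <- data.frame(truth = rep(c(TRUE, FALSE), 5),
                        prediction = rep(c(TRUE, FALSE), 5))
  cc2 <- confusion(allgood)
  expect_equal(cc2$FN + cc2$FP, 0L)

  set.seed(14)
  rnd <- data.frame(truth = runif(200) < 0.5, prediction = runif(200) < 0.5)
  cc3 <- confusion(rnd)
  # brute-force loop oracle
  tp <- fn <- tn <- fp <- 0L
  for (i in 1:200) {
    if (rnd$truth[i] && rnd$prediction[i]) tp <- tp + 1L
    else if (rnd$truth[i]) fn <- fn + 1L
    else if (rnd$prediction[i]) fp <- fp + 1L
    else tn <- tn + 1L
  }
  expect_equal(c(cc3$TP, cc3$FN, cc3$TN, cc3$FP), c(tp, fn, tn, fp))
  expect_equal(cc3$TP + cc3$FN + cc3$TN + cc3$FP, 200L)
})

test_that("metrics follow their defining formulas with undefined guards", {
  cc <- structure(list(TP = 3L, FN = 1L, TN = 4L, FP = 0L),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$f1, 6 / 7)

  none <- structure(list(TP = 0L, FN = 0L, TN = 5L, FP = 0L),
                    class = "confusion_counts")
  expect_true(is.na(compute_metrics(none)$sensitivity))
  expect_true(is.na(compute_metrics(none)$f1))

  # F1 is the harmonic mean of precision and sensitivity
  set.seed(3)
  for (i in 1:100) {
    cc <- structure(as.list(setNames(as.integer(rpois(4, 20) + 1),
                                     c("TP", "FN", "TN", "FP"))),
                    class = "confusion_counts")
    m <- compute_metrics(cc)
    prec <- cc$TP / (cc$TP + cc$FP)
    expect_equal(m$f1, 2 * prec * m$sensitivity / (prec + m$sensitivity))
    expect_equal(m$sensitivity + cc$FN / (cc$TP + cc$FN), 1)
    expect_equal(m$specificity + cc$FP / (cc$TN + cc$FP), 1)
  }
})

test_that("metrics are invariant under permutation of pairs", {
  set.seed(6)
  pairs <- data.frame(truth = runif(80) < 0.4, prediction = runif(80) < 0.4)
  m1 <- compute_metrics(confusion(pairs))
  m2 <- compute_metrics(confusion(pairs[sample(80), ]))
  expect_equal(m1[c("sensitivity", "specificity", "f1")],
               m2[c("sensitivity", "specificity", "f1")])
})

test_that("false-positive rates are tallied per activity", {
  pairs <- data.frame(
    truth = rep(FALSE, 40),
    prediction = c(rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 6), rep(FALSE, 10)),
    activity = c(rep("brushing_teeth", 30), rep("eating", 10)))
  fpr <- fp_by_activity(pairs)
  expect_equal(fpr[["brushing_teeth"]], 0.2)
  expect_equal(fpr[["eating"]], 0)

  # loop oracle on a random mixed session
  set.seed(9)
  acts <- sample(c("eating", "washing_hands", "transition", "other"),
                 150, replace = TRUE)
  pr <- runif(150) < 0.3
  fpr2 <- fp_by_activity(data.frame(truth = FALSE, prediction = pr,
                                    activity = acts))
  for (a in unique(acts))
    expect_equal(fpr2[[a]], sum(pr[acts == a]) / sum(acts == a))
})

test_that("group summaries report unweighted means and ranges", {
  mk <- function(sens, spec, f1)
    structure(list(sensitivity = sens, specificity = spec, f1 = f1),
              class = "gait_metrics")
  per <- list(a = mk(0.9, 0.8, 0.6), b = mk(0.8, 0.9, 0.7),
              c = mk(0.7, 0.7, 0.8))
  groups <- c(a = "no_aid", b = "cane", c = "rollator")
  gs <- group_summary(per, groups)
  ov <- gs[gs$metric == "f1" & gs$group == "overall", ]
  expect_equal(ov$mean, 0.7)
  expect_equal(c(ov$min, ov$max), c(0.6, 0.8))

  # degenerate: identical subjects (single-group cohort warns about the
  # groups it cannot report)
  expect_warning(
    same <- group_summary(list(a = mk(0.5, 0.5, 0.5),
                               b = mk(0.5, 0.5, 0.5)),
                          c(a = "cane", b = "cane")),
    "omitted")
  expect_true(all(same$mean == 0.5 & same$min == 0.5 & same$max == 0.5,
                  na.rm = TRUE))

  # random cohort against a brute-force tally
  set.seed(12)
  vals <- round(runif(10), 3)
  per10 <- setNames(lapply(vals, function(v) mk(v, v, v)), letters[1:10])
  g10 <- setNames(sample(c("no_aid", "cane", "rollator"), 10, replace = TRUE),
                  letters[1:10])
  gs10 <- group_summary(per10, g10)
  for (g in unique(g10)) {
    v <- vals[g10 == g]
    row <- gs10[gs10$metric == "f1" & gs10$group == g, ]
    expect_equal(c(row$mean, row$min, row$max), c(mean(v), min(v), max(v)))
  }

  # undefined metrics leave the subject out of that metric only
  per_na <- list(a = mk(NA_real_, 1, 0.5), b = mk(0.6, 0.9, 0.7))
  expect_message(
    suppressWarnings(
      gs_na <- group_summary(per_na, c(a = "cane", b = "cane"))),
    "excluded")
  expect_equal(gs_na[gs_na$metric == "sensitivity" &
                       gs_na$group == "overall", ]$mean, 0.6)
})
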