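small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- prepare_cohort(gen_cohort(
        3, c(none = 1, cane = 1, rollator = 1), seed = 55,
        walk_duration = 60))
    cache
  }
})

test_that("the F1 objective matches the metric-module definition", {
  prep <- small_cohort()
  p <- gait_preset("calibrated")
  # definitional identity: pooled seconds through the evaluation module
  pairs <- do.call(rbind, lapply(prep, function(s) {
    ann <- detect_walking(s$features, p)
    align_annotation(ann, s$labels)
  }))
  expect_equal(objective_f1(p, prep),
               compute_metrics(confusion(pairs))$f1)
  # parameters that never fire score zero, with a warning-free path for
  # cohorts that do contain walking
  blind <- gait_params(A = 4, alpha = 0, beta = 0, f_min = 1.4,
                       f_max = 2.3, T = 10)
  expect_equal(objective_f1(blind, prep), 0)
  # near-oracle parameters on clean synthetic gait approach a perfect
  # score; beta must be small enough to reject the irregular oscillatory
  # confounders, whose spectral spread reaches into the walking band
  expect_gte(objective_f1(gait_params(A = 0.05, alpha = 50, beta = 2,
                                      f_min = 0.7, f_max = 2.4, T = 4),
                          prep), 0.9)
})

test_that("the objective warns and returns 0 without labeled walking", {
  prep <- small_cohort()
  nowalk <- prep[1]
  nowalk[[1]]$truth <- rep(FALSE, length(nowalk[[1]]$truth))
  expect_warning(s <- objective_f1(gait_preset("default"), nowalk),
                 "no labeled walking")
  expect_equal(s, 0)
})

test_that("TPE search is seeded, reproducible, and improves monotonically", {
  space <- search_space()
  # deterministic toy objective over the box
  fn <- function(x) -((x[["A"]] - 0.2)^2 + (x[["f_min"]] - 1)^2 +
                        ((x[["T"]] - 4) / 10)^2)
  r1 <- tpe_maximize(fn, space, n_trials = 60, seed = 9)
  r2 <- tpe_maximize(fn, space, n_trials = 60, seed = 9)
  expect_identical(r1, r2)
  # a single trial returns the single sampled point
  r3 <- tpe_maximize(fn, space, n_trials = 1, seed = 9)
  expect_equal(nrow(r3$trials), 1)
  expect_equal(r3$best_score, fn(r3$best))
  # best-so-far never decreases with more trials under a fixed seed
  expect_true(all(diff(cummax(r1$trials$score)) >= 0))
  r4 <- tpe_maximize(fn, space, n_trials = 30, seed = 9)
  expect_gte(r1$best_score, r4$best_score)
  # the search gets near the known optimum
  expect_gt(r1$best_score, -0.05)
  # integer dimension stays integer
  expect_true(all(r1$trials$T == round(r1$trials$T)))
  # sampled points respect the printed box
  expect_true(all(r1$trials$A >= 0.05 & r1$trials$A <= 0.5))
  expect_true(all(r1$trials$f_min >= 0.6 & r1$trials$f_min <= 1.5))
})

test_that("fold tuning recovers parameters that see slow soft gait", {
  prep <- prepare_cohort(gen_cohort(
    3, c(cane = 1, rollator = 2), seed = 71, walk_duration = 90,
    step_freq_range = c(0.9, 1.1), impact_amp_range = c(0.10, 0.15)))
  best <- tune_fold(prep, n_trials = 60, seed = 72)
  expect_s3_class(best, "gait_params")
  expect_lte(best$A, 0.2)
  expect_lte(best$f_min, 1.1)
  expect_gte(attr(best, "score"), 0.8)
  # deterministic under the same seed
  best2 <- tune_fold(prep, n_trials = 60, seed = 72)
  expect_identical(unclass(best)[], unclass(best2)[])
})

test_that("fold averaging rounds parameters as specified", {
  mk <- function(A, al, be, fl, fh, T)
    gait_params(A = A, alpha = al, beta = be, f_min = fl, f_max = fh, T = T)
  folds <- list(mk(0.08, 60, 70, 0.8, 2.8, 9),
                mk(0.12, 70, 85, 0.8, 2.8, 10),
                mk(0.10, 66.2, 76.5, 0.8, 2.8, 10))
  cal <- walkwatch:::consolidate_params(folds)
  expect_equal(cal$A, 0.1)                 # mean 0.1, one decimal
  expect_equal(cal$alpha, 65.4)            # mean 65.4
  expect_equal(cal$beta, 77.2)             # mean 77.1667 -> 77.2
  expect_equal(cal$T, 10)                  # mean 9.667 -> whole second
  # identical folds are a fixed point
  same <- list(mk(0.1, 65.4, 77.1, 0.8, 2.8, 10),
               mk(0.1, 65.4, 77.1, 0.8, 2.8, 10),
               mk(0.1, 65.4, 77.1, 0.8, 2.8, 10))
  expect_equal(unclass(walkwatch:::consolidate_params(same))[],
               unclass(same[[1]])[])
})

test_that("LOSO folds never see their held-out subject", {
  mix <- c(none = 1, cane = 1, rollator = 1)
  base <- gen_cohort(3, mix, seed = 81, walk_duration = 45)
  poisoned <- base
  # replace subject 1's session with radically different content
  alt <- gen_cohort(3, mix, seed = 82, walk_duration = 45,
                    step_freq_range = c(2.0, 2.2),
                    impact_amp_range = c(0.4, 0.45))
  poisoned[[1]] <- alt[[1]]
  t1 <- loso_calibrate(base, n_trials = 15, seed = 83)
  t2 <- loso_calibrate(poisoned, n_trials = 15, seed = 83)
  # fold 1 trains only on subjects 2 and 3, so its tuned parameters are
  # unchanged by the held-out subject's data
  expect_identical(unclass(t1$fold_params[[1]])[],
                   unclass(t2$fold_params[[1]])[])
  # but other folds do train on subject 1 and shift detectably
  others_same <- vapply(2:3, function(i)
    identical(unclass(t1$fold_params[[i]])[],
              unclass(t2$fold_params[[i]])[]), logical(1))
  expect_false(all(others_same))
})

test_that("the three-row report orders parameter sets sensibly", {
  # fold averaging only stabilizes with enough folds, so this uses the
  # 8-subject calibration study rather than a miniature cohort
  run <- calibration_run(11)
  tab <- report_three_rows(run$prep, run$tuning)
  expect_setequal(unique(tab$parameter_set),
                  c("default", "loso", "calibrated"))
  f1 <- function(set) tab[tab$parameter_set == set & tab$metric == "f1" &
                            tab$group == "overall", "mean"]
  # defaults miss slow soft gait; calibration recovers it
  expect_gt(f1("calibrated"), f1("default"))
  expect_lt(abs(f1("calibrated") - f1("loso")), 0.1)
})

test_that("a cohort without negatives reports specificity as missing", {
  w <- gen_walk(gait_profile(1.8, 0.3, 0.3, 0.2, 0.02), 40, seed = 95)
  subj <- list(subject_id = "W1", aid = "none",
               recording = triaxial_recording(w$time, w$x, w$y, w$z,
                                              nominal_rate = 50),
               labels = label_track(0, 40, "walking"))
  rep <- evaluate_annotation(detect_walking(subj$recording,
                                            gait_preset("calibrated")),
                             subj$labels)
  expect_true(is.na(rep$specificity))
  expect_false(is.na(rep$sensitivity))
  suppressMessages(suppressWarnings(
    gs <- group_summary(list(W1 = rep), c(W1 = "no_aid"))))
  expect_true(is.na(gs[gs$metric == "specificity" &
                         gs$group == "overall", "mean"]))
})
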