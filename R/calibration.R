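#' Calibration search space
#'
#' Box bounds for hyperparameter tuning of the six detector knobs. The
#' defaults are the published tuning ranges: `A` in \[0.05, 0.5\] g,
#' `alpha` and `beta` in \[0, 100\], `f_min` in \[0.6, 1.5\] Hz, `f_max`
#' in \[2.0, 3.0\] Hz, and integer `T` in \[1, 10\] s. Sampled points with
#' `f_min >= f_max` are scored 0 rather than reparametrized, keeping the
#' printed box bounds intact (the default boxes cannot produce them).
#'
#' @param A,alpha,beta,f_min,f_max,T length-2 numeric bounds `c(lo, hi)`.
#' @return A list of class `search_space`; each element has `lo`, `hi`,
#'   `integer`.
#' @export
search_space <- function(A = c(0.05, 0.5), alpha = c(0, 100),
                         beta = c(0, 100), f_min = c(0.6, 1.5),
                         f_max = c(2.0, 3.0), T = c(1, 10)) {
  dims <- list(A = A, alpha = alpha, beta = beta, f_min = f_min,
               f_max = f_max, T = T)
  out <- lapply(names(dims), function(nm) {
    b <- dims[[nm]]
    stopifnot(length(b) == 2L, b[1L] < b[2L])
    list(lo = b[1L], hi = b[2L], integer = nm == "T")
  })
  names(out) <- names(dims)
  structure(out, class = "search_space")
}

# One uniform draw from the box.
sample_space <- function(space) {
  vapply(space, function(d) {
    x <- runif(1, d$lo, d$hi)
    if (d$integer) round(x) else x
  }, numeric(1))
}

# Per-dimension Parzen mixture over observed values: one Gaussian per
# observation with a neighbor-distance bandwidth (wide where points are
# sparse, narrow where they cluster) plus one box-wide uniform-prior
# component that keeps exploration alive. Returns sampling and density
# closures.
parzen_1d <- function(vals, lo, hi, integer = FALSE) {
  n <- length(vals)
  o <- order(vals)
  centers <- vals[o]
  ext <- c(lo, centers, hi)
  bw <- pmax(diff(ext)[-(n + 1L)], diff(ext)[-1L])
  bw <- pmin(pmax(bw, (hi - lo) / min(100, 1 + n)), hi - lo)
  w <- rep(1 / (n + 1), n + 1L)           # last component = prior
  list(
    draw = function(m) {
      k <- sample.int(n + 1L, m, replace = TRUE)
      x <- ifelse(k <= n,
                  centers[pmin(k, n)] + rnorm(m, 0, bw[pmin(k, n)]),
                  runif(m, lo, hi))
      x <- pmin(pmax(x, lo), hi)
      if (integer) round(x) else x
    },
    dens = function(x) {
      kd <- vapply(x, function(v) sum(dnorm(v, centers, bw)), numeric(1))
      w[1L] * kd + w[n + 1L] / (hi - lo)
    })
}

#' Tree-structured Parzen estimator maximization
#'
#' Sequential model-based optimization over a box: after `n_startup`
#' uniform trials, observed points are split at the `gamma` quantile of
#' the objective into good and bad sets; each dimension is modeled by a
#' Parzen window (one Gaussian per observation, neighbor-distance
#' bandwidths, a box-wide uniform prior component) over each set, and the
#' next trial evaluates the candidate — out of `n_candidates` draws from
#' the good density — that maximizes the density ratio l(x)/g(x). Fully
#' seeded and deterministic.
#'
#' @param fn objective to maximize; takes a named numeric vector.
#' @param space a [search_space()].
#' @param n_trials number of objective evaluations (>= 1).
#' @param seed RNG seed.
#' @param n_startup uniform warm-up trials before the Parzen model kicks
#'   in.
#' @param gamma fraction of trials treated as "good".
#' @param n_candidates candidate draws per model-based trial.
#' @return A list with `best` (named parameter vector), `best_score`, and
#'   `trials` (data frame of all sampled points with their scores).
#' @export
tpe_maximize <- function(fn, space, n_trials, seed, n_startup = 30,
                         gamma = 0.15, n_candidates = 24) {
  stopifnot(inherits(space, "search_space"), n_trials >= 1)
  nd <- length(space)
  with_seed(seed, {
    X <- matrix(NA_real_, nrow = n_trials, ncol = nd,
                dimnames = list(NULL, names(space)))
    y <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      if (i <= max(n_startup, 2L)) {
        x <- sample_space(space)
      } else {
        done <- seq_len(i - 1L)
        n_good <- max(1L, ceiling(gamma * length(done)))
        ord <- order(y[done], decreasing = TRUE)
        good <- X[done[ord[seq_len(n_good)]], , drop = FALSE]
        bad <- X[done[ord[-seq_len(n_good)]], , drop = FALSE]
        if (!nrow(bad)) bad <- good
        score <- numeric(n_candidates)
        cand <- matrix(NA_real_, nrow = n_candidates, ncol = nd)
        for (j in seq_len(nd)) {
          d <- space[[j]]
          lm <- parzen_1d(good[, j], d$lo, d$hi, d$integer)
          gm <- parzen_1d(bad[, j], d$lo, d$hi, d$integer)
          prop <- lm$draw(n_candidates)
          cand[, j] <- prop
          score <- score + log(lm$dens(prop) + 1e-300) -
            log(gm$dens(prop) + 1e-300)
        }
        x <- cand[which.max(score), ]
        names(x) <- names(space)
      }
      X[i, ] <- x
      y[i] <- fn(x)
    }
    best <- which.max(y)
    list(best = X[best, ], best_score = y[best],
         trials = data.frame(X, score = y))
  })
}

# Consolidate per-fold optima: per-parameter mean across folds, rounded to
# one decimal; T is rounded to a whole number of seconds.
consolidate_params <- function(fold_params) {
  pmat <- vapply(fold_params, function(p) unlist(unclass(p)), numeric(6))
  avg <- rowMeans(pmat)
  gait_params(A = round(avg[["A"]], 1), alpha = round(avg[["alpha"]], 1),
              beta = round(avg[["beta"]], 1),
              f_min = round(avg[["f_min"]], 1),
              f_max = round(avg[["f_max"]], 1), T = round(avg[["T"]]))
}

# named vector from the search space -> gait_params (NULL when invalid)
params_from_point <- function(x) {
  if (x[["f_min"]] >= x[["f_max"]]) return(NULL)
  gait_params(A = x[["A"]], alpha = x[["alpha"]], beta = x[["beta"]],
              f_min = x[["f_min"]], f_max = x[["f_max"]],
              T = round(x[["T"]]))
}

# Precompute, per subject, everything a tuning trial needs: detector
# features and the parameter-free ground truth per scored second.
prepare_subject <- function(subject) {
  if (!is.null(subject$features)) return(subject)  # already prepared
  feats <- gait_features(subject$recording)
  n_win <- nrow(feats$profiles)
  dummy <- data.frame(second = seq_len(n_win) - 1L,
                      walking = rep(FALSE, n_win),
                      cadence = rep(0, n_win))
  class(dummy) <- c("walking_annotation", "data.frame")
  pairs <- align_annotation(dummy, subject$labels)
  list(subject_id = subject$subject_id, aid = subject$aid,
       features = feats, labels = subject$labels,
       sec_idx = pairs$second + 1L, truth = pairs$truth,
       activity = pairs$activity)
}

#' Precompute detector features for a whole cohort
#'
#' Runs [gait_features()] and the ground-truth alignment once per subject
#' so that tuning trials reduce to cheap thresholding. [loso_calibrate()]
#' accepts either a raw cohort or the output of this function; preparing
#' explicitly lets you reuse the work across calibration runs.
#'
#' @param cohort a [gen_cohort()] result, or any list of subjects each
#'   holding `subject_id`, `aid`, `recording`, `labels`.
#' @return A list of class `prepared_cohort`.
#' @export
prepare_cohort <- function(cohort) {
  if (inherits(cohort, "prepared_cohort")) return(cohort)
  structure(lapply(cohort, prepare_subject), class = "prepared_cohort")
}

#' @export
`[.prepared_cohort` <- function(x, i) {
  structure(NextMethod(), class = "prepared_cohort")
}

predictions_for <- function(prep, params) {
  cls <- classify_features(prep$features, params)
  keep <- enforce_min_duration(cls$candidate, params$T)
  keep[prep$sec_idx]
}

#' Calibration objective: pooled F1-score
#'
#' Scores a parameter set by running the detector on every training
#' subject, pooling the per-second confusion counts across subjects, and
#' returning the pooled F1-score. The F1-score balances sensitivity and
#' precision, which is what the calibration optimizes. When the pooled
#' data holds no labeled walking seconds the score is 0 with a warning.
#'
#' @param params a [gait_params()] object.
#' @param train a [prepare_cohort()] subset (or raw cohort).
#' @return F1 in `[0, 1]`.
#' @export
objective_f1 <- function(params, train) {
  train <- prepare_cohort(train)
  TP <- FN <- FP <- 0L
  for (prep in train) {
    pred <- predictions_for(prep, params)
    TP <- TP + sum(prep$truth & pred)
    FN <- FN + sum(prep$truth & !pred)
    FP <- FP + sum(!prep$truth & pred)
  }
  if (TP + FN == 0L) {
    warning("no labeled walking seconds in the training pool; F1 = 0")
    return(0)
  }
  if (2L * TP + FN + FP == 0L) return(0)
  2 * TP / (2 * TP + FN + FP)
}

#' Tune detector parameters on a training set
#'
#' One fold of the calibration: a seeded TPE search of [search_space()]
#' maximizing the pooled training F1 ([objective_f1()]). Invalid samples
#' (`f_min >= f_max`) score 0.
#'
#' @param train training subjects (raw or [prepare_cohort()] output).
#' @param space a [search_space()].
#' @param n_trials TPE trials (500 is the full-scale budget; 50-100 is
#'   a reasonable desk scale).
#' @param seed RNG seed.
#' @return The best [gait_params()] found, with attributes `score` (its
#'   pooled training F1) and `trials` (the full trial history).
#' @export
tune_fold <- function(train, space = search_space(), n_trials = 500,
                      seed = 1) {
  train <- prepare_cohort(train)
  fn <- function(x) {
    p <- params_from_point(x)
    if (is.null(p)) return(0)
    suppressWarnings(objective_f1(p, train))
  }
  res <- tpe_maximize(fn, space, n_trials, seed)
  p <- params_from_point(res$best)
  if (is.null(p))
    stop("no valid trial found in ", n_trials, " trials", call. = FALSE)
  attr(p, "score") <- res$best_score
  attr(p, "trials") <- res$trials
  p
}

#' Leave-one-subject-out calibration
#'
#' For each subject, tunes the detector on all other subjects
#' ([tune_fold()]) and scores the fold's best parameters on the held-out
#' subject. The consolidated calibrated set is the per-parameter mean
#' across folds, rounded to one decimal — except `T`, rounded to a whole
#' number of seconds.
#'
#' @param cohort >= 2 subjects (raw or [prepare_cohort()] output).
#' @param space a [search_space()].
#' @param n_trials TPE trials per fold.
#' @param seed base RNG seed; fold `i` uses `seed + i`.
#' @return An object of class `gait_tuning`: `fold_params` and
#'   `fold_metrics` (named by held-out subject), `calibrated`
#'   ([gait_params()]), `n_trials`, `seed`.
#' @examples
#' \donttest{
#' cohort <- gen_cohort(3, aid_mix = c(none = 3), seed = 7)
#' tuning <- loso_calibrate(cohort, n_trials = 25, seed = 7)
#' coef(tuning)
#' }
#' @export
loso_calibrate <- function(cohort, space = search_space(), n_trials = 500,
                           seed = 1) {
  prepared <- prepare_cohort(cohort)
  if (length(prepared) < 2L)
    stop("LOSO needs a cohort of at least 2 subjects", call. = FALSE)
  ids <- vapply(prepared, `[[`, character(1), "subject_id")
  fold_params <- fold_metrics <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(prepared)) {
    held <- prepared[[i]]
    res <- tryCatch(
      tune_fold(prepared[-i], space, n_trials, seed = seed + i),
      error = function(e)
        stop("fold '", ids[i], "' failed: ", conditionMessage(e),
             call. = FALSE))
    attr(res, "trials") <- NULL
    fold_params[[i]] <- res
    ann <- detect_walking(held$features, res)
    fold_metrics[[i]] <- evaluate_annotation(ann, held$labels)
  }
  calibrated <- consolidate_params(fold_params)
  structure(list(fold_params = fold_params, fold_metrics = fold_metrics,
                 calibrated = calibrated, n_trials = n_trials, seed = seed),
            class = "gait_tuning")
}

#' @export
coef.gait_tuning <- function(object, ...) {
  unlist(unclass(object$calibrated))
}

#' @export
print.gait_tuning <- function(x, ...) {
  cat(sprintf("LOSO calibration: %d folds, %d TPE trials/fold, seed %d\n",
              length(x$fold_params), x$n_trials, x$seed))
  cat("Calibrated parameters (fold average, rounded):\n")
  print(x$calibrated)
  invisible(x)
}

#' @export
summary.gait_tuning <- function(object, ...) {
  print(object)
  f1 <- vapply(object$fold_metrics, `[[`, numeric(1), "f1")
  f1 <- f1[!is.na(f1)]
  if (length(f1))
    cat(sprintf("Held-out F1: mean %.3f, range %.3f-%.3f\n",
                mean(f1), min(f1), max(f1)))
  invisible(object)
}

#' Three-row performance report
#'
#' The standard cohort report: per-group metric summaries for (1) the
#' default parameters applied to every subject, (2) the LOSO rows — each
#' fold's tuned parameters scored on its held-out subject
#' (subject-independent), and (3) the consolidated calibrated parameters
#' applied to every subject.
#'
#' @param cohort the evaluation cohort (raw or prepared).
#' @param tuning a [loso_calibrate()] result.
#' @param default_params the untuned reference parameter set.
#' @return A `data.frame`: `parameter_set`, `metric`, `group`, `mean`,
#'   `min`, `max`, `n`.
#' @export
report_three_rows <- function(cohort, tuning,
                              default_params = gait_preset("default")) {
  stopifnot(inherits(tuning, "gait_tuning"))
  prepared <- prepare_cohort(cohort)
  ids <- vapply(prepared, `[[`, character(1), "subject_id")
  groups <- setNames(vapply(prepared, function(s)
    switch(s$aid, none = "no_aid", s$aid), character(1)), ids)
  eval_all <- function(params) {
    out <- lapply(prepared, function(prep)
      evaluate_annotation(detect_walking(prep$features, params),
                          prep$labels))
    setNames(out, ids)
  }
  blocks <- list(
    default = group_summary(eval_all(default_params), groups),
    loso = group_summary(tuning$fold_metrics, groups),
    calibrated = group_summary(eval_all(tuning$calibrated), groups))
  out <- do.call(rbind, lapply(names(blocks), function(nm)
    cbind(parameter_set = nm, blocks[[nm]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
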