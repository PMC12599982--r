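#' Align a walking annotation with ground-truth labels
#'
#' Produces one (truth, prediction) pair per annotated second. A second's
#' ground truth is walking when more than 50% of it overlaps a labeled
#' walking interval (majority rule). Seconds with at most 50% coverage by
#' *any* labeled interval are dropped from scoring — only annotated time
#' counts. Each kept second also carries the activity covering most of it,
#' for the per-activity false-positive breakdown.
#'
#' @param annotation a [detect_walking()] result.
#' @param labels a [label_track()].
#' @return A `data.frame` with columns `second`, `truth` (logical),
#'   `prediction` (logical), `activity` (character). Zero rows (with a
#'   warning) when annotation and labels do not overlap in time.
#' @export
align_annotation <- function(annotation, labels) {
  stopifnot(inherits(annotation, "walking_annotation"),
            inherits(labels, "label_track"))
  if (!nrow(annotation) || !nrow(labels)) {
    warning("annotation and labels do not overlap; nothing to score")
    return(data.frame(second = integer(0), truth = logical(0),
                      prediction = logical(0), activity = character(0)))
  }
  secs <- annotation$second
  acts <- unique(labels$activity)
  # coverage[i, a]: seconds of activity a inside second i
  cover <- matrix(0, nrow = length(secs), ncol = length(acts),
                  dimnames = list(NULL, acts))
  for (k in seq_len(nrow(labels))) {
    lo <- pmax(secs, labels$start[k])
    hi <- pmin(secs + 1, labels$end[k])
    ov <- pmax(0, hi - lo)
    cover[, labels$activity[k]] <- cover[, labels$activity[k]] + ov
  }
  total <- rowSums(cover)
  keep <- total > 0.5
  if (!any(keep)) {
    warning("annotation and labels do not overlap; nothing to score")
    return(data.frame(second = integer(0), truth = logical(0),
                      prediction = logical(0), activity = character(0)))
  }
  cover <- cover[keep, , drop = FALSE]
  walk_cov <- if ("walking" %in% acts) cover[, "walking"] else
    numeric(nrow(cover))
  data.frame(second = secs[keep],
             truth = walk_cov > 0.5,
             prediction = annotation$walking[keep],
             activity = acts[max.col(cover, ties.method = "first")],
             stringsAsFactors = FALSE)
}

#' Second-level confusion counts
#'
#' Tallies the aligned pairs into true positives (correctly detected
#' walking seconds), false negatives (missed walking seconds), true
#' negatives and false positives. The four counts always partition the
#' pairs exhaustively.
#'
#' @param pairs an [align_annotation()] data frame (columns `truth`,
#'   `prediction`).
#' @return A list of class `confusion_counts` with integer fields
#'   `TP`, `FN`, `TN`, `FP`.
#' @export
confusion <- function(pairs) {
  t <- pairs$truth; p <- pairs$prediction
  structure(list(TP = sum(t & p), FN = sum(t & !p),
                 TN = sum(!t & !p), FP = sum(!t & p)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion (seconds): TP=%d FN=%d TN=%d FP=%d\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Sensitivity, specificity and F1-score from confusion counts
#'
#' Applies the second-level definitions
#' `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`,
#' `F1 = 2 TP / (2 TP + FN + FP)`.
#' A metric whose denominator is zero is undefined and reported as `NA`,
#' never as 0: a session without labeled walking has no sensitivity.
#'
#' @param counts a [confusion()] result.
#' @param per_activity_fp optional named false-positive-rate vector from
#'   [fp_by_activity()], carried along in the report.
#' @return A list of class `gait_metrics` with fields `sensitivity`,
#'   `specificity`, `f1`, `counts` and `per_activity_fp`.
#' @export
compute_metrics <- function(counts, per_activity_fp = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    sensitivity = safe_div(counts$TP, counts$TP + counts$FN),
    specificity = safe_div(counts$TN, counts$TN + counts$FP),
    f1 = safe_div(2 * counts$TP, 2 * counts$TP + counts$FN + counts$FP),
    counts = counts,
    per_activity_fp = per_activity_fp), class = "gait_metrics")
}

#' @export
print.gait_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat("Second-level metrics\n")
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  F1-score:   ", fmt(x$f1), "\n")
  if (!is.null(x$per_activity_fp) && length(x$per_activity_fp)) {
    cat("  false-positive rate by activity:\n")
    for (a in names(x$per_activity_fp))
      cat(sprintf("    %-18s %.3f\n", a, x$per_activity_fp[[a]]))
  }
  invisible(x)
}

#' False-positive rate per activity of daily living
#'
#' For every non-walking activity, the fraction of its labeled seconds that
#' the detector called walking. Activities with zero labeled seconds are
#' omitted. High rates for oscillatory activities (tooth brushing, hand
#' washing) are the price of a permissive superharmonic ratio `beta`.
#'
#' @param pairs an [align_annotation()] data frame with `activity` tags.
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
fp_by_activity <- function(pairs) {
  neg <- pairs[!pairs$truth & pairs$activity != "walking", , drop = FALSE]
  if (!nrow(neg)) return(setNames(numeric(0), character(0)))
  tot <- tapply(rep(1L, nrow(neg)), neg$activity, sum)
  fp <- tapply(as.integer(neg$prediction), neg$activity, sum)
  setNames(as.numeric(fp / tot), names(tot))
}

#' Evaluate one annotated session
#'
#' Convenience wrapper: aligns, counts, and computes metrics plus the
#' per-activity false-positive breakdown in one call.
#'
#' @param annotation a [detect_walking()] result.
#' @param labels a [label_track()].
#' @return A [compute_metrics()] report.
#' @export
evaluate_annotation <- function(annotation, labels) {
  pairs <- align_annotation(annotation, labels)
  compute_metrics(confusion(pairs), per_activity_fp = fp_by_activity(pairs))
}

#' Per-group summary of subject metrics
#'
#' Summarizes per-subject metric reports by mobility-aid group in the
#' cohort-table style: unweighted mean across subjects plus the (min, max)
#' range, for each of sensitivity, specificity and F1, with an `overall`
#' column pooling all subjects. Subjects whose metric is undefined are
#' excluded from that metric's summary (with a message); a group with no
#' subjects is omitted with a warning.
#'
#' @param per_subject named list of [compute_metrics()] reports.
#' @param groups named character vector mapping subject -> group
#'   (`no_aid`, `cane`, `rollator`).
#' @return A `data.frame` with columns `metric`, `group`, `mean`, `min`,
#'   `max`, `n`.
#' @export
group_summary <- function(per_subject, groups) {
  stopifnot(length(per_subject) >= 1L,
            all(names(per_subject) %in% names(groups)))
  metrics <- c("sensitivity", "specificity", "f1")
  grp_levels <- c("overall", intersect(c("no_aid", "cane", "rollator"),
                                       unique(groups[names(per_subject)])))
  empty <- setdiff(c("no_aid", "cane", "rollator"),
                   unique(groups[names(per_subject)]))
  if (length(empty))
    warning("group(s) with no subjects omitted: ",
            paste(empty, collapse = ", "))
  rows <- list()
  for (m in metrics) {
    vals <- vapply(per_subject, function(r) r[[m]], numeric(1))
    if (anyNA(vals))
      message(sum(is.na(vals)), " subject(s) excluded from ", m,
              " summary (undefined metric)")
    for (g in grp_levels) {
      v <- if (g == "overall") vals else
        vals[groups[names(per_subject)] == g]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = g,
        mean = if (length(v)) mean(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
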