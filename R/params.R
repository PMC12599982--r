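#' Detector parameters
#'
#' Bundle of the six knobs steering the walking detector: the dynamic
#' amplitude threshold `A`, the subharmonic and superharmonic admission
#' ratios `alpha` and `beta`, the walking frequency band `[f_min, f_max]`,
#' and the minimum bout duration `T`.
#'
#' A 1-second window is a walking candidate when its dynamic amplitude
#' (max absolute deviation of the vector magnitude from the window mean)
#' exceeds `A`, its walking-band spectral peak `p_w` exists, and
#' `alpha * |p_w| > |p_min|` and `beta * |p_w| > |p_max|` hold against the
#' subharmonic and superharmonic peaks (strict inequalities; an absent peak
#' imposes no constraint). Candidate runs shorter than `T` seconds are then
#' discarded.
#'
#' @param A amplitude threshold in g; must be positive.
#' @param alpha subharmonic ratio (unitless, >= 0).
#' @param beta superharmonic ratio (unitless, >= 0).
#' @param f_min,f_max walking band bounds in Hz; `0 < f_min < f_max <= 5`
#'   (the Nyquist frequency at the 10 Hz working rate).
#' @param T minimum walking bout duration in whole seconds, >= 1.
#'
#' @return An object of class `gait_params` (a named list).
#' @seealso [gait_preset()] for the shipped parameter sets.
#' @examples
#' gait_params()                   # wrist defaults
#' gait_params(A = 0.1, f_min = 0.8, f_max = 2.8)
#' @export
gait_params <- function(A = 0.3, alpha = 31.7, beta = 1.4,
                        f_min = 1.4, f_max = 2.3, T = 6) {
  p <- list(A = as.numeric(A), alpha = as.numeric(alpha),
            beta = as.numeric(beta), f_min = as.numeric(f_min),
            f_max = as.numeric(f_max), T = as.numeric(T))
  for (nm in names(p)) {
    if (length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$A <= 0) stop("A must be > 0", call. = FALSE)
  if (p$alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (p$beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (p$f_min <= 0 || p$f_min >= p$f_max)
    stop("need 0 < f_min < f_max", call. = FALSE)
  if (p$f_max > 5)
    stop("f_max must be <= 5 Hz (Nyquist at the 10 Hz working rate)",
         call. = FALSE)
  if (p$T < 1 || p$T != round(p$T))
    stop("T must be a whole number of seconds >= 1", call. = FALSE)
  structure(p, class = "gait_params")
}

#' @export
print.gait_params <- function(x, ...) {
  cat("Gait detector parameters\n")
  cat(sprintf("  A     = %.3g g   (amplitude threshold)\n", x$A))
  cat(sprintf("  alpha = %.4g     (subharmonic ratio)\n", x$alpha))
  cat(sprintf("  beta  = %.4g     (superharmonic ratio)\n", x$beta))
  cat(sprintf("  f_w   = [%.3g, %.3g] Hz (walking band)\n", x$f_min, x$f_max))
  cat(sprintf("  T     = %d s     (minimum bout duration)\n", as.integer(x$T)))
  invisible(x)
}

#' Shipped parameter presets
#'
#' Two operating points ship with the package: `"default"`, the published
#' wrist parameters derived from large healthy-adult corpora
#' (A = 0.3 g, alpha = 31.7, beta = 1.4, f_w = \[1.4, 2.3\] Hz, T = 6 s),
#' and `"calibrated"`, the older-adult set obtained by leave-one-subject-out
#' tuning on a mobility-aid cohort
#' (A = 0.1 g, alpha = 65.4, beta = 77.1, f_w = \[0.8, 2.8\] Hz, T = 10 s).
#'
#' @param name `"default"` or `"calibrated"`.
#' @return A [gait_params()] object.
#' @examples
#' gait_preset("calibrated")
#' @export
gait_preset <- function(name = c("default", "calibrated")) {
  name <- match.arg(name)
  path <- system.file("extdata", "params", paste0(name, ".json"),
                      package = "walkwatch", mustWork = TRUE)
  read_gait_params(path)
}

#' Read / write detector parameters as JSON
#'
#' The on-disk format is a flat JSON object with keys
#' `A`, `alpha`, `beta`, `f_min`, `f_max`, `T`.
#'
#' @param path file path.
#' @param params a [gait_params()] object.
#' @return `read_gait_params()` returns a [gait_params()] object;
#'   `write_gait_params()` returns `path` invisibly.
#' @export
read_gait_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("A", "alpha", "beta", "f_min", "f_max", "T")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file ", path, " is missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  do.call(gait_params, x[need])
}

#' @rdname read_gait_params
#' @export
write_gait_params <- function(params, path) {
  stopifnot(inherits(params, "gait_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
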