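#' Landmark specification for piecewise-linear time warping
#'
#' Holds the warp landmarks: the two peak times of the population template and
#' the left/right boundaries of each peak's domain. The warp maps template
#' time to trial time, moving each peak by a trial-specific shift while fixing
#' all other landmarks.
#'
#' @param t1L,tpeak1,t1R left boundary, location, and right boundary of the
#'   first peak (ms); must satisfy `0 < t1L < tpeak1 < t1R`.
#' @param t2L,tpeak2,t2R same for the second peak; `t1R <= t2L` (the domains
#'   may share a boundary) and `t2R < T`.
#' @param T analysis window length (ms).
#' @return object of class `warp_spec`.
#' @export
warp_spec <- function(t1L, tpeak1, t1R, t2L, tpeak2, t2R, T = 500) {
  ok <- 0 < t1L && t1L < tpeak1 && tpeak1 < t1R && t1R <= t2L &&
    t2L < tpeak2 && tpeak2 < t2R && t2R < T
  if (!ok) stop("warp landmarks must satisfy 0 < t1L < tpeak1 < t1R <= t2L < tpeak2 < t2R < T")
  structure(list(t1L = t1L, tpeak1 = tpeak1, t1R = t1R,
                 t2L = t2L, tpeak2 = tpeak2, t2R = t2R, T = T),
            class = "warp_spec")
}

#' Admissible domain of the peak shifts
#'
#' The shift for peak k must keep the warped peak strictly inside its domain;
#' a safety `margin` (default one 2 ms bin) keeps warp segments from
#' degenerating.
#'
#' @param spec a [warp_spec()].
#' @param margin shrinkage of the open domain at each end (ms).
#' @return 2x2 matrix: rows = (peak1, peak2), columns = (lower, upper).
#' @export
shift_domain <- function(spec, margin = 2) {
  rbind(peak1 = c(spec$t1L - spec$tpeak1 + margin, spec$t1R - spec$tpeak1 - margin),
        peak2 = c(spec$t2L - spec$tpeak2 + margin, spec$t2R - spec$tpeak2 - margin))
}

#' Build a piecewise-linear warp from peak shifts
#'
#' Constructs the monotone map `phi: [0, T] -> [0, T]` interpolating linearly
#' through the join-points `(0,0)`, `(t1L,t1L)`, `(tpeak1, tpeak1+peak1)`,
#' `(t1R,t1R)`, `(t2L,t2L)`, `(tpeak2, tpeak2+peak2)`, `(t2R,t2R)`, `(T,T)`.
#' `phi` maps template time to trial time, so the template's peak-k is
#' observed at `tpeak_k + peak_k` on this trial.
#'
#' @param spec a [warp_spec()].
#' @param peak1,peak2 shifts (ms) within the open domains given by
#'   [shift_domain()] with zero margin.
#' @return object of class `warp_fun` with join-point vectors `x` (template
#'   time) and `y` (trial time).
#' @export
build_warp <- function(spec, peak1 = 0, peak2 = 0) {
  dom <- shift_domain(spec, margin = 0)
  if (peak1 <= dom[1, 1] || peak1 >= dom[1, 2])
    stop("peak1 shift outside its admissible domain")
  if (peak2 <= dom[2, 1] || peak2 >= dom[2, 2])
    stop("peak2 shift outside its admissible domain")
  x <- c(0, spec$t1L, spec$tpeak1, spec$t1R, spec$t2L, spec$tpeak2, spec$t2R, spec$T)
  y <- c(0, spec$t1L, spec$tpeak1 + peak1, spec$t1R, spec$t2L,
         spec$tpeak2 + peak2, spec$t2R, spec$T)
  # drop a duplicated interior point when t1R == t2L
  keep <- c(TRUE, diff(x) > 0)
  structure(list(x = x[keep], y = y[keep], spec = spec,
                 peak1 = peak1, peak2 = peak2),
            class = "warp_fun")
}

#' Evaluate a warp (or its inverse)
#'
#' @param warp a [build_warp()] object.
#' @param t times in ms within `[0, T]`.
#' @param inverse if `TRUE`, evaluate `phi^{-1}` instead of `phi`.
#' @return warped times; endpoints are fixed and order is preserved.
#' @export
warp_time <- function(warp, t, inverse = FALSE) {
  if (inverse) piecewise_linear(warp$y, warp$x, t)
  else piecewise_linear(warp$x, warp$y, t)
}

#' Invert a warp
#'
#' The inverse of a piecewise-linear monotone warp is the piecewise-linear map
#' through the swapped join-points.
#'
#' @param warp a [build_warp()] object.
#' @return a `warp_fun` representing `phi^{-1}`.
#' @export
invert_warp <- function(warp) {
  structure(list(x = warp$y, y = warp$x, spec = warp$spec,
                 peak1 = warp$peak1, peak2 = warp$peak2),
            class = "warp_fun")
}

#' Map spike times into template coordinates
#'
#' Applies `phi^{-1}` to each spike time, aligning trial spikes to template
#' time so that warped trains can be scored against the unwarped template.
#'
#' @param times spike times (ms) in `[0, T]`.
#' @param warp a [build_warp()] object (the forward warp).
#' @return warped spike times, same order as input.
#' @export
warp_spike_times <- function(times, warp) {
  if (length(times) && (min(times) < 0 || max(times) > warp$spec$T))
    stop("spike times outside [0, T]")
  warp_time(warp, times, inverse = TRUE)
}
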