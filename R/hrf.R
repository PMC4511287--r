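#' Haemodynamic response parameters
#'
#' Parameter set for the canonical double-gamma haemodynamic response
#' function (HRF) used to build task regressors. The response peaks
#' `peak_s` seconds after stimulus onset, shows a late undershoot peaking at
#' `undershoot_s`, with a peak-to-undershoot amplitude ratio of `ratio`.
#' `lag_s` is an additional onset shift applied to the boxcar before
#' convolution, standing in for the per-participant haemodynamic lag of the
#' original protocol (assumed between 3 and 6 s; the default is the
#' midpoint).
#'
#' @param peak_s Time to peak of the positive gamma lobe, seconds.
#' @param undershoot_s Time to peak of the undershoot lobe, seconds.
#' @param ratio Peak:undershoot amplitude ratio.
#' @param lag_s Onset shift applied to the boxcar, seconds.
#' @param type `"double-gamma"` or `"impulse"` (an identity kernel, mainly
#'   for testing: the regressor then equals the lagged boxcar).
#' @return An object of class `hrf_params`.
#' @examples
#' hrf_params()
#' hrf_params(lag_s = 3)
#' @export
hrf_params <- function(peak_s = 5, undershoot_s = 15, ratio = 6,
                       lag_s = 4.5, type = c("double-gamma", "impulse")) {
  type <- match.arg(type)
  stopifnot(peak_s > 0, undershoot_s > peak_s, ratio > 0, lag_s >= 0)
  structure(
    list(peak_s = peak_s, undershoot_s = undershoot_s, ratio = ratio,
         lag_s = lag_s, type = type),
    class = "hrf_params"
  )
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf("<hrf_params> %s: peak %gs, undershoot %gs, ratio %g, lag %gs\n",
              x$type, x$peak_s, x$undershoot_s, x$ratio, x$lag_s))
  invisible(x)
}

#' Sample the HRF kernel on a time grid
#'
#' Double-gamma impulse response `g(t; a1, 1) - g(t; a2, 1) / ratio` where
#' the gamma shapes are chosen so the modes fall at `peak_s` and
#' `undershoot_s` (rate 1). Normalised to unit peak.
#'
#' @param hrf An [hrf_params()] object.
#' @param t Time points in seconds (non-negative).
#' @return Numeric vector of kernel values, peak value 1.
#' @export
hrf_kernel <- function(hrf = hrf_params(), t) {
  stopifnot(inherits(hrf, "hrf_params"))
  if (hrf$type == "impulse") {
    # discrete identity: handled by the convolution caller; on a continuous
    # grid return a spike at t == 0
    return(as.numeric(t == 0))
  }
  a1 <- hrf$peak_s + 1        # mode of gamma(shape, rate = 1) is shape - 1
  a2 <- hrf$undershoot_s + 1
  h <- dgamma(t, shape = a1, rate = 1) - dgamma(t, shape = a2, rate = 1) / hrf$ratio
  h[t < 0] <- 0
  h / max(h)
}
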