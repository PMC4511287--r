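#' Temporal high-pass filter on a Fourier basis
#'
#' Removes slow drift by regressing out sine/cosine pairs at 1..`cycles`
#' whole cycles per run from every voxel time series. The basis is
#' orthogonal to the constant, so the temporal mean is preserved, and the
#' projection is idempotent. The default (2 cycles per run) matches the
#' "low frequencies up to two cycles per scan" convention.
#'
#' @param run A [bold_run()], or a numeric matrix (time x series) /
#'   vector.
#' @param cycles Highest drift harmonic removed (whole cycles per run);
#'   must be below the Nyquist count `n_volumes / 2`.
#' @return Same type as the input, filtered.
#' @export
highpass_fourier <- function(run, cycles = 2) {
  if (inherits(run, "bold_run")) {
    m <- run_matrix(run)
    return(matrix_to_run(highpass_fourier(m, cycles), run))
  }
  x <- if (is.matrix(run)) run else matrix(run, ncol = 1)
  n <- nrow(x)
  if (cycles >= n / 2) {
    abort(sprintf("cycles (%g) must be below the Nyquist count n/2 = %g",
                  cycles, n / 2))
  }
  if (cycles < 1) return(run)
  tt <- (seq_len(n) - 1) / n
  B <- do.call(cbind, lapply(seq_len(floor(cycles)), function(k) {
    cbind(sin(2 * pi * k * tt), cos(2 * pi * k * tt))
  }))
  Q <- qr.Q(qr(B))
  out <- x - Q %*% crossprod(Q, x)
  if (is.matrix(run)) out else as.vector(out)
}

# 1D Gaussian smoothing operator with reflection padding, as a dense
# n x n matrix (rows sum to 1)
gaussian_operator <- function(n, sd_vox) {
  if (sd_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sd_vox))
  k <- dnorm(seq(-r, r) / sd_vox)
  k <- k / sum(k)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in seq(-r, r)) {
      j <- i + o
      if (j < 1) j <- 1L - j + 1L       # reflect about the edge
      if (j > n) j <- 2L * n - j + 1L
      j <- min(max(j, 1L), n)
      A[i, j] <- A[i, j] + k[o + r + 1L]
    }
  }
  A
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian kernel with per-axis SD `fwhm / (2 sqrt(2 ln 2))`
#' (in mm, converted to voxels), applied along the three spatial axes with
#' reflection padding at the borders. The kernel is normalised so a
#' constant volume is unchanged.
#'
#' @param x A [bold_run()], a 3D volume or a 4D array (smoothed volume by
#'   volume).
#' @param fwhm Full width at half maximum, mm; 0 is the identity.
#' @param voxel_mm Voxel edge lengths, mm (taken from the run when `x` is a
#'   `bold_run`).
#' @return Same type and shape as the input.
#' @export
smooth_gaussian <- function(x, fwhm = 6, voxel_mm = 3) {
  if (inherits(x, "bold_run")) {
    out <- x
    out$data <- smooth_gaussian(x$data, fwhm, x$voxel_mm)
    return(out)
  }
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(x)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  sd_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_mm
  d <- dim(x)
  for (axis in 1:3) {
    A <- gaussian_operator(d[axis], sd_vox[axis])
    x <- apply_along_axis(x, axis, A)
  }
  x
}

# multiply operator A along one axis of an n-d array
apply_along_axis <- function(x, axis, A) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  m <- A %*% matrix(xp, nrow = d[axis])
  xp <- array(m, dim = d[perm])
  aperm(xp, order(perm))
}

#' Mean-centre runs per voxel and concatenate in time
#'
#' The control analysis that pools runs into one time course: each run's
#' per-voxel temporal mean is subtracted (killing DC offsets between
#' scans), then runs are appended along time and the motion traces are
#' concatenated in the same order. Per-run boundaries are recorded so
#' timelines can be merged to match.
#'
#' @param runs List of [bold_run()]s sharing grid, voxel size and TR.
#' @param motions Optional list of motion matrices matching `runs`.
#' @return List with `run` (the concatenated, centred [bold_run()]),
#'   `motion` (row-bound matrix or `NULL`) and `boundaries` (tibble with
#'   per-run `first_volume`, `last_volume`).
#' @export
center_and_concatenate <- function(runs, motions = NULL) {
  stopifnot(length(runs) >= 1)
  d0 <- dim(runs[[1]]$data)[1:3]
  tr0 <- runs[[1]]$tr_s
  for (r in runs) {
    if (!identical(dim(r$data)[1:3], d0) || !isTRUE(all.equal(r$tr_s, tr0))) {
      abort("runs must share the spatial grid and TR")
    }
  }
  if (!is.null(motions)) stopifnot(length(motions) == length(runs))
  mats <- lapply(runs, function(r) {
    m <- run_matrix(r)
    sweep(m, 2, colMeans(m))
  })
  nvols <- vapply(mats, nrow, integer(1))
  last <- cumsum(nvols)
  first <- c(1L, head(last, -1) + 1L)
  all_mat <- do.call(rbind, mats)
  out <- runs[[1]]
  out$data <- array(t(all_mat), dim = c(d0, nrow(all_mat)))
  out$run <- "concatenated"
  motion <- if (!is.null(motions)) do.call(rbind, motions) else NULL
  list(run = out, motion = motion,
       boundaries = tibble(run = seq_along(runs),
                           first_volume = as.integer(first),
                           last_volume = as.integer(last)))
}

#' Standard preprocessing for one run
#'
#' High-pass filtering followed by spatial smoothing (in that order), with
#' the study defaults: drift removal up to 2 cycles per run and a 6-mm
#' FWHM kernel.
#'
#' @param run A [bold_run()].
#' @param highpass_cycles Drift harmonics to remove; 0 disables.
#' @param fwhm Smoothing FWHM, mm; 0 disables.
#' @param smooth_first Reverse the stage order.
#' @return The preprocessed [bold_run()].
#' @export
preprocess_run <- function(run, highpass_cycles = 2, fwhm = 6,
                           smooth_first = FALSE) {
  stopifnot(highpass_cycles >= 0, fwhm >= 0)
  stages <- list(
    hp = function(r) if (highpass_cycles >= 1) highpass_fourier(r, highpass_cycles) else r,
    sm = function(r) smooth_gaussian(r, fwhm)
  )
  if (smooth_first) stages <- rev(stages)
  for (f in stages) run <- f(run)
  run
}
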