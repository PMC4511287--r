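#' Extract the five respiration measures from an airflow trace
#'
#' Inhales are maximal contiguous positive-flow segments whose peak clears
#' a hysteresis threshold (by default 5% of the trace SD, rejecting noise
#' blips around zero flow). Segment boundaries are refined by linear
#' interpolation of the flow zero crossings. The five measures are:
#' respiration pace (breaths/min over the trace), mean inhale duration
#' (s), mean per-inhale peak flow, mean flow within inhales, and mean
#' per-inhale trapezoidal flow integral.
#'
#' @param trace Tibble (`time_s`, `flow`) such as from
#'   [generate_respiration()].
#' @param hysteresis_frac Hysteresis band as a fraction of the trace SD.
#' @param smooth_s Width (s) of the moving average used for breath
#'   *detection* only; measures are computed on the raw flow.
#' @return One-row tibble (`pace`, `inhale_duration`, `inhale_peak`,
#'   `inhale_mean`, `inhale_integral`, `n_breaths`).
#' @export
extract_breath_params <- function(trace, hysteresis_frac = 0.05,
                                  smooth_s = 0.2) {
  stopifnot(all(c("time_s", "flow") %in% names(trace)))
  t <- trace$time_s
  f <- trace$flow
  n <- length(f)
  span <- t[n] - t[1]
  h <- hysteresis_frac * sd(f)

  # detection trace: light moving average suppresses sample noise around
  # the zero crossings without shifting them
  fs_hz <- 1 / stats::median(diff(t))
  w <- max(1L, round(smooth_s * fs_hz))
  fd <- if (w > 1) {
    sm <- stats::filter(f, rep(1 / w, w), sides = 2)
    ifelse(is.na(sm), f, as.numeric(sm))
  } else f

  # hysteresis state: +1 after crossing above +h, -1 after crossing below
  # -h, carried forward between crossings (dips inside the band do not
  # split a breath)
  v <- integer(n)
  v[fd > h] <- 1L
  v[fd < -h] <- -1L
  last_nz <- cummax(ifelse(v != 0L, seq_len(n), 0L))
  state <- ifelse(last_nz == 0L, 0L, v[pmax(last_nz, 1L)])

  runs <- rle(state == 1L)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  sel <- which(runs$values)
  durations <- peaks <- means <- integrals <- numeric(0)
  for (s in sel) {
    i1 <- starts[s]
    i2 <- ends[s]
    if (i2 == n && state[n] == 1L) next   # unfinished trailing inhale
    # widen to the full positive lobe of the detection trace
    while (i1 > 1 && fd[i1 - 1] > 0) i1 <- i1 - 1L
    while (i2 > i1 && fd[i2] <= 0) i2 <- i2 - 1L
    if (fd[i2] <= 0) next
    # refine boundaries by interpolating the zero crossings
    t_on <- if (i1 > 1 && fd[i1 - 1] <= 0) {
      t[i1 - 1] + (t[i1] - t[i1 - 1]) * (0 - fd[i1 - 1]) / (fd[i1] - fd[i1 - 1])
    } else t[i1]
    t_off <- if (i2 < n && fd[i2 + 1] <= 0) {
      t[i2] + (t[i2 + 1] - t[i2]) * (0 - fd[i2]) / (fd[i2 + 1] - fd[i2])
    } else t[i2]
    ts <- c(t_on, t[i1:i2], t_off)
    fs <- c(0, f[i1:i2], 0)
    durations <- c(durations, t_off - t_on)
    peaks <- c(peaks, max(fs))
    means <- c(means, mean(f[i1:i2]))
    integrals <- c(integrals, sum(diff(ts) * (head(fs, -1) + tail(fs, -1)) / 2))
  }
  if (length(durations) == 0) abort("no breaths detected")
  if (length(durations) < 2) abort("trace shorter than two breath periods")
  tibble(pace = length(durations) / span * 60,
         inhale_duration = mean(durations),
         inhale_peak = mean(peaks),
         inhale_mean = mean(means),
         inhale_integral = mean(integrals),
         n_breaths = length(durations))
}

#' Compare respiration measures between conditions
#'
#' Per-measure paired t-tests between two conditions with a Bonferroni
#' family of five (the five extracted measures).
#'
#' @param summaries Tibble with `subject`, `condition` and the five
#'   measure columns (one row per subject x condition), e.g. row-bound
#'   [extract_breath_params()] results.
#' @param conditions Length-2 character: the pair to compare.
#' @param families Bonferroni family size (default 5).
#' @return Tibble, one row per measure (`t`, `p`, `p_bonferroni`, `df`,
#'   `mean_diff`).
#' @export
compare_breath <- function(summaries, conditions = NULL, families = 5) {
  measures <- c("pace", "inhale_duration", "inhale_peak", "inhale_mean",
                "inhale_integral")
  stopifnot(all(c("subject", "condition", measures) %in% names(summaries)))
  if (is.null(conditions)) conditions <- unique(summaries$condition)
  if (length(conditions) != 2) abort("exactly two conditions required")
  long <- tidyr::pivot_longer(summaries[, c("subject", "condition", measures)],
                              dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  compare_conditions(long, conditions, unit = "measure", value = "value",
                     families = families)
}
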