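#' Build a block-design experiment timeline
#'
#' Lays out task blocks in (pseudo)random order, each followed by a rest
#' epoch, on the volume grid of the scanner. The default geometry is the
#' study protocol: five 21-s blocks per condition, 12-s rests, TR 3 s.
#' Block onsets are snapped to the volume grid by rounding `onset / tr_s`
#' to the nearest whole volume.
#'
#' @param conditions Character vector of task condition labels. May be
#'   empty, giving an empty timeline of duration 0.
#' @param n_blocks Number of blocks per condition.
#' @param block_s Task block duration, seconds.
#' @param rest_s Rest epoch duration, seconds.
#' @param tr_s Repetition time, seconds.
#' @param seed Integer seed for the pseudorandom block order. Ignored when
#'   `order` is given.
#' @param order Optional explicit block order: a character vector of length
#'   `length(conditions) * n_blocks` containing each condition exactly
#'   `n_blocks` times.
#' @param cue_s Optional auditory-cue duration at each block onset, seconds
#'   (recorded, not modelled by default).
#' @param rest_label Label used for rest epochs.
#' @return A `bold_timeline`: a tibble of epochs (`condition`, `onset`,
#'   `duration`, seconds) with attributes `tr_s`, `n_volumes`, `cue_s` and
#'   `rest_label`.
#' @examples
#' tl <- build_timeline(c("RS", "Motor", "ThoughtControl"), seed = 1)
#' timeline_duration(tl) / 60  # 8.25 min
#' @export
build_timeline <- function(conditions, n_blocks = 5, block_s = 21,
                           rest_s = 12, tr_s = 3, seed = 1, order = NULL,
                           cue_s = NA_real_, rest_label = "Rest") {
  if (block_s <= 0 || rest_s <= 0 || tr_s <= 0) {
    abort("block, rest and TR durations must all be positive")
  }
  if (length(conditions) > 0 && n_blocks < 1) {
    abort("n_blocks must be at least 1")
  }
  if (anyDuplicated(conditions)) abort("duplicated condition labels")
  if (rest_label %in% conditions) abort("rest_label clashes with a condition")

  if (length(conditions) == 0) {
    epochs <- tibble(condition = character(), onset = numeric(),
                     duration = numeric())
    return(new_timeline(epochs, tr_s, 0L, cue_s, rest_label))
  }

  if (is.null(order)) {
    order <- with_seed(seed, sample(rep(conditions, n_blocks)))
  } else {
    if (!identical(sort(order), sort(rep(conditions, n_blocks)))) {
      abort("order must contain each condition exactly n_blocks times")
    }
  }

  # snap the (block, rest) grid to whole volumes
  n_total <- length(order)
  onsets <- numeric(2L * n_total)
  durations <- numeric(2L * n_total)
  labels <- character(2L * n_total)
  t0 <- 0
  for (i in seq_len(n_total)) {
    b_on <- round(t0 / tr_s) * tr_s
    b_off <- round((t0 + block_s) / tr_s) * tr_s
    r_off <- round((t0 + block_s + rest_s) / tr_s) * tr_s
    labels[2L * i - 1L] <- order[i]
    onsets[2L * i - 1L] <- b_on
    durations[2L * i - 1L] <- b_off - b_on
    labels[2L * i] <- rest_label
    onsets[2L * i] <- b_off
    durations[2L * i] <- r_off - b_off
    t0 <- t0 + block_s + rest_s
  }
  epochs <- tibble(condition = labels, onset = onsets, duration = durations)
  n_vol <- as.integer(round(sum(durations) / tr_s))
  new_timeline(epochs, tr_s, n_vol, cue_s, rest_label)
}

new_timeline <- function(epochs, tr_s, n_volumes, cue_s, rest_label) {
  structure(epochs,
            class = c("bold_timeline", class(epochs)),
            tr_s = tr_s, n_volumes = as.integer(n_volumes),
            cue_s = cue_s, rest_label = rest_label)
}

#' Study timelines for the two experiments
#'
#' Convenience constructors for the two experiment protocols: a
#' repetitive-speech run (`timeline_rs()`: RS, a tone-discrimination motor
#' task, and a thought-control condition — 8.25 min, 15 rest epochs) and a
#' verbal-fluency run (`timeline_vf()`: VF, abstract thought, imagery and
#' sentence conjugation — 11 min, 20 rest epochs).
#'
#' @param seed Seed for the pseudorandom block order.
#' @inheritParams build_timeline
#' @return A `bold_timeline`.
#' @export
timeline_rs <- function(seed = 1, order = NULL) {
  build_timeline(c("RS", "Motor", "ThoughtControl"), seed = seed,
                 order = order, cue_s = 1.1)
}

#' @rdname timeline_rs
#' @export
timeline_vf <- function(seed = 1, order = NULL) {
  build_timeline(c("VF", "Abstract", "Imagery", "SentenceConjugation"),
                 seed = seed, order = order, cue_s = 1.1)
}

#' @export
print.bold_timeline <- function(x, ...) {
  cat(sprintf("<bold_timeline> %d epochs, %.1f s (%d volumes at TR %g s), %d rest epochs\n",
              nrow(x), timeline_duration(x), n_volumes(x),
              attr(x, "tr_s"), n_rest_epochs(x)))
  NextMethod()
}

#' Timeline accessors
#'
#' @param timeline A `bold_timeline`.
#' @return `timeline_duration()`: total duration in seconds;
#'   `n_volumes()`: volume count; `n_rest_epochs()`: number of rest epochs;
#'   `task_conditions()`: unique task condition labels in block order.
#' @export
timeline_duration <- function(timeline) sum(timeline$duration)

#' @rdname timeline_duration
#' @export
n_volumes <- function(timeline) attr(timeline, "n_volumes")

#' @rdname timeline_duration
#' @export
n_rest_epochs <- function(timeline) {
  sum(timeline$condition == attr(timeline, "rest_label"))
}

#' @rdname timeline_duration
#' @export
task_conditions <- function(timeline) {
  unique(timeline$condition[timeline$condition != attr(timeline, "rest_label")])
}

#' Build a task regressor
#'
#' Unit-height boxcar over the condition's epochs, shifted by the
#' haemodynamic lag, convolved with the HRF kernel on a fine time grid and
#' sampled at volume acquisition times. The peak is normalised to 1 so the
#' regression coefficient is the peak response in signal units.
#'
#' @param timeline A `bold_timeline`.
#' @param condition Condition label present in the timeline.
#' @param hrf An [hrf_params()] object.
#' @param normalize Divide by the peak value (default). Disable to keep the
#'   raw convolution, which is linear in the boxcar.
#' @param dt Fine-grid resolution for the convolution, seconds.
#' @return Numeric vector of length `n_volumes(timeline)`.
#' @export
make_regressor <- function(timeline, condition, hrf = hrf_params(),
                           normalize = TRUE, dt = 0.1) {
  if (!condition %in% timeline$condition) {
    abort(sprintf("condition '%s' not present in the timeline", condition))
  }
  tr <- attr(timeline, "tr_s")
  nv <- n_volumes(timeline)
  t_vol <- (seq_len(nv) - 1) * tr
  eps <- timeline[timeline$condition == condition, , drop = FALSE]

  boxcar_at <- function(t) {
    out <- numeric(length(t))
    for (i in seq_len(nrow(eps))) {
      on <- eps$onset[i] + hrf$lag_s
      out[t >= on & t < on + eps$duration[i]] <- 1
    }
    out
  }

  if (hrf$type == "impulse") {
    reg <- boxcar_at(t_vol)
  } else {
    tail_s <- 32
    t_fine <- seq(0, timeline_duration(timeline) + tail_s, by = dt)
    box <- boxcar_at(t_fine)
    h <- hrf_kernel(hrf, seq(0, tail_s, by = dt))
    conv <- convolve_open(box, h) * dt
    reg <- conv[round(t_vol / dt) + 1L]
  }
  if (normalize) {
    m <- max(abs(reg))
    if (m > 0) reg <- reg / m
  }
  reg
}

# full ("open") discrete convolution, truncated to length(x)
convolve_open <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                       stats::fft(c(k, numeric(nf - length(k)))),
                     inverse = TRUE)) / nf
  y[seq_along(x)]
}

#' Assemble a GLM design matrix
#'
#' Task regressors for the requested conditions, optional six motion
#' nuisance columns, and an intercept. Rest is never modelled: the
#' intercept absorbs the pooled average of all rest periods, so a contrast
#' on a task column is that condition versus the mean rest baseline.
#'
#' @param timeline A `bold_timeline`.
#' @param conditions Task conditions to model; defaults to all task
#'   conditions in the timeline.
#' @param motion Optional motion-parameter matrix or data frame with
#'   `n_volumes(timeline)` rows and 6 columns (3 translations mm, 3
#'   rotations deg). Columns are mean-centred before entering the design.
#' @param hrf An [hrf_params()] object.
#' @return A `bold_design`: list with elements `matrix`
#'   (`n_volumes x n_regressors`), `labels`, `task_columns`, `hrf`, `tr_s`.
#' @export
build_design_matrix <- function(timeline, conditions = task_conditions(timeline),
                                motion = NULL, hrf = hrf_params()) {
  if (anyDuplicated(conditions)) abort("duplicated condition labels in design")
  nv <- n_volumes(timeline)
  task <- vapply(conditions, function(cc) make_regressor(timeline, cc, hrf),
                 numeric(nv))
  task <- matrix(task, nrow = nv,
                 dimnames = list(NULL, conditions))
  cols <- task
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nv || ncol(motion) != 6) {
      abort(sprintf("motion trace must be %d x 6 (got %d x %d)",
                    nv, nrow(motion), ncol(motion)))
    }
    motion <- scale(motion, center = TRUE, scale = FALSE)
    colnames(motion) <- paste0("motion", 1:6)
    cols <- cbind(cols, motion)
  }
  X <- cbind(cols, "(Intercept)" = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(sprintf("design matrix is rank deficient; collinear columns: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(
    list(matrix = X, labels = colnames(X), task_columns = conditions,
         hrf = hrf, tr_s = attr(timeline, "tr_s")),
    class = "bold_design"
  )
}

#' @export
print.bold_design <- function(x, ...) {
  cat(sprintf("<bold_design> %d volumes x %d regressors: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' @describeIn build_design_matrix Long-format tibble of the design
#'   (`volume`, `time_s`, `regressor`, `value`).
#' @param x A `bold_design`.
#' @param ... Unused.
#' @method tidy bold_design
#' @export
tidy.bold_design <- function(x, ...) {
  m <- x$matrix
  tibble(
    volume = rep(seq_len(nrow(m)), times = ncol(m)),
    time_s = rep((seq_len(nrow(m)) - 1) * x$tr_s, times = ncol(m)),
    regressor = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Write / read event timing files
#'
#' Tab-separated files with columns `onset`, `duration`, `trial_type`
#' (seconds, 3 decimal places), one row per epoch including rests.
#'
#' @param timeline A `bold_timeline`.
#' @param path File path.
#' @export
write_events <- function(timeline, path) {
  df <- data.frame(onset = sprintf("%.3f", timeline$onset),
                   duration = sprintf("%.3f", timeline$duration),
                   trial_type = timeline$condition)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_events
#' @param tr_s Repetition time of the run the events belong to, seconds.
#' @param rest_label Label of rest epochs in `trial_type`.
#' @param cue_s Optional cue duration to record.
#' @export
read_events <- function(path, tr_s, rest_label = "Rest", cue_s = NA_real_) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df))) {
    abort("events file must have columns onset, duration, trial_type")
  }
  epochs <- tibble(condition = as.character(df$trial_type),
                   onset = as.numeric(df$onset),
                   duration = as.numeric(df$duration))
  epochs <- epochs[order(epochs$onset), ]
  n_vol <- as.integer(round(sum(epochs$duration) / tr_s))
  new_timeline(epochs, tr_s, n_vol, cue_s, rest_label)
}
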