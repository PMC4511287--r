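#' Noise parameters for the BOLD simulator
#'
#' The noise model stands in for unmodelled physiology: white innovations
#' with optional AR(1) serial correlation, slow sinusoidal drift at 1 to
#' `drift_cycles` whole cycles per run (the component the high-pass stage
#' targets), a motion-coupled component, and optional spatial smoothing of
#' the noise field.
#'
#' @param white_sd Innovation standard deviation, signal units.
#' @param ar1 AR(1) coefficient in `[0, 1)`. The marginal noise SD is
#'   `white_sd / sqrt(1 - ar1^2)`.
#' @param drift_amplitude Amplitude of each drift harmonic, signal units.
#' @param drift_cycles Highest whole-cycle drift harmonic per run.
#' @param motion_amplitude Amplitude of the motion-coupled component.
#' @param spatial_fwhm FWHM (mm) of spatial smoothing applied to the noise
#'   field; 0 disables it.
#' @param seed Mandatory integer seed.
#' @return A `noise_params` object.
#' @export
noise_params <- function(white_sd = 1, ar1 = 0.2, drift_amplitude = 2,
                         drift_cycles = 2, motion_amplitude = 0.1,
                         spatial_fwhm = 0, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("noise_params() requires an explicit seed")
  }
  stopifnot(white_sd >= 0, ar1 >= 0, ar1 < 1, drift_amplitude >= 0,
            motion_amplitude >= 0, spatial_fwhm >= 0)
  structure(
    list(white_sd = white_sd, ar1 = ar1, drift_amplitude = drift_amplitude,
         drift_cycles = drift_cycles, motion_amplitude = motion_amplitude,
         spatial_fwhm = spatial_fwhm, seed = as.integer(seed)),
    class = "noise_params"
  )
}

#' Ground-truth voxel regimes
#'
#' Labels every voxel of a grid as `task_positive` (+1), `task_negative`
#' (-1) or `null` (0) with signed response amplitudes in percent signal
#' change. Two hypothetical response regimes are supported: `antagonistic`
#' (balanced positive and negative populations, the push-pull prediction)
#' and `gating` (deactivation only — the positive fraction is forced to 0).
#' Responders are placed as compact spherical blobs around seeded centres
#' in opposite corners of the grid ("language-like" for positive,
#' "DMN-like" for negative), since real (de)activation foci are spatially
#' contiguous; counts are exact.
#'
#' @param regime `"antagonistic"` or `"gating"`.
#' @param grid Grid dimensions, voxels (length 3).
#' @param voxel_mm Voxel edge length, mm.
#' @param fractions Named fractions `c(pos =, neg =)` of grid voxels per
#'   sign; must sum to at most 1.
#' @param amplitudes Named amplitudes `c(pos =, neg =)` in percent signal
#'   change (pos > 0, neg < 0).
#' @param seed Seed for blob-centre placement.
#' @return A `ground_truth`: labels and amplitude arrays, disjoint region
#'   masks, and the generating parameters.
#' @examples
#' gt <- make_ground_truth("gating", grid = c(10, 10, 10), seed = 1)
#' glance(gt)
#' @export
make_ground_truth <- function(regime = c("antagonistic", "gating"),
                              grid = c(20, 20, 20), voxel_mm = 3,
                              fractions = c(pos = 0.1, neg = 0.1),
                              amplitudes = c(pos = 1, neg = -1),
                              seed = 1) {
  regime <- match.arg(regime)
  if (regime == "gating") fractions[["pos"]] <- 0
  if (any(fractions < 0) || sum(fractions) > 1) {
    abort("fractions must be non-negative and sum to at most 1")
  }
  if (fractions[["pos"]] > 0 && amplitudes[["pos"]] <= 0) {
    abort("positive amplitude must be > 0")
  }
  if (fractions[["neg"]] > 0 && amplitudes[["neg"]] >= 0) {
    abort("negative amplitude must be < 0")
  }
  n_vox <- prod(grid)
  n_pos <- round(fractions[["pos"]] * n_vox)
  n_neg <- round(fractions[["neg"]] * n_vox)

  labels <- array(0L, grid)
  amplitude <- array(0, grid)
  coords <- which(array(TRUE, grid), arr.ind = TRUE)

  centres <- with_seed(seed, {
    jit <- function(lo, hi) lo + (hi - lo) * runif(3)
    list(pos = grid * jit(0.15, 0.35),   # "language-like" corner
         neg = grid * jit(0.65, 0.85))   # "DMN-like" corner
  })
  take_blob <- function(centre, k, taken) {
    if (k == 0) return(integer(0))
    d2 <- (coords[, 1] - centre[1])^2 + (coords[, 2] - centre[2])^2 +
      (coords[, 3] - centre[3])^2
    ord <- order(d2, seq_len(n_vox))   # ties: lexicographic linear index
    ord <- ord[!ord %in% taken]
    ord[seq_len(k)]
  }
  pos_idx <- take_blob(centres$pos, n_pos, integer(0))
  neg_idx <- take_blob(centres$neg, n_neg, pos_idx)
  labels[pos_idx] <- 1L
  labels[neg_idx] <- -1L
  amplitude[pos_idx] <- amplitudes[["pos"]]
  amplitude[neg_idx] <- amplitudes[["neg"]]

  region <- function(idx) {
    m <- array(FALSE, grid)
    m[idx] <- TRUE
    m
  }
  structure(
    list(labels = labels, amplitude = amplitude,
         regions = list("language-like" = region(pos_idx),
                        "DMN-like" = region(neg_idx)),
         voxel_mm = rep_len(as.numeric(voxel_mm), 3),
         regime = regime, fractions = fractions, amplitudes = amplitudes,
         seed = seed),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s regime, %s grid, %d pos / %d neg voxels\n",
              x$regime, paste(dim(x$labels), collapse = "x"),
              sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}

#' @describeIn make_ground_truth One-row summary including the ideal
#'   antagonism index implied by the labels.
#' @param x A `ground_truth`.
#' @param ... Unused.
#' @method glance ground_truth
#' @export
glance.ground_truth <- function(x, ...) {
  n_pos <- sum(x$labels == 1L)
  n_neg <- sum(x$labels == -1L)
  tibble(regime = x$regime, n_voxels = length(x$labels),
         n_pos = n_pos, n_neg = n_neg,
         ideal_antagonism = antagonism_index(n_pos, n_neg, quiet = TRUE))
}

#' Simulate one subject's BOLD run
#'
#' Forward model: `baseline * (1 + amplitude/100 * regressor)` per voxel,
#' plus slow sinusoidal drift, AR(1)-filtered white noise and a
#' motion-coupled component. The emitted motion trace is exactly the one
#' mixed into the data, so it can serve as the nuisance regressor set.
#'
#' @param truth A [make_ground_truth()] object.
#' @param timeline A `bold_timeline` on the same TR grid.
#' @param noise A [noise_params()] object.
#' @param subject Subject identifier.
#' @param respond_to Condition whose regressor carries the response;
#'   defaults to the first task condition of the timeline.
#' @param baseline Baseline intensity, signal units.
#' @param hrf HRF used to build the response regressor.
#' @param seed Seed for this subject; defaults to `noise$seed`.
#' @return List with elements `run` (a [bold_run()]) and `motion`
#'   (a `n_volumes x 6` matrix: 3 translations mm, 3 rotations deg).
#' @export
generate_subject_bold <- function(truth, timeline, noise,
                                  subject = "s01",
                                  respond_to = task_conditions(timeline)[1],
                                  baseline = 100, hrf = hrf_params(),
                                  seed = noise$seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_params"))
  grid <- dim(truth$labels)
  nv <- n_volumes(timeline)
  n_vox <- prod(grid)
  reg <- make_regressor(timeline, respond_to, hrf)
  amp <- as.vector(truth$amplitude)

  with_seed(seed, {
    signal <- baseline * (1 + outer(reg, amp / 100))

    if (noise$drift_amplitude > 0 && noise$drift_cycles >= 1) {
      tt <- (seq_len(nv) - 1) / nv
      for (k in seq_len(floor(noise$drift_cycles))) {
        phase <- runif(n_vox, 0, 2 * pi)
        basis <- 2 * pi * k * tt
        # per-voxel random phase: sin(b + phi) = sin b cos phi + cos b sin phi
        signal <- signal +
          (noise$drift_amplitude / k) *
          (outer(sin(basis), cos(phase)) + outer(cos(basis), sin(phase)))
      }
    }

    eps <- matrix(0, nv, n_vox)
    if (noise$white_sd > 0) {
      eps <- matrix(rnorm(nv * n_vox, sd = noise$white_sd), nv, n_vox)
      if (noise$ar1 > 0) {
        eps[1, ] <- eps[1, ] / sqrt(1 - noise$ar1^2)  # stationary start
        for (t in 2:nv) eps[t, ] <- noise$ar1 * eps[t - 1, ] + eps[t, ]
      }
      if (noise$spatial_fwhm > 0) {
        arr <- array(t(eps), dim = c(grid, nv))
        arr <- smooth_gaussian(arr, noise$spatial_fwhm, truth$voxel_mm)
        eps <- t(matrix(arr, nrow = n_vox))
      }
    }

    motion <- cbind(
      matrix(apply(matrix(rnorm(nv * 3, sd = 0.02), nv), 2, cumsum), nv),
      matrix(apply(matrix(rnorm(nv * 3, sd = 0.02), nv), 2, cumsum), nv)
    )
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    if (noise$motion_amplitude > 0) {
      m1 <- as.vector(scale(motion[, 1]))
      loading <- rnorm(n_vox)
      signal <- signal + noise$motion_amplitude * outer(m1, loading)
    }

    data <- array(t(signal + eps), dim = c(grid, nv))
    list(run = bold_run(data, tr_s = attr(timeline, "tr_s"),
                        voxel_mm = truth$voxel_mm, subject = subject),
         motion = motion)
  })
}

#' Simulate a cohort of subjects
#'
#' Applies [generate_subject_bold()] with per-subject seeds derived from
#' `seed`.
#'
#' @inheritParams generate_subject_bold
#' @param n_subjects Number of subjects.
#' @param seed Cohort seed.
#' @return List of per-subject lists (`run`, `motion`), names `s01`, ...
#' @export
simulate_cohort <- function(truth, timeline, noise, n_subjects = 23,
                            seed = noise$seed, ...) {
  ids <- sprintf("s%02d", seq_len(n_subjects))
  out <- lapply(seq_len(n_subjects), function(i) {
    generate_subject_bold(truth, timeline, noise, subject = ids[i],
                          seed = child_seed(seed, i), ...)
  })
  names(out) <- ids
  out
}

# latent-to-Likert cut-points (SD units) and the attenuation factor
# lambda = cor(latent, discretised latent) under N(0,1)
likert_cuts <- c(-1.5, -0.5, 0.5, 1.5)

likert_attenuation <- function(cuts = likert_cuts) {
  p <- diff(c(0, pnorm(cuts), 1))
  lev <- seq_along(p)
  mu <- sum(p * lev)
  sd_d <- sqrt(sum(p * (lev - mu)^2))
  sum(dnorm(cuts)) / sd_d
}

discretise_likert <- function(x, cuts = likert_cuts) {
  findInterval(x, cuts) + 1L
}

#' Default questionnaire item categories
#'
#' Seventeen retained items `q01`..`q17`: seven "Thoughts" items, three
#' "Sensations" items, the rest uncategorised. The original item wording is
#' not public; only the category structure matters for the analysis.
#'
#' @return Named character vector mapping item id to category.
#' @export
default_item_categories <- function() {
  setNames(
    c(rep("Thoughts", 7), rep("Sensations", 3), rep("other", 7)),
    sprintf("q%02d", 1:17)
  )
}

#' Simulate a Likert questionnaire cohort
#'
#' Each subject x condition draws category factors from a bivariate normal
#' whose Thoughts x Sensations correlation is calibrated (through the item
#' loading and the discretisation attenuation) so the *observed* mean
#' cross-category item correlation targets `correlation[condition]`. Item
#' scores load on their category factor, receive the per-category mean
#' shift for the condition, and are discretised to 1-5 by fixed latent
#' cut-points at -1.5, -0.5, 0.5, 1.5 SD. The defaults emulate the study's
#' behavioural cohort: 30 subjects, Rest vs RS, Thoughts and Sensations
#' reduced during RS, and a Rest anti-correlation of -0.24 that collapses
#' to -0.04 during RS.
#'
#' @param n_subjects Number of subjects (0 gives an empty table).
#' @param item_categories Named map item -> category, as
#'   [default_item_categories()].
#' @param condition_effects Named list (per condition) of per-category mean
#'   shifts in latent SD units.
#' @param correlation Named vector of target Thoughts x Sensations observed
#'   correlations per condition (|r| < 1 and feasible).
#' @param within_loading Variance fraction an item shares with its category
#'   factor.
#' @param seed Integer seed.
#' @return Tibble (`subject`, `condition`, `item`, `rating`).
#' @export
generate_questionnaire <- function(
    n_subjects = 30,
    item_categories = default_item_categories(),
    condition_effects = list(
      Rest = c(Thoughts = 0, Sensations = 0, other = 0),
      RS = c(Thoughts = -0.8, Sensations = -0.6, other = 0)
    ),
    correlation = c(Rest = -0.24, RS = -0.04),
    within_loading = 0.5,
    seed = 1) {
  conditions <- names(condition_effects)
  stopifnot(length(conditions) >= 1, all(conditions %in% names(correlation)))
  lambda2 <- likert_attenuation()^2
  rho <- correlation[conditions] / (lambda2 * within_loading)
  if (any(abs(rho) >= 1)) {
    abort("infeasible correlation target: implied latent factor correlation >= 1 (not positive definite)")
  }
  shifts <- lapply(condition_effects, function(s) {
    if (any(abs(s) > 2)) abort("category shifts must keep means within [1, 5]")
    s
  })
  items <- names(item_categories)
  if (n_subjects == 0) {
    return(tibble(subject = character(), condition = character(),
                  item = character(), rating = integer()))
  }
  w <- within_loading
  with_seed(seed, {
    rows <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      r <- rho[[cond]]
      # factor draws: F_S = r F_T + sqrt(1 - r^2) Z
      f_t <- rnorm(n_subjects)
      f_s <- r * f_t + sqrt(1 - r^2) * rnorm(n_subjects)
      lat <- matrix(rnorm(n_subjects * length(items)), n_subjects)
      for (j in seq_along(items)) {
        cat_j <- item_categories[[j]]
        f <- switch(cat_j, Thoughts = f_t, Sensations = f_s,
                    rnorm(n_subjects))
        lat[, j] <- sqrt(w) * f + sqrt(1 - w) * lat[, j] +
          shifts[[cond]][[cat_j]]
      }
      rows[[ci]] <- tibble(
        subject = rep(sprintf("s%02d", seq_len(n_subjects)), length(items)),
        condition = cond,
        item = rep(items, each = n_subjects),
        rating = discretise_likert(as.vector(lat))
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a respiration airflow trace
#'
#' Quasi-sinusoidal airflow: each breath is one sine cycle (positive lobe =
#' inhale) whose period is the nominal `60 / pace` multiplied by a
#' per-breath lognormal jitter factor, plus optional white measurement
#' noise.
#'
#' @param pace Nominal respiration pace, breaths/min.
#' @param depth Peak inhale flow amplitude.
#' @param duration_s Trace duration, seconds.
#' @param fs Sampling rate, Hz (>= 10).
#' @param noise_sd White noise SD added to the flow.
#' @param jitter_sd SD (log scale) of the per-breath period jitter; 0 gives
#'   a strictly periodic trace.
#' @param seed Integer seed.
#' @return Tibble (`time_s`, `flow`) of class `breath_trace`.
#' @export
generate_respiration <- function(pace = 15, depth = 1, duration_s = 60,
                                 fs = 20, noise_sd = 0, jitter_sd = 0.05,
                                 seed = 1) {
  stopifnot(pace > 0, fs >= 10, duration_s > 0, depth > 0)
  nominal <- 60 / pace
  with_seed(seed, {
    starts <- 0
    while (tail(starts, 1) < duration_s) {
      period <- nominal * if (jitter_sd > 0) rlnorm(1, 0, jitter_sd) else 1
      starts <- c(starts, tail(starts, 1) + period)
    }
    t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
    breath <- findInterval(t, starts)
    u <- (t - starts[breath]) / diff(starts)[breath]
    flow <- depth * sin(2 * pi * u)
    if (noise_sd > 0) flow <- flow + rnorm(length(t), sd = noise_sd)
    structure(tibble(time_s = t, flow = flow),
              class = c("breath_trace", class(tibble())))
  })
}
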