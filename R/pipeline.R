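#' Simulate a cohort and fit the single-subject analysis chain
#'
#' For each subject: simulate the BOLD run from the ground truth, apply
#' the temporal high-pass (and optional spatial smoothing), fit the GLM
#' with the six motion nuisance regressors, and compute the task-vs-rest
#' contrast t map and percent-signal-change map.
#'
#' @param truth A [make_ground_truth()] object.
#' @param timeline A `bold_timeline`.
#' @param noise A [noise_params()] object.
#' @param n_subjects Cohort size.
#' @param seed Cohort seed.
#' @param highpass_cycles Drift harmonics removed before fitting.
#' @param fwhm Spatial smoothing FWHM, mm (0 = none; voxelwise
#'   ground-truth comparisons assume 0 so labels stay aligned).
#' @param respond_to Condition carrying the simulated response.
#' @param use_motion Include the six motion nuisance columns.
#' @return List with `t_maps`, `psc_maps` (per-subject [stat_map()]s) and
#'   `df` (single-subject residual df).
#' @export
fit_simulated_cohort <- function(truth, timeline, noise, n_subjects = 23,
                                 seed = noise$seed, highpass_cycles = 2,
                                 fwhm = 0,
                                 respond_to = task_conditions(timeline)[1],
                                 use_motion = TRUE) {
  t_maps <- vector("list", n_subjects)
  psc_maps <- vector("list", n_subjects)
  df <- NA_integer_
  for (i in seq_len(n_subjects)) {
    sim <- generate_subject_bold(truth, timeline, noise,
                                 subject = sprintf("s%02d", i),
                                 respond_to = respond_to,
                                 seed = child_seed(seed, i))
    run <- sim$run
    if (highpass_cycles >= 1) run <- highpass_fourier(run, highpass_cycles)
    if (fwhm > 0) run <- smooth_gaussian(run, fwhm)
    design <- build_design_matrix(timeline,
                                  motion = if (use_motion) sim$motion)
    fit <- fit_subject_glm(run, design,
                           exclude = motion_exclusions(sim$motion))
    t_maps[[i]] <- contrast_t(fit, respond_to)
    psc_maps[[i]] <- contrast_psc(fit, respond_to)
    df <- fit$df
  }
  names(t_maps) <- names(psc_maps) <- sprintf("s%02d", seq_len(n_subjects))
  list(t_maps = t_maps, psc_maps = psc_maps, df = df)
}

#' Compare response regimes on synthetic cohorts
#'
#' Runs the full single-subject chain on one cohort per regime (same
#' subjects, different ground truth — e.g. a deactivation-only "gating"
#' run versus a balanced "antagonistic" run), then summarises
#' significant-voxel counts and antagonism indices and performs the
#' paired tests, treating regimes as tasks.
#'
#' @param regimes Character vector of regimes (see
#'   [make_ground_truth()]).
#' @param n_subjects Cohort size.
#' @param grid Grid dimensions, voxels.
#' @param timeline A `bold_timeline` (default the repetitive-speech
#'   protocol).
#' @param noise A [noise_params()]; defaults to the standard noise model
#'   seeded from `seed`.
#' @param fractions,amplitudes Ground-truth responder fractions and
#'   amplitudes (percent signal change).
#' @param t_crit Significance criterion for voxel counting.
#' @param highpass_cycles,fwhm Preprocessing applied before the GLM.
#' @param seed Master seed.
#' @return List: `summary` (a [distribution_summary()] with one "task"
#'   per regime), `t_maps` (named by regime), `group_maps` (random-effects
#'   [stat_map()]s per regime), `truths`, `subject_df`.
#' @export
run_regime_comparison <- function(regimes = c("gating", "antagonistic"),
                                  n_subjects = 23, grid = c(20, 20, 20),
                                  timeline = timeline_rs(seed = seed),
                                  noise = NULL,
                                  fractions = c(pos = 0.1, neg = 0.1),
                                  amplitudes = c(pos = 1, neg = -1),
                                  t_crit = 2.819, highpass_cycles = 2,
                                  fwhm = 0, seed = 1) {
  if (is.null(noise)) noise <- noise_params(seed = seed)
  truths <- list()
  t_maps <- list()
  group_maps <- list()
  subject_df <- NA_integer_
  for (k in seq_along(regimes)) {
    rg <- regimes[k]
    truth <- make_ground_truth(rg, grid = grid, fractions = fractions,
                               amplitudes = amplitudes,
                               seed = child_seed(seed, 1000 + k))
    fits <- fit_simulated_cohort(truth, timeline, noise, n_subjects,
                                 seed = child_seed(seed, 2000 + k),
                                 highpass_cycles = highpass_cycles,
                                 fwhm = fwhm)
    truths[[rg]] <- truth
    t_maps[[rg]] <- fits$t_maps
    group_maps[[rg]] <- group_random_effects(fits$t_maps)
    subject_df <- fits$df
  }
  summary <- distribution_summary(t_maps, t_crit = t_crit)
  list(summary = summary, t_maps = t_maps, group_maps = group_maps,
       truths = truths, subject_df = subject_df)
}

#' Voxelwise recovery of ground truth by the group analysis
#'
#' Simulates a cohort from one ground truth, computes the random-effects
#' group t map of the task-vs-rest contrast, classifies voxels two-tailed
#' at `alpha`, and scores the classification against the truth labels:
#' sensitivity on responders of each sign (detected with the correct
#' sign) and the false-positive rate on null voxels.
#'
#' @inheritParams fit_simulated_cohort
#' @param alpha Two-tailed voxel alpha for the group map.
#' @return One-row tibble: `sensitivity_neg`, `sensitivity_pos` (NA if no
#'   voxels of that sign), `fpr`, `t_crit_group`, `n_subjects`.
#' @export
evaluate_recovery <- function(truth, timeline, noise, n_subjects = 23,
                              seed = noise$seed, alpha = 0.01,
                              highpass_cycles = 2, fwhm = 0) {
  fits <- fit_simulated_cohort(truth, timeline, noise, n_subjects,
                               seed = seed,
                               highpass_cycles = highpass_cycles,
                               fwhm = fwhm)
  gmap <- group_random_effects(fits$t_maps)
  tc <- critical_t(gmap$df, alpha, tails = 2)
  v <- gmap$values
  lab <- truth$labels
  sens <- function(sign) {
    n <- sum(lab == sign)
    if (n == 0) return(NA_real_)
    sum(sign * v[lab == sign] > tc) / n
  }
  fpr <- sum(abs(v[lab == 0L]) > tc) / sum(lab == 0L)
  tibble(sensitivity_neg = sens(-1L), sensitivity_pos = sens(1L),
         fpr = fpr, t_crit_group = tc, n_subjects = n_subjects)
}
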