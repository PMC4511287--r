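test_that("ground-truth labels honour fractions, regimes and determinism", {
  gt <- make_ground_truth("antagonistic", grid = c(10, 10, 10),
                          fractions = c(pos = 0.1, neg = 0.1), seed = 1)
  expect_equal(sum(gt$labels == 1), 100)
  expect_equal(sum(gt$labels == -1), 100)
  expect_equal(glance(gt)$ideal_antagonism, 0)
  expect_true(all(gt$amplitude[gt$labels == 1] > 0))
  expect_true(all(gt$amplitude[gt$labels == -1] < 0))
  expect_true(all(gt$amplitude[gt$labels == 0] == 0))
  expect_false(any(gt$regions[["language-like"]] & gt$regions[["DMN-like"]]))

  gate <- make_ground_truth("gating", grid = c(10, 10, 10),
                            fractions = c(pos = 0.3, neg = 0.2), seed = 1)
  expect_equal(sum(gate$labels == 1), 0)
  expect_equal(glance(gate)$ideal_antagonism, -1)

  expect_identical(make_ground_truth(seed = 9)$labels,
                   make_ground_truth(seed = 9)$labels)
  expect_error(make_ground_truth(fractions = c(pos = 0.6, neg = 0.6)),
               "fractions")
})

test_that("simulated runs are pure functions of the seed", {
  tl <- build_timeline(c("a", "b"), n_blocks = 2, seed = 1)
  gt <- make_ground_truth("gating", grid = c(6, 6, 6), seed = 2)
  np <- noise_params(seed = 3)
  s1 <- generate_subject_bold(gt, tl, np)
  s2 <- generate_subject_bold(gt, tl, np)
  expect_identical(s1$run$data, s2$run$data)
  expect_identical(s1$motion, s2$motion)
  s3 <- generate_subject_bold(gt, tl, np, seed = 4)
  expect_false(identical(s1$run$data, s3$run$data))
  expect_error(noise_params(seed = NA), "seed")
})

test_that("noiseless simulation is inverted exactly by the GLM", {
  tl <- build_timeline(c("a", "b"), n_blocks = 2, seed = 1)
  gt <- make_ground_truth("antagonistic", grid = c(6, 6, 6),
                          amplitudes = c(pos = 1.5, neg = -0.7), seed = 2)
  np <- noise_params(white_sd = 0, drift_amplitude = 0,
                     motion_amplitude = 0, seed = 3)
  sim <- generate_subject_bold(gt, tl, np, baseline = 100)
  fit <- fit_subject_glm(sim$run, build_design_matrix(tl))
  psc <- contrast_psc(fit, "a")
  expect_equal(as.vector(psc$values), as.vector(gt$amplitude),
               tolerance = 1e-8)
})

test_that("AR(1) = 0 noise has no residual lag-1 autocorrelation", {
  tl <- timeline_rs(seed = 1)
  gt <- make_ground_truth("antagonistic", grid = c(10, 10, 10),
                          fractions = c(pos = 0, neg = 0), seed = 2)
  np <- noise_params(ar1 = 0, drift_amplitude = 0, motion_amplitude = 0,
                     seed = 5)
  sim <- generate_subject_bold(gt, tl, np, baseline = 0)
  m <- matrix(sim$run$data, nrow = 1000)  # voxels x time
  r <- cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
  expect_lt(abs(r), 0.05)
})

test_that("questionnaire tables are well-formed, seeded and bounded", {
  q <- generate_questionnaire(n_subjects = 12, seed = 1)
  expect_equal(nrow(q), 12 * 17 * 2)
  expect_true(all(q$rating %in% 1:5))
  expect_identical(q, generate_questionnaire(n_subjects = 12, seed = 1))

  expect_equal(nrow(generate_questionnaire(n_subjects = 0, seed = 1)), 0)
  expect_error(
    generate_questionnaire(correlation = c(Rest = 0.9, RS = 0), seed = 1),
    "positive definite")
  expect_error(
    generate_questionnaire(condition_effects = list(
      Rest = c(Thoughts = 0, Sensations = 0, other = 0),
      RS = c(Thoughts = -3, Sensations = 0, other = 0)), seed = 1),
    "within")
})

test_that("respiration traces obey the closed forms of the half-sine", {
  # strictly periodic: period 4 s, amplitude 2
  tr <- generate_respiration(pace = 15, depth = 2, duration_s = 60,
                             fs = 50, noise_sd = 0, jitter_sd = 0, seed = 1)
  bp <- extract_breath_params(tr)
  expect_equal(bp$pace, 15, tolerance = 0.01)
  expect_equal(bp$inhale_duration, 2, tolerance = 0.01)
  expect_equal(bp$inhale_peak, 2, tolerance = 0.01)
  expect_equal(bp$inhale_mean, 2 * 2 / pi, tolerance = 0.01)
  # inhale integral of a half-sine of amplitude A, period T is A*T/pi;
  # cross-checked against numeric quadrature
  quad <- integrate(function(t) 2 * sin(2 * pi * t / 4), 0, 2)$value
  expect_equal(quad, 2 * 4 / pi, tolerance = 1e-6)
  expect_equal(bp$inhale_integral, quad, tolerance = 0.01 * quad)
})

test_that("breath extraction recovers the pace across jitter levels", {
  for (j in c(0, 0.05, 0.1)) {
    tr <- generate_respiration(pace = 12, duration_s = 120, fs = 20,
                               noise_sd = 0.05, jitter_sd = j, seed = 7)
    bp <- extract_breath_params(tr)
    expect_lt(abs(bp$pace - 12) / 12, 0.05)
  }
})
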