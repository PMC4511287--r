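test_that("study timelines reproduce the protocol arithmetic", {
  rs <- timeline_rs(seed = 1)
  expect_equal(timeline_duration(rs), 8.25 * 60)
  expect_equal(n_rest_epochs(rs), 15)
  expect_equal(n_volumes(rs), 165)

  vf <- timeline_vf(seed = 1)
  expect_equal(timeline_duration(vf), 11 * 60)
  expect_equal(n_rest_epochs(vf), 20)
})

test_that("timeline totals match the closed-form block arithmetic", {
  set.seed(42)
  for (i in 1:20) {
    nc <- sample(1:5, 1)
    nb <- sample(1:6, 1)
    tr <- sample(c(1, 2, 3), 1)
    block <- tr * sample(3:9, 1)
    rest <- tr * sample(2:6, 1)
    tl <- build_timeline(letters[seq_len(nc)], n_blocks = nb,
                         block_s = block, rest_s = rest, tr_s = tr,
                         seed = i)
    expect_equal(timeline_duration(tl), nc * nb * (block + rest))
    expect_equal(n_rest_epochs(tl), nc * nb)
    # every task epoch followed by a rest epoch
    task_rows <- which(tl$condition != "Rest")
    expect_true(all(tl$condition[task_rows + 1] == "Rest"))
    # non-overlapping, sorted
    expect_true(all(diff(tl$onset) > 0))
    expect_true(all(tl$onset + tl$duration <= timeline_duration(tl) + 1e-9))
  }
})

test_that("degenerate and invalid timeline specs are handled", {
  empty <- build_timeline(character(0))
  expect_equal(nrow(empty), 0)
  expect_equal(timeline_duration(empty), 0)

  expect_error(build_timeline("a", block_s = -1), "positive")
  expect_error(build_timeline(c("a", "a")), "duplicated")
  expect_error(build_timeline(c("a", "b"), order = c("a", "a")), "order")
})

test_that("block order is reproducible from the seed and overridable", {
  expect_identical(build_timeline(c("a", "b"), seed = 7),
                   build_timeline(c("a", "b"), seed = 7))
  fixed <- build_timeline(c("a", "b"), n_blocks = 1,
                          order = c("b", "a"))
  expect_equal(fixed$condition[fixed$condition != "Rest"], c("b", "a"))
})

test_that("impulse HRF with zero lag returns the TR-sampled boxcar", {
  tl <- build_timeline(c("a", "b"), n_blocks = 2, seed = 3)
  reg <- make_regressor(tl, "a", hrf_params(lag_s = 0, type = "impulse"))
  t_vol <- (seq_len(n_volumes(tl)) - 1) * 3
  expected <- rep(0, n_volumes(tl))
  for (i in which(tl$condition == "a")) {
    expected[t_vol >= tl$onset[i] & t_vol < tl$onset[i] + tl$duration[i]] <- 1
  }
  expect_equal(reg, expected)
  expect_error(make_regressor(tl, "nope"), "not present")
})

test_that("regressor matches a direct-summation convolution oracle", {
  tl <- build_timeline("a", n_blocks = 1, seed = 1)
  hrf <- hrf_params()
  dt <- 0.1
  reg <- make_regressor(tl, "a", hrf, normalize = FALSE, dt = dt)

  t_fine <- seq(0, timeline_duration(tl) + 32, by = dt)
  box <- as.numeric(t_fine >= tl$onset[1] + hrf$lag_s &
                      t_fine < tl$onset[1] + hrf$lag_s + tl$duration[1])
  h <- hrf_kernel(hrf, seq(0, 32, by = dt))
  t_vol <- (seq_len(n_volumes(tl)) - 1) * 3
  oracle <- vapply(round(t_vol / dt) + 1, function(i) {
    js <- seq_len(min(i, length(h)))
    sum(box[i - js + 1] * h[js]) * dt
  }, numeric(1))
  expect_equal(reg, oracle, tolerance = 1e-10)
})

test_that("unnormalised regressors are linear in the block structure", {
  both <- epochs_timeline(data.frame(
    condition = c("a", "Rest", "b", "Rest", "a", "Rest"),
    onset = c(0, 21, 33, 54, 66, 87),
    duration = c(21, 12, 21, 12, 21, 12)))
  first <- epochs_timeline(data.frame(
    condition = c("a", "Rest", "b", "Rest", "x", "Rest"),
    onset = c(0, 21, 33, 54, 66, 87),
    duration = c(21, 12, 21, 12, 21, 12)))
  second <- epochs_timeline(data.frame(
    condition = c("x", "Rest", "b", "Rest", "a", "Rest"),
    onset = c(0, 21, 33, 54, 66, 87),
    duration = c(21, 12, 21, 12, 21, 12)))
  r_both <- make_regressor(both, "a", normalize = FALSE)
  r_1 <- make_regressor(first, "a", normalize = FALSE)
  r_2 <- make_regressor(second, "a", normalize = FALSE)
  expect_equal(r_both, r_1 + r_2, tolerance = 1e-12)
})

test_that("design matrix has the documented column structure", {
  tl <- timeline_rs(seed = 1)
  motion <- matrix(rnorm(n_volumes(tl) * 6, sd = 0.05), ncol = 6)
  with_motion <- build_design_matrix(tl, motion = motion)
  expect_equal(ncol(with_motion$matrix), 3 + 6 + 1)
  expect_equal(qr(with_motion$matrix)$rank, 10)

  no_motion <- build_design_matrix(tl)
  expect_equal(ncol(no_motion$matrix), 3 + 1)
  expect_false("Rest" %in% no_motion$labels)

  expect_error(build_design_matrix(tl, conditions = c("RS", "RS")),
               "duplicated")
  expect_error(build_design_matrix(tl, motion = motion[-1, ]), "6")
})

test_that("collinear designs fail naming the offending columns", {
  tl <- timeline_rs(seed = 1)
  reg <- make_regressor(tl, "RS")
  motion <- cbind(reg, matrix(rnorm(n_volumes(tl) * 5, sd = 0.05), ncol = 5))
  expect_error(build_design_matrix(tl, motion = motion), "collinear")
})

test_that("designs are bit-reproducible and tidy to long format", {
  tl <- timeline_rs(seed = 5)
  d1 <- build_design_matrix(tl)
  d2 <- build_design_matrix(tl)
  expect_identical(d1$matrix, d2$matrix)

  long <- tidy(d1)
  expect_equal(nrow(long), nrow(d1$matrix) * ncol(d1$matrix))
  expect_setequal(unique(long$regressor), d1$labels)
})

test_that("event files round-trip the timeline", {
  tl <- timeline_rs(seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(tl, path)
  back <- read_events(path, tr_s = 3)
  expect_equal(back$condition, tl$condition)
  expect_equal(back$onset, tl$onset)
  expect_equal(n_volumes(back), n_volumes(tl))
})
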