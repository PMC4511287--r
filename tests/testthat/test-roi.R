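# independent nearest-first region grower: full rescans, explicit adjacency
oracle_roi <- function(map, p_thresh, cap_mm3) {
  d <- dim(map$values)
  vox_mm3 <- prod(map$voxel_mm)
  p <- 2 * pt(-abs(map$values), map$df)
  sup <- which(p < p_thresh & map$mask)
  peak <- sup[which.max(abs(map$values[sup]))]
  members <- peak
  repeat {
    if (length(members) * vox_mm3 + vox_mm3 > cap_mm3) break
    rest <- setdiff(sup, members)
    if (!length(rest)) break
    mc <- arrayInd(members, d)
    pk <- arrayInd(peak, d)
    best <- NA
    best_key <- c(Inf, Inf)
    for (v in rest) {
      cv <- arrayInd(v, d)
      adj <- any(apply(mc, 1, function(m) all(abs(m - cv) <= 1)))
      if (!adj) next
      key <- c(sum((cv - pk)^2), v)
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best <- v
        best_key <- key
      }
    }
    if (is.na(best)) break
    members <- c(members, best)
  }
  sort(members)
}

test_that("ROI growth is capped, seeded at the peak and deterministic", {
  vals <- array(0, c(6, 6, 6))
  vals[3, 3, 3] <- 8
  one <- stat_map(vals, kind = "t", df = 20)
  roi1 <- define_roi(one)
  expect_equal(roi1$members, which(vals == 8))
  expect_equal(roi1$volume_mm3, 27)

  vals2 <- array(6, c(6, 6, 6))  # everything suprathreshold
  big <- define_roi(stat_map(vals2, kind = "t", df = 20))
  expect_lte(length(big$members), 37)  # floor(1000 / 27)
  expect_equal(length(big$members), 37)

  expect_identical(define_roi(one)$members, define_roi(one)$members)
  expect_error(define_roi(stat_map(array(0, c(4, 4, 4)), kind = "t", df = 20)),
               "suprathreshold")
})

test_that("ROI membership matches the exhaustive nearest-first oracle", {
  set.seed(12)
  for (i in 1:4) {
    vals <- array(rnorm(7^3, sd = 2.2), c(7, 7, 7))
    m <- stat_map(vals, kind = "t", df = 25)
    got <- define_roi(m, p_thresh = 0.05, volume_cap_mm3 = 500)
    want <- oracle_roi(m, p_thresh = 0.05, cap_mm3 = 500)
    expect_identical(got$members, want)
  }
})

test_that("time courses convert to percent change and recover plateaus", {
  tl <- build_timeline("a", n_blocks = 3, seed = 1)
  grid <- c(4, 4, 4)
  reg <- make_regressor(tl, "a", hrf_params(lag_s = 0, type = "impulse"))
  amp <- 2.4
  series <- 100 * (1 + amp / 100 * reg)
  run <- bold_run(array(rep(series, each = prod(grid)), c(grid, length(series))),
                  tr_s = 3)
  vals <- array(0, grid)
  vals[2, 2, 2] <- 10
  roi <- define_roi(stat_map(vals, kind = "t", df = 20))

  flat <- bold_run(array(50, c(grid, n_volumes(tl))), tr_s = 3)
  f <- extract_roi_timecourse(flat, roi, tl, "a")
  expect_true(all(abs(f$mean) < 1e-12))

  crs <- extract_roi_timecourse(run, roi, tl, "a")
  expect_equal(plateau_response(crs, window_s = c(6, 18)), amp,
               tolerance = 1e-10)
  # pre-onset baseline window is zero by construction
  expect_true(all(abs(crs$mean[crs$time_s < 0]) < 1e-10))

  # negating the response negates the plateau
  series_n <- 100 * (1 - amp / 100 * reg)
  run_n <- bold_run(array(rep(series_n, each = prod(grid)),
                          c(grid, length(series_n))), tr_s = 3)
  crs_n <- extract_roi_timecourse(run_n, roi, tl, "a")
  expect_equal(plateau_response(crs_n, window_s = c(6, 18)), -amp,
               tolerance = 1e-10)
})

test_that("block response tests follow the one-sample t with Bonferroni", {
  expect_equal(block_response_test(rep(0, 8))$t, 0)
  expect_equal(block_response_test(rep(0, 8))$p, 1)

  set.seed(13)
  x <- rnorm(23, mean = -0.4)
  got <- block_response_test(x, families = 4)
  tt <- mean(x) / (sd(x) / sqrt(23))
  expect_equal(got$t, tt, tolerance = 1e-10)
  expect_equal(got$p_bonferroni, min(1, got$p * 4))
  expect_equal(block_response_test(-x, families = 4)$t, -got$t,
               tolerance = 1e-12)
  # p = 0.01 with family 4 corrects to 0.04 by definition
  expect_equal(min(1, 0.01 * 4), 0.04)
})

test_that("noisy plateau estimates cover the truth across subjects", {
  tl <- build_timeline("a", n_blocks = 5, seed = 2)
  grid <- c(4, 4, 4)
  reg <- make_regressor(tl, "a", hrf_params(lag_s = 0, type = "impulse"))
  vals <- array(10, grid)
  roi <- define_roi(stat_map(vals, kind = "t", df = 20),
                    volume_cap_mm3 = 27 * 64)
  amp <- -1.5
  set.seed(14)
  plateaus <- vapply(1:23, function(i) {
    series <- 100 * (1 + amp / 100 * reg)
    noisy <- rep(series, each = prod(grid)) +
      rnorm(prod(grid) * length(series), sd = 1)
    run <- bold_run(array(noisy, c(grid, length(series))), tr_s = 3)
    plateau_response(extract_roi_timecourse(run, roi, tl, "a"),
                     window_s = c(6, 18))
  }, numeric(1))
  ci <- mean(plateaus) + c(-2, 2) * sd(plateaus) / sqrt(23)
  expect_gte(amp, ci[1])
  expect_lte(amp, ci[2])
})
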