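# build a small random design wrapped as bold_design
random_design <- function(n, p_task = 2, seed = 1) {
  set.seed(seed)
  X <- cbind(matrix(rnorm(n * p_task), n), 1)
  colnames(X) <- c(paste0("task", seq_len(p_task)), "(Intercept)")
  structure(list(matrix = X, labels = colnames(X),
                 task_columns = colnames(X)[seq_len(p_task)],
                 hrf = hrf_params(), tr_s = 3),
            class = "bold_design")
}

test_that("subject GLM and contrast t match the normal-equations oracle", {
  des <- random_design(24, p_task = 3, seed = 5)
  set.seed(6)
  Y <- matrix(rnorm(24 * 20), 24, 20)
  fit <- fit_subject_glm(matrix_run(Y), des)
  w <- c(1, -1, 0, 0)
  tmap <- contrast_t(fit, w)
  for (v in c(1, 7, 20)) {
    orc <- oracle_ols(des$matrix, Y[, v], w)
    expect_equal(unname(fit$betas[, v]), orc$beta, tolerance = 1e-8)
    expect_equal(tmap$values[v, 1, 1], orc$t, tolerance = 1e-8)
    expect_equal(fit$df, orc$df)
  }
})

test_that("volume exclusion adjusts the degrees of freedom exactly", {
  des <- random_design(30, seed = 2)
  Y <- matrix(rnorm(30 * 5), 30, 5)
  full <- fit_subject_glm(matrix_run(Y), des)
  part <- fit_subject_glm(matrix_run(Y), des, exclude = c(3, 9, 10, 21))
  expect_equal(part$df, full$df - 4)
  expect_error(fit_subject_glm(matrix_run(Y), des, exclude = 31),
               "range")
  # oracle on the kept rows
  keep <- setdiff(1:30, c(3, 9, 10, 21))
  orc <- oracle_ols(des$matrix[keep, ], Y[keep, 2], c(1, 0, 0))
  expect_equal(unname(part$betas[, 2]), orc$beta, tolerance = 1e-8)
})

test_that("motion exclusion applies the 1-mm displacement rule", {
  motion <- matrix(0, 20, 6)
  motion[7, 1] <- 1.4
  motion[13, 3] <- -1.2
  motion[15, 2] <- 0.8
  expect_equal(motion_exclusions(motion), c(7L, 13L))
  expect_length(motion_exclusions(motion, threshold_mm = 2), 0)
})

test_that("contrasts are antisymmetric and validated", {
  des <- random_design(24, seed = 3)
  Y <- matrix(rnorm(24 * 6), 24)
  fit <- fit_subject_glm(matrix_run(Y), des)
  up <- contrast_t(fit, c(1, 0, 0))
  down <- contrast_t(fit, c(-1, 0, 0))
  expect_equal(down$values, -up$values)
  expect_error(contrast_t(fit, c(0, 0, 0)), "all-zero")
  expect_error(contrast_t(fit, "nope"), "unknown")
  expect_error(contrast_t(fit, c(1, 0)), "length")
})

test_that("a zero-variance voxel keeps its beta but flags t undefined", {
  des <- random_design(24, seed = 4)
  Y <- matrix(rnorm(24 * 3), 24)
  Y[, 2] <- des$matrix %*% c(2, -1, 5)  # exact fit, zero residual
  fit <- fit_subject_glm(matrix_run(Y), des)
  expect_equal(unname(fit$betas[, 2]), c(2, -1, 5), tolerance = 1e-10)
  tmap <- contrast_t(fit, "task1")
  expect_true(is.nan(tmap$values[2, 1, 1]))
  expect_false(anyNA(tmap$values[c(1, 3), 1, 1]))
})

test_that("task betas are immune to an orthogonal nuisance regressor", {
  des <- random_design(40, p_task = 2, seed = 8)
  X <- des$matrix
  set.seed(9)
  extra <- rnorm(40)
  extra <- extra - X %*% solve(crossprod(X), crossprod(X, extra))  # orthogonalise
  des2 <- des
  des2$matrix <- cbind(X[, 1:2], nuisance = drop(extra), X[, 3, drop = FALSE])
  des2$labels <- colnames(des2$matrix)
  Y <- matrix(rnorm(40 * 8), 40)
  f1 <- fit_subject_glm(matrix_run(Y), des)
  f2 <- fit_subject_glm(matrix_run(Y), des2)
  expect_equal(f1$betas["task1", ], f2$betas["task1", ], tolerance = 1e-8)
})

test_that("a null contrast over pure noise has mean t near zero", {
  tl <- build_timeline(c("a", "b"), n_blocks = 2, seed = 1)
  des <- build_design_matrix(tl)
  set.seed(10)
  n_vox <- 4000
  Y <- matrix(rnorm(n_volumes(tl) * n_vox), n_volumes(tl))
  fit <- fit_subject_glm(matrix_run(Y), des)
  tmap <- contrast_t(fit, "a")
  se <- sd(tmap$values) / sqrt(n_vox)
  expect_lt(abs(mean(tmap$values)), 3 * se + 1e-12)
})

test_that("group random effects match the one-sample t oracle", {
  set.seed(11)
  Y <- matrix(rnorm(23 * 50), 23)
  g <- group_random_effects(Y)
  expect_equal(g$df, 22)
  for (v in c(1, 25, 50)) {
    tt <- t.test(Y[, v])
    expect_equal(g$values[v, 1, 1], unname(tt$statistic), tolerance = 1e-10)
  }
  # symmetric subject values give t = 0
  sym <- matrix(c(-2, -1, 1, 2), ncol = 1)
  expect_equal(group_random_effects(sym)$values[1, 1, 1], 0)
  # negating every subject negates the map
  expect_equal(group_random_effects(-Y)$values, -g$values)
  expect_error(group_random_effects(Y[1, , drop = FALSE]), "2 subjects")
})

test_that("degenerate group voxels yield the infinite sentinel", {
  Y <- matrix(1, 5, 2)
  Y[, 2] <- 0
  expect_warning(g <- group_random_effects(Y), "zero between-subject")
  expect_equal(g$values[1, 1, 1], Inf)
  expect_equal(g$values[2, 1, 1], 0)
})

test_that("OLS oracle equivalence holds across random small designs", {
  worst <- 0
  for (i in 1:25) {
    set.seed(100 + i)
    n <- sample(15:40, 1)
    p <- sample(2:4, 1)
    des <- random_design(n, p_task = p, seed = 200 + i)
    Y <- matrix(rnorm(n * 6), n)
    w <- numeric(p + 1)
    w[sample(p, 1)] <- 1
    fit <- fit_subject_glm(matrix_run(Y), des)
    tmap <- contrast_t(fit, w)
    for (v in 1:6) {
      orc <- oracle_ols(des$matrix, Y[, v], w)
      worst <- max(worst, abs(tmap$values[v, 1, 1] - orc$t))
    }
  }
  expect_lt(worst, 1e-6)
})
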