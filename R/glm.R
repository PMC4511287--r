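#' Volumes to exclude for movement artifacts
#'
#' Applies the 1-mm displacement rule to a precomputed motion trace: a
#' volume is excluded when any translational parameter deviates from its
#' run median by more than `threshold_mm`.
#'
#' @param motion Motion matrix (`n_volumes x 6`; columns 1-3 translations
#'   in mm).
#' @param threshold_mm Displacement threshold, mm.
#' @return Integer vector of excluded volume indices (possibly empty).
#' @export
motion_exclusions <- function(motion, threshold_mm = 1) {
  trans <- as.matrix(motion)[, 1:3, drop = FALSE]
  dev <- abs(sweep(trans, 2, apply(trans, 2, stats::median)))
  which(apply(dev, 1, max) > threshold_mm)
}

#' Fit the single-subject GLM
#'
#' Mass-univariate ordinary least squares of every voxel time series on
#' the design matrix, over the non-excluded volumes. Serial correlation is
#' not modelled (plain OLS); degrees of freedom are
#' `n_used - rank(design)`.
#'
#' @param run A [bold_run()].
#' @param design A [build_design_matrix()] object with
#'   `n_volumes` rows.
#' @param exclude Integer volume indices to drop (e.g. from
#'   [motion_exclusions()]).
#' @return A `subject_fit`: per-voxel coefficients and residual variance,
#'   plus the design bookkeeping needed for contrasts.
#' @export
fit_subject_glm <- function(run, design, exclude = integer(0)) {
  stopifnot(inherits(run, "bold_run"), inherits(design, "bold_design"))
  X <- design$matrix
  Y <- run_matrix(run)
  if (nrow(X) != nrow(Y)) {
    abort(sprintf("design has %d rows but the run has %d volumes",
                  nrow(X), nrow(Y)))
  }
  exclude <- sort(unique(as.integer(exclude)))
  if (length(exclude) && (min(exclude) < 1 || max(exclude) > nrow(X))) {
    abort("excluded volumes out of range")
  }
  keep <- setdiff(seq_len(nrow(X)), exclude)
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  qrX <- qr(X)
  rank <- qrX$rank
  df <- nrow(X) - rank
  if (df <= 0) abort("non-positive residual degrees of freedom")
  if (rank < ncol(X)) abort("design matrix rank deficient after exclusion")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  betas <- xtx_inv %*% crossprod(X, Y)
  resid <- Y - X %*% betas
  sigma2 <- colSums(resid^2) / df
  # a voxel is flagged constant/perfectly-fit when its residual variance is
  # numerically indistinguishable from 0 at the data's scale
  zero_var <- sigma2 <= 1e-24 * (colMeans(Y^2) + .Machine$double.xmin)
  rownames(betas) <- colnames(design$matrix)
  structure(
    list(betas = betas, sigma2 = sigma2, zero_var = zero_var,
         xtx_inv = xtx_inv,
         design = design, df = df, excluded = exclude,
         grid = dim(run$data)[1:3], voxel_mm = run$voxel_mm,
         mask = run$mask, subject = run$subject),
    class = "subject_fit"
  )
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf("<subject_fit> subject %s: %d regressors x %d voxels, df %d, %d volumes excluded\n",
              x$subject, nrow(x$betas), ncol(x$betas), x$df,
              length(x$excluded)))
  invisible(x)
}

#' @describeIn fit_subject_glm Per-term summary of the voxelwise
#'   coefficients.
#' @param x A `subject_fit`.
#' @param ... Unused.
#' @method tidy subject_fit
#' @export
tidy.subject_fit <- function(x, ...) {
  tibble(term = rownames(x$betas),
         mean_estimate = rowMeans(x$betas),
         sd_estimate = apply(x$betas, 1, sd))
}

#' @describeIn fit_subject_glm One-row fit summary.
#' @method glance subject_fit
#' @export
glance.subject_fit <- function(x, ...) {
  tibble(subject = x$subject, n_voxels = ncol(x$betas),
         n_regressors = nrow(x$betas), df = x$df,
         n_excluded = length(x$excluded),
         mean_sigma2 = mean(x$sigma2))
}

# resolve a contrast given as weights or as a task-column name
resolve_contrast <- function(fit, contrast) {
  labels <- rownames(fit$betas)
  if (is.character(contrast) && length(contrast) == 1) {
    if (!contrast %in% labels) {
      abort(sprintf("unknown design column '%s'", contrast))
    }
    w <- setNames(numeric(length(labels)), labels)
    w[contrast] <- 1
    return(w)
  }
  if (length(contrast) != length(labels)) {
    abort(sprintf("contrast length %d != %d design columns",
                  length(contrast), length(labels)))
  }
  setNames(as.numeric(contrast), labels)
}

#' Contrast t map for one subject
#'
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)`. A single task-column name is
#' shorthand for the unit contrast on that column, i.e. that condition
#' versus the pooled rest baseline absorbed by the intercept. Voxels with
#' zero residual variance get an undefined (`NaN`) t.
#'
#' @param fit A [fit_subject_glm()] result.
#' @param contrast Numeric weight vector over design columns, or one task
#'   column name.
#' @return A [stat_map()] of kind `"t"`.
#' @export
contrast_t <- function(fit, contrast) {
  w <- resolve_contrast(fit, contrast)
  if (all(w == 0)) abort("all-zero contrast")
  num <- drop(crossprod(w, fit$betas))
  cvc <- drop(t(w) %*% fit$xtx_inv %*% w)
  tval <- num / sqrt(fit$sigma2 * cvc)
  tval[fit$zero_var] <- NaN
  stat_map(array(tval, fit$grid), kind = "t", df = fit$df,
           contrast = w, mask = fit$mask, voxel_mm = fit$voxel_mm)
}

#' Contrast effect size in percent signal change
#'
#' Converts a task coefficient to percent signal change relative to the
#' intercept (the pooled rest baseline level).
#'
#' @inheritParams contrast_t
#' @return A [stat_map()] of kind `"beta"` holding percent signal change.
#' @export
contrast_psc <- function(fit, contrast) {
  w <- resolve_contrast(fit, contrast)
  num <- drop(crossprod(w, fit$betas))
  base <- fit$betas["(Intercept)", ]
  stat_map(array(100 * num / base, fit$grid), kind = "beta",
           df = NA_real_, contrast = w, mask = fit$mask,
           voxel_mm = fit$voxel_mm)
}

#' Random-effects group map
#'
#' Per voxel, a one-sample t of the subject-level contrast values against
#' zero; with `n` subjects the map has `n - 1` degrees of freedom (23
#' subjects give df 22). Voxels with zero between-subject variance and a
#' non-zero mean are reported as a signed infinite sentinel with a
#' warning.
#'
#' @param subject_maps List (>= 2) of per-subject [stat_map()]s on a
#'   common grid, or a `subjects x voxels` matrix.
#' @param mask Optional mask (required for matrix input; default
#'   intersection of subject masks otherwise).
#' @param voxel_mm Voxel size for matrix input.
#' @param grid Grid dims for matrix input.
#' @return A [stat_map()] of kind `"t"` with `df = n_subjects - 1`.
#' @export
group_random_effects <- function(subject_maps, mask = NULL, voxel_mm = 3,
                                 grid = NULL) {
  if (is.list(subject_maps)) {
    if (length(subject_maps) < 2) abort("need at least 2 subjects")
    grid <- dim(subject_maps[[1]]$values)
    for (m in subject_maps) {
      if (!identical(dim(m$values), grid)) abort("subject maps on different grids")
    }
    if (is.null(mask)) {
      mask <- Reduce(`&`, lapply(subject_maps, `[[`, "mask"))
    }
    voxel_mm <- subject_maps[[1]]$voxel_mm
    Y <- do.call(rbind, lapply(subject_maps, function(m) as.vector(m$values)))
  } else {
    Y <- as.matrix(subject_maps)
    if (nrow(Y) < 2) abort("need at least 2 subjects")
    if (is.null(grid)) grid <- c(ncol(Y), 1L, 1L)
    if (is.null(mask)) mask <- array(TRUE, grid)
  }
  n <- nrow(Y)
  mu <- colMeans(Y)
  s <- sqrt(colSums(sweep(Y, 2, mu)^2) / (n - 1))
  tval <- mu / (s / sqrt(n))
  degenerate <- s == 0 & mu != 0
  if (any(degenerate)) {
    warn(sprintf("%d voxels with zero between-subject variance and non-zero mean; t set to +/-Inf",
                 sum(degenerate)))
    tval[degenerate] <- sign(mu[degenerate]) * Inf
  }
  tval[s == 0 & mu == 0] <- 0
  stat_map(array(tval, grid), kind = "t", df = n - 1,
           contrast = "group one-sample", mask = mask, voxel_mm = voxel_mm)
}
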