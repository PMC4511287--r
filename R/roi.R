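#' Define an ROI around the activity peak of a localizer map
#'
#' Starting from the maximum-|t| suprathreshold voxel, the ROI grows by
#' repeatedly adding the suprathreshold voxel that is adjacent (26
#' neighbourhood) to the current region and closest (Euclidean, in voxel
#' units; ties broken by lexicographic linear index) to the peak, until
#' adding the next voxel would exceed the volume cap. With the default
#' 1000 mm^3 cap and 3-mm voxels an ROI holds at most 37 voxels.
#'
#' @param map A [stat_map()] of kind `"t"` from an independent localizer.
#' @param p_thresh Two-tailed defining p threshold (default 0.02).
#' @param volume_cap_mm3 Maximum ROI volume, mm^3.
#' @return An `roi_definition`: peak voxel, member voxel indices
#'   (linear), volume and parameters.
#' @export
define_roi <- function(map, p_thresh = 0.02, volume_cap_mm3 = 1000) {
  stopifnot(inherits(map, "stat_map"), map$kind == "t")
  d <- dim(map$values)
  vox_mm3 <- prod(map$voxel_mm)
  pvals <- 2 * pt(-abs(map$values), df = map$df)
  supra <- pvals < p_thresh & map$mask & is.finite(map$values)
  if (!any(supra)) abort("no suprathreshold voxel at the defining threshold")
  sup_idx <- which(supra)
  peak <- sup_idx[which.max(abs(map$values[sup_idx]))]
  coords <- arrayInd(sup_idx, d)
  pk <- arrayInd(peak, d)
  d2 <- rowSums(sweep(coords, 2, as.numeric(pk))^2)

  max_n <- floor(volume_cap_mm3 / vox_mm3)
  members <- peak
  cand <- setdiff(sup_idx, peak)
  cand_d2 <- d2[match(cand, sup_idx)]
  adjacent <- function(i, set) {
    ci <- arrayInd(i, d)
    cs <- arrayInd(set, d)
    any(abs(cs[, 1] - ci[1]) <= 1 & abs(cs[, 2] - ci[2]) <= 1 &
          abs(cs[, 3] - ci[3]) <= 1)
  }
  while (length(members) < max_n && length(cand) > 0) {
    ord <- order(cand_d2, cand)
    nxt <- NA_integer_
    for (k in ord) {
      if (adjacent(cand[k], members)) {
        nxt <- k
        break
      }
    }
    if (is.na(nxt)) break
    members <- c(members, cand[nxt])
    cand_d2 <- cand_d2[-nxt]
    cand <- cand[-nxt]
  }
  structure(
    list(peak = peak, members = sort(members),
         volume_mm3 = length(members) * vox_mm3,
         p_thresh = p_thresh, volume_cap_mm3 = volume_cap_mm3,
         grid = d, voxel_mm = map$voxel_mm),
    class = "roi_definition"
  )
}

#' @export
print.roi_definition <- function(x, ...) {
  cat(sprintf("<roi_definition> %d voxels (%g mm^3, cap %g), peak index %d, defining p %g\n",
              length(x$members), x$volume_mm3, x$volume_cap_mm3, x$peak,
              x$p_thresh))
  invisible(x)
}

#' ROI mask as a logical array
#'
#' @param roi An `roi_definition`.
#' @return 3D logical array on the ROI's grid.
#' @export
roi_mask <- function(roi) {
  m <- array(FALSE, roi$grid)
  m[roi$members] <- TRUE
  m
}

#' Block-locked ROI time course in percent signal change
#'
#' The ROI-mean series is converted to percent signal change against the
#' mean of all rest volumes, cut into per-block windows running from the
#' pre-onset rest through the post-offset rest, re-baselined so the
#' pre-onset window mean is 0, and averaged across blocks.
#'
#' @param run A [bold_run()].
#' @param roi An `roi_definition` on the run's grid.
#' @param timeline The run's `bold_timeline`.
#' @param condition Task condition whose blocks are extracted.
#' @param pre_s,post_s Window extent before onset / after offset, seconds.
#' @return An `event_locked_course`: tibble (`time_s`, `mean`, `sd`,
#'   `n_blocks`) with block/cue metadata attributes; `time_s` is relative
#'   to block onset.
#' @export
extract_roi_timecourse <- function(run, roi, timeline, condition,
                                   pre_s = 12, post_s = 12) {
  if (length(roi$members) == 0) abort("empty ROI")
  if (!identical(roi$grid, dim(run$data)[1:3])) {
    abort("ROI grid does not match the run")
  }
  tr <- run$tr_s
  m <- run_matrix(run)[, roi$members, drop = FALSE]
  series <- rowMeans(m)
  rest_label <- attr(timeline, "rest_label")
  t_vol <- (seq_along(series) - 1) * tr
  rest_vols <- rep(FALSE, length(series))
  for (i in which(timeline$condition == rest_label)) {
    rest_vols <- rest_vols |
      (t_vol >= timeline$onset[i] & t_vol < timeline$onset[i] + timeline$duration[i])
  }
  base <- mean(series[rest_vols])
  psc <- 100 * (series - base) / base

  blocks <- timeline[timeline$condition == condition, , drop = FALSE]
  if (nrow(blocks) == 0) abort(sprintf("no '%s' blocks in timeline", condition))
  rel_times <- seq(-floor(pre_s / tr), floor((blocks$duration[1] + post_s) / tr)) * tr
  courses <- matrix(NA_real_, nrow(blocks), length(rel_times))
  for (b in seq_len(nrow(blocks))) {
    vols <- round((blocks$onset[b] + rel_times) / tr) + 1L
    ok <- vols >= 1 & vols <= length(psc)
    w <- psc[vols[ok]]
    pre <- rel_times[ok] < 0
    courses[b, ok] <- w - mean(w[pre])
  }
  out <- tibble(time_s = rel_times,
                mean = colMeans(courses, na.rm = TRUE),
                sd = apply(courses, 2, sd, na.rm = TRUE),
                n_blocks = colSums(!is.na(courses)))
  structure(out,
            class = c("event_locked_course", class(out)),
            condition = condition, block_s = blocks$duration[1],
            cue_s = attr(timeline, "cue_s"), tr_s = tr)
}

#' Mean sustained (plateau) response of a course
#'
#' Mean percent signal change over the plateau window, by default 6-21 s
#' after block onset (skipping the haemodynamic rise).
#'
#' @param course An `event_locked_course`.
#' @param window_s Plateau window `(from, to)` seconds after onset.
#' @return Scalar mean plateau, percent signal change.
#' @export
plateau_response <- function(course, window_s = c(6, 21)) {
  sel <- course$time_s >= window_s[1] & course$time_s <= window_s[2]
  mean(course$mean[sel])
}

#' Test sustained block responses against baseline
#'
#' One-sample t-test of per-subject plateau responses against 0, with a
#' Bonferroni correction over the test family (default 4: two ROIs by two
#' conditions).
#'
#' @param plateaus Per-subject plateau responses (percent signal change).
#' @param families Bonferroni family size.
#' @return One-row tibble (`t`, `p`, `p_bonferroni`, `df`, `mean`).
#' @export
block_response_test <- function(plateaus, families = 4) {
  stopifnot(length(plateaus) >= 2, families >= 1)
  if (sd(plateaus) == 0) {
    if (mean(plateaus) == 0) {
      return(tibble(t = 0, p = 1, p_bonferroni = 1,
                    df = length(plateaus) - 1, mean = 0))
    }
    warn("zero-variance plateaus with non-zero mean; t undefined")
    return(tibble(t = NaN, p = NaN, p_bonferroni = NaN,
                  df = length(plateaus) - 1, mean = mean(plateaus)))
  }
  tt <- t.test(plateaus)
  tibble(t = unname(tt$statistic), p = tt$p.value,
         p_bonferroni = min(1, tt$p.value * families),
         df = unname(tt$parameter), mean = unname(tt$estimate))
}
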