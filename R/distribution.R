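#' Student-t criterion for voxel significance
#'
#' The Student-t quantile with total tail mass `alpha` (split across tails
#' when two-tailed). The shipped default criterion elsewhere in the
#' package is 2.819, which is this quantile at df 22, alpha 0.01,
#' two-tailed; the pairing of the printed criterion with a specific
#' df/alpha is ambiguous in the source analysis, so both knobs are
#' exposed.
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Total tail probability, in (0, 1).
#' @param tails 1 or 2.
#' @return The positive critical value.
#' @examples
#' critical_t(22, 0.01)  # 2.819
#' @export
critical_t <- function(df, alpha, tails = 2) {
  stopifnot(df >= 1, alpha > 0, alpha <= 1, tails %in% c(1, 2))
  qt(1 - alpha / tails, df)
}

#' Histogram of map t-values
#'
#' Per-bin voxel counts of the in-mask t-values, by default on unit-width
#' bins from -6 to 6. With `clip = TRUE` (default) out-of-range values are
#' absorbed by the outermost bins, so the counts always sum to the mask
#' size; otherwise they are dropped and the dropped count reported.
#'
#' @param map A [stat_map()] (or a numeric vector of t-values).
#' @param mask Optional mask overriding the map's own.
#' @param edges Strictly increasing bin edges.
#' @param clip Clip policy (see above).
#' @return Tibble (`bin_lo`, `bin_hi`, `bin_mid`, `count`) with attribute
#'   `dropped`.
#' @export
tvalue_histogram <- function(map, mask = NULL, edges = -6:6, clip = TRUE) {
  if (inherits(map, "stat_map")) {
    if (is.null(mask)) mask <- map$mask
    v <- map$values[mask]
  } else {
    v <- as.numeric(map)
  }
  if (length(v) == 0) abort("empty mask")
  if (any(diff(edges) <= 0)) abort("edges must be strictly increasing")
  nb <- length(edges) - 1L
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  dropped <- 0L
  if (clip) {
    bin[bin < 1L] <- 1L
    bin[bin > nb] <- nb
  } else {
    out <- bin < 1L | bin > nb
    dropped <- sum(out)
    bin <- bin[!out]
  }
  counts <- tabulate(bin, nbins = nb)
  structure(
    tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
           bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
           count = counts),
    dropped = dropped
  )
}

#' Histograms for a cohort of maps
#'
#' @param maps Named list: condition -> list of per-subject [stat_map()]s
#'   (the same subjects in the same order in every condition).
#' @inheritParams tvalue_histogram
#' @return Long tibble (`subject`, `condition`, `bin_mid`, `bin_lo`,
#'   `bin_hi`, `count`), suitable for [average_histograms()].
#' @export
cohort_histograms <- function(maps, edges = -6:6, clip = TRUE) {
  purrr::imap_dfr(maps, function(cond_maps, cond) {
    purrr::imap_dfr(cond_maps, function(m, i) {
      h <- tvalue_histogram(m, edges = edges, clip = clip)
      dplyr::mutate(h,
                    subject = if (is.character(i)) i else sprintf("s%02d", i),
                    condition = cond, .before = 1)
    })
  })
}

#' Average histograms with within-subject error bars
#'
#' Condition means per bin with Cousineau-Morey within-subject SEMs: each
#' subject's counts are recentred per bin (subtract the subject's mean
#' over conditions, add the grand mean), the SEM of the recentred values
#' is taken across subjects, and multiplied by `sqrt(C / (C - 1))` with
#' `C` the number of conditions.
#'
#' @param hists Long tibble as returned by [cohort_histograms()]: columns
#'   `subject`, `condition`, `bin_mid`, `count` (extra columns kept).
#' @return Tibble (`condition`, `bin_mid`, `mean`, `sem`, `n_subjects`) of
#'   class `histogram_summary`.
#' @export
average_histograms <- function(hists) {
  conds <- unique(hists$condition)
  if (length(conds) < 2) {
    abort("within-subject correction undefined with a single condition")
  }
  if (length(unique(hists$subject)) < 2) abort("need at least 2 subjects")
  morey <- sqrt(length(conds) / (length(conds) - 1))
  out <- hists |>
    dplyr::group_by(.data$subject, .data$bin_mid) |>
    dplyr::mutate(subj_mean = mean(.data$count)) |>
    dplyr::group_by(.data$bin_mid) |>
    dplyr::mutate(norm = .data$count - .data$subj_mean + mean(.data$count)) |>
    dplyr::group_by(.data$condition, .data$bin_mid) |>
    dplyr::summarise(mean = mean(.data$count),
                     sem = sd(.data$norm) / sqrt(dplyr::n()) * morey,
                     n_subjects = dplyr::n(), .groups = "drop")
  class(out) <- c("histogram_summary", class(out))
  out
}

#' Count significant voxels of each sign
#'
#' `n_pos = #\{t > t_crit\}`, `n_neg = #\{t < -t_crit\}`; percentages are
#' relative to the mask size.
#'
#' @param map A [stat_map()] or numeric vector of t-values.
#' @param t_crit Positive t criterion (default the printed study criterion
#'   2.819; see [critical_t()]).
#' @param mask Optional mask override.
#' @return One-row tibble (`n_pos`, `n_neg`, `pct_pos`, `pct_neg`,
#'   `n_mask`).
#' @export
count_significant <- function(map, t_crit = 2.819, mask = NULL) {
  stopifnot(t_crit > 0)
  if (inherits(map, "stat_map")) {
    if (is.null(mask)) mask <- map$mask
    v <- map$values[mask]
  } else {
    v <- as.numeric(map)
  }
  n <- length(v)
  n_pos <- sum(v > t_crit, na.rm = TRUE)
  n_neg <- sum(v < -t_crit, na.rm = TRUE)
  tibble(n_pos = n_pos, n_neg = n_neg,
         pct_pos = 100 * n_pos / n, pct_neg = 100 * n_neg / n,
         n_mask = n)
}

#' Antagonism index
#'
#' `(n_pos - n_neg) / (n_pos + n_neg)`: -1 for purely deactivating
#' ("gating") maps, 0 for balanced ("antagonistic", push-pull) maps, +1
#' for purely activating maps. Undefined (NaN, with a warning) when both
#' counts are zero.
#'
#' @param n_pos,n_neg Significant voxel counts (vectorised).
#' @param quiet Suppress the undefined-value warning.
#' @return Numeric in `[-1, 1]`, or NaN where undefined.
#' @examples
#' antagonism_index(30, 10)  # 0.5
#' @export
antagonism_index <- function(n_pos, n_neg, quiet = FALSE) {
  tot <- n_pos + n_neg
  out <- (n_pos - n_neg) / tot
  if (any(tot == 0) && !quiet) {
    warn("antagonism index undefined (no significant voxels of either sign); returning NaN")
  }
  out
}

#' Paired t-test
#'
#' Classic two-tailed paired Student t-test on per-subject differences.
#' All-zero differences give `t = 0, p = 1`; zero-variance non-zero
#' differences give an undefined (`NaN`) sentinel with a warning.
#'
#' @param a,b Paired per-subject values (equal length >= 2, no missing
#'   pairs).
#' @return One-row tibble (`t`, `p`, `df`, `mean_diff`).
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors of unequal length")
  if (length(a) < 2) abort("need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) abort("missing pairs not allowed")
  d <- a - b
  if (sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    if (mean(d) == 0) {
      return(tibble(t = 0, p = 1, df = length(d) - 1, mean_diff = 0))
    }
    warn("zero-variance differences with non-zero mean; t undefined")
    return(tibble(t = NaN, p = NaN, df = length(d) - 1, mean_diff = mean(d)))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' Cohort distribution summary
#'
#' The study's core statistic: per subject and task, significant-voxel
#' counts, percentages and the antagonism index; within each task a
#' paired t-test of positive vs negative percentages; and across each pair
#' of tasks a paired t-test on the antagonism index. Subjects whose index
#' is undefined (no significant voxels of either sign) in a task are
#' dropped pairwise from the tests, with a warning.
#'
#' @param maps Named list: task -> list of per-subject [stat_map()]s, or a
#'   precomputed tibble with columns `subject`, `task`, `n_pos`, `n_neg`,
#'   `pct_pos`, `pct_neg`.
#' @param t_crit Positive t criterion.
#' @return A `distribution_summary`: list with tibbles `subjects`
#'   (per-subject rows including `antagonism`) and `tests` (one row per
#'   test).
#' @export
distribution_summary <- function(maps, t_crit = 2.819) {
  if (is.data.frame(maps)) {
    subjects <- as_tibble(maps)
  } else {
    subjects <- purrr::imap_dfr(maps, function(task_maps, task) {
      purrr::imap_dfr(task_maps, function(m, i) {
        dplyr::mutate(count_significant(m, t_crit),
                      subject = if (is.character(i)) i else sprintf("s%02d", i),
                      task = task, .before = 1)
      })
    })
  }
  subjects$antagonism <- antagonism_index(subjects$n_pos, subjects$n_neg,
                                          quiet = TRUE)
  n_undef <- sum(is.nan(subjects$antagonism))
  if (n_undef > 0) {
    warn(sprintf("%d subject/task rows have an undefined antagonism index and are dropped pairwise from tests",
                 n_undef))
  }
  tasks <- unique(subjects$task)
  tests <- list()
  for (tk in tasks) {
    s <- subjects[subjects$task == tk, ]
    tests[[length(tests) + 1L]] <- dplyr::mutate(
      paired_t_test(s$pct_pos, s$pct_neg),
      test = "pos_vs_neg_pct", task = tk, .before = 1)
  }
  if (length(tasks) >= 2) {
    for (i in seq_len(length(tasks) - 1)) {
      for (j in seq(i + 1, length(tasks))) {
        a <- subjects[subjects$task == tasks[i], c("subject", "antagonism")]
        b <- subjects[subjects$task == tasks[j], c("subject", "antagonism")]
        m <- dplyr::inner_join(a, b, by = "subject", suffix = c("_a", "_b"))
        ok <- !is.nan(m$antagonism_a) & !is.nan(m$antagonism_b)
        tests[[length(tests) + 1L]] <- dplyr::mutate(
          paired_t_test(m$antagonism_a[ok], m$antagonism_b[ok]),
          test = "antagonism",
          task = paste(tasks[i], "vs", tasks[j]), .before = 1)
      }
    }
  }
  structure(list(subjects = subjects, tests = dplyr::bind_rows(tests),
                 t_crit = t_crit),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary> %d subject/task rows, |t| criterion %g\n",
              nrow(x$subjects), x$t_crit))
  print(x$tests)
  invisible(x)
}

#' @describeIn distribution_summary Per-subject rows.
#' @param x A `distribution_summary`.
#' @param ... Unused.
#' @method tidy distribution_summary
#' @export
tidy.distribution_summary <- function(x, ...) x$subjects

#' @describeIn distribution_summary Test results, one row per test.
#' @method glance distribution_summary
#' @export
glance.distribution_summary <- function(x, ...) x$tests
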