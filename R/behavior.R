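#' Score questionnaire categories
#'
#' Unweighted mean of the member items of each category ("Thoughts": seven
#' items, "Sensations": three items, plus uncategorised items) per subject
#' and condition. Every category item must be present for every
#' subject/condition; a missing item is an error naming it.
#'
#' @param table Likert tibble (`subject`, `condition`, `item`, `rating`
#'   in 1..5), as from [generate_questionnaire()].
#' @param item_categories Named map item -> category.
#' @return Tibble (`subject`, `condition`, `category`, `score`).
#' @export
score_questionnaire <- function(table,
                                item_categories = default_item_categories()) {
  stopifnot(all(c("subject", "condition", "item", "rating") %in% names(table)))
  if (any(table$rating < 1 | table$rating > 5)) {
    abort("ratings must lie in 1..5")
  }
  cells <- unique(table[, c("subject", "condition")])
  for (it in names(item_categories)) {
    have <- table$item == it
    n_have <- sum(have)
    if (n_have < nrow(cells)) {
      abort(sprintf("item '%s' missing for some subject/condition cells", it))
    }
  }
  table |>
    dplyr::filter(.data$item %in% names(item_categories)) |>
    dplyr::mutate(category = unname(item_categories[.data$item])) |>
    dplyr::group_by(.data$subject, .data$condition, .data$category) |>
    dplyr::summarise(score = mean(.data$rating), .groups = "drop")
}

#' Paired condition comparison with Bonferroni correction
#'
#' Paired t-tests between two conditions, per category score (family 2 for
#' the Thoughts/Sensations categories) or per item (family 17 for the full
#' form), with p-values multiplied by the family size and capped at 1.
#'
#' @param scores Long tibble with `subject`, `condition`, a unit column
#'   (`category` or `item`) and a value column (`score` or `rating`).
#' @param conditions Length-2 character: the pair to compare (first minus
#'   second).
#' @param unit,value Column names of the tested unit and its value.
#' @param families Bonferroni family size; defaults to the number of
#'   units tested.
#' @return Tibble with one row per unit (`t`, `p`, `p_bonferroni`, `df`,
#'   `mean_diff`).
#' @export
compare_conditions <- function(scores, conditions = NULL,
                               unit = if ("category" %in% names(scores)) "category" else "item",
                               value = if ("score" %in% names(scores)) "score" else "rating",
                               families = NULL) {
  if (is.null(conditions)) conditions <- unique(scores$condition)
  if (length(conditions) != 2) abort("exactly two conditions required")
  units <- unique(scores[[unit]])
  if (is.null(families)) families <- length(units)
  stopifnot(families >= 1)
  out <- lapply(units, function(u) {
    s <- scores[scores[[unit]] == u, ]
    a <- s[s$condition == conditions[1], c("subject", value)]
    b <- s[s$condition == conditions[2], c("subject", value)]
    m <- dplyr::inner_join(a, b, by = "subject", suffix = c("_a", "_b"))
    if (nrow(m) < nrow(a) || nrow(m) < nrow(b)) {
      abort(sprintf("unpaired data for %s '%s'", unit, u))
    }
    res <- paired_t_test(m[[paste0(value, "_a")]], m[[paste0(value, "_b")]])
    res[[unit]] <- u
    res[, c(unit, setdiff(names(res), unit))]
  })
  out <- dplyr::bind_rows(out)
  out$p_bonferroni <- pmin(1, out$p * families)
  out
}

#' Thoughts x Sensations correlation matrix
#'
#' Across-subject Pearson correlation of every Thoughts item with every
#' Sensations item within one condition, with the mean and SD over item
#' pairs. Constant items are flagged, their entries set to NA and excluded
#' from the summary.
#'
#' @param table Likert tibble (`subject`, `condition`, `item`, `rating`).
#' @param condition Condition to analyse.
#' @param item_categories Named map item -> category.
#' @return A `category_correlation`: list with `matrix` (Thoughts x
#'   Sensations), `mean_r`, `sd_r`, `n_subjects`, `flagged` (constant
#'   items).
#' @export
category_correlation <- function(table, condition,
                                 item_categories = default_item_categories()) {
  t_items <- names(item_categories)[item_categories == "Thoughts"]
  s_items <- names(item_categories)[item_categories == "Sensations"]
  sub <- table[table$condition == condition, ]
  wide <- tidyr::pivot_wider(sub[, c("subject", "item", "rating")],
                             names_from = "item", values_from = "rating")
  if (nrow(wide) < 3) abort("need at least 3 subjects for correlations")
  flagged <- character(0)
  mat <- matrix(NA_real_, length(t_items), length(s_items),
                dimnames = list(t_items, s_items))
  for (ti in t_items) {
    for (si in s_items) {
      x <- wide[[ti]]
      y <- wide[[si]]
      if (sd(x) == 0) flagged <- union(flagged, ti)
      if (sd(y) == 0) flagged <- union(flagged, si)
      if (sd(x) > 0 && sd(y) > 0) mat[ti, si] <- cor(x, y)
    }
  }
  if (length(flagged)) {
    warn(sprintf("constant items excluded from correlations: %s",
                 paste(flagged, collapse = ", ")))
  }
  rs <- mat[!is.na(mat)]
  structure(
    list(matrix = mat, mean_r = mean(rs), sd_r = sd(rs),
         n_subjects = nrow(wide), condition = condition, flagged = flagged),
    class = "category_correlation"
  )
}

#' @export
print.category_correlation <- function(x, ...) {
  cat(sprintf("<category_correlation> %s: mean r = %.3f (SD %.3f) over %d pairs, n = %d subjects\n",
              x$condition, x$mean_r, x$sd_r, sum(!is.na(x$matrix)),
              x$n_subjects))
  invisible(x)
}

#' @describeIn category_correlation Long tibble of item-pair correlations.
#' @param x A `category_correlation`.
#' @param ... Unused.
#' @method tidy category_correlation
#' @export
tidy.category_correlation <- function(x, ...) {
  tibble(
    thoughts_item = rep(rownames(x$matrix), times = ncol(x$matrix)),
    sensations_item = rep(colnames(x$matrix), each = nrow(x$matrix)),
    r = as.vector(x$matrix),
    condition = x$condition
  )
}

#' @describeIn category_correlation One-row summary.
#' @method glance category_correlation
#' @export
glance.category_correlation <- function(x, ...) {
  tibble(condition = x$condition, mean_r = x$mean_r, sd_r = x$sd_r,
         n_pairs = sum(!is.na(x$matrix)), n_subjects = x$n_subjects,
         n_flagged = length(x$flagged))
}
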