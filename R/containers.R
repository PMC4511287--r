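#' 4D BOLD run container
#'
#' Thin container around a 4D intensity array (x, y, z, time) with the
#' acquisition metadata the pipeline needs: voxel size, repetition time,
#' subject/run identifiers and an inclusion mask.
#'
#' @param data 4D numeric array (x, y, z, volumes).
#' @param tr_s Repetition time, seconds.
#' @param voxel_mm Voxel edge lengths, mm (length 3 or scalar).
#' @param subject,run Identifiers.
#' @param mask Logical 3D array matching the spatial grid; default all
#'   voxels included.
#' @return A `bold_run`.
#' @export
bold_run <- function(data, tr_s, voxel_mm = 3, subject = NA_character_,
                     run = NA_character_, mask = NULL) {
  stopifnot(length(dim(data)) == 4, tr_s > 0)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  dims <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))
  structure(
    list(data = data, tr_s = tr_s, voxel_mm = voxel_mm,
         subject = as.character(subject), run = as.character(run),
         mask = mask),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %dx%dx%d voxels (%g mm) x %d volumes, TR %g s, subject %s\n",
              d[1], d[2], d[3], x$voxel_mm[1], d[4], x$tr_s, x$subject))
  invisible(x)
}

# time x voxel matrix view of a run (voxels in array order)
run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, nrow = prod(d[1:3]), ncol = d[4]))
}

matrix_to_run <- function(mat, template) {
  d <- dim(template$data)
  out <- template
  out$data <- array(t(mat), dim = c(d[1:3], nrow(mat)))
  out
}

#' Per-voxel statistic map
#'
#' A 3D map of a per-voxel statistic (`beta` or `t`) with its degrees of
#' freedom, the contrast that produced it, and the mask it is defined on.
#'
#' @param values 3D numeric array.
#' @param kind `"beta"` or `"t"`.
#' @param df Degrees of freedom (required for t maps).
#' @param contrast Named contrast weight vector over design columns, or a
#'   short description.
#' @param mask Logical 3D array; values are meaningful inside it only.
#' @param voxel_mm Voxel edge lengths, mm.
#' @return A `stat_map`.
#' @export
stat_map <- function(values, kind = c("t", "beta"), df = NA_real_,
                     contrast = NULL, mask = NULL, voxel_mm = 3) {
  kind <- match.arg(kind)
  stopifnot(length(dim(values)) == 3)
  if (kind == "t" && (is.na(df) || df <= 0)) {
    abort("t maps require positive degrees of freedom")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  structure(
    list(values = values, kind = kind, df = df, contrast = contrast,
         mask = mask, voxel_mm = rep_len(as.numeric(voxel_mm), 3)),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  rng <- range(x$values[x$mask], finite = TRUE)
  cat(sprintf("<stat_map> %s, %dx%dx%d, df %s, range [%.2f, %.2f], %d mask voxels\n",
              x$kind, d[1], d[2], d[3], format(x$df), rng[1], rng[2],
              sum(x$mask)))
  invisible(x)
}

#' @describeIn stat_map Tibble of in-mask voxels (`x`, `y`, `z`, `value`).
#' @param x A `stat_map`.
#' @param ... Unused.
#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
         value = x$values[x$mask])
}

#' @describeIn stat_map One-row summary tibble.
#' @method glance stat_map
#' @export
glance.stat_map <- function(x, ...) {
  v <- x$values[x$mask]
  tibble(kind = x$kind, df = x$df, n_voxels = sum(x$mask),
         mean = mean(v), sd = sd(v), min = min(v), max = max(v))
}
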