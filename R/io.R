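#' Read and write BOLD runs as NIfTI-1
#'
#' 4D data with voxel size and TR recorded in the header (`pixdim`).
#' Voxel indexing is 0-based on disk and 1-based in R arrays; round trips
#' are bit exact.
#'
#' @param run A [bold_run()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @export
write_bold <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_mm, run$tr_s)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @param tr_s Repetition time override; required if the header has no
#'   usable TR.
#' @param subject,run_id Identifiers to attach.
#' @export
read_bold <- function(path, tr_s = NULL, subject = NA_character_,
                      run_id = NA_character_) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf("cannot parse NIfTI '%s': %s",
                                                    path, conditionMessage(e))))
  arr <- strip_nifti_attrs(as.array(img))
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else tr_s
  if (is.null(tr) || is.na(tr) || tr <= 0) {
    abort(sprintf("'%s' has no TR in its header; supply tr_s", path))
  }
  bold_run(arr, tr_s = tr, voxel_mm = pd[1:3], subject = subject,
           run = run_id)
}

#' Read and write statistic maps as NIfTI-1 with a JSON sidecar
#'
#' The 3D values go to the NIfTI file; kind, degrees of freedom, contrast
#' and mask bookkeeping go to `<path sans ext>.json`.
#'
#' @param map A [stat_map()].
#' @param path NIfTI file path.
#' @export
write_stat_map <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_mm
  RNifti::writeNifti(img, path)
  side <- sidecar_path(path)
  jsonlite::write_json(
    list(kind = map$kind, df = map$df,
         contrast = as.list(map$contrast),
         mask_indices = which(!map$mask)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- strip_nifti_attrs(as.array(img))
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  mask <- array(TRUE, dim(arr))
  if (length(side$mask_indices)) mask[side$mask_indices] <- FALSE
  contrast <- side$contrast
  if (is.list(contrast)) contrast <- unlist(contrast)
  stat_map(arr, kind = side$kind, df = side$df, contrast = contrast,
           mask = mask, voxel_mm = RNifti::pixdim(img)[1:3])
}

strip_nifti_attrs <- function(arr) {
  array(as.numeric(arr), dim(arr))
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read and write motion traces
#'
#' Tab-separated, six columns: three translations (mm), three rotations
#' (deg), one row per volume.
#'
#' @param motion `n_volumes x 6` matrix.
#' @param path File path.
#' @export
write_motion <- function(motion, path) {
  df <- as.data.frame(motion)
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(df) != 6) abort("motion trace must have 6 columns")
  as.matrix(df)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with sections `protocol`, `simulate`, `preprocess`,
#' `distribution` and `cluster`; every stochastic stage must carry an
#' explicit seed, checked before anything executes.
#'
#' @param path YAML file path.
#' @return The validated config (a named list).
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A config list.
#' @export
validate_pipeline_config <- function(config) {
  need <- c("protocol", "simulate")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    abort(sprintf("config missing sections: %s", paste(miss, collapse = ", ")))
  }
  if (is.null(config$protocol$conditions)) {
    abort("config: protocol$conditions is required")
  }
  for (stage in c("protocol", "simulate")) {
    if (is.null(config[[stage]]$seed)) {
      abort(sprintf("config: stage '%s' is stochastic and has no seed", stage))
    }
  }
  if (!is.null(config$cluster) && is.null(config$cluster$seed)) {
    abort("config: stage 'cluster' is stochastic and has no seed")
  }
  config
}

#' Run the full synthetic pipeline
#'
#' simulate -> preprocess -> subject GLM -> group map -> Monte-Carlo
#' cluster threshold -> voxel-distribution/antagonism report, writing CSV
#' and JSON artifacts to `out_dir`. Identical configs produce
#' byte-identical result tables; every output records the config hash and
#' the seeds used.
#'
#' @param config Config list (see [read_pipeline_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main results (`summary`,
#'   `histograms`, `cluster`, `group_maps`) and the artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(config)
  log <- list()
  stamp <- function(stage, ...) {
    log[[stage]] <<- c(list(stage = stage, ...))
  }

  pr <- config$protocol
  timeline <- build_timeline(pr$conditions,
                             n_blocks = pr$n_blocks %||% 5,
                             block_s = pr$block_s %||% 21,
                             rest_s = pr$rest_s %||% 12,
                             tr_s = pr$tr_s %||% 3,
                             seed = pr$seed)
  stamp("protocol", seed = pr$seed, n_volumes = n_volumes(timeline))

  sm <- config$simulate
  regimes <- sm$regimes %||% c("gating", "antagonistic")
  res <- run_regime_comparison(
    regimes = regimes,
    n_subjects = sm$n_subjects %||% 23,
    grid = sm$grid %||% c(20, 20, 20),
    timeline = timeline,
    fractions = c(pos = sm$fraction_pos %||% 0.1,
                  neg = sm$fraction_neg %||% 0.1),
    amplitudes = c(pos = sm$amplitude_pos %||% 1,
                   neg = sm$amplitude_neg %||% -1),
    highpass_cycles = config$preprocess$highpass_cycles %||% 2,
    fwhm = config$preprocess$fwhm %||% 0,
    t_crit = config$distribution$t_crit %||% 2.819,
    seed = sm$seed)
  stamp("simulate_fit", seed = sm$seed, regimes = regimes)

  hist_tab <- average_histograms(
    cohort_histograms(res$t_maps,
                      edges = config$distribution$edges %||% -6:6))
  stamp("distribution", t_crit = res$summary$t_crit)

  cl <- config$cluster
  cluster <- if (!is.null(cl)) {
    estimate_min_cluster_size(
      array(TRUE, sm$grid %||% c(20, 20, 20)),
      fwhm = cl$fwhm %||% 6, voxel_mm = cl$voxel_mm %||% 3,
      voxel_p = cl$voxel_p %||% 0.01, alpha = cl$alpha %||% 0.05,
      iterations = cl$iterations %||% 1000, seed = cl$seed)
  }
  if (!is.null(cluster)) stamp("cluster", seed = cl$seed,
                               min_size = cluster$min_cluster_size)

  readr::write_csv(res$summary$subjects, file.path(out_dir, "subjects.csv"))
  readr::write_csv(res$summary$tests, file.path(out_dir, "tests.csv"))
  readr::write_csv(hist_tab, file.path(out_dir, "histograms.csv"))
  if (!is.null(cluster)) {
    jsonlite::write_json(glance(cluster), file.path(out_dir, "cluster_threshold.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(
    list(config_hash = cfg_hash, stages = unname(log)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(summary = res$summary, histograms = hist_tab,
                 cluster = cluster, group_maps = res$group_maps,
                 out_dir = out_dir))
}

config_hash <- function(config) {
  # dependency-free stable hash (djb2 over the serialised config)
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
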