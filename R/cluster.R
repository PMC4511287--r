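# neighbourhood offsets for 6/18/26-connectivity
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26)) abort("connectivity must be 6, 18 or 26")
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  ord <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  as.matrix(off[keep, ])
}

#' Label connected clusters in a binary 3D map
#'
#' Connected components of the suprathreshold voxels under face (6), edge
#' (18) or corner (26) adjacency. Components are found on the adjacency
#' graph of suprathreshold voxels (via igraph), which is fast when the
#' suprathreshold set is sparse.
#'
#' @param binary 3D logical (or 0/1) array.
#' @param connectivity 6, 18 or 26.
#' @return List of clusters, each an integer vector of linear voxel
#'   indices, ordered by decreasing size.
#' @export
label_clusters <- function(binary, connectivity = 6) {
  d <- dim(binary)
  stopifnot(length(d) == 3)
  idx <- which(binary != 0)
  if (length(idx) == 0) return(list())
  off <- connectivity_offsets(connectivity)
  coords <- arrayInd(idx, d)
  inside <- array(0L, d)
  inside[idx] <- seq_along(idx)   # voxel -> node id
  edges <- list()
  for (k in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    to <- inside[nb_lin]
    hit <- to > 0L
    if (any(hit)) {
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], to[hit])
    }
  }
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(e[e[, 1] < e[, 2], , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(idx)
  }
  cl <- unname(split(idx, comp))
  cl[order(lengths(cl), decreasing = TRUE)]
}

#' Monte-Carlo minimum cluster extent
#'
#' Estimates the smallest cluster size whose family-wise false-positive
#' probability is at most `alpha` at the given voxelwise threshold. Each
#' iteration fills the mask's bounding grid with white Gaussian noise,
#' smooths it to the nominal FWHM, standardises it within the mask,
#' thresholds two-tailed at `voxel_p`, and records the maximum cluster
#' size. The minimum extent is the smallest `k` for which the fraction of
#' iterations with a maximum cluster of at least `k` voxels does not
#' exceed `alpha`.
#'
#' @param mask 3D logical array (the analysis mask).
#' @param fwhm Smoothness of the simulated noise, mm.
#' @param voxel_mm Voxel edge lengths, mm.
#' @param voxel_p Two-tailed voxelwise probability threshold.
#' @param alpha Corrected family-wise alpha.
#' @param iterations Monte-Carlo iterations (>= 100 and >= `1/alpha`).
#' @param connectivity Cluster adjacency (6, 18 or 26).
#' @param seed Integer seed.
#' @return A `cluster_threshold`: the minimum cluster size, the null
#'   distribution of maximum cluster sizes, and the parameters used.
#' @export
estimate_min_cluster_size <- function(mask, fwhm = 6, voxel_mm = 3,
                                      voxel_p = 0.01, alpha = 0.05,
                                      iterations = 1000, connectivity = 6,
                                      seed = 1) {
  stopifnot(voxel_p > 0, voxel_p < 1, alpha > 0, alpha < 1)
  if (iterations < 100) abort("need at least 100 iterations")
  if (alpha < 1 / iterations) {
    abort(sprintf("alpha = %g is not resolvable with %d iterations; increase iterations",
                  alpha, iterations))
  }
  d <- dim(mask)
  stopifnot(length(d) == 3)
  n_in <- sum(mask)
  if (n_in == 0) abort("empty mask")
  zthr <- qnorm(1 - voxel_p / 2)
  max_sizes <- integer(iterations)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      noise <- array(rnorm(prod(d)), d)
      if (fwhm > 0) noise <- smooth_gaussian(noise, fwhm, voxel_mm)
      v <- noise[mask]
      z <- array(0, d)
      z[mask] <- (v - mean(v)) / sd(v)
      supra <- abs(z) > zthr & mask
      if (!any(supra)) next
      cl <- label_clusters(supra, connectivity)
      max_sizes[it] <- length(cl[[1]])
    }
  })
  ks <- seq_len(max(max_sizes) + 1L)
  exceed <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  min_size <- ks[which(exceed <= alpha)[1]]
  structure(
    list(min_cluster_size = as.integer(min_size), voxel_p = voxel_p,
         alpha = alpha, iterations = iterations,
         null_max_sizes = max_sizes, fwhm = fwhm, voxel_mm = voxel_mm,
         connectivity = connectivity, seed = seed, n_mask = n_in),
    class = "cluster_threshold"
  )
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(
    "<cluster_threshold> min cluster size %d voxels (voxel p %g two-tailed, alpha %g, fwhm %g mm, %d iterations)\n",
    x$min_cluster_size, x$voxel_p, x$alpha, x$fwhm, x$iterations))
  invisible(x)
}

#' @describeIn estimate_min_cluster_size Null distribution as a tibble
#'   (`max_cluster_size`, `n`, `fraction`).
#' @param x A `cluster_threshold`.
#' @param ... Unused.
#' @method tidy cluster_threshold
#' @export
tidy.cluster_threshold <- function(x, ...) {
  tab <- table(x$null_max_sizes)
  tibble(max_cluster_size = as.integer(names(tab)),
         n = as.integer(tab),
         fraction = as.integer(tab) / x$iterations)
}

#' @describeIn estimate_min_cluster_size One-row parameter/result summary.
#' @method glance cluster_threshold
#' @export
glance.cluster_threshold <- function(x, ...) {
  tibble(min_cluster_size = x$min_cluster_size, voxel_p = x$voxel_p,
         alpha = x$alpha, iterations = x$iterations, fwhm = x$fwhm,
         connectivity = x$connectivity, n_mask = x$n_mask, seed = x$seed)
}

#' Apply a cluster-extent threshold to a statistic map
#'
#' Keeps only suprathreshold voxels (two-tailed at `t_crit`) belonging to
#' clusters of at least the calibrated minimum size.
#'
#' @param map A [stat_map()].
#' @param t_crit Voxelwise |t| threshold.
#' @param threshold A `cluster_threshold` (or an integer minimum size).
#' @param connectivity Cluster adjacency.
#' @return A [stat_map()] with subthreshold voxels set to 0 and a mask
#'   restricted to surviving clusters.
#' @export
apply_cluster_threshold <- function(map, t_crit, threshold,
                                    connectivity = 6) {
  k <- if (inherits(threshold, "cluster_threshold")) {
    threshold$min_cluster_size
  } else {
    as.integer(threshold)
  }
  supra <- abs(map$values) > t_crit & map$mask
  keep <- array(FALSE, dim(map$values))
  for (cl in label_clusters(supra, connectivity)) {
    if (length(cl) >= k) keep[cl] <- TRUE
  }
  out <- map
  out$values[!keep] <- 0
  out$mask <- keep
  out
}
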