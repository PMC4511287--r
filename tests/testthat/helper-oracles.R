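# Independent oracles and small fixture builders used across the suite.

# brute-force OLS via the normal equations, with contrast t
oracle_ols <- function(X, y, w) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  df <- nrow(X) - qr(X)$rank
  s2 <- sum((y - X %*% beta)^2) / df
  tval <- drop(t(w) %*% beta) / sqrt(s2 * drop(t(w) %*% xtx_inv %*% w))
  list(beta = unname(drop(beta)), t = tval, df = df)
}

# textbook paired t
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), n - 1), df = n - 1)
}

# recursive flood fill over a binary 3D array
oracle_flood_fill <- function(binary, connectivity = 6) {
  d <- dim(binary)
  off <- switch(as.character(connectivity),
                "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                            c(0, 0, 1), c(0, 0, -1)),
                "26" = {
                  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  g[rowSums(abs(g)) > 0, ]
                })
  seen <- array(FALSE, d)
  clusters <- list()
  for (start in which(binary != 0)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      members <- c(members, v)
      cv <- arrayInd(v, d)
      for (k in seq_len(nrow(off))) {
        nb <- cv + off[k, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1) * d[1] * d[2] + (nb[2] - 1) * d[1] + nb[1]
        if (binary[lin] != 0 && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
  }
  clusters
}

# canonical partition representation for comparing cluster labelings
partition_string <- function(clusters) {
  paste(sort(vapply(clusters, function(cl) paste(sort(cl), collapse = ","),
                    character(1))), collapse = ";")
}

# fresh smoothed+standardised null fields, mirroring the Monte-Carlo
# threshold estimator's null model; applies `fun` to each z field
with_fresh_nulls <- function(mask, fwhm, n, seed, fun, voxel_mm = 3) {
  d <- dim(mask)
  out <- vector("list", n)
  set.seed(seed)
  for (i in seq_len(n)) {
    noise <- array(rnorm(prod(d)), d)
    if (fwhm > 0) noise <- smooth_gaussian(noise, fwhm, voxel_mm)
    v <- noise[mask]
    z <- array(0, d)
    z[mask] <- (v - mean(v)) / sd(v)
    out[[i]] <- fun(z)
  }
  unlist(out)
}

# wrap a time x voxel matrix as a bold_run on a flat grid
matrix_run <- function(mat, tr_s = 3) {
  bold_run(array(t(mat), dim = c(ncol(mat), 1, 1, nrow(mat))), tr_s = tr_s)
}

# a tiny two-condition timeline via the events reader (explicit epochs)
epochs_timeline <- function(epochs, tr_s = 3) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(
    data.frame(onset = sprintf("%.3f", epochs$onset),
               duration = sprintf("%.3f", epochs$duration),
               trial_type = epochs$condition),
    path)
  read_events(path, tr_s = tr_s)
}
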