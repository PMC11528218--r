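# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's own code paths: dense per-voxel
# window scans, direct distance searches, and plain BFS labelling in R.

# grey erosion/dilation by scanning the full box window per voxel
oracle_box_filter <- function(x, footprint, do_max) {
  f <- as.integer(footprint)
  f <- ifelse(f %% 2L == 0L, f + 1L, f)
  r <- (f - 1L) %/% 2L
  d <- dim(x)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    w <- x[max(1, i - r[1]):min(d[1], i + r[1]),
           max(1, j - r[2]):min(d[2], j + r[2]),
           max(1, k - r[3]):min(d[3], k + r[3])]
    out[i, j, k] <- if (do_max) max(w) else min(w)
  }
  out
}

oracle_tophat <- function(x, footprint) {
  x - oracle_box_filter(oracle_box_filter(x, footprint, FALSE), footprint, TRUE)
}

# dense separable-equivalent Gaussian convolution with half-sample
# symmetric reflection, computed voxel by voxel from the full 3D kernel
oracle_gaussian <- function(x, sigma) {
  d <- dim(x)
  ks <- lapply(sigma, function(s) {
    if (s == 0) return(1)
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k / sum(k)
  })
  rs <- vapply(ks, function(k) (length(k) - 1L) %/% 2L, 0L)
  refl <- function(j, n) {
    j <- ((j - 1) %% (2 * n))
    ifelse(j >= n, 2 * n - 1 - j, j) + 1
  }
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc <- 0
    for (dz in -rs[3]:rs[3]) for (dx in -rs[2]:rs[2]) for (dy in -rs[1]:rs[1]) {
      acc <- acc + ks[[1]][dy + rs[1] + 1] * ks[[2]][dx + rs[2] + 1] *
        ks[[3]][dz + rs[3] + 1] *
        x[refl(i + dy, d[1]), refl(j + dx, d[2]), refl(k + dz, d[3])]
    }
    out[i, j, k] <- acc
  }
  out
}

# exact min distance of every foreground voxel to the nearest background
# voxel inside the array, by direct pairwise search
oracle_edt_distances <- function(mask) {
  fg <- which(mask != 0, arr.ind = TRUE)
  bg <- which(mask == 0, arr.ind = TRUE)
  if (nrow(fg) == 0) return(numeric(0))
  if (nrow(bg) == 0) return(rep(Inf, nrow(fg)))
  # |f - b|^2 = |f|^2 + |b|^2 - 2 f.b
  f2 <- rowSums(fg^2)
  b2 <- rowSums(bg^2)
  cross <- fg %*% t(bg)
  d2 <- outer(f2, b2, "+") - 2 * cross
  sqrt(pmax(apply(d2, 1, min), 0))
}

# 3D connected components by BFS in plain R
oracle_label3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  nextlab <- 0L
  idx <- which(mask != 0)
  for (start in idx) {
    if (lab[start] > 0) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        p <- co + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (mask[li] != 0 && lab[li] == 0) {
          lab[li] <- nextlab
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# 2D connected components by BFS in plain R (8-connectivity)
oracle_label2d <- function(m) {
  d <- dim(m)
  lab <- matrix(0L, d[1], d[2])
  nextlab <- 0L
  for (start in which(m != 0)) {
    if (lab[start] > 0) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      ci <- ((cur - 1) %% d[1]) + 1; cj <- ((cur - 1) %/% d[1]) + 1
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        i <- ci + di; j <- cj + dj
        if (i < 1 || i > d[1] || j < 1 || j > d[2]) next
        li <- i + (j - 1) * d[1]
        if (m[li] != 0 && lab[li] == 0) { lab[li] <- nextlab; queue <- c(queue, li) }
      }
    }
  }
  lab
}

# two label volumes induce the same partition of foreground voxels?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  tab <- table(a[fg], b[fg])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# detection F1 with IoU matching plus per-match errors against ground truth
match_against_truth <- function(seg, truth, channel = NULL, iou_min = 0.5) {
  ntruth <- nrow(truth$centroids)
  tp <- 0
  centroid_err <- numeric(0)
  intensity_err <- numeric(0)
  for (tl in seq_len(ntruth)) {
    tv <- truth$instance_labels == tl
    best <- 0; bestlab <- 0
    for (pl in seq_len(seg$n_cells)) {
      pv <- seg$labels == pl
      iou <- sum(tv & pv) / sum(tv | pv)
      if (iou > best) { best <- iou; bestlab <- pl }
    }
    if (best >= iou_min) {
      tp <- tp + 1
      w <- which(seg$labels == bestlab, arr.ind = TRUE)
      centroid_err <- c(centroid_err,
                        sqrt(sum((colMeans(w) - truth$centroids[tl, ])^2)))
      if (!is.null(channel)) {
        m <- mean(channel[seg$labels == bestlab])
        intensity_err <- c(intensity_err,
                           abs(m - truth$true_means[tl, 1]) /
                             truth$true_means[tl, 1])
      }
    }
  }
  list(f1 = 2 * tp / (ntruth + seg$n_cells),
       centroid_err = centroid_err, intensity_err = intensity_err)
}

# minimal unit count by exhaustive pairing (for <= 6 cells): try every way
# of matching cells into pairs within reach; units = pairs + singletons
oracle_min_units <- function(positions, pair_distance) {
  n <- nrow(positions)
  if (n <= 1) return(n)
  d <- as.matrix(dist(positions))
  best <- n
  pairs_within <- which(upper.tri(d) & d <= pair_distance, arr.ind = TRUE)
  explore <- function(used, npairs) {
    best <<- min(best, npairs + (n - 2 * npairs))
    if (nrow(pairs_within) == 0) return()
    for (k in seq_len(nrow(pairs_within))) {
      i <- pairs_within[k, 1]; j <- pairs_within[k, 2]
      if (!used[i] && !used[j]) {
        used2 <- used; used2[c(i, j)] <- TRUE
        explore(used2, npairs + 1L)
      }
    }
  }
  explore(rep(FALSE, n), 0L)
  best
}

# oriented paired measurements (reporter-designated high vs low)
orient_pairs <- function(pm) {
  list(high = ifelse(pm$high_is == "a", pm$cell_a, pm$cell_b),
       low = ifelse(pm$high_is == "a", pm$cell_b, pm$cell_a))
}
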