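# Slice-wise z-tracking: linking, merge events, splits, traversal order and
# agreement with 3D connected components when nothing merges.

cylinder_mask <- function(shape, centers_yx, radius, z_range) {
  m <- array(FALSE, shape)
  Y <- row(matrix(0, shape[1], shape[2]))
  X <- col(matrix(0, shape[1], shape[2]))
  for (z in z_range) {
    sl <- m[, , z]
    for (c in centers_yx)
      sl <- sl | ((Y - c[1])^2 + (X - c[2])^2 <= radius^2)
    m[, , z] <- sl
  }
  m
}

test_that("two disjoint cylinders equal plain 3D components", {
  m <- cylinder_mask(c(24, 40, 8), list(c(12, 10), c(12, 30)), 4, 1:8)
  res <- split_by_ztracking(m, min_object_voxels = 0)
  expect_equal(res$n_cells, 2L)
  expect_equal(nrow(res$merge_events), 0L)
  expect_true(same_partition(res$labels, label_components_3d(m)))
})

test_that("cylinders fused over the last slices split at the merge event", {
  shape <- c(24, 40, 10)
  m <- cylinder_mask(shape, list(c(12, 12), c(12, 28)), 4, 1:10)
  # bridge joining both cylinders over the last 3 slices
  m[10:14, 12:28, 8:10] <- TRUE
  expect_equal(max(label_components_3d(m)), 1L)   # one fused 3D component

  res <- split_by_ztracking(m, min_object_voxels = 0)
  expect_equal(res$n_cells, 2L)
  expect_equal(nrow(res$merge_events), 1L)
  expect_equal(res$merge_events$slice, 8)
  expect_equal(res$merge_events$participants, "1,2")

  # both trajectories end at the slice before the merge
  for (t in res$trajectories[1:2]) {
    expect_equal(t$status, "terminated_at_merge")
    expect_equal(max(t$slices$slice), 7)
  }
  # labelled voxels stop before the merge; fused voxels stay 0
  expect_equal(sort(unique(which(res$labels > 0, arr.ind = TRUE)[, 3])), 1:7)
  expect_true(all(res$labels[, , 8:10] == 0))
})

test_that("a single sphere is one label, equal to its 3D component", {
  co <- expand.grid(y = 1:20, x = 1:20, z = 1:12)
  m <- array((co$y - 10)^2 + (co$x - 10)^2 + (2 * (co$z - 6))^2 <= 49,
             c(20, 20, 12))
  res <- split_by_ztracking(m, min_object_voxels = 20)
  expect_equal(res$n_cells, 1L)
  expect_true(same_partition(res$labels, label_components_3d(m)))
})

test_that("tracking equals 3D components on random merge-free masks", {
  for (s in 1:20) {
    mask <- generate_blob_mask(c(40, 40, 12), n_blobs = 1 + s %% 4, seed = s)
    res <- split_by_ztracking(mask, min_object_voxels = 0)
    expect_equal(nrow(res$merge_events), 0L)
    expect_true(same_partition(res$labels, label_components_3d(mask)))
  }
})

test_that("no label owns voxels at or after its merge slice", {
  shape <- c(30, 40, 12)
  m <- cylinder_mask(shape, list(c(10, 10), c(10, 30), c(22, 20)), 4, 1:12)
  m[8:24, 8:32, 9:12] <- TRUE     # everything fuses at slice 9
  res <- split_by_ztracking(m, min_object_voxels = 0)
  expect_equal(res$n_cells, 3L)
  for (ev in seq_len(nrow(res$merge_events))) {
    s <- res$merge_events$slice[ev]
    ids <- as.integer(strsplit(res$merge_events$participants[ev], ",")[[1]])
    for (id in ids) {
      t <- res$trajectories[[id]]
      if (t$label > 0)
        expect_true(all(which(res$labels == t$label, arr.ind = TRUE)[, 3] < s))
    }
  }
})

test_that("a splitting blob continues by largest overlap and opens a new track", {
  shape <- c(20, 30, 8)
  m <- array(FALSE, shape)
  m[6:15, 8:22, 1:4] <- TRUE             # one wide slab
  m[6:15, 8:14, 5:8] <- TRUE             # big continuation
  m[6:15, 19:22, 5:8] <- TRUE            # smaller offshoot
  res <- split_by_ztracking(m, min_object_voxels = 0)
  expect_equal(res$n_cells, 2L)
  expect_equal(nrow(res$merge_events), 0L)
  # label 1 (first-slice order) spans all 8 slices; the offshoot only 5:8
  z1 <- range(which(res$labels == 1, arr.ind = TRUE)[, 3])
  z2 <- range(which(res$labels == 2, arr.ind = TRUE)[, 3])
  expect_equal(z1, c(1, 8))
  expect_equal(z2, c(5, 8))
})

test_that("traversal can start from the last slice", {
  shape <- c(24, 40, 10)
  m <- cylinder_mask(shape, list(c(12, 12), c(12, 28)), 4, 1:10)
  m[10:14, 12:28, 1:3] <- TRUE           # fused structure at the START
  fwd <- split_by_ztracking(m, min_object_voxels = 0)
  rev <- split_by_ztracking(m, traverse_from = "last_slice",
                            min_object_voxels = 0)
  # forward traversal sees one blob splitting (no merge); reverse sees the
  # merge at slice 3 and recovers the two cells
  expect_equal(nrow(fwd$merge_events), 0L)
  expect_equal(rev$n_cells, 2L)
  expect_equal(nrow(rev$merge_events), 1L)
  expect_equal(rev$merge_events$slice, 3)
  expect_true(all(rev$labels[, , 1:3] == 0))
})

test_that("the size filter drops specks", {
  m <- array(FALSE, c(16, 16, 6))
  m[4:12, 4:12, 2:5] <- TRUE
  m[15, 15, 1] <- TRUE                   # single-voxel speck
  res <- split_by_ztracking(m, min_object_voxels = 20)
  expect_equal(res$n_cells, 1L)
  res0 <- split_by_ztracking(m, min_object_voxels = 0)
  expect_equal(res0$n_cells, 2L)
})

test_that("labels equal the union of their trajectory components", {
  mask <- generate_blob_mask(c(32, 32, 10), n_blobs = 3, seed = 9)
  res <- split_by_ztracking(mask, min_object_voxels = 0)
  for (t in res$trajectories) {
    if (t$label == 0) next
    expect_equal(sum(res$labels == t$label), sum(t$slices$area))
  }
})
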