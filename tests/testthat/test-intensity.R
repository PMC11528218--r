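# Fluorescence quantification: cell means, projections, rolling-ball
# subtraction, ROI means, brightest-slice selection and paired asymmetry.

test_that("measurement top-hat zeroes constants and matches the oracle", {
  x <- array(75, c(20, 20, 4))
  expect_equal(tophat_bg_subtract(x), array(0, dim(x)))
  set.seed(2)
  co <- expand.grid(y = 1:20, x = 1:20, z = 1:4)
  ramp <- array(1.5 * co$y + 2 * co$x, c(20, 20, 4))
  ramp[9:12, 9:12, 2] <- ramp[9:12, 9:12, 2] + 900
  expect_equal(tophat_bg_subtract(ramp, c(7, 7, 1)),
               oracle_tophat(ramp, c(7, 7, 1)), tolerance = 1e-10)
})

test_that("cell means are exact on constants and error on absent labels", {
  lab <- array(0L, c(10, 10, 4))
  lab[2:4, 2:4, 2] <- 1L
  lab[7:9, 7:9, 3] <- 2L
  ch <- array(42, dim(lab))
  m <- cell_mean_intensities(lab, ch)
  expect_equal(m$mean_intensity, c(42, 42))
  expect_equal(m$n_voxels, c(9L, 9L))
  expect_error(cell_mean_intensities(lab, ch, cell_ids = 3), "absent")
  expect_error(cell_mean_intensities(lab, array(0, c(9, 9, 4))), "share")
})

test_that("cell means are equivariant to label permutation and extra channels", {
  set.seed(4)
  lab <- array(0L, c(12, 12, 4))
  lab[2:5, 2:5, 1:2] <- 1L
  lab[8:11, 8:11, 3:4] <- 2L
  ch <- array(runif(12 * 12 * 4, 0, 100), dim(lab))
  m1 <- cell_mean_intensities(lab, list(sig = ch))
  # swap the two labels
  lab2 <- lab
  lab2[lab == 1L] <- 2L; lab2[lab == 2L] <- 1L
  m2 <- cell_mean_intensities(lab2, list(sig = ch))
  expect_equal(m1$mean_intensity, rev(m2$mean_intensity))
  # an extra untouched channel does not alter the first channel's rows
  m3 <- cell_mean_intensities(lab, list(sig = ch, other = ch * 0 + 7))
  expect_equal(m3$mean_intensity[m3$channel == "sig"], m1$mean_intensity)
})

test_that("max projection is the voxelwise maximum", {
  x <- array(runif(8^3), c(8, 8, 8))
  mp <- max_projection(x)
  want <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) want[i, j] <- max(x[i, j, ])
  expect_equal(mp, want)
  one <- array(runif(64), c(8, 8, 1))
  expect_equal(max_projection(one), one[, , 1])
})

test_that("rolling ball removes constants and smooth domes, keeps peaks", {
  img <- matrix(120, 40, 40)
  expect_equal(rolling_ball_subtract(img, 50), matrix(0, 40, 40))
  # isolated small peak survives nearly unchanged
  img[20, 20] <- 1120
  out <- rolling_ball_subtract(img, 50)
  expect_lt(abs(out[20, 20] - 1000), 1)
  expect_true(all(out >= 0))
  # wide smooth dome (radius >> ball) is treated as background
  co <- expand.grid(y = 1:60, x = 1:60)
  dome <- matrix(pmax(0, 400 * (1 - ((co$y - 30)^2 + (co$x - 30)^2) / 400^2)),
                 60, 60)
  res <- rolling_ball_subtract(dome, 20)
  expect_lt(max(res), 0.1 * max(dome))
  expect_error(rolling_ball_subtract(img, 0), "positive")
})

test_that("ROI means match the per-pixel oracle and area-weighted additivity", {
  img <- matrix(42, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[3:6, 3:6] <- TRUE
  expect_equal(roi_mean(img, roi), 42)
  set.seed(8)
  img2 <- matrix(runif(100), 10, 10)
  expect_equal(roi_mean(img2, roi), sum(img2[roi]) / sum(roi))
  roi2 <- matrix(FALSE, 10, 10); roi2[8:9, 8:9] <- TRUE
  both <- roi | roi2
  expect_equal(roi_mean(img2, both),
               (roi_mean(img2, roi) * sum(roi) +
                  roi_mean(img2, roi2) * sum(roi2)) / sum(both))
  expect_error(roi_mean(img2, matrix(FALSE, 10, 10)), "empty")
})

test_that("brightest-slice selection follows the slice-sum ranking", {
  x <- array(0, c(6, 6, 5))
  x[3, 3, 4] <- 10
  expect_equal(brightest_substack_projection(x, 1), x[, , 4])
  set.seed(12)
  y <- array(runif(6 * 6 * 3), c(6, 6, 3))
  expect_equal(brightest_substack_projection(y, 3), max_projection(y))
  z <- array(runif(8 * 8 * 6), c(8, 8, 6))
  sums <- sapply(1:6, function(s) sum(z[, , s]))
  top2 <- sort(order(sums, decreasing = TRUE)[1:2])
  expect_equal(brightest_substack_projection(z, 2),
               max_projection(z[, , top2, drop = FALSE]))
  expect_error(brightest_substack_projection(y, 4), "must be")
  two <- array(runif(6 * 6 * 2), c(6, 6, 2))
  expect_error(brightest_substack_projection(two, 3), "slices")
  # ROI-restricted ranking picks the slice brightest inside the ROI
  w <- array(0, c(6, 6, 2))
  w[1, 1, 1] <- 100            # bright outside ROI
  w[4, 4, 2] <- 10             # bright inside ROI
  roi <- matrix(FALSE, 6, 6); roi[3:5, 3:5] <- TRUE
  expect_equal(brightest_substack_projection(w, 1, roi), w[, , 2])
})

test_that("pair asymmetry orders, flags ties and flips under swap", {
  tie <- pair_asymmetry(10, 10)
  expect_true(tie$tie)
  expect_equal(tie$ratio, 1)
  expect_equal(tie$high_cell, 1L)        # tie broken by cell id
  pm <- pair_asymmetry(list(cell_id = "c7", intensity = 200),
                       list(cell_id = "c2", intensity = 100))
  expect_equal(pm$high_cell, "c7")
  expect_equal(pm$ratio, 2)
  sw <- pair_asymmetry(list(cell_id = "c2", intensity = 100),
                       list(cell_id = "c7", intensity = 200))
  expect_equal(sw$high_cell, "c7")
  expect_equal(sw$ratio, pm$ratio)
  expect_error(pair_asymmetry(0, 10), "nonpositive")
})
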