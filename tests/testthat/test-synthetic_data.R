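# Synthetic stack and count-experiment generators: determinism, analytic
# noiseless output, truth geometry, and count-model calibration.

noiseless_one_cell <- function(shape = c(32, 32, 10),
                               center = c(16, 16, 5), radii = c(5, 5, 2.5),
                               peak = 3000) {
  stack_spec(shape, list(cell_spec(center, radii, peak)),
             background = c(0, 0, 0, 0), noise = noise_spec(0, 0))
}

test_that("a noiseless single cell gives one label and the exact peak", {
  sim <- generate_stack(noiseless_one_cell(), seed = 1)
  expect_equal(max(sim$truth$instance_labels), 1L)
  expect_equal(max(get_channel(sim$stack)), 3000)
  # flat-top support means the true mean equals the peak
  expect_equal(unname(sim$truth$true_means[1, 1]), 3000)
  # voxelwise equal to the analytic profile (zero noise, zero background)
  expect_equal(get_channel(sim$stack), sim$truth$noiseless[[1]])
})

test_that("generation is a pure function of (spec, seed)", {
  spec <- stack_spec(c(24, 24, 8), list(cell_spec(c(12, 12, 4), c(4, 4, 2), 2000)))
  a <- generate_stack(spec, seed = 7)
  b <- generate_stack(spec, seed = 7)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$instance_labels, b$truth$instance_labels)
  c <- generate_stack(spec, seed = 8)
  expect_false(identical(a$stack$channels, c$stack$channels))
})

test_that("truth labels count cells plus one for the basal structure", {
  cells <- list(cell_spec(c(12, 10, 6), c(4, 4, 2), 2500),
                cell_spec(c(12, 26, 6), c(4, 4, 2), 2500))
  base <- base_spec(c(12, 18), c(10, 16), z_extent = 3, intensity = 2000)
  spec <- stack_spec(c(24, 36, 10), cells, base = base)
  sim <- generate_stack(spec, seed = 1)
  expect_equal(sort(unique(as.vector(sim$truth$instance_labels))),
               0:3)  # background, 2 cells, base
  expect_equal(sim$truth$base_id, 3L)
  # centroids lie inside their own labels
  for (i in 1:2) {
    ctr <- round(sim$truth$centroids[i, ])
    expect_equal(sim$truth$instance_labels[ctr[1], ctr[2], ctr[3]], i)
  }
})

test_that("overlapping cells without a base are rejected", {
  cells <- list(cell_spec(c(12, 12, 5), c(5, 5, 2), 2000),
                cell_spec(c(12, 14, 5), c(5, 5, 2), 2000))
  expect_error(generate_stack(stack_spec(c(24, 24, 10), cells), seed = 1),
               "overlap")
})

test_that("a cell that misses the basal structure is rejected", {
  cells <- list(cell_spec(c(12, 12, 3), c(4, 4, 1.5), 2000))
  base <- base_spec(c(12, 12), c(10, 10), z_extent = 2)
  expect_error(generate_stack(stack_spec(c(24, 24, 12), cells, base = base),
                              seed = 1),
               "does not overlap")
})

test_that("merge_z matches brute-force per-slice labelling of the truth", {
  cells <- list(cell_spec(c(14, 10, 7), c(4, 4, 2.5), 2500),
                cell_spec(c(14, 26, 7), c(4, 4, 2.5), 2500))
  base <- base_spec(c(14, 18), c(12, 16), z_extent = 3)
  sim <- generate_stack(stack_spec(c(28, 36, 11), cells, base = base), seed = 2)
  lab <- sim$truth$instance_labels
  found <- NA_integer_
  for (z in seq_len(dim(lab)[3])) {
    comp <- oracle_label2d(lab[, , z] > 0)
    shared <- FALSE
    for (ci in seq_len(max(comp))) {
      ids <- setdiff(unique(lab[, , z][comp == ci]), c(0, sim$truth$base_id))
      if (length(ids) >= 2) shared <- TRUE
    }
    if (shared) { found <- z; break }
  }
  expect_false(is.na(sim$truth$merge_z))
  expect_equal(sim$truth$merge_z, found)
})

test_that("pair stacks encode the requested asymmetry exactly", {
  sim1 <- generate_pair_stack(1, seed = 1, noise = noise_spec(0, 0))
  expect_equal(sim1$truth$true_means[1, "signal"],
               sim1$truth$true_means[2, "signal"])
  sim2 <- generate_pair_stack(2, seed = 1, noise = noise_spec(0, 0))
  # quantify the noiseless signal channel over the truth labels
  meas <- cell_mean_intensities(sim2$truth$instance_labels,
                                get_channel(sim2$stack, "signal"))
  expect_equal(meas$mean_intensity[1] / meas$mean_intensity[2], 2,
               tolerance = 1e-6)
})

test_that("count experiments honour rates, zeros and the seed contract", {
  d0 <- experiment_design(c(ctrl = 1), n_larvae = 5, baseline_rate = 0,
                          progenitor_rate = 0)
  tab0 <- generate_count_experiment(d0)
  expect_true(all(tab0$mature_units == 0) && all(tab0$progenitor_units == 0))
  expect_equal(per_larva_average(tab0)$value, rep(0, 5))

  # law of large numbers: pooled mean within 3 SE of rate * (1 - pi)
  d <- experiment_design(c(a = 1, b = 1), n_larvae = 500,
                         baseline_rate = 0.5, zero_inflation = 0.2, seed = 3)
  tab <- generate_count_experiment(d)
  x <- tab$mature_units
  expect_lt(abs(mean(x) - 0.5 * 0.8), 3 * sd(x) / sqrt(length(x)))

  expect_identical(generate_count_experiment(d),
                   generate_count_experiment(d))

  # negative-binomial alternative runs and respects the seed
  dn <- experiment_design(c(a = 1), n_larvae = 10, count_model = "nb",
                          nb_size = 1, seed = 5)
  expect_identical(generate_count_experiment(dn),
                   generate_count_experiment(dn))
})

test_that("design validation rejects impossible settings", {
  expect_error(experiment_design(c(a = -1)))
  expect_error(experiment_design(zero_inflation = 1.5))
  expect_error(experiment_design(n_larvae = 0))
})

test_that("count tables use the ten-neuromast panel", {
  tab <- generate_count_experiment(experiment_design(n_larvae = 2))
  expect_setequal(unique(tab$neuromast_id), neuromast_panel())
  expect_equal(length(neuromast_panel()), 10L)
  # (larva, neuromast) unique within replicate
  expect_false(any(duplicated(tab[c("replicate", "larva_id", "neuromast_id")])))
})
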