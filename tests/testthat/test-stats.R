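# Adaptive statistics: normality gate, two-group selection, paired test,
# multi-group omnibus + post-hoc, against enumeration and simulation oracles.

test_that("ks_normality contracts: constants error, tiny n flagged", {
  expect_error(ks_normality(rep(3, 10)), "constant")
  p <- ks_normality(c(1, 2, 2.5, 4))
  expect_true(isTRUE(attr(p, "unreliable")))
  p2 <- ks_normality(rnorm(50))
  expect_null(attr(p2, "unreliable"))
  expect_true(p2 >= 0 && p2 <= 1)
})

test_that("Lilliefors-corrected normality check holds its level", {
  set.seed(31)
  ps_lillie <- replicate(400, ks_normality(rnorm(1000), "lilliefors"))
  # correct rejection rates at two working thresholds (binomial tolerance)
  expect_gt(mean(ps_lillie < 0.05), 0.02)
  expect_lt(mean(ps_lillie < 0.05), 0.09)
  expect_gt(mean(ps_lillie < 0.5), 0.40)
  expect_lt(mean(ps_lillie < 0.5), 0.60)
  # the plain KS gate with estimated parameters is anticonservative: its
  # null p-values pile up near 1 instead of being uniform
  ps_ks <- replicate(300, as.numeric(ks_normality(rnorm(1000), "ks")))
  expect_gt(mean(ps_ks), 0.7)
  expect_lt(mean(ps_ks < 0.05), 0.01)
})

test_that("two-group input contracts are enforced", {
  expect_error(compare_two_groups(c(1, 2), c(1, 2, 3)), "at least 3")
  expect_error(compare_two_groups(1:4, 1:5, paired = TRUE), "equal length")
})

test_that("identical paired samples give the degenerate p = 1 result", {
  r <- compare_two_groups(c(1, 2, 3, 4), c(1, 2, 3, 4), paired = TRUE)
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
  expect_equal(r$test, "Wilcoxon_paired")
})

test_that("exact Mann-Whitney p matches full assignment enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- compare_two_groups(a, b, test = "MannWhitney")
  expect_equal(r$test, "MannWhitney")
  # enumerate all C(6,3) = 20 assignments of the pooled values to group a,
  # two-sided p = fraction with |U - n1 n2 / 2| at least as extreme
  pool <- c(a, b)
  U_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- combn(6, 3)
  U_all <- apply(combos, 2, function(idx)
    sum(outer(pool[idx], pool[-idx], ">")))
  p_exact <- mean(abs(U_all - 4.5) >= abs(U_obs - 4.5))
  expect_equal(p_exact, 0.1)
  expect_equal(r$p, p_exact)
})

test_that("test selection is deterministic and recorded", {
  set.seed(41)
  a <- rnorm(15); b <- rnorm(15)
  r1 <- compare_two_groups(a, b)
  r2 <- compare_two_groups(a, b)
  expect_identical(r1$test, r2$test)
  expect_identical(r1$p, r2$p)
  expect_equal(unname(r1$groups$mean), c(mean(a), mean(b)))
  expect_equal(unname(r1$groups$sem),
               c(sd(a) / sqrt(15), sd(b) / sqrt(15)))
  skewed <- exp(rnorm(20, 0, 1.5))
  r3 <- compare_two_groups(skewed, exp(rnorm(20, 0, 1.5)))
  expect_true(r3$test %in% c("t", "MannWhitney"))
  expect_length(r3$normality_p, 2)
})

test_that("omnibus p is 1 for identical groups and powerful for big shifts", {
  g <- c(1.3, 2.1, 0.7, 1.9, 1.1)
  r <- compare_multi_groups(list(a = g, b = g, c = g), "anova_dunn")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  set.seed(51)
  hits <- replicate(200, {
    gs <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 2))  # 2 sd shift
    compare_multi_groups(gs, "anova_dunn")$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Kruskal-Wallis statistic matches the hand-computed rank formula", {
  groups <- list(a = c(2.1, 3.5, 1.0), b = c(4.2, 5.8, 3.9), c = c(0.5, 6.1, 2.8))
  r <- compare_multi_groups(groups, "kw_dunn")
  x <- unlist(groups)
  rk <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, rep(names(groups), each = 3), sum)^2 / 3) - 3 * (N + 1)
  expect_equal(unname(r$statistic), H, tolerance = 1e-12)
  expect_equal(nrow(r$posthoc), 3)   # all pairs
})

test_that("Dunn z statistics agree with the direct rank formula under ties", {
  groups <- list(a = c(1, 2, 2, 3), b = c(2, 4, 4, 5), c = c(5, 6, 7, 7))
  r <- compare_multi_groups(groups, "kw_dunn", control = "a")
  x <- unlist(groups); g <- rep(names(groups), each = 4)
  rk <- rank(x); N <- length(x)
  ties <- table(x)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  zb <- (mean(rk[g == "b"]) - mean(rk[g == "a"])) / sqrt(s2 * (1 / 4 + 1 / 4))
  row_b <- r$posthoc[r$posthoc$comparison == "b vs a", ]
  expect_equal(unname(row_b$z), zb, tolerance = 1e-12)
  expect_equal(unname(row_b$p_raw), 2 * pnorm(-abs(zb)), tolerance = 1e-12)
  expect_equal(nrow(r$posthoc), 2)   # only vs control
})

test_that("Dunnett post-hoc needs a control and flags the shifted group", {
  set.seed(61)
  gs <- list(ctrl = rnorm(12), t1 = rnorm(12), t2 = rnorm(12, 3))
  expect_error(compare_multi_groups(gs, "anova_dunnett"), "control")
  r <- compare_multi_groups(gs, "anova_dunnett", control = "ctrl")
  ph <- r$posthoc
  expect_lt(ph$p_adj[grepl("t2", ph$comparison)], 0.01)
  expect_gt(ph$p_adj[grepl("t1", ph$comparison)], 0.1)
  expect_error(compare_multi_groups(gs[1:2], "kw_dunn"), "3 groups")
})
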