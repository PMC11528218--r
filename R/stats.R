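# Adaptive group comparison over per-larva values: a Kolmogorov-Smirnov
# normality gate decides between the parametric and rank-based two-group
# tests; paired data use the Wilcoxon matched-pairs signed-rank test;
# multi-group designs use ANOVA or Kruskal-Wallis with Dunnett (vs control)
# or Dunn (all pairs / vs control) post-hoc tests. Significance threshold
# 0.05 throughout.

sem <- function(x) sd(x) / sqrt(length(x))

group_summary <- function(groups) {
  data.frame(group = names(groups),
             n = vapply(groups, length, 0L),
             mean = vapply(groups, mean, 0),
             sem = vapply(groups, sem, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov normality check
#'
#' KS test of a sample against a normal distribution with the sample's own
#' mean and standard deviation. With estimated parameters the plain KS
#' p-value is anticonservative (it accepts normality too readily); the
#' Lilliefors correction is available via `method = "lilliefors"`.
#'
#' @param x numeric sample.
#' @param method `"ks"` (plain KS with estimated parameters, default) or
#'   `"lilliefors"` (via [nortest::lillie.test()]).
#' @return the p-value, with attribute `unreliable = TRUE` when `n < 5`.
#' @export
ks_normality <- function(x, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 observations")
  if (sd(x) == 0) stop("constant sample: normality undefined (sd = 0)")
  p <- if (method == "ks")
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  else nortest::lillie.test(x)$p.value
  if (length(x) < 5) attr(p, "unreliable") <- TRUE
  p
}

new_stat_result <- function(comparison, test, statistic, p, groups, alpha,
                            normality_p = NULL, posthoc = NULL,
                            degenerate = FALSE) {
  structure(list(comparison = comparison, test = test,
                 statistic = unname(statistic), p = unname(p),
                 groups = groups, alpha = alpha,
                 normality_p = normality_p, posthoc = posthoc,
                 degenerate = degenerate),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("StatResult: %s\n  test: %s  statistic = %.4g  p = %.4g%s\n",
              x$comparison, x$test, x$statistic, x$p,
              if (isTRUE(x$degenerate)) "  (degenerate)" else ""))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %-12s n = %-3d mean = %.4g  sem = %.4g\n",
                x$groups$group[i], x$groups$n[i], x$groups$mean[i],
                x$groups$sem[i]))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Compare two groups with the adaptive test selection
#'
#' Unpaired data: if both groups pass the KS normality check (p > 0.05), a
#' two-tailed unpaired t-test; otherwise a two-tailed Mann-Whitney U test
#' (exact p when both groups have at most 8 untied observations, normal
#' approximation with tie correction otherwise). Paired data: the Wilcoxon
#' matched-pairs signed-rank test. All tests are two-sided.
#'
#' @param a,b numeric vectors (each `n >= 3`).
#' @param paired logical; paired samples must have equal length.
#' @param alpha significance threshold recorded in the result (default
#'   0.05).
#' @param names group names for the summary.
#' @param normality_method passed to [ks_normality()].
#' @param test `"auto"` (default: normality-gated selection) or force
#'   `"t"` / `"MannWhitney"`.
#' @return a `StatResult`: test used, statistic, p-value, per-group n /
#'   mean / s.e.m., and the per-group normality p-values (unpaired only).
#'   Identical paired samples give a degenerate result with p = 1.
#' @examples
#' compare_two_groups(c(1, 2, 3), c(4, 5, 6), test = "MannWhitney")  # p = 0.1
#' @export
compare_two_groups <- function(a, b, paired = FALSE, alpha = 0.05,
                               names = c("a", "b"),
                               normality_method = "ks",
                               test = c("auto", "t", "MannWhitney")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 observations per group")
  groups <- group_summary(setNames(list(a, b), names))
  comparison <- paste(names, collapse = " vs ")
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    d <- a - b
    if (all(d == 0))
      return(new_stat_result(comparison, "Wilcoxon_paired", 0, 1, groups,
                             alpha, degenerate = TRUE))
    w <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                      alternative = "two.sided"))
    return(new_stat_result(comparison, "Wilcoxon_paired", w$statistic,
                           w$p.value, groups, alpha))
  }
  if (test == "auto") {
    pa <- as.numeric(ks_normality(a, normality_method))
    pb <- as.numeric(ks_normality(b, normality_method))
    norm_p <- setNames(c(pa, pb), names)
    use_t <- pa > 0.05 && pb > 0.05
  } else {
    norm_p <- NULL
    use_t <- test == "t"
  }
  if (use_t) {
    tt <- t.test(a, b, var.equal = TRUE, alternative = "two.sided")
    new_stat_result(comparison, "t", tt$statistic, tt$p.value, groups, alpha,
                    normality_p = norm_p)
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- length(a) <= 8 && length(b) <= 8 && !ties
    w <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE,
                                      alternative = "two.sided"))
    new_stat_result(comparison, "MannWhitney", w$statistic, w$p.value,
                    groups, alpha, normality_p = norm_p)
  }
}

# Dunn's rank-based multiple-comparison z tests with tie correction
dunn_posthoc <- function(groups, control = NULL, p_adjust = "bonferroni") {
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- if (is.null(control)) utils::combn(names(groups), 2)
           else rbind(setdiff(names(groups), control),
                      rep(control, length(groups) - 1L))
  res <- data.frame(comparison = apply(pairs, 2, paste, collapse = " vs "),
                    z = NA_real_, p_raw = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    z <- (rbar[[i]] - rbar[[j]]) / sqrt(s2 * (1 / n[[i]] + 1 / n[[j]]))
    res$z[k] <- z
    res$p_raw[k] <- 2 * pnorm(-abs(z))
  }
  res$p_adj <- p.adjust(res$p_raw, method = p_adjust)
  res
}

#' Compare three or more groups with a post-hoc test
#'
#' Runs the omnibus test (one-way ANOVA or Kruskal-Wallis) and the named
#' post-hoc family: Dunnett's test against a control (via
#' [multcomp::glht()]) or Dunn's rank-based z tests (all pairs, or versus
#' the control when one is given) with multiplicity adjustment.
#'
#' @param groups named list of at least three numeric vectors.
#' @param method `"anova_dunnett"` (default), `"anova_dunn"` or `"kw_dunn"`.
#' @param control control group name; required for Dunnett, optional for
#'   Dunn (restricts comparisons to control vs others).
#' @param alpha significance threshold recorded in the result.
#' @param p_adjust adjustment for Dunn p-values (default `"bonferroni"`,
#'   Dunn's classical correction).
#' @return a `StatResult` with the omnibus statistic/p and a `posthoc`
#'   data frame of adjusted p-values.
#' @export
compare_multi_groups <- function(groups,
                                 method = c("anova_dunnett", "anova_dunn",
                                            "kw_dunn"),
                                 control = NULL, alpha = 0.05,
                                 p_adjust = "bonferroni") {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 3)
    stop("need at least 3 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (method == "anova_dunnett" && is.null(control))
    stop("Dunnett's test requires a control group")
  if (!is.null(control) && !control %in% names(groups))
    stop("control group '", control, "' not found")
  gs <- group_summary(groups)
  comparison <- paste(names(groups), collapse = " / ")
  values <- unlist(groups, use.names = FALSE)
  lev <- if (!is.null(control)) c(control, setdiff(names(groups), control))
         else names(groups)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)), levels = lev)

  if (method %in% c("anova_dunnett", "anova_dunn")) {
    fit <- aov(values ~ g)
    s <- summary(fit)[[1]]
    stat <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
    omnibus <- if (method == "anova_dunnett") "ANOVA+Dunnett" else "ANOVA+Dunn"
  } else {
    kw <- kruskal.test(values, g)
    stat <- kw$statistic
    p <- kw$p.value
    omnibus <- "KruskalWallis+Dunn"
  }

  if (method == "anova_dunnett") {
    fit <- aov(values ~ g)
    # the single-step adjustment integrates a multivariate t by quasi-Monte
    # Carlo; pin the stream so results are reproducible
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(20260101)
    gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    posthoc <- data.frame(
      comparison = names(gl$test$coefficients),
      z = as.numeric(gl$test$tstat),
      p_adj = as.numeric(gl$test$pvalues),
      stringsAsFactors = FALSE)
  } else {
    posthoc <- dunn_posthoc(groups, control = control, p_adjust = p_adjust)
  }
  new_stat_result(comparison, omnibus, stat, p, gs, alpha, posthoc = posthoc)
}
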