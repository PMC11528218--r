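# Simulated ionocyte count experiments. Per larva and neuromast, mature and
# progenitor unit counts are drawn from a zero-inflated Poisson whose rate is
# the baseline times a per-condition multiplier (most neuromasts contain 0 or
# 1 unit, which the zero-inflated model reflects); a negative-binomial
# alternative is available. Optional replicate-level lognormal effects emulate
# the between-replicate spread that motivates per-replicate control
# normalization.

#' The quantified neuromast panel
#'
#' The ten lateral-line neuromasts scored per larva: five from the anterior
#' lateral line and five from the posterior lateral line.
#' @return character vector of ten neuromast names.
#' @export
neuromast_panel <- function() {
  c("Ml1", "O2", "Ml2", "IO4", "O1", "L1", "L2", "L3", "LII.1", "LII.2")
}

#' Specify a simulated count experiment
#'
#' @param conditions data frame with columns `name` and `rate_multiplier`,
#'   or a named numeric vector of multipliers. The first condition is the
#'   control by convention.
#' @param n_larvae larvae per condition per replicate (recycled across
#'   conditions if scalar).
#' @param neuromasts_per_larva number of neuromasts quantified per larva
#'   (default 10, the standard panel).
#' @param baseline_rate expected mature units per neuromast in the control.
#' @param progenitor_rate expected progenitor units per neuromast in the
#'   control.
#' @param zero_inflation probability that a neuromast carries no unit at
#'   all, on top of Poisson zeros.
#' @param n_replicates independent replicates (default 1).
#' @param replicate_sd lognormal sd of a shared per-replicate rate effect
#'   (default 0; set > 0 to emulate wide between-replicate spread).
#' @param count_model `"zip"` (zero-inflated Poisson, default) or `"nb"`
#'   (negative binomial).
#' @param nb_size negative-binomial size (dispersion) when
#'   `count_model = "nb"`.
#' @param seed default RNG seed used by [generate_count_experiment()].
#' @return a list of class `ExperimentDesign`.
#' @export
experiment_design <- function(conditions = c(EM = 1, DI = 2),
                              n_larvae = 18,
                              neuromasts_per_larva = 10,
                              baseline_rate = 0.5,
                              progenitor_rate = 0.3,
                              zero_inflation = 0.2,
                              n_replicates = 1,
                              replicate_sd = 0,
                              count_model = c("zip", "nb"),
                              nb_size = 2,
                              seed = 1L) {
  if (is.data.frame(conditions)) {
    cond <- data.frame(name = as.character(conditions$name),
                       rate_multiplier = as.numeric(conditions$rate_multiplier))
  } else {
    cond <- data.frame(name = names(conditions),
                       rate_multiplier = as.numeric(conditions))
  }
  stopifnot(nrow(cond) >= 1, all(cond$rate_multiplier >= 0),
            all(n_larvae >= 1), neuromasts_per_larva >= 1,
            baseline_rate >= 0, progenitor_rate >= 0,
            zero_inflation >= 0, zero_inflation <= 1,
            n_replicates >= 1, replicate_sd >= 0)
  structure(list(conditions = cond,
                 n_larvae = rep(as.integer(n_larvae), length.out = nrow(cond)),
                 neuromasts_per_larva = as.integer(neuromasts_per_larva),
                 baseline_rate = baseline_rate,
                 progenitor_rate = progenitor_rate,
                 zero_inflation = zero_inflation,
                 n_replicates = as.integer(n_replicates),
                 replicate_sd = replicate_sd,
                 count_model = match.arg(count_model),
                 nb_size = nb_size,
                 seed = as.integer(seed)),
            class = "ExperimentDesign")
}

rzicount <- function(n, rate, design) {
  counts <- if (design$count_model == "zip") rpois(n, rate)
            else rnbinom(n, size = design$nb_size, mu = rate)
  occupied <- rbinom(n, 1L, 1 - design$zero_inflation)
  counts * occupied
}

#' Simulate a per-larva x per-neuromast ionocyte count table
#'
#' @param design an [experiment_design()].
#' @param seed RNG seed; defaults to the design's seed.
#' @return long-format data frame of class `CountTable` with columns
#'   `condition`, `replicate`, `larva_id`, `neuromast_id`, `mature_units`,
#'   `progenitor_units`. Neuromast names come from [neuromast_panel()] when
#'   the panel size is 10.
#' @examples
#' counts <- generate_count_experiment(experiment_design(n_larvae = 4))
#' head(counts)
#' @export
generate_count_experiment <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "ExperimentDesign"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  npm <- design$neuromasts_per_larva
  nm_names <- if (npm == 10L) neuromast_panel()
              else sprintf("NM%02d", seq_len(npm))
  rows <- list()
  for (rep_i in seq_len(design$n_replicates)) {
    rep_eff <- if (design$replicate_sd > 0) rlnorm(1, 0, design$replicate_sd) else 1
    for (ci in seq_len(nrow(design$conditions))) {
      cname <- design$conditions$name[ci]
      mult <- design$conditions$rate_multiplier[ci]
      for (li in seq_len(design$n_larvae[ci])) {
        mature <- rzicount(npm, design$baseline_rate * mult * rep_eff, design)
        prog <- rzicount(npm, design$progenitor_rate * mult * rep_eff, design)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cname,
          replicate = rep_i,
          larva_id = sprintf("%s_r%d_L%02d", cname, rep_i, li),
          neuromast_id = nm_names,
          mature_units = mature,
          progenitor_units = prog,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("CountTable", "data.frame")
  out
}
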