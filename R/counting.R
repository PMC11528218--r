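# Ionocyte classification and counting conventions: marker-based cell
# classification, progenitor "units" (a solitary cell or a sibling pair both
# count as one unit), per-larva averaging over the quantified neuromast
# panel, neuromast frequency, and per-replicate normalization to the control
# condition.

#' Classify a cell record as progenitor, mature or other
#'
#' A progenitor is a foxi3a-positive, trpv6-negative cell immediately
#' adjacent to a neuromast with crescent morphology. A mature ionocyte is
#' foxi3a- (or foxi3b-) positive and trpv6-positive, located inside or
#' caught invading a neuromast. Everything else is `other`.
#'
#' @param records data frame with columns `foxi3a`, `foxi3b`, `trpv6`
#'   (each `"+"` or `"-"`), `location` (`"inside"`, `"adjacent"` or
#'   `"invading"`), `morphology` (`"crescent"`, `"round"` or `"other"`).
#' @return character vector: `"progenitor"`, `"mature"` or `"other"` per row.
#' @examples
#' classify_cells(data.frame(foxi3a = "+", foxi3b = "-", trpv6 = "-",
#'                           location = "adjacent", morphology = "crescent"))
#' @export
classify_cells <- function(records) {
  need <- c("foxi3a", "foxi3b", "trpv6", "location", "morphology")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  mk <- function(col) {
    v <- as.character(records[[col]])
    if (!all(v %in% c("+", "-"))) stop("marker '", col, "' must be '+' or '-'")
    v == "+"
  }
  a <- mk("foxi3a"); b <- mk("foxi3b"); t6 <- mk("trpv6")
  loc <- as.character(records$location)
  if (!all(loc %in% c("inside", "adjacent", "invading")))
    stop("location must be inside, adjacent or invading")
  morph <- as.character(records$morphology)
  prog <- a & !t6 & loc == "adjacent" & morph == "crescent"
  mature <- (a | b) & t6 & loc %in% c("inside", "invading")
  ifelse(prog, "progenitor", ifelse(mature, "mature", "other"))
}

#' Count progenitor units for one neuromast
#'
#' Both individual cells and sibling pairs count as one progenitor unit.
#' Cells within `pair_distance` of each other are eligible to form a pair;
#' the unit count is the minimal one, i.e. cells are matched into as many
#' pairs as possible (exact maximum matching for up to 12 cells — the
#' realistic regime, since a neuromast carries only a few progenitors — and
#' greedy nearest-neighbour pairing beyond that). Every pair contributes
#' one unit and every leftover singleton one unit.
#'
#' @param positions numeric matrix (one row per progenitor cell; 1-3
#'   coordinate columns, micrometres) or a vector of 1D positions. `NULL`
#'   with at most one cell is fine; `NULL` with several cells is an error
#'   unless pairing is disabled.
#' @param pair_distance maximum centre-to-centre pairing distance in
#'   micrometres; default 10 (about one cell diameter).
#' @param pair set `FALSE` to disable pairing (each cell is its own unit).
#' @return integer unit count.
#' @examples
#' group_progenitor_units(c(0, 4))        # one pair -> 1 unit
#' group_progenitor_units(c(0, 4, 40))    # a pair and a distant singleton
#' @export
group_progenitor_units <- function(positions, pair_distance = 10,
                                   pair = TRUE) {
  if (is.null(positions)) n <- 0L
  else {
    if (!is.matrix(positions)) positions <- matrix(positions, ncol = 1)
    n <- nrow(positions)
  }
  if (n <= 1L || !pair) {
    if (is.null(positions) && pair) return(0L)
    return(as.integer(n))
  }
  if (anyNA(positions))
    stop("missing positions with more than one cell; disable pairing or supply positions")
  d <- as.matrix(dist(positions))
  diag(d) <- Inf
  within <- d <= pair_distance
  if (n <= 12L) {
    # exact maximum matching by branching on the first unmatched cell
    max_pairs <- function(avail) {
      i <- which(avail)[1]
      if (is.na(i) || sum(avail) < 2) return(0L)
      avail[i] <- FALSE
      best <- max_pairs(avail)                  # i stays a singleton
      for (j in which(avail & within[i, ])) {
        avail2 <- avail; avail2[j] <- FALSE
        best <- max(best, 1L + max_pairs(avail2))
      }
      best
    }
    n_pairs <- max_pairs(rep(TRUE, n))
  } else {
    # greedy nearest-neighbour fallback
    alive <- rep(TRUE, n)
    n_pairs <- 0L
    repeat {
      dd <- d
      dd[!alive, ] <- Inf
      dd[, !alive] <- Inf
      m <- min(dd)
      if (!is.finite(m) || m > pair_distance) break
      idx <- which(dd == m, arr.ind = TRUE)[1, ]
      alive[idx] <- FALSE
      n_pairs <- n_pairs + 1L
    }
  }
  as.integer(n - n_pairs)
}

#' Per-larva average unit count
#'
#' The mean unit count across each larva's quantified neuromasts, the
#' per-larva summary value used in all downstream comparisons. It can fall
#' below 1 when not every neuromast contains an ionocyte.
#'
#' @param table a `CountTable` (long format; see
#'   [generate_count_experiment()]).
#' @param kind `"mature"` (default) or `"progenitor"`.
#' @return data frame: `condition`, `replicate`, `larva_id`, `value` (one
#'   row per larva), ordered by condition, replicate, larva.
#' @export
per_larva_average <- function(table, kind = c("mature", "progenitor")) {
  kind <- match.arg(kind)
  col <- paste0(kind, "_units")
  stopifnot(col %in% names(table))
  agg <- aggregate(table[[col]],
                   by = list(condition = table$condition,
                             replicate = table$replicate,
                             larva_id = table$larva_id),
                   FUN = mean)
  names(agg)[4] <- "value"
  agg[order(agg$condition, agg$replicate, agg$larva_id), , drop = FALSE] ->
    agg
  rownames(agg) <- NULL
  agg
}

#' Percentage of neuromasts containing ionocytes
#'
#' @param table a `CountTable`.
#' @param kind `"mature"` (default) or `"progenitor"`.
#' @param by optional grouping columns (e.g. `"condition"` or
#'   `c("condition", "replicate")`). With no grouping a single percentage
#'   is returned.
#' @return a percentage (0-100), or a data frame with a `frequency_pct`
#'   column when `by` is given.
#' @export
ionocyte_frequency <- function(table, kind = c("mature", "progenitor"),
                               by = NULL) {
  kind <- match.arg(kind)
  col <- paste0(kind, "_units")
  stopifnot(col %in% names(table))
  occupied <- table[[col]] > 0
  if (is.null(by) || length(by) == 0) return(100 * mean(occupied))
  agg <- aggregate(occupied, by = lapply(by, function(b) table[[b]]),
                   FUN = function(v) 100 * mean(v))
  names(agg) <- c(by, "frequency_pct")
  agg
}

#' Normalize per-larva values to the control condition, per replicate
#'
#' Divides every larva's value by the mean value of the control-condition
#' larvae of the same replicate, so the control group has mean 1 in each
#' replicate. Used when between-replicate spread makes raw values hard to
#' compare.
#'
#' @param values data frame as returned by [per_larva_average()]
#'   (`condition`, `replicate`, `larva_id`, `value`).
#' @param control_condition name of the control condition.
#' @param by_replicate normalize within each replicate (default `TRUE`);
#'   `FALSE` uses the pooled control mean.
#' @return the input with `value` replaced by the normalized value.
#' @export
normalize_to_control <- function(values, control_condition,
                                 by_replicate = TRUE) {
  stopifnot(all(c("condition", "replicate", "value") %in% names(values)))
  if (!control_condition %in% values$condition)
    stop("control condition '", control_condition, "' not present")
  out <- values
  reps <- if (by_replicate) unique(values$replicate) else NA
  for (r in reps) {
    in_rep <- if (by_replicate) values$replicate == r else rep(TRUE, nrow(values))
    ctrl <- values$value[in_rep & values$condition == control_condition]
    if (length(ctrl) == 0)
      stop("replicate ", r, " has no control larvae")
    m <- mean(ctrl)
    if (m == 0) stop("control mean is zero in replicate ", r)
    out$value[in_rep] <- values$value[in_rep] / m
  }
  out
}
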