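#' Code the change between two maps
#'
#' Produces the change-code grid used by the perfect-match metric:
#' 1 where a forest cell became deforested, 2 where a regeneration cell
#' became deforested, 3 where a deforested cell became regeneration, and 0
#' everywhere else (unchanged cells and transitions outside the three
#' modelled ones). Nodata cells are `NA`.
#'
#' @param initial,final [lc_grid()] maps sharing shape and mask.
#' @return Integer matrix of codes \{0, 1, 2, 3\} with `NA` on nodata.
#' @export
change_code <- function(initial, final) {
  if (!identical(dim(initial$cells), dim(final$cells)))
    stop("initial and final maps have different shapes")
  a <- initial$cells
  b <- final$cells
  codes <- matrix(0L, nrow(a), ncol(a))
  sel <- function(cond) !is.na(cond) & cond
  codes[sel(a == LC_FOREST & b == LC_DEFORESTED)] <- 1L
  codes[sel(a == LC_REGEN & b == LC_DEFORESTED)] <- 2L
  codes[sel(a == LC_DEFORESTED & b == LC_REGEN)] <- 3L
  codes[is.na(a) | is.na(b)] <- NA_integer_
  codes
}

#' Perfect-match validation metric
#'
#' For each predicted change-code grid (one per stochastic iteration), the
#' percentage of observed changed cells whose exact transition code is
#' reproduced: `100 * |{x : observed(x) = predicted(x), observed(x) != 0}| /
#' |{x : observed(x) != 0}|`. The denominator is the total observed change
#' over all three transitions, so cells that did not change in the observed
#' maps are never validated, and predicted change at observed-unchanged
#' cells is not penalised. The result carries the per-iteration percentages
#' and their arithmetic mean.
#'
#' @param observed change-code grid of the observed map pair (from
#'   [change_code()]).
#' @param predicted a single change-code grid or a list of them (one per
#'   iteration).
#' @return An object of class `perfect_match_result`: `per_iteration`
#'   (percentages), `mean`, `n_observed_changes`.
#' @export
perfect_match <- function(observed, predicted) {
  if (is.matrix(predicted)) predicted <- list(predicted)
  obs <- as.vector(observed)
  keep <- !is.na(obs)
  obs <- obs[keep]
  n_changed <- sum(obs != 0)
  if (n_changed == 0)
    stop("no observed change: perfect match is undefined")
  per <- vapply(predicted, function(p) {
    if (!identical(dim(p), dim(observed)))
      stop("predicted grid shape differs from observed")
    pv <- as.vector(p)[keep]
    100 * sum(obs != 0 & !is.na(pv) & pv == obs) / n_changed
  }, numeric(1))
  structure(list(per_iteration = per, mean = mean(per),
                 n_observed_changes = n_changed),
            class = "perfect_match_result")
}

#' @export
print.perfect_match_result <- function(x, ...) {
  cat(sprintf("<perfect_match> mean %.2f%% over %d iteration(s), %d observed changed cells\n",
              x$mean, length(x$per_iteration), x$n_observed_changes))
  invisible(x)
}

#' Perfect match of a simulation against an observed map
#'
#' Convenience wrapper: codes observed change between `initial` and
#' `observed_final`, codes predicted change between `initial` and each
#' iteration's simulated map for `year`, and scores the match.
#'
#' @param sim a `sim_output` from [lcc_simulate()].
#' @param initial the calibration-start map the simulation began from.
#' @param observed_final the observed map at the validation year.
#' @param year validation year; must be one of `sim$years`.
#' @return A `perfect_match_result`.
#' @export
validate_simulation <- function(sim, initial, observed_final, year) {
  k <- match(year, sim$years)
  if (is.na(k)) stop("year ", year, " was not simulated")
  obs <- change_code(initial, observed_final)
  pred <- lapply(sim$maps, function(m) change_code(initial, m[[k]]))
  perfect_match(obs, pred)
}
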