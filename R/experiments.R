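#' Calibration-window model design
#'
#' A model design is a pair of map dates used for calibration: the start
#' year and the end year, whose difference is the transition length. The
#' simulation advances from the start year in steps of one transition
#' length, so the years the design can predict are
#' `start_year + k * transition_length` for `k = 1, 2, ...` (the first of
#' which is the calibration end year itself, time step 1).
#'
#' @param start_year,end_year calibration map years, `end_year > start_year`.
#' @return An object of class `model_design` with fields `start_year`,
#'   `end_year`, `transition_length`.
#' @export
model_design <- function(start_year, end_year) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  if (end_year <= start_year) stop("end_year must exceed start_year")
  structure(list(start_year = start_year, end_year = end_year,
                 transition_length = end_year - start_year),
            class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat(sprintf("<model_design> %d-%d (transition length %d)\n",
              x$start_year, x$end_year, x$transition_length))
  invisible(x)
}

#' Time step at which a design predicts a target year
#'
#' The step index of `target_year` in the design's prediction sequence,
#' counting the calibration end year as step 1 (so a 1991-1995 design
#' reaches 2011 at time step 5).
#'
#' @param design a [model_design()].
#' @param target_year year to locate.
#' @return Integer step index; error if the design never predicts the year.
#' @export
time_step_of <- function(design, target_year) {
  k <- (target_year - design$start_year) / design$transition_length
  if (k != round(k) || k < 1)
    stop(sprintf("design %d-%d never predicts %d", design$start_year,
                 design$end_year, target_year))
  as.integer(k)
}

#' Prediction years of a design
#'
#' @param design a [model_design()].
#' @param last_year horizon (inclusive).
#' @return Integer vector `start + k * length` for `k >= 1` up to
#'   `last_year` (the first entry is the calibration end year).
#' @export
predicted_years <- function(design, last_year) {
  if (last_year < design$end_year) return(integer(0))
  seq.int(design$end_year, last_year, by = design$transition_length)
}

#' Enumerate the designs that can predict a target year
#'
#' All ordered pairs of available map years `(start, end)` with
#' `end < target_year` such that stepping forward from the calibration pair
#' in increments of the transition length lands exactly on the target year.
#'
#' @param available_years integer vector of map dates.
#' @param target_year the year every returned design must predict.
#' @return Data frame with columns `start_year`, `end_year`,
#'   `transition_length`, `time_step` (step index of the target year), one
#'   row per admissible design.
#' @export
enumerate_designs <- function(available_years, target_year) {
  years <- sort(unique(as.integer(available_years)))
  if (!length(years)) stop("no available years")
  if (target_year <= min(years))
    stop("target year must follow the earliest available map")
  rows <- list()
  for (s in years) {
    for (e in years[years > s]) {
      if (e >= target_year) next
      len <- e - s
      if ((target_year - e) %% len != 0) next
      rows[[length(rows) + 1]] <- data.frame(
        start_year = s, end_year = e, transition_length = len,
        time_step = as.integer((target_year - s) / len))
    }
  }
  if (!length(rows))
    return(data.frame(start_year = integer(0), end_year = integer(0),
                      transition_length = integer(0), time_step = integer(0)))
  do.call(rbind, rows)
}

#' Validation years available to a design
#'
#' The design's prediction years that fall strictly after the calibration
#' end year and have an observed map available, up to `last_year`.
#'
#' @param design a [model_design()].
#' @param available_years integer vector of observed map dates.
#' @param last_year horizon (inclusive).
#' @return Integer vector of validation years (possibly empty).
#' @export
validation_years <- function(design, available_years, last_year) {
  pred <- predicted_years(design, last_year)
  sort(intersect(pred[pred > design$end_year], as.integer(available_years)))
}

#' Run a grid of calibration-window designs
#'
#' For each design: fits the three transition models by forward stepwise
#' selection on the design's calibration pair, simulates forward from the
#' calibration start map to the design's last available validation year,
#' and scores the mean perfect match against every validation year. This is
#' the engine of the calibration-window experiment: the resulting table is
#' the input to [anova_decomposition()].
#'
#' @param series an `lc_series` of observed maps.
#' @param features a [feature_layers()] object.
#' @param designs data frame as returned by [enumerate_designs()] (or a
#'   subset of it).
#' @param candidates named list of candidate covariate vectors per
#'   transition (defaults: the six shared layers, plus history metrics for
#'   RtoD).
#' @param chain a [chain_config()] for the stepwise fits.
#' @param n_iterations stochastic iterations per simulation.
#' @param last_year validation horizon (default: last series year).
#' @param radius contagion neighbourhood half-width.
#' @return Data frame with one row per (design, validation year):
#'   `start_year`, `end_year`, `transition_length`, `validation_year`,
#'   `time_step`, `perfect_match` (mean over iterations),
#'   `n_observed_changes`.
#' @export
run_design_grid <- function(series, features, designs,
                            candidates = default_candidates(),
                            chain = chain_config(), n_iterations = 100,
                            last_year = max(series$years), radius = 1) {
  if (!nrow(designs)) stop("no designs to run")
  out <- list()
  for (r in seq_len(nrow(designs))) {
    des <- model_design(designs$start_year[r], designs$end_year[r])
    vyears <- validation_years(des, series$years, last_year)
    if (!length(vyears)) next
    initial <- series_grid(series, des$start_year)
    final <- series_grid(series, des$end_year)
    hist_series <- truncate_series(series, des$start_year)
    stack <- assemble_stack(initial, hist_series, features, des$start_year,
                            radius = radius)
    fits <- tryCatch(
      lapply(stats::setNames(LC_TRANSITIONS, LC_TRANSITIONS), function(tr) {
        forward_stepwise(tr, candidates[[tr]], initial, final, stack,
                         chain = chain,
                         split_seed = chain$seed + des$start_year)
      }),
      error = function(e) stop("design ", des$start_year, "-", des$end_year,
                               ": ", conditionMessage(e)))
    n_steps <- (max(vyears) - des$start_year) / des$transition_length
    sim <- lcc_simulate(initial, fits, features, history = hist_series,
                        config = sim_config(
                          n_iterations = n_iterations,
                          transition_length = des$transition_length,
                          n_steps = n_steps,
                          seed = chain$seed + des$end_year,
                          radius = radius))
    for (vy in vyears) {
      pm <- validate_simulation(sim, initial, series_grid(series, vy), vy)
      out[[length(out) + 1]] <- data.frame(
        start_year = des$start_year, end_year = des$end_year,
        transition_length = des$transition_length, validation_year = vy,
        time_step = time_step_of(des, vy), perfect_match = pm$mean,
        n_observed_changes = pm$n_observed_changes)
    }
  }
  do.call(rbind, out)
}

# series truncated to dates <= year (history available at calibration start)
truncate_series <- function(series, year) {
  keep <- series$years <= year
  if (sum(keep) < 2) {
    # pad with a copy of the earliest map so history metrics start empty
    g <- series$grids[[which(keep)[1]]]
    pre <- g
    pre$year <- g$year - 1L
    return(build_series(list(pre, g)))
  }
  structure(list(grids = series$grids[keep], years = series$years[keep]),
            class = "lc_series")
}

#' Default candidate covariate sets per transition
#'
#' The six shared driver layers for every transition, plus the land-use
#' history metrics for the regeneration-to-deforested transition only.
#'
#' @return Named list of character vectors (`FtoD`, `RtoD`, `DtoR`).
#' @export
default_candidates <- function() {
  shared <- c("contagion_defor", "contagion_regen", "dist_roads",
              "dist_rivers", "dist_settlements", "protected")
  list(FtoD = shared, RtoD = c(shared, "arf", "fc", "palu"), DtoR = shared)
}

#' Sequential ANOVA decomposition of perfect-match results
#'
#' Decomposes the perfect-match scores of a design-grid run as a function of
#' initial calibration year, transition length, time step and validation
#' year, all treated as continuous covariates (1 df per term), with
#' sequential (Type I) sums of squares. Terms enter in the order: the four
#' main effects; the two-way interactions initial:length, initial:step,
#' initial:validation, length:validation, step:validation; the three-way
#' interactions initial:length:step, initial:length:validation,
#' initial:step:validation, length:step:validation; and the four-way
#' interaction. The length:step interaction is excluded by construction:
#' `transition_length * time_step = validation_year - start_year`, so it is
#' an exact linear combination of terms already in the model.
#'
#' @param results data frame from [run_design_grid()] (needs columns
#'   `start_year`, `transition_length`, `time_step`, `validation_year`,
#'   `perfect_match`).
#' @return The `anova` table of the sequential fit (one row per term plus
#'   residuals), with `Sum Sq`, `F value` and `Pr(>F)` columns.
#' @export
anova_decomposition <- function(results) {
  need <- c("start_year", "transition_length", "time_step",
            "validation_year", "perfect_match")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing column(s): ",
                         paste(miss, collapse = ", "))
  for (v in c("start_year", "transition_length", "time_step",
              "validation_year"))
    if (length(unique(results[[v]])) < 2)
      stop("factor '", v, "' needs at least 2 distinct values")
  # covariates are centred before products are formed: calendar-year scale
  # interactions are otherwise ill-conditioned (year^2 ~ 4e6 against a
  # variance of a few years); sequential main-effect SS are unaffected
  ctr <- function(x) as.numeric(x) - mean(as.numeric(x))
  d <- data.frame(pm = results$perfect_match,
                  I = ctr(results$start_year),
                  L = ctr(results$transition_length),
                  S = ctr(results$time_step),
                  V = ctr(results$validation_year))
  f <- pm ~ I + L + S + V + I:L + I:S + I:V + L:V + S:V +
    I:L:S + I:L:V + I:S:V + L:S:V + I:L:S:V
  fit <- lm(terms(f, keep.order = TRUE), data = d)
  al <- is.na(stats::coef(fit))
  if (any(al))
    stop("rank-deficient decomposition; collinear term(s): ",
         paste(names(al)[al], collapse = ", "))
  tab <- anova(fit)
  rownames(tab) <- gsub("\\bI\\b", "initial", rownames(tab))
  rownames(tab) <- gsub("\\bL\\b", "length", rownames(tab))
  rownames(tab) <- gsub("\\bS\\b", "step", rownames(tab))
  rownames(tab) <- gsub("\\bV\\b", "validation", rownames(tab))
  tab
}

#' Univariate parameter series across adjacent intervals
#'
#' Fits a single-covariate transition model (intercept plus one driver) on
#' every adjacent pair of dates in the series and returns the posterior mean
#' and 95% credible bounds of the driver's coefficient per interval. The
#' resulting series is the input to [trend_test()] for detecting temporal
#' drift in a driver's effect.
#'
#' @param series an `lc_series`.
#' @param features a [feature_layers()] object.
#' @param covariate one covariate layer name.
#' @param transition one of `"FtoD"`, `"RtoD"`, `"DtoR"`.
#' @param chain a [chain_config()]; per-interval fits derive their seeds
#'   from `chain$seed`.
#' @param radius contagion neighbourhood half-width.
#' @return Data frame with one row per interval: `start_year`, `end_year`,
#'   `mean`, `lower`, `upper` (coefficient posterior summary).
#' @export
univariate_parameter_series <- function(series, features, covariate,
                                        transition, chain = chain_config(),
                                        radius = 1) {
  n_int <- length(series$years) - 1
  if (n_int < 3)
    stop("need at least 3 adjacent intervals (4 dates); have ", n_int)
  spec <- predictor_spec(transition, covariate)
  static <- NULL
  rows <- list()
  for (i in seq_len(n_int)) {
    y0 <- series$years[i]
    y1 <- series$years[i + 1]
    initial <- series$grids[[i]]
    final <- series$grids[[i + 1]]
    out <- transition_outcomes(initial, final, transition)
    if (!length(out$cells))
      stop("interval ", y0, "-", y1, " has no ", transition, " source cells")
    stack <- assemble_stack(initial, truncate_series(series, y0), features,
                            y0, radius = radius, static = static)
    static <- stack$static
    cfg <- chain
    cfg$seed <- as.integer((chain$seed + 131L * i) %% 2147483647L)
    post <- fit_mcmc(spec, out$z, stack, out$cells, cfg)
    rows[[i]] <- data.frame(start_year = y0, end_year = y1,
                            mean = post$mean[[covariate]],
                            lower = post$ci95[1, covariate],
                            upper = post$ci95[2, covariate])
  }
  do.call(rbind, rows)
}

#' Ordinary least-squares trend test
#'
#' Simple linear regression of a value series on a predictor (years or
#' rates), testing whether the series drifts: slope, its t statistic,
#' R-squared, residual degrees of freedom (n - 2) and the two-sided p-value.
#'
#' @param values numeric response (e.g. per-interval parameter estimates).
#' @param predictor numeric covariate of the same length (e.g. interval end
#'   years).
#' @return A list of class `trend_result`: `slope`, `t_statistic`,
#'   `r_squared`, `degrees_freedom`, `p_value`.
#' @export
trend_test <- function(values, predictor) {
  if (length(values) != length(predictor))
    stop("values and predictor must have the same length")
  if (length(values) < 3) stop("need at least 3 points")
  if (sd(predictor) == 0) stop("predictor has zero variance")
  if (sd(values) == 0)    # constant response: flat line fits exactly
    return(structure(list(slope = 0, t_statistic = 0, r_squared = 0,
                          degrees_freedom = length(values) - 2L,
                          p_value = 1),
                     class = "trend_result"))
  fit <- lm(values ~ predictor)
  # exact linear inputs are legitimate here; summary.lm warns about them
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  tt <- if (nrow(co) > 1) co[2, 3] else NA_real_
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no explainable variance
  structure(list(slope = unname(stats::coef(fit)[2]),
                 t_statistic = unname(tt),
                 r_squared = r2,
                 degrees_freedom = fit$df.residual,
                 p_value = unname(if (nrow(co) > 1) co[2, 4] else NA_real_)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend> slope %.4g (t = %.3g, R2 = %.3f, df = %d, p = %.3g)\n",
              x$slope, x$t_statistic, x$r_squared, x$degrees_freedom,
              x$p_value))
  invisible(x)
}

#' Landscape composition and transition rates
#'
#' Per-date class proportions over the valid (non-nodata) cells, and
#' per-interval annualised transition rates: transitioned cells divided by
#' source-class cells at the interval start, divided by the interval length
#' in years.
#'
#' @param series an `lc_series`.
#' @return List of two data frames: `proportions` (`year`, `forest`,
#'   `regen`, `deforested`) and `rates` (`start_year`, `end_year`,
#'   `transition`, `rate`).
#' @export
landscape_composition <- function(series) {
  props <- do.call(rbind, lapply(series$grids, function(g) {
    v <- g$cells[!is.na(g$cells)]
    data.frame(year = g$year,
               forest = mean(v == LC_FOREST),
               regen = mean(v == LC_REGEN),
               deforested = mean(v == LC_DEFORESTED))
  }))
  rates <- list()
  for (i in seq_len(length(series$years) - 1)) {
    a <- series$grids[[i]]$cells
    b <- series$grids[[i + 1]]$cells
    len <- series$years[i + 1] - series$years[i]
    ok <- !is.na(a) & !is.na(b)
    for (tr in LC_TRANSITIONS) {
      src <- transition_source(tr)
      tgt <- transition_target(tr)
      n_src <- sum(ok & a == src)
      n_ev <- sum(ok & a == src & b == tgt)
      rates[[length(rates) + 1]] <- data.frame(
        start_year = series$years[i], end_year = series$years[i + 1],
        transition = tr,
        rate = if (n_src > 0) n_ev / n_src / len else NA_real_)
    }
  }
  list(proportions = props, rates = do.call(rbind, rates))
}
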