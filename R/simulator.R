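#' Simulation configuration
#'
#' @param n_iterations number of stochastic iterations, each with its own
#'   posterior coefficient draw (default 100).
#' @param transition_length years advanced per simulation step; equal to the
#'   calibration interval length, so one step applies the fitted transition
#'   probabilities once.
#' @param n_steps number of steps to simulate.
#' @param seed RNG seed; each iteration derives its own stream from
#'   `(seed, iteration)` so iterations are independently reproducible.
#' @param radius contagion neighbourhood half-width in cells (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_iterations = 100, transition_length = 1,
                       n_steps = 1, seed = 1, radius = 1) {
  stopifnot(n_iterations >= 1, n_steps >= 1, transition_length >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 transition_length = as.integer(transition_length),
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 radius = as.integer(radius)),
            class = "sim_config")
}

iteration_seed <- function(seed, iteration) {
  as.integer((as.double(seed) + 7919 * iteration) %% 2147483647)
}

# per-source-class transition probabilities for one map state
step_probabilities <- function(map, stack, coefs) {
  d <- dim(map$cells)
  p_defor <- matrix(0, d[1], d[2])
  p_reg <- matrix(0, d[1], d[2])
  cls <- list(FtoD = which(!is.na(map$cells) & map$cells == LC_FOREST),
              RtoD = which(!is.na(map$cells) & map$cells == LC_REGEN),
              DtoR = which(!is.na(map$cells) & map$cells == LC_DEFORESTED))
  for (tr in LC_TRANSITIONS) {
    cf <- coefs[[tr]]
    cells <- cls[[tr]]
    if (is.null(cf) || !length(cells)) next
    p <- transition_probability(kappa(cf$spec, cf$beta, stack, cells))
    if (tr == "DtoR") p_reg[cells] <- p else p_defor[cells] <- p
  }
  nod <- is.na(map$cells)
  p_defor[nod] <- NA_real_
  p_reg[nod] <- NA_real_
  list(p_defor = p_defor, p_reg = p_reg, cells = cls)
}

#' Advance the landscape by one stochastic step
#'
#' Recomputes the dynamic covariates from the incoming map, evaluates each
#' transition's probability on its source-class cells, and flips each cell
#' independently by comparing a uniform draw against its probability
#' (forest and regeneration cells to deforested; deforested cells to
#' regeneration). The update is synchronous: every draw sees the incoming
#' map, and covariates are only recomputed between steps. Nodata cells
#' never change.
#'
#' @param map incoming [lc_grid()].
#' @param coefs named list (`FtoD`, `RtoD`, `DtoR`) of
#'   `list(spec = predictor_spec, beta = coefficient vector)`; a `NULL`
#'   entry freezes that transition.
#' @param features a [feature_layers()] object.
#' @param history the trajectory series up to and including `map`'s year.
#' @param year the calendar year of the resulting map.
#' @param radius contagion neighbourhood half-width.
#' @param static optional precomputed static covariates (see
#'   [assemble_stack()]).
#' @return List: `map` (the new [lc_grid()]), `counts` (named FtoD/RtoD/DtoR
#'   event counts), `p_defor`, `p_reg` (probability grids of the incoming
#'   state), `stack` (the covariate stack used).
#' @export
lcc_step <- function(map, coefs, features, history, year, radius = 1,
                     static = NULL) {
  stack <- assemble_stack(map, history, features, map$year, radius = radius,
                          static = static)
  pr <- step_probabilities(map, stack, coefs)
  new_cells <- map$cells
  counts <- c(FtoD = 0L, RtoD = 0L, DtoR = 0L)
  for (tr in LC_TRANSITIONS) {
    cells <- pr$cells[[tr]]
    if (!length(cells)) next
    p <- if (tr == "DtoR") pr$p_reg[cells] else pr$p_defor[cells]
    flip <- runif(length(cells)) < p
    new_cells[cells[flip]] <- transition_target(tr)
    counts[tr] <- sum(flip)
  }
  list(map = lc_grid(new_cells, year = year, cell_size = map$cell_size),
       counts = counts, p_defor = pr$p_defor, p_reg = pr$p_reg,
       stack = stack)
}

#' Stochastic forward simulation with posterior uncertainty
#'
#' Runs `n_iterations` independent stochastic trajectories from the initial
#' map. Each iteration draws one joint coefficient row per transition from
#' its fitted posterior sample (so within-model coefficient correlations are
#' preserved) and advances the landscape `n_steps` times, one transition
#' interval per step, recomputing the dynamic covariates (contagion and
#' history metrics) from the simulated trajectory between steps. The spread
#' across iterations carries both the Bernoulli event noise and the
#' statistical uncertainty of the coefficient estimates.
#'
#' @param initial the starting [lc_grid()].
#' @param fits named list (`FtoD`, `RtoD`, `DtoR`) of `fit_result` objects
#'   (from [forward_stepwise()] or [fit_transition()]); a `NULL` entry
#'   freezes that transition.
#' @param features a [feature_layers()] object.
#' @param history an `lc_series` of the observed trajectory up to the
#'   initial map's year (used to initialise the history metrics); if `NULL`
#'   a two-date stub ending at the initial map is used.
#' @param config a [sim_config()].
#' @return An object of class `sim_output`: `maps` (list over iterations of
#'   lists over steps of [lc_grid()]), `prob_defor`/`prob_reg` (per-step
#'   probability grids averaged over iterations), `change_rates` (data frame
#'   with iteration, step, year, transition, count), `years` (predicted
#'   years), `config`.
#' @export
lcc_simulate <- function(initial, fits, features, history = NULL,
                         config = sim_config()) {
  stopifnot(inherits(initial, "lc_grid"), inherits(config, "sim_config"))
  for (tr in names(fits))
    if (!is.null(fits[[tr]]) && nrow(fits[[tr]]$posterior$samples) < 1)
      stop("posterior for ", tr, " has no samples")
  if (is.null(history)) {
    pre <- initial
    pre$year <- initial$year - config$transition_length
    history <- build_series(list(pre, initial))
  }
  if (max(history$years) != initial$year)
    stop("history must end at the initial map's year")
  static <- static_covariates(features, initial$cell_size)
  years <- initial$year + seq_len(config$n_steps) * config$transition_length
  d <- dim(initial$cells)
  sum_pd <- lapply(seq_len(config$n_steps), function(i) matrix(0, d[1], d[2]))
  sum_pr <- lapply(seq_len(config$n_steps), function(i) matrix(0, d[1], d[2]))
  maps <- vector("list", config$n_iterations)
  rates <- vector("list", config$n_iterations)

  for (it in seq_len(config$n_iterations)) {
    res <- withr::with_seed(iteration_seed(config$seed, it), {
      coefs <- lapply(fits, function(f) {
        if (is.null(f)) return(NULL)
        s <- f$posterior$samples
        list(spec = f$spec, beta = s[sample.int(nrow(s), 1), ])
      })
      traj <- history
      cur <- initial
      it_maps <- vector("list", config$n_steps)
      it_rates <- vector("list", config$n_steps)
      for (k in seq_len(config$n_steps)) {
        st <- lcc_step(cur, coefs, features, traj, year = years[k],
                       radius = config$radius, static = static)
        sum_pd[[k]] <- sum_pd[[k]] + ifelse(is.na(st$p_defor), 0, st$p_defor)
        sum_pr[[k]] <- sum_pr[[k]] + ifelse(is.na(st$p_reg), 0, st$p_reg)
        cur <- st$map
        traj <- series_append(traj, cur)
        it_maps[[k]] <- cur
        it_rates[[k]] <- data.frame(iteration = it, step = k,
                                    year = years[k],
                                    transition = LC_TRANSITIONS,
                                    count = as.integer(st$counts))
      }
      list(maps = it_maps, rates = do.call(rbind, it_rates))
    })
    maps[[it]] <- res$maps
    rates[[it]] <- res$rates
  }
  nod <- is.na(initial$cells)
  avg <- function(s) {
    m <- s / config$n_iterations
    m[nod] <- NA_real_
    m
  }
  structure(list(maps = maps,
                 prob_defor = lapply(sum_pd, avg),
                 prob_reg = lapply(sum_pr, avg),
                 change_rates = do.call(rbind, rates),
                 years = years, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d iterations x %d steps (%s)\n",
              x$config$n_iterations, x$config$n_steps,
              paste(x$years, collapse = ", ")))
  agg <- stats::aggregate(count ~ year + transition, x$change_rates, mean)
  print(agg)
  invisible(x)
}

#' Write simulation outputs
#'
#' Writes per-iteration final maps (ASCII grids), per-step mean probability
#' grids, and the change-rate table as CSV.
#'
#' @param sim a `sim_output` from [lcc_simulate()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (it in seq_along(sim$maps)) {
    final <- sim$maps[[it]][[length(sim$maps[[it]])]]
    write_landcover(final, file.path(dir, sprintf("map_iter%03d.asc", it)))
  }
  for (k in seq_along(sim$years)) {
    write_asc(sim$prob_defor[[k]],
              file.path(dir, sprintf("p_defor_step%d.asc", k)), cellsize = 30)
    write_asc(sim$prob_reg[[k]],
              file.path(dir, sprintf("p_reg_step%d.asc", k)), cellsize = 30)
  }
  write.csv(sim$change_rates, file.path(dir, "change_rates.csv"),
            row.names = FALSE)
  invisible(dir)
}
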