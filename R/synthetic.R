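# rasterise the straight segment p0 -> p1 (row, col) onto a logical mask
rasterize_segment <- function(mask, p0, p1) {
  n <- max(abs(p1 - p0)) * 2 + 1
  t <- seq(0, 1, length.out = n)
  rr <- pmin(pmax(round(p0[1] + t * (p1[1] - p0[1])), 1), nrow(mask))
  cc <- pmin(pmax(round(p0[2] + t * (p1[2] - p0[2])), 1), ncol(mask))
  mask[cbind(rr, cc)] <- TRUE
  mask
}

rasterize_polyline <- function(shape, pts) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(pts) - 1))
    mask <- rasterize_segment(mask, pts[i, ], pts[i + 1, ])
  mask
}

#' Generate synthetic driver feature layers
#'
#' Builds a parametric driver geometry on a rectangular grid: two road
#' polylines (one roughly west-east, one roughly north-south), one
#' meandering river, a single settlement point on the first road, and a
#' protected rectangle covering roughly a quarter of the landscape.
#' Deterministic given the seed.
#'
#' @param shape integer vector `c(nrow, ncol)`, at least 50 x 50.
#' @param seed RNG seed.
#' @return A [feature_layers()] object.
#' @export
make_features <- function(shape, seed = 1) {
  if (length(shape) != 2 || any(shape < 50))
    stop("shape must be at least 50 x 50")
  nr <- shape[1]
  nc <- shape[2]
  withr::with_seed(as.integer(seed), {
    jitter_rows <- function(base, k) {
      round(pmin(pmax(base + stats::rnorm(k, 0, nr * 0.04), 2), nr - 1))
    }
    # road 1: west-east with gentle jitter
    cols1 <- round(seq(1, nc, length.out = 6))
    road1 <- cbind(jitter_rows(nr * 0.35, 6), cols1)
    # road 2: north-south crossing road 1
    rows2 <- round(seq(1, nr, length.out = 6))
    c2 <- round(pmin(pmax(nc * 0.6 + stats::rnorm(6, 0, nc * 0.04), 2),
                     nc - 1))
    road2 <- cbind(rows2, c2)
    roads <- rasterize_polyline(shape, road1) |
      rasterize_polyline(shape, road2)
    # river: meandering north-south near the west side
    rows_r <- round(seq(1, nr, length.out = 12))
    cr <- round(pmin(pmax(nc * 0.22 + nc * 0.06 *
                            sin(seq(0, 3 * pi, length.out = 12)) +
                            stats::rnorm(12, 0, nc * 0.015), 2), nc - 1))
    rivers <- rasterize_polyline(shape, cbind(rows_r, cr))
    # settlement: one point on road 1, mid-landscape
    settlements <- matrix(FALSE, nr, nc)
    sc <- round(nc * 0.5)
    sr <- road1[which.min(abs(road1[, 2] - sc)), 1]
    settlements[sr, sc] <- TRUE
    # protected rectangle, ~25% of the area, in the northwest
    pr <- round(nr * stats::runif(1, 0.48, 0.55))
    pc <- round(nc * stats::runif(1, 0.45, 0.52))
    protected <- matrix(FALSE, nr, nc)
    protected[1:pr, 1:pc] <- TRUE
    feature_layers(roads = roads, rivers = rivers,
                   settlements = settlements, protected = protected)
  })
}

#' Default ground-truth transition coefficients
#'
#' Annual-step coefficients used by [synthetic_scenario()] unless
#' overridden, chosen to mimic a colonisation-frontier landscape:
#' deforestation of forest is strongly contagious, concentrated near roads
#' and suppressed inside the protected area; clearance of regeneration is
#' mildly contagious and more likely where land was cleared before;
#' abandonment (regeneration) is contagious, biased away from roads and
#' towards the protected area. Distance coefficients are per metre.
#'
#' @return Named list of coefficient vectors (`FtoD`, `RtoD`, `DtoR`), each
#'   with an `(Intercept)` entry followed by covariate coefficients.
#' @export
default_truth <- function() {
  list(
    FtoD = c("(Intercept)" = -4.0, contagion_defor = 4.0,
             dist_roads = -8e-4, protected = -1.5),
    RtoD = c("(Intercept)" = -3.0, contagion_defor = 1.2,
             dist_roads = -4e-4, fc = 0.3),
    DtoR = c("(Intercept)" = -2.5, contagion_regen = 1.5,
             dist_roads = 4e-4, protected = 0.5))
}

#' Define a synthetic landscape scenario
#'
#' A scenario bundles everything needed to generate a ground-truth land
#' cover series: grid shape, driver geometry (from [make_features()]), true
#' transition coefficients, observation years (gaps allowed), the initial
#' state, and a shared nodata (water) mask. The truth may be constant (a
#' named list of coefficient vectors, see [default_truth()]) or
#' time-varying (a function of the calendar year returning such a list).
#'
#' @param shape grid dimensions `c(nrow, ncol)` (default 100 x 100).
#' @param seed RNG seed controlling geometry, initial state and the
#'   generative simulation.
#' @param years observation dates; the landscape is simulated annually from
#'   the first to the last and recorded at these dates. The default is 20
#'   dates spanning 1986-2011 with irregular gaps.
#' @param truth coefficient list or `function(year)` returning one.
#' @param initial_class state code filling the initial map (default forest).
#' @param n_nuclei number of single-cell nuclei of `nuclei_class` seeded
#'   into the initial map so contagion can act (default 25).
#' @param nuclei_class state of the nuclei (default deforested).
#' @param initial_props optional named vector of fractions (`forest`,
#'   `deforested`, `regen`); if given, the initial map is an iid mixture of
#'   the three classes in these proportions (overriding `initial_class` and
#'   the nuclei), which guarantees source cells for all three transitions.
#' @param water_fraction approximate fraction of cells set to nodata as a
#'   shared water mask (default 0.02; 0 disables).
#' @param cell_size cell size in metres (default 30).
#' @param radius contagion neighbourhood half-width (default 1).
#' @return An object of class `lc_scenario`.
#' @export
synthetic_scenario <- function(shape = c(100, 100), seed = 1,
                               years = c(1986, 1987, 1989, 1990, 1991, 1992,
                                         1994, 1995, 1996, 1997, 1998, 1999,
                                         2001, 2002, 2004, 2005, 2006, 2008,
                                         2010, 2011),
                               truth = default_truth(),
                               initial_class = LC_FOREST,
                               n_nuclei = 25,
                               nuclei_class = LC_DEFORESTED,
                               initial_props = NULL,
                               water_fraction = 0.02,
                               cell_size = 30, radius = 1) {
  years <- sort(unique(as.integer(years)))
  if (length(years) < 2) stop("need at least 2 observation years")
  features <- make_features(shape, seed)
  structure(list(shape = shape, seed = as.integer(seed), years = years,
                 truth = truth, initial_class = initial_class,
                 n_nuclei = n_nuclei, nuclei_class = nuclei_class,
                 initial_props = initial_props,
                 water_fraction = water_fraction, cell_size = cell_size,
                 radius = radius, features = features),
            class = "lc_scenario")
}

truth_at <- function(truth, year) {
  if (is.function(truth)) truth(year) else truth
}

# coefficient list -> per-transition spec/beta pairs usable by lcc_step
truth_coefs <- function(tr_list) {
  lapply(stats::setNames(LC_TRANSITIONS, LC_TRANSITIONS), function(tr) {
    b <- tr_list[[tr]]
    if (is.null(b)) return(NULL)
    covs <- setdiff(names(b), "(Intercept)")
    list(spec = predictor_spec(tr, covs),
         beta = c(b[["(Intercept)"]], unname(b[covs])))
  })
}

# initial map of a scenario (seeded nuclei, water mask)
scenario_initial <- function(scenario) {
  nr <- scenario$shape[1]
  nc <- scenario$shape[2]
  withr::with_seed(scenario$seed + 1L, {
    if (!is.null(scenario$initial_props)) {
      pr <- scenario$initial_props[c("forest", "deforested", "regen")]
      cells <- matrix(sample(c(LC_FOREST, LC_DEFORESTED, LC_REGEN),
                             nr * nc, replace = TRUE, prob = pr), nr, nc)
    } else {
      cells <- matrix(scenario$initial_class, nr, nc)
      if (scenario$n_nuclei > 0) {
        idx <- sample.int(nr * nc, scenario$n_nuclei)
        cells[idx] <- scenario$nuclei_class
      }
    }
    if (scenario$water_fraction > 0) {
      # a compact water body in the southeast corner
      side <- max(2, round(sqrt(scenario$water_fraction * nr * nc)))
      r0 <- nr - side + 1
      c0 <- nc - side + 1
      cells[r0:nr, c0:nc] <- NA_integer_
    }
    lc_grid(cells, year = min(scenario$years),
            cell_size = scenario$cell_size)
  })
}

#' Generate a ground-truth land cover series from a scenario
#'
#' Simulates the landscape forward annually from the scenario's initial map
#' using the true coefficients in the same logistic-contagion model the
#' fitting code assumes (one Bernoulli round per year, dynamic covariates
#' recomputed from the evolving trajectory), and records grids only at the
#' scenario's observation years. The generated series therefore has, by
#' construction, the statistical structure the transition models estimate,
#' with realistic observation gaps.
#'
#' @param scenario an [synthetic_scenario()].
#' @return An `lc_series` of the recorded observation dates.
#' @export
generate_truth_series <- function(scenario) {
  stopifnot(inherits(scenario, "lc_scenario"))
  initial <- scenario_initial(scenario)
  y0 <- min(scenario$years)
  y1 <- max(scenario$years)
  static <- static_covariates(scenario$features, scenario$cell_size)
  pre <- initial
  pre$year <- y0 - 1L
  traj <- build_series(list(pre, initial))
  recorded <- list(initial)
  total_events <- 0L
  withr::with_seed(scenario$seed + 2L, {
    cur <- initial
    for (yr in seq.int(y0 + 1L, y1)) {
      coefs <- truth_coefs(truth_at(scenario$truth, yr))
      st <- lcc_step(cur, coefs, scenario$features, traj, year = yr,
                     radius = scenario$radius, static = static)
      total_events <- total_events + sum(st$counts)
      cur <- st$map
      traj <- series_append(traj, cur)
      if (yr %in% scenario$years) recorded[[length(recorded) + 1]] <- cur
    }
  })
  if (total_events == 0L)
    warning("truth produced no transition events over the whole horizon")
  build_series(recorded)
}
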