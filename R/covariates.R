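#' Euclidean distance to the nearest feature cell
#'
#' Distance (in metres) from every cell centre to the nearest cell where
#' `mask` is `TRUE`. Feature cells themselves get 0. Uses an exact
#' Euclidean distance transform.
#'
#' @param mask logical matrix; `TRUE` marks feature (source) cells.
#' @param cell_size cell edge length in metres.
#' @return Numeric matrix of distances in metres.
#' @export
distance_grid <- function(mask, cell_size = 30) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("'mask' must be a logical matrix")
  if (!any(mask, na.rm = TRUE)) stop("empty feature mask")
  m <- matrix(1, nrow(mask), ncol(mask))
  m[which(mask)] <- 0
  d <- EBImage::distmap(m, metric = "euclidean")
  as.matrix(d) * cell_size
}

# sum of a matrix over all offsets of a square neighbourhood of half-width
# `radius`, centre excluded; cells shifted in from outside count as 0
neighbour_sum <- function(x, radius) {
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (di in -radius:radius) {
    ri_dst <- max(1, 1 - di):min(nr, nr - di)
    ri_src <- ri_dst + di
    for (dj in -radius:radius) {
      if (di == 0 && dj == 0) next
      cj_dst <- max(1, 1 - dj):min(nc, nc - dj)
      cj_src <- cj_dst + dj
      out[ri_dst, cj_dst] <- out[ri_dst, cj_dst] + x[ri_src, cj_src]
    }
  }
  out
}

#' Neighbourhood contagion of a land cover state
#'
#' For every cell, the proportion of valid (in-bounds, non-nodata)
#' neighbours within a square (Moore) neighbourhood of half-width `radius`
#' that are currently in `target_state`. The centre cell is excluded and the
#' proportion is normalised by the count of valid neighbours, so edge and
#' mask-adjacent cells are handled without bias. This is the dynamic
#' covariate through which change spreads from recently changed neighbours.
#'
#' @param map an [lc_grid()].
#' @param target_state state code counted in the neighbourhood
#'   (e.g. [LC_DEFORESTED]).
#' @param radius neighbourhood half-width in cells (default 1: 8 neighbours).
#' @return Numeric matrix of proportions in \[0, 1\]; `NA` on nodata cells.
#' @export
contagion <- function(map, target_state, radius = 1) {
  stopifnot(inherits(map, "lc_grid"), radius >= 1)
  valid <- !is.na(map$cells)
  hit <- valid & map$cells == target_state
  n_hit <- neighbour_sum(hit + 0, radius)
  n_valid <- neighbour_sum(valid + 0, radius)
  out <- ifelse(n_valid > 0, n_hit / n_valid, 0)
  out[!valid] <- NA_real_
  out
}

#' Land-use history metrics (PALU, ARF, FC)
#'
#' Computes, per cell, three metrics from the observed state sequence up to
#' `upto_year`:
#' \describe{
#'   \item{fc}{frequency of clearance: number of observed transitions into
#'     the deforested state (from forest or regeneration).}
#'   \item{arf}{age of regenerating forest: calendar years since the most
#'     recent observed deforested-to-regeneration transition, for cells
#'     currently regenerating; 0 otherwise.}
#'   \item{palu}{period of active land use: calendar-year length of the
#'     maximal deforested interval immediately preceding that most recent
#'     abandonment; 0 for cells not currently regenerating.}
#' }
#' States are carried forward between observation dates, and a transition
#' observed between two dates is attributed to the later date of the pair.
#'
#' @param series an `lc_series` from [build_series()] (or with simulated
#'   grids appended).
#' @param upto_year a year present in `series$years`.
#' @return List with numeric matrices `palu`, `arf`, `fc`; `NA` on nodata.
#' @export
history_metrics <- function(series, upto_year) {
  k <- match(upto_year, series$years)
  if (is.na(k)) stop("year ", upto_year, " not in series")
  years <- series$years[seq_len(k)]
  states <- lapply(series$grids[seq_len(k)], function(g) g$cells)
  d <- dim(states[[1]])
  fc <- matrix(0, d[1], d[2])
  last_dr <- matrix(NA_real_, d[1], d[2])   # year of latest D->R transition
  palu_last <- matrix(0, d[1], d[2])        # PALU attached to that transition
  # year attributed to the start of the current deforested run
  d_start <- matrix(NA_real_, d[1], d[2])
  d_start[states[[1]] == LC_DEFORESTED] <- years[1]
  if (k >= 2) {
    for (i in 2:k) {
      cur <- states[[i]]
      prev <- states[[i - 1]]
      ok <- !is.na(cur) & !is.na(prev)
      enter_d <- ok & cur == LC_DEFORESTED & prev != LC_DEFORESTED
      fc[enter_d] <- fc[enter_d] + 1
      d_start[enter_d] <- years[i]
      abandon <- ok & cur == LC_REGEN & prev == LC_DEFORESTED
      last_dr[abandon] <- years[i]
      palu_last[abandon] <- years[i] - d_start[abandon]
    }
  }
  cur <- states[[k]]
  is_regen <- !is.na(cur) & cur == LC_REGEN & !is.na(last_dr)
  arf <- matrix(0, d[1], d[2])
  arf[is_regen] <- upto_year - last_dr[is_regen]
  palu <- matrix(0, d[1], d[2])
  palu[is_regen] <- palu_last[is_regen]
  nod <- is.na(cur)
  fc[nod] <- NA_real_
  arf[nod] <- NA_real_
  palu[nod] <- NA_real_
  list(palu = palu, arf = arf, fc = fc)
}

#' Names of covariate layers
#'
#' Static layers are computed once from the feature geometry; dynamic layers
#' are recomputed from the current map and trajectory at every simulation
#' step. The history metrics (`palu`, `arf`, `fc`) are meaningful only for
#' the regeneration-to-deforested transition.
#'
#' @return Character vector of the nine layer names.
#' @export
covariate_names <- function() {
  c("dist_roads", "dist_rivers", "dist_settlements", "protected",
    "contagion_defor", "contagion_regen", "palu", "arf", "fc")
}

static_covariates <- function(features, cell_size) {
  list(dist_roads = distance_grid(features$roads, cell_size),
       dist_rivers = distance_grid(features$rivers, cell_size),
       dist_settlements = distance_grid(features$settlements, cell_size),
       protected = features$protected + 0)
}

#' Assemble the covariate stack for one date
#'
#' Builds the nine named covariate layers used in the transition models:
#' static drivers (distance to roads, rivers and settlements; protection
#' status) and dynamic layers (contagion of deforestation and regeneration
#' from `map`; PALU/ARF/FC from the trajectory in `series`). All layers are
#' masked to `NA` where the map is nodata. The static layers may be
#' precomputed once with the internal cache argument and reused across
#' simulation steps; dynamic layers are always recomputed.
#'
#' @param map the [lc_grid()] whose state drives the dynamic layers.
#' @param series the `lc_series` holding the trajectory up to `year`.
#' @param features a [feature_layers()] object.
#' @param year the date of the stack; must be in `series$years`.
#' @param radius contagion neighbourhood half-width (cells).
#' @param static optional precomputed static layer list (from a previous
#'   stack's `static` element) to avoid recomputing distance transforms.
#' @return An object of class `covariate_stack`: list with `year`, `layers`
#'   (named list of matrices) and `static` (reusable static layer list).
#' @export
assemble_stack <- function(map, series, features, year, radius = 1,
                           static = NULL) {
  stopifnot(inherits(map, "lc_grid"), inherits(features, "feature_layers"))
  if (!identical(dim(map$cells), dim(features$roads)))
    stop("map and feature layers have different shapes")
  if (is.null(static)) static <- static_covariates(features, map$cell_size)
  hist <- history_metrics(series, year)
  layers <- c(static,
              list(contagion_defor = contagion(map, LC_DEFORESTED, radius),
                   contagion_regen = contagion(map, LC_REGEN, radius)),
              hist[c("palu", "arf", "fc")])
  nod <- is.na(map$cells)
  layers <- lapply(layers, function(l) {
    l[nod] <- NA_real_
    l
  })
  structure(list(year = as.integer(year), layers = layers[covariate_names()],
                 static = static),
            class = "covariate_stack")
}

#' Write a covariate stack for inspection
#'
#' Writes each layer of the stack as an ESRI ASCII grid named
#' `<prefix>_<layer>.asc`.
#'
#' @param stack a `covariate_stack` from [assemble_stack()].
#' @param prefix output path prefix.
#' @param cell_size cell size recorded in the headers.
#' @return Character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, prefix, cell_size = 30) {
  paths <- character(0)
  for (nm in names(stack$layers)) {
    p <- paste0(prefix, "_", nm, ".asc")
    write_asc(stack$layers[[nm]], p, cellsize = cell_size)
    paths <- c(paths, p)
  }
  invisible(paths)
}
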