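#' Construct a land cover grid
#'
#' A land cover grid is an integer matrix of state codes
#' ([LC_DEFORESTED], [LC_FOREST], [LC_REGEN], with `NA` marking nodata)
#' stamped with a calendar year and a cell size in metres. Row 1 is the
#' northern edge; positions are (row, col), and cell centres define
#' locations for distance computations.
#'
#' @param cells integer matrix of state codes; `NA` for nodata.
#' @param year calendar year of the map.
#' @param cell_size cell edge length in metres (default 30, Landsat scale).
#' @return An object of class `lc_grid`.
#' @export
lc_grid <- function(cells, year, cell_size = 30) {
  if (!is.matrix(cells) || nrow(cells) < 1 || ncol(cells) < 1)
    stop("'cells' must be a non-empty matrix")
  storage.mode(cells) <- "integer"
  bad <- !is.na(cells) & !(cells %in% c(LC_DEFORESTED, LC_FOREST, LC_REGEN))
  if (any(bad))
    stop("invalid state codes in grid: ",
         paste(unique(cells[bad]), collapse = ", "))
  structure(list(cells = cells, year = as.integer(year),
                 cell_size = as.numeric(cell_size)),
            class = "lc_grid")
}

#' @export
print.lc_grid <- function(x, ...) {
  cat(sprintf("<lc_grid %d> %d x %d cells, %g m; F=%d R=%d D=%d NA=%d\n",
              x$year, nrow(x$cells), ncol(x$cells), x$cell_size,
              sum(x$cells == LC_FOREST, na.rm = TRUE),
              sum(x$cells == LC_REGEN, na.rm = TRUE),
              sum(x$cells == LC_DEFORESTED, na.rm = TRUE),
              sum(is.na(x$cells))))
  invisible(x)
}

#' @export
dim.lc_grid <- function(x) dim(x$cells)

# ---- ESRI ASCII grid -------------------------------------------------------

read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stop("ASCII grid header missing ", key)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA
  list(values = m, cellsize = hdr$cellsize, nodata = nodata)
}

write_asc <- function(values, path, cellsize, nodata = -9999) {
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(values)),
           sprintf("nrows %d", nrow(values)),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %s", format(cellsize)),
           sprintf("NODATA_value %s", format(nodata)))
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- TIFF (single band, 8-bit integer codes) -------------------------------

read_tif_codes <- function(path) {
  r <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(r)) == 3) r <- r[, , 1]
  storage.mode(r) <- "integer"
  r
}

write_tif_codes <- function(values, path, nodata_code = 255L) {
  v <- values
  v[is.na(v)] <- nodata_code
  if (any(v < 0 | v > 255))
    stop("TIFF writer stores 8-bit codes; values must lie in 0..255")
  tiff::writeTIFF(v / 255, path, bits.per.sample = 8L)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a land cover map from file
#'
#' Reads a single-band raster in ESRI ASCII grid (`.asc`) or TIFF
#' (`.tif`/`.tiff`) format and maps its cell values onto land cover state
#' codes. A JSON sidecar written by [write_landcover()] (`<path>.json`)
#' supplies year, cell size and nodata code when present; arguments override.
#'
#' @param path raster file path.
#' @param year calendar year of the map (required unless a sidecar has it).
#' @param class_map named integer vector mapping raster values (names) to
#'   state codes (values); entries with value `NA` mark nodata. Defaults to
#'   the identity mapping of the three state codes.
#' @param cell_size cell size in metres; defaults to the sidecar or file
#'   header value, else 30.
#' @param nodata raster value to treat as nodata (ASCII grids default to the
#'   header `NODATA_value`; TIFFs to code 255).
#' @return An [lc_grid()].
#' @export
read_landcover <- function(path, year = NULL, class_map = NULL,
                           cell_size = NULL, nodata = NULL) {
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else list()
  is_tif <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tif) {
    vals <- read_tif_codes(path)
    cs <- 30
    nd <- if (!is.null(meta$nodata)) meta$nodata else 255
  } else {
    a <- read_asc(path)
    vals <- a$values
    cs <- a$cellsize
    nd <- a$nodata
  }
  if (!is.null(nodata)) nd <- nodata
  if (!is.null(meta$cell_size)) cs <- meta$cell_size
  if (!is.null(cell_size)) cs <- cell_size
  if (is.null(year)) year <- meta$year
  if (is.null(year)) stop("'year' not given and no sidecar found for ", path)

  out <- matrix(NA_integer_, nrow(vals), ncol(vals))
  if (!is.na(nd)) out[vals == nd] <- NA_integer_
  todo <- is.na(out) & !(!is.na(nd) & vals == nd)
  if (is.null(class_map)) {
    states <- c(LC_DEFORESTED, LC_FOREST, LC_REGEN)
    class_map <- stats::setNames(states, as.character(states))
  }
  for (k in names(class_map)) {
    sel <- vals == as.numeric(k) & todo
    out[sel] <- as.integer(class_map[[k]])
    todo[sel] <- FALSE
  }
  if (any(todo))
    stop("unmapped raster value(s) in ", path, ": ",
         paste(sort(unique(vals[todo])), collapse = ", "))
  lc_grid(out, year = year, cell_size = cs)
}

#' Write a land cover map to file
#'
#' Writes an [lc_grid()] as an ESRI ASCII grid (`.asc`) or 8-bit TIFF
#' (`.tif`/`.tiff`), plus a JSON sidecar (`<path>.json`) recording year,
#' cell size and the nodata code, so [read_landcover()] can round-trip it.
#'
#' @param grid an [lc_grid()].
#' @param path output path; the extension selects the format.
#' @param nodata nodata code written into the raster (default -9999 for
#'   ASCII, 255 for TIFF).
#' @return `path`, invisibly.
#' @export
write_landcover <- function(grid, path, nodata = NULL) {
  stopifnot(inherits(grid, "lc_grid"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    nd <- if (is.null(nodata)) 255L else as.integer(nodata)
    write_tif_codes(grid$cells, path, nodata_code = nd)
  } else {
    nd <- if (is.null(nodata)) -9999 else nodata
    write_asc(grid$cells, path, cellsize = grid$cell_size, nodata = nd)
  }
  jsonlite::write_json(list(year = grid$year, cell_size = grid$cell_size,
                            nodata = if (is.null(nodata)) {
                              if (grepl("\\.tiff?$", path, ignore.case = TRUE))
                                255 else -9999
                            } else nodata),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Assemble a dated land cover series
#'
#' Orders grids by year, checks that shapes, cell sizes and years are
#' consistent, and applies the common nodata mask: a cell that is nodata at
#' any date becomes nodata at all dates (the equivalent of a shared water
#' mask over the whole series).
#'
#' @param grids list of [lc_grid()] objects with distinct years.
#' @return An object of class `lc_series` with elements `grids` (sorted by
#'   year) and `years`.
#' @export
build_series <- function(grids) {
  if (length(grids) < 2) stop("a series needs at least 2 dated grids")
  if (!all(vapply(grids, inherits, logical(1), "lc_grid")))
    stop("all elements must be lc_grid objects")
  years <- vapply(grids, function(g) g$year, integer(1))
  if (anyDuplicated(years)) stop("duplicate years in series")
  dims <- vapply(grids, function(g) dim(g$cells), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all grids in a series must share the same shape")
  cs <- vapply(grids, function(g) g$cell_size, numeric(1))
  if (any(cs != cs[1])) stop("all grids in a series must share cell size")
  ord <- order(years)
  grids <- grids[ord]
  years <- years[ord]
  mask <- Reduce(`|`, lapply(grids, function(g) is.na(g$cells)))
  grids <- lapply(grids, function(g) {
    g$cells[mask] <- NA_integer_
    g
  })
  structure(list(grids = grids, years = years), class = "lc_series")
}

#' @export
print.lc_series <- function(x, ...) {
  cat(sprintf("<lc_series> %d dates %d-%d, %d x %d cells\n",
              length(x$years), min(x$years), max(x$years),
              nrow(x$grids[[1]]$cells), ncol(x$grids[[1]]$cells)))
  invisible(x)
}

# grid of a series at a given year
series_grid <- function(series, year) {
  i <- match(year, series$years)
  if (is.na(i)) stop("year ", year, " not in series")
  series$grids[[i]]
}

# append a (simulated) grid to a series, keeping the shared mask invariant
series_append <- function(series, grid) {
  stopifnot(inherits(grid, "lc_grid"))
  if (grid$year <= max(series$years))
    stop("appended grid year must follow the series")
  series$grids <- c(series$grids, list(grid))
  series$years <- c(series$years, grid$year)
  series
}

#' Driver feature layers
#'
#' Boolean masks of the landscape features that drive land cover change:
#' road cells, river cells, settlement cells and the protected area. All
#' masks must share the grid shape of the land cover series they are used
#' with.
#'
#' @param roads,rivers,settlements logical matrices marking feature cells.
#' @param protected logical matrix marking protected-area cells.
#' @return An object of class `feature_layers`.
#' @export
feature_layers <- function(roads, rivers, settlements, protected) {
  layers <- list(roads = roads, rivers = rivers,
                 settlements = settlements, protected = protected)
  d <- dim(roads)
  for (nm in names(layers)) {
    if (!is.matrix(layers[[nm]]) || !is.logical(layers[[nm]]))
      stop("'", nm, "' must be a logical matrix")
    if (!identical(dim(layers[[nm]]), d))
      stop("feature layers must share one shape")
  }
  structure(layers, class = "feature_layers")
}
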