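#' Construct an environmental raster stack
#'
#' A set of named, co-registered layers on a shared regular grid. Layers are
#' numeric matrices indexed `[row, col]` with row 1 the northernmost row
#' (map order); the geotransform is the lower-left corner of the grid plus a
#' square cell size in degrees.
#'
#' @param layers named list of numeric matrices of identical dimension.
#' @param xll,yll lower-left corner (degrees, WGS84).
#' @param cellsize cell size in degrees.
#' @param nodata nodata sentinel used on disk (default -9999).
#' @param crs CRS identifier string.
#' @param scenario "current" or "future".
#' @return an `env_stack` object.
#' @export
env_stack <- function(layers, xll, yll, cellsize, nodata = -9999,
                      crs = "EPSG:4326", scenario = "current") {
  stopifnot(is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), all(nzchar(names(layers))))
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1) stop("layers are not co-registered")
  structure(list(layers = lapply(layers, as.matrix), xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = crs,
                 scenario = scenario),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("env_stack [%s]: %d layers, %d x %d cells at %.4g deg\n",
              x$scenario, length(x$layers), d[1], d[2], x$cellsize))
  cat(" layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

# cell-centre coordinates; rows run north -> south
stack_coords <- function(st) {
  d <- dim(st$layers[[1]])
  lon <- st$xll + (seq_len(d[2]) - 0.5) * st$cellsize
  lat <- st$yll + (d[1] - seq_len(d[1]) + 0.5) * st$cellsize
  list(lon = lon, lat = lat)
}

#' Extract layer values at point locations
#' @param st an `env_stack`.
#' @param lat,lon point coordinates (degrees).
#' @return data.frame, one column per layer.
#' @export
extract_at <- function(st, lat, lon) {
  d <- dim(st$layers[[1]])
  col <- floor((lon - st$xll) / st$cellsize) + 1
  row <- d[1] - floor((lat - st$yll) / st$cellsize)
  if (any(row < 1 | row > d[1] | col < 1 | col > d[2])) {
    stop("points outside the raster extent")
  }
  as.data.frame(lapply(st$layers, function(m) m[cbind(row, col)]))
}

#' Write one layer as an ESRI ASCII grid
#' @param st an `env_stack`.
#' @param layer layer name.
#' @param path output file.
#' @export
write_ascii_grid <- function(st, layer, path) {
  m <- st$layers[[layer]]
  if (is.null(m)) stop("no such layer: ", layer)
  m[is.na(m)] <- st$nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", st$xll),
           sprintf("yllcorner %.10g", st$yll),
           sprintf("cellsize %.10g", st$cellsize),
           sprintf("NODATA_value %.10g", st$nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid into a one-layer stack
#' @param path ASCII grid file.
#' @param name layer name (default: file base name).
#' @param scenario scenario tag.
#' @export
read_ascii_grid <- function(path, name = NULL,
                            scenario = "current") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  nod <- hdr[["nodata_value"]] %||% -9999
  m[m == nod] <- NA
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lay <- list(m)
  names(lay) <- name
  env_stack(lay, xll = hdr$xllcorner, yll = hdr$yllcorner,
            cellsize = hdr$cellsize, nodata = nod, scenario = scenario)
}

#' Region mask from a GeoJSON polygon
#'
#' Reads the first Polygon (or MultiPolygon part) of a GeoJSON file, or
#' accepts a two-column matrix of (lon, lat) vertices, and derives the
#' boolean in/out grid for a raster stack via point-in-polygon on cell
#' centres.
#'
#' @param polygon path to a GeoJSON file, or a matrix of vertices
#'   (lon, lat columns).
#' @param st an `env_stack` supplying the grid.
#' @return a `region_mask`: list with `polygon` and logical matrix `inside`.
#' @export
region_mask <- function(polygon, st) {
  if (is.character(polygon)) {
    gj <- jsonlite::read_json(polygon)
    geom <- if (!is.null(gj$features)) gj$features[[1]]$geometry else
      gj$geometry %||% gj
    ring <- if (identical(geom$type, "MultiPolygon"))
      geom$coordinates[[1]][[1]] else geom$coordinates[[1]]
    polygon <- do.call(rbind, lapply(ring, function(p)
      c(p[[1]], p[[2]])))
  }
  polygon <- as.matrix(polygon)
  cc <- stack_coords(st)
  pts <- cbind(rep(cc$lon, each = length(cc$lat)),
               rep(cc$lat, times = length(cc$lon)))
  inside_vec <- mgcv::in.out(rbind(polygon, polygon[1, ]), pts)
  inside <- matrix(inside_vec, nrow = length(cc$lat), ncol = length(cc$lon))
  if (!any(inside)) stop("mask contains no raster cells")
  structure(list(polygon = polygon, inside = inside),
            class = "region_mask")
}

#' Full-extent mask covering every cell of a stack
#' @param st an `env_stack`.
#' @export
full_mask <- function(st) {
  d <- dim(st$layers[[1]])
  cc <- stack_coords(st)
  poly <- cbind(c(st$xll, st$xll + d[2] * st$cellsize,
                  st$xll + d[2] * st$cellsize, st$xll),
                c(st$yll, st$yll, st$yll + d[1] * st$cellsize,
                  st$yll + d[1] * st$cellsize))
  structure(list(polygon = poly,
                 inside = matrix(TRUE, d[1], d[2])),
            class = "region_mask")
}
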