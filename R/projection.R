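#' Transform an environmental stack through fitted GDM splines
#'
#' Maps every environmental layer cellwise through its fitted partial
#' spline f_p, and adds two geographic layers obtained by evaluating the
#' fitted geographic spline on each cell's easting and northing offsets (in
#' great-circle km) from the mask's west and south edges. Out-of-range
#' values are clamped to the training range and counted.
#'
#' @param model a `gdm_model`.
#' @param st an `env_stack` covering all model predictors.
#' @param mask a `region_mask` (default: full extent).
#' @param include_geography add the two geographic layers (default TRUE).
#' @return a `projection_result`: list with `transformed` (env_stack),
#'   `clamp_count`, `model_deviance_explained`, `scenario`.
#' @export
transform_environment <- function(model, st, mask = full_mask(st),
                                  include_geography = TRUE) {
  env_preds <- setdiff(model$predictors, "geographic")
  missing <- setdiff(env_preds, names(st$layers))
  if (length(missing)) stop("missing predictor layer: ",
                            paste(missing, collapse = ", "))
  inside <- mask$inside
  clamp <- 0L
  out <- list()
  for (p in env_preds) {
    m <- st$layers[[p]]
    f <- partial_response(model, p, as.numeric(m))
    clamp <- clamp + attr(f, "n_clamped")
    fm <- matrix(as.numeric(f), nrow(m), ncol(m))
    fm[!inside | is.na(m)] <- NA
    out[[p]] <- fm
  }
  if (include_geography) {
    cc <- stack_coords(st)
    d <- dim(st$layers[[1]])
    lon0 <- min(cc$lon[colSums(inside) > 0])
    lat0 <- min(cc$lat[rowSums(inside) > 0])
    # easting: along-parallel distance from the mask's west edge;
    # northing: along-meridian distance from the mask's south edge
    east_km <- outer(cc$lat, cc$lon, function(la, lo)
      haversine_km(la, lon0, la, lo))
    north_km <- matrix(rep(haversine_km(lat0, 0, cc$lat, 0), d[2]),
                       d[1], d[2])
    fe <- partial_response(model, "geographic", as.numeric(east_km))
    fn <- partial_response(model, "geographic", as.numeric(north_km))
    clamp <- clamp + attr(fe, "n_clamped") + attr(fn, "n_clamped")
    ge <- matrix(as.numeric(fe), d[1], d[2])
    gn <- matrix(as.numeric(fn), d[1], d[2])
    ge[!inside] <- NA
    gn[!inside] <- NA
    out[["geo_easting"]] <- ge
    out[["geo_northing"]] <- gn
  }
  structure(list(
    transformed = env_stack(out, xll = st$xll, yll = st$yll,
                            cellsize = st$cellsize, nodata = st$nodata,
                            crs = st$crs, scenario = st$scenario),
    mask = mask, clamp_count = clamp,
    scenario = st$scenario), class = "projection_result")
}

# scalar/vector haversine on the package's spherical Earth
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' PCA RGB genomic-composition map
#'
#' Runs a centred PCA over in-mask cells of a transformed stack (layers as
#' variables), rescales the first three principal components linearly to
#' [0, 255] and assigns them to the red, green and blue channels. Regions
#' with similar colours are predicted to hold similar genomic composition.
#'
#' @param proj a `projection_result` from [transform_environment()].
#' @return the `projection_result` with elements `rgb` (rows x cols x 3
#'   array), `loadings`, `percent_variance` added.
#' @export
pca_rgb <- function(proj) {
  st <- proj$transformed
  inside <- proj$mask$inside & Reduce(`&`, lapply(st$layers, function(m)
    !is.na(m)))
  vals <- vapply(st$layers, function(m) m[inside],
                 numeric(sum(inside)))
  keep <- apply(vals, 2, stats::sd) > 0
  if (sum(keep) < 3) {
    stop("fewer than three transformed layers with variance inside the ",
         "mask; consider an environment-only or reduced-channel map")
  }
  pca <- stats::prcomp(vals[, keep, drop = FALSE], center = TRUE,
                       scale. = FALSE)
  d <- dim(st$layers[[1]])
  rgb_arr <- array(NA_real_, c(d[1], d[2], 3))
  for (k in 1:3) {
    pc <- pca$x[, k]
    rng <- range(pc)
    chan <- if (diff(rng) > 0) 255 * (pc - rng[1]) / diff(rng) else
      rep(127.5, length(pc))
    plane <- matrix(NA_real_, d[1], d[2])
    plane[inside] <- chan
    rgb_arr[, , k] <- plane
  }
  proj$rgb <- rgb_arr
  proj$loadings <- pca$rotation[, 1:3, drop = FALSE]
  proj$percent_variance <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  proj
}

#' Genomic vulnerability under a future scenario
#'
#' Per cell, the GDM-predicted dissimilarity between the cell's current and
#' future environments at zero geographic distance:
#' `1 - exp(-sum_p |f_p(current) - f_p(future)|)`. The intercept is excluded
#' by default (it encodes the baseline dissimilarity of distinct samples and
#' would put a constant floor under same-place comparisons).
#'
#' @param model a `gdm_model`.
#' @param current,future co-registered `env_stack`s with the model's
#'   predictors.
#' @param mask a `region_mask` (default: full extent).
#' @param include_intercept include beta0 (default FALSE).
#' @return numeric matrix in [0, 1); NA outside the mask.
#' @export
genomic_vulnerability <- function(model, current, future,
                                  mask = full_mask(current),
                                  include_intercept = FALSE) {
  if (!identical(dim(current$layers[[1]]), dim(future$layers[[1]]))) {
    stop("current and future stacks are not co-registered")
  }
  if (identical(current$scenario, "current") &&
      identical(future$scenario, "current")) {
    warning("both stacks are tagged 'current'")
  }
  env_preds <- setdiff(model$predictors, "geographic")
  missing <- setdiff(env_preds, c(names(current$layers)))
  if (length(missing)) stop("missing predictor layer: ",
                            paste(missing, collapse = ", "))
  d <- dim(current$layers[[1]])
  eta <- matrix(if (include_intercept) model$intercept else 0, d[1], d[2])
  na_any <- matrix(FALSE, d[1], d[2])
  for (p in env_preds) {
    cur <- current$layers[[p]]
    fut <- future$layers[[p]]
    na_any <- na_any | is.na(cur) | is.na(fut)
    fc <- as.numeric(partial_response(model, p, as.numeric(cur)))
    ff <- as.numeric(partial_response(model, p, as.numeric(fut)))
    dd <- abs(fc - ff)
    dd[is.na(dd)] <- 0
    eta <- eta + matrix(dd, d[1], d[2])
  }
  v <- 1 - exp(-eta)
  v[!mask$inside | na_any] <- NA
  v
}

#' Seed-source matching map for a restoration site
#'
#' Per cell, the GDM-predicted dissimilarity between the target site under
#' its future environment and the cell under its current environment,
#' including the geographic spline evaluated at the great-circle distance
#' between target and cell centre. Low values mark good seed sources.
#'
#' @param model a `gdm_model`.
#' @param target c(lat, lon) of the restoration site (inside the mask).
#' @param future_env_at_target named vector: future values of every model
#'   predictor at the target.
#' @param current `env_stack` of current conditions.
#' @param mask a `region_mask` (default: full extent).
#' @param include_intercept include beta0 (default FALSE).
#' @return numeric matrix in [0, 1); NA outside the mask.
#' @export
seed_source_map <- function(model, target, future_env_at_target, current,
                            mask = full_mask(current),
                            include_intercept = FALSE) {
  env_preds <- setdiff(model$predictors, "geographic")
  missing <- setdiff(env_preds, names(future_env_at_target))
  if (length(missing)) stop("missing future predictor value: ",
                            paste(missing, collapse = ", "))
  d <- dim(current$layers[[1]])
  cc <- stack_coords(current)
  tcol <- floor((target[2] - current$xll) / current$cellsize) + 1
  trow <- d[1] - floor((target[1] - current$yll) / current$cellsize)
  if (trow < 1 || trow > d[1] || tcol < 1 || tcol > d[2] ||
      !mask$inside[trow, tcol]) {
    stop("target lies outside the mask")
  }
  eta <- matrix(if (include_intercept) model$intercept else 0, d[1], d[2])
  na_any <- matrix(FALSE, d[1], d[2])
  for (p in env_preds) {
    cur <- current$layers[[p]]
    na_any <- na_any | is.na(cur)
    fc <- as.numeric(partial_response(model, p, as.numeric(cur)))
    ft <- as.numeric(partial_response(model, p,
                                      future_env_at_target[[p]]))
    dd <- abs(fc - ft)
    dd[is.na(dd)] <- 0
    eta <- eta + matrix(dd, d[1], d[2])
  }
  lonm <- matrix(rep(cc$lon, each = d[1]), d[1], d[2])
  latm <- matrix(rep(cc$lat, times = d[2]), d[1], d[2])
  gd <- matrix(haversine_km(target[1], target[2], as.numeric(latm),
                            as.numeric(lonm)), d[1], d[2])
  eta <- eta + matrix(
    as.numeric(partial_response(model, "geographic", as.numeric(gd))),
    d[1], d[2])
  m <- 1 - exp(-eta)
  m[!mask$inside | na_any] <- NA
  m
}

#' Write an RGB array as PNG with a world file
#'
#' Optional visual export; requires the `png` package.
#'
#' @param rgb_arr rows x cols x 3 array in [0, 255] (NA allowed).
#' @param st the `env_stack` that supplied the grid.
#' @param path output PNG path.
#' @export
write_rgb_png <- function(rgb_arr, st, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  a <- rgb_arr / 255
  alpha <- 1 - is.na(a[, , 1])
  a[is.na(a)] <- 0
  img <- array(0, c(dim(a)[1], dim(a)[2], 4))
  img[, , 1:3] <- a
  img[, , 4] <- alpha
  png::writePNG(img, path)
  wld <- c(st$cellsize, 0, 0, -st$cellsize,
           st$xll + st$cellsize / 2,
           st$yll + nrow(st$layers[[1]]) * st$cellsize - st$cellsize / 2)
  writeLines(format(wld, digits = 12), sub("\\.png$", ".pgw", path))
  invisible(path)
}
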