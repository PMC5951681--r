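#' Construct a site table
#'
#' Per-site coordinates (WGS84 decimal degrees) and named environmental
#' values: the predictor side of a generalized dissimilarity model.
#'
#' @param site_id character site identifiers (unique).
#' @param lat,lon coordinates in decimal degrees.
#' @param env data.frame (or NULL) of named environmental values, one row
#'   per site; must be complete for sites entering a GDM.
#' @return a `site_table` data.frame.
#' @export
site_table <- function(site_id, lat, lon, env = NULL) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) stop("site ids must be unique")
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    stop("coordinates out of range")
  }
  df <- data.frame(site_id = site_id, lat = lat, lon = lon,
                   stringsAsFactors = FALSE)
  if (!is.null(env)) {
    stopifnot(nrow(env) == length(site_id))
    df <- cbind(df, env)
  }
  class(df) <- c("site_table", "data.frame")
  df
}

#' Names of the environmental columns of a site table
#' @param sites a `site_table`.
#' @export
env_names <- function(sites) {
  setdiff(names(sites), c("site_id", "lat", "lon", "n_genotyped"))
}

# authalic Earth radius, km
EARTH_RADIUS_KM <- 6371.0087714

#' Great-circle distances between sites or samples
#'
#' Haversine distances on a sphere of authalic radius 6371.0087714 km.
#'
#' @param lat,lon coordinate vectors in decimal degrees, or a `site_table`
#'   passed as `lat` (then `lon` is ignored and labels are site ids).
#' @param labels optional labels for the output matrix.
#' @return a `pairwise_matrix` of kind "geographic", in km.
#' @export
geographic_distance <- function(lat, lon = NULL, labels = NULL) {
  if (inherits(lat, "site_table") || (is.data.frame(lat) &&
      all(c("lat", "lon") %in% names(lat)))) {
    labels <- labels %||% lat$site_id %||% as.character(seq_len(nrow(lat)))
    lon <- lat$lon
    lat <- lat$lat
  }
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    stop("coordinates out of range")
  }
  labels <- labels %||% as.character(seq_along(lat))
  pts <- cbind(lon, lat)
  n <- nrow(pts)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts,
                                       r = EARTH_RADIUS_KM * 1000) / 1000
  }
  m <- (m + t(m)) / 2
  pairwise_matrix(m, labels = labels, kind = "geographic")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: double-centre -0.5 * D^2, eigendecompose, and scale
#' eigenvectors by sqrt(lambda) for the positive eigenvalues. Percent
#' variance per axis is computed from the positive eigenvalues only.
#'
#' @param dm a symmetric distance matrix (zero diagonal).
#' @param n_axes number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return an `ordination_result`: list with `coordinates`, `eigenvalues`,
#'   `percent_variance`.
#' @export
pcoa <- function(dm, n_axes = NULL) {
  m <- as.matrix(dm)
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(m)
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # positive subset is exactly what classical scaling keeps
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(eig) * 1e-12 & eig > 0
  coords <- fit$points[, seq_len(sum(pos[seq_len(ncol(fit$points))])),
                       drop = FALSE]
  pct <- 100 * eig[pos] / sum(eig[pos])
  k <- min(n_axes %||% ncol(coords), ncol(coords))
  rownames(coords) <- rownames(m)
  structure(list(coordinates = coords[, seq_len(k), drop = FALSE],
                 eigenvalues = eig[pos][seq_len(k)],
                 percent_variance = pct[seq_len(k)]),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("PCoA: %d items, %d axes; first axes explain %s%%\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f", utils::head(x$percent_variance, 3)),
                    collapse = "/")))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over lower-triangle pairs, with a one-sided
#' permutation p-value under simultaneous row/column permutation of the
#' second matrix: `p = (1 + #\{r* >= r\}) / (n_perm + 1)`. With
#' `transform_b = "log"` the second matrix is natural-log transformed first;
#' zero off-diagonal distances (co-located samples) are set to 0.001 km
#' (1 m) before the log, and the number of such pairs is recorded.
#'
#' @param dm_a,dm_b `pairwise_matrix` objects with identical labels.
#' @param n_perm number of permutations (default 9999).
#' @param transform_b "none" or "log".
#' @param exhaustive if TRUE, enumerate all permutations instead of sampling
#'   (only feasible for small matrices).
#' @param seed optional integer seed.
#' @return a `mantel_result`: list with `r`, `r_squared`, `p_value`,
#'   `n_perm`, `n_zero_distance`.
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 9999,
                        transform_b = c("log", "none"),
                        exhaustive = FALSE, seed = NULL) {
  transform_b <- match.arg(transform_b)
  if (!identical(rownames(dm_a), rownames(dm_b))) {
    stop("label mismatch between distance matrices")
  }
  a <- as.matrix(dm_a)
  b <- as.matrix(dm_b)
  n_zero <- 0L
  if (transform_b == "log") {
    off <- row(b) != col(b)
    zero <- off & b <= 0
    n_zero <- sum(zero) / 2
    b[zero] <- 0.001
    b[off] <- log(b[off])
  }
  n <- nrow(a)
  lt <- lower.tri(a)
  av <- a[lt]
  r_obs <- stats::cor(av, b[lt])
  av_c <- av - mean(av)
  ss_a <- sqrt(sum(av_c^2))
  perm_r <- function(p) {
    bv <- b[p, p][lt]
    bv_c <- bv - mean(bv)
    sum(av_c * bv_c) / (ss_a * sqrt(sum(bv_c^2)))
  }
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    # identity permutation included: p over all n! orderings
    p <- sum(rs >= r_obs - 1e-12) / length(rs)
    n_perm <- length(rs) - 1L
  } else {
    if (!is.null(seed)) set.seed(seed)
    rs <- vapply(seq_len(n_perm), function(i) perm_r(sample.int(n)),
                 numeric(1))
    p <- (1 + sum(rs >= r_obs - 1e-12)) / (n_perm + 1)
  }
  structure(list(r = r_obs, r_squared = r_obs^2, p_value = p,
                 n_perm = n_perm, n_zero_distance = n_zero,
                 transform_b = transform_b),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f (r^2 = %.4f), p = %.5g (%d permutations)\n",
              x$r, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

# all permutations of 1..n as a list (for exhaustive Mantel enumeration)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}
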