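#' Weir-Cockerham variance components for a set of populations
#'
#' Multilocus Weir & Cockerham (1984) theta, computed as the ratio of summed
#' variance components sum(a) / sum(a + b + c) over loci polymorphic in the
#' populations considered (ratio-of-averages combining). Works for two or
#' more populations; loci where fewer than two populations have at least one
#' called genotype, or that are monomorphic across the populations, are
#' skipped.
#'
#' @param gm a `genotype_matrix`.
#' @param sites character vector of site ids to include (default: all).
#' @return list with `theta` (multilocus estimate), and per-locus component
#'   matrices `a`, `b`, `c` (NA where a locus was skipped).
#' @export
wc_fst_components <- function(gm, sites = NULL) {
  sites <- sites %||% unique(gm$samples$site_id)
  r <- length(sites)
  if (r < 2) stop("need at least two sites")
  x <- gm$calls
  L <- ncol(x)
  # per-site per-locus: n (called diploids), p (alt freq), h (obs het freq)
  n_mat <- p_mat <- h_mat <- matrix(NA_real_, r, L)
  for (i in seq_len(r)) {
    rows <- gm$samples$site_id == sites[i]
    if (!any(rows)) stop("site not present in genotype matrix: ", sites[i])
    xi <- x[rows, , drop = FALSE]
    n <- colSums(!is.na(xi))
    n_mat[i, ] <- n
    p_mat[i, ] <- ifelse(n > 0, colSums(xi, na.rm = TRUE) / (2 * n), NA)
    h_mat[i, ] <- ifelse(n > 0, colMeans(xi == 1, na.rm = TRUE), NA)
  }
  use <- colSums(n_mat > 0) == r
  # require >= 2 samples somewhere per site overall
  for (i in seq_len(r)) {
    if (!any(n_mat[i, ] >= 2)) {
      stop("site has fewer than two genotyped samples at every locus: ",
           sites[i])
    }
  }
  nbar <- colMeans(n_mat)
  sum_n <- colSums(n_mat)
  sum_n2 <- colSums(n_mat^2)
  nc <- (sum_n - sum_n2 / sum_n) / (r - 1)
  pbar <- colSums(n_mat * p_mat) / sum_n
  s2 <- colSums(n_mat * sweep(p_mat, 2, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(n_mat * h_mat) / sum_n
  poly <- use & pbar > 0 & pbar < 1 & nbar > 1 & nc > 0
  a <- b <- cc <- rep(NA_real_, L)
  w <- which(poly)
  if (length(w)) {
    nb <- nbar[w]; ncw <- nc[w]; pb <- pbar[w]; s2w <- s2[w]; hb <- hbar[w]
    a[w] <- (nb / ncw) *
      (s2w - (1 / (nb - 1)) * (pb * (1 - pb) - ((r - 1) / r) * s2w - hb / 4))
    b[w] <- (nb / (nb - 1)) *
      (pb * (1 - pb) - ((r - 1) / r) * s2w - ((2 * nb - 1) / (4 * nb)) * hb)
    cc[w] <- hb / 2
  }
  denom <- sum(a + b + cc, na.rm = TRUE)
  theta <- if (length(w) == 0 || denom == 0) NA_real_ else
    sum(a[w]) / denom
  list(theta = theta, a = a, b = b, c = cc, n_loci_used = length(w))
}

#' Pairwise Weir-Cockerham Fst between sites
#'
#' Two-population multilocus Weir-Cockerham theta for every pair of sites.
#' Estimates may be slightly negative; the diagonal is 0. Use
#' [scale_unit_interval()] before dissimilarity modelling.
#'
#' @param gm a `genotype_matrix` with site assignments.
#' @return a `pairwise_matrix` of kind "fst".
#' @export
pairwise_fst_wc <- function(gm) {
  sites <- unique(gm$samples$site_id)
  S <- length(sites)
  if (S < 2) stop("need at least two sites")
  for (s in sites) {
    rows <- gm$samples$site_id == s
    n <- colSums(!is.na(gm$calls[rows, , drop = FALSE]))
    if (!any(n >= 2)) {
      stop("site has fewer than two genotyped samples at every locus: ", s)
    }
  }
  L <- ncol(gm$calls)
  n_mat <- p_mat <- h_mat <- matrix(NA_real_, S, L)
  for (i in seq_len(S)) {
    rows <- gm$samples$site_id == sites[i]
    xi <- gm$calls[rows, , drop = FALSE]
    n <- colSums(!is.na(xi))
    n_mat[i, ] <- n
    p_mat[i, ] <- ifelse(n > 0, colSums(xi, na.rm = TRUE) / (2 * n), NA)
    h_mat[i, ] <- ifelse(n > 0, colMeans(xi == 1, na.rm = TRUE), NA)
  }
  m <- matrix(0, S, S)
  for (i in seq_len(S - 1)) {
    for (j in seq(i + 1, S)) {
      th <- wc_theta_pair(n_mat[i, ], p_mat[i, ], h_mat[i, ],
                          n_mat[j, ], p_mat[j, ], h_mat[j, ])
      m[i, j] <- m[j, i] <- th
    }
  }
  pairwise_matrix(m, labels = sites, kind = "fst")
}

# two-population multilocus WC84 theta from per-site per-locus summaries
wc_theta_pair <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  use <- n1 > 0 & n2 > 0
  nbar <- (n1 + n2) / 2
  sum_n <- n1 + n2
  nc <- (sum_n - (n1^2 + n2^2) / sum_n) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / sum_n
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / sum_n
  poly <- use & !is.na(pbar) & pbar > 0 & pbar < 1 & nbar > 1 & nc > 0
  if (!any(poly)) return(NA_real_)
  nb <- nbar[poly]; ncw <- nc[poly]; pb <- pbar[poly]
  s2w <- s2[poly]; hb <- hbar[poly]
  a <- (nb / ncw) *
    (s2w - (1 / (nb - 1)) * (pb * (1 - pb) - ((r - 1) / r) * s2w - hb / 4))
  b <- (nb / (nb - 1)) *
    (pb * (1 - pb) - ((r - 1) / r) * s2w - ((2 * nb - 1) / (4 * nb)) * hb)
  cc <- hb / 2
  sum(a) / sum(a + b + cc)
}

#' Multilocus Fst with a locus bootstrap
#'
#' Global multilocus Weir-Cockerham theta over the given sites, plus
#' bootstrap replicates obtained by resampling loci with replacement and
#' recomputing the ratio of summed components.
#'
#' @param gm a `genotype_matrix`.
#' @param sites site ids to include.
#' @param n_boot number of bootstrap replicates (0 = none).
#' @return list with `theta` and numeric vector `boot`.
#' @export
multilocus_fst <- function(gm, sites = NULL, n_boot = 0) {
  comp <- wc_fst_components(gm, sites = sites)
  ok <- which(!is.na(comp$a))
  if (length(ok) == 0) stop("no polymorphic loci in the selected sites")
  a <- comp$a[ok]; tot <- a + comp$b[ok] + comp$c[ok]
  boot <- numeric(0)
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(a), replace = TRUE)
      sum(a[idx]) / sum(tot[idx])
    }, numeric(1))
  }
  list(theta = comp$theta, boot = boot, n_loci_used = length(ok))
}
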