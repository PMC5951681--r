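# Small in-code fixtures shared across tests.

# genotype matrix with explicit calls; sites assigned round-robin
make_gm <- function(calls, n_sites = 2, positions = NULL, chrom = "chr1") {
  n <- nrow(calls)
  L <- ncol(calls)
  loci <- data.frame(chrom = chrom,
                     pos = positions %||% seq(1, by = 1000, length.out = L),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    site_id = sprintf("P%d", rep_len(seq_len(n_sites), n)),
    stringsAsFactors = FALSE)
  genotype_matrix(calls, loci, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-site genotype matrix from per-site call blocks
make_gm_sites <- function(...) {
  blocks <- list(...)
  calls <- do.call(rbind, blocks)
  n_per <- vapply(blocks, nrow, integer(1))
  loci <- data.frame(chrom = "chr1",
                     pos = seq(1, by = 1000, length.out = ncol(calls)),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(calls))),
    site_id = rep(sprintf("P%d", seq_along(blocks)), n_per),
    stringsAsFactors = FALSE)
  genotype_matrix(calls, loci, samples)
}

# a small site table with env columns drawn deterministically
make_sites <- function(S, n_env = 2, seed = 42) {
  set.seed(seed)
  env <- as.data.frame(matrix(rnorm(S * n_env), S, n_env))
  names(env) <- paste0("env", seq_len(n_env))
  site_table(sprintf("S%02d", seq_len(S)),
             lat = runif(S, -38, -28), lon = runif(S, 141, 152),
             env = env)
}

# pair table + noiseless response generated from known coefficients
make_known_world <- function(S = 12, n_env = 2, seed = 9,
                             intercept = 0.05,
                             coefs = list(c(0.2, 0.1, 0.1),
                                          c(0.05, 0.05, 0.05)),
                             geo_coefs = c(0.05, 0.1, 0.1),
                             noise_sd = 0) {
  sites <- make_sites(S, n_env = n_env, seed = seed)
  geo <- geographic_distance(sites)
  # build a provisional pair table to reuse its basis-difference columns
  resp0 <- pairwise_matrix(matrix(0.5, S, S), labels = sites$site_id,
                           kind = "scaled_fst")
  pt <- make_pair_table(sites, paste0("env", seq_len(n_env)), resp0, geo)
  beta <- c(unlist(coefs[seq_len(n_env)]), geo_coefs)
  eta <- intercept + drop(pt$X %*% beta)
  mu <- 1 - exp(-eta)
  set.seed(seed + 1)
  d <- pmin(pmax(mu + rnorm(length(mu), 0, noise_sd), 0), 1)
  resp <- matrix(0, S, S, dimnames = list(sites$site_id, sites$site_id))
  resp[cbind(match(pt$pairs$site_a, sites$site_id),
             match(pt$pairs$site_b, sites$site_id))] <- d
  resp <- pairwise_matrix(resp + t(resp), labels = sites$site_id,
                          kind = "scaled_fst")
  pt$d <- d
  pt$pairs$d <- d
  list(sites = sites, geo = geo, pt = pt, response = resp,
       mu_true = mu, eta_true = eta, beta = beta, intercept = intercept)
}

# world whose generating truth is smooth (not an exact I-spline), of the
# form eta = sum_p |g_p(x_i) - g_p(x_j)| + f_geo(d): representable to high
# accuracy by any subset's spline basis
make_smooth_world <- function(S = 30, seed = 9, noise_sd = 0) {
  sites <- make_sites(S, n_env = 2, seed = seed)
  geo <- geographic_distance(sites)
  ids <- sites$site_id
  ii <- rep(seq_len(S - 1), times = (S - 1):1)
  jj <- unlist(lapply(seq_len(S - 1), function(i) seq(i + 1, S)))
  g1 <- 0.5 * pnorm(sites$env1)
  g2 <- 0.3 * pnorm(sites$env2 / 1.5)
  gd <- as.matrix(geo)[cbind(ii, jj)]
  eta <- 0.05 + abs(g1[ii] - g1[jj]) + abs(g2[ii] - g2[jj]) +
    0.3 * (gd / max(gd))^1.5
  mu <- 1 - exp(-eta)
  set.seed(seed + 1)
  d <- pmin(pmax(mu + rnorm(length(mu), 0, noise_sd), 0), 1)
  resp <- matrix(0, S, S, dimnames = list(ids, ids))
  resp[cbind(ii, jj)] <- d
  resp <- pairwise_matrix(resp + t(resp), labels = ids,
                          kind = "scaled_fst")
  list(sites = sites, geo = geo, response = resp, mu_true = mu)
}

# tiny env stack with named layers built from a function of (row, col)
make_stack <- function(layers, nr = 6, nc = 8, scenario = "current") {
  env_stack(layers, xll = 145, yll = -35, cellsize = 0.25,
            scenario = scenario)
}
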