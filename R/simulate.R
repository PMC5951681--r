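#' Configuration of a synthetic landscape-genomics world
#'
#' Bundles every knob of the synthetic generator with defaults that emulate
#' the study design this package targets: 36 sampling sites with 3-10
#' genotyped trees each, 9,378 biallelic SNPs, pairwise Fst of roughly
#' 0.02-0.10 structured by geographic and environmental distance, four
#' environmental drivers plus geography with a flat-to-500-km geographic
#' effect, and maternal half-sib phenotypes with site/family/residual
#' variance components. The master seed fixes every downstream draw.
#'
#' @param n_rows,n_cols grid dimension (cells).
#' @param cellsize cell size in degrees (~0.25 deg = ~25 km N-S).
#' @param xll,yll lower-left corner of the grid (degrees).
#' @param n_drivers environmental layers that truly shape differentiation.
#' @param n_noise extra environmental layers with no effect.
#' @param corr_length Gaussian-field correlation length, in cells.
#' @param n_sites number of sampling sites.
#' @param samples_per_site inclusive range of genotyped trees per site.
#' @param n_loci number of biallelic SNPs.
#' @param missing_rate genotype missingness rate.
#' @param intercept true GDM intercept (baseline dissimilarity).
#' @param env_coefs list of length `n_drivers`; each a non-negative
#'   3-vector of I-spline coefficients (partial response maxima sum them).
#' @param geo_effect list: `type` "threshold" (flat to `threshold_km`, then
#'   linear to `max_effect` at `ref_km`) or "ispline" with `coefs`.
#' @param freq_scale s: sd of site logit-frequency deviations; pairwise
#'   covariance is `s^2 * exp(-eta_true)`.
#' @param phenotype list: `sigma2_fam`, `sigma2_res`, `condition_effect`,
#'   `neutral` (derive site variance from realized Fst), `site_inflation`
#'   (multiplier on the neutral site variance; 1 = neutral).
#' @param future list: per-layer `shift` (in sd units) and `gradient`
#'   (north-south, in sd units across the grid) for the future scenario.
#' @param seed master seed.
#' @return a `world_config` list.
#' @export
world_config <- function(n_rows = 40, n_cols = 48, cellsize = 0.25,
                         xll = 141, yll = -38,
                         n_drivers = 4, n_noise = 0, corr_length = 6,
                         n_sites = 36, samples_per_site = c(3, 10),
                         n_loci = 9378, missing_rate = 0.05,
                         intercept = 0,
                         env_coefs = NULL,
                         geo_effect = list(type = "threshold",
                                           threshold_km = 500,
                                           ref_km = 1200,
                                           max_effect = 0.6),
                         freq_scale = 0.8,
                         phenotype = list(sigma2_fam = 1, sigma2_res = 4,
                                          condition_effect = 0.5,
                                          neutral = TRUE,
                                          site_inflation = 1),
                         future = list(shift = 1, gradient = 0.5),
                         seed = 1) {
  if (is.null(env_coefs)) {
    base <- c(0.45, 0.3, 0.2, 0.12, 0.1, 0.1)
    env_coefs <- lapply(seq_len(n_drivers), function(i)
      rep(base[min(i, length(base))] / 3, 3))
  }
  stopifnot(n_rows > 0, n_cols > 0, n_sites > 1, n_loci > 0,
            corr_length < min(n_rows, n_cols),
            all(unlist(env_coefs) >= 0))
  structure(list(n_rows = n_rows, n_cols = n_cols, cellsize = cellsize,
                 xll = xll, yll = yll, n_drivers = n_drivers,
                 n_noise = n_noise, corr_length = corr_length,
                 n_sites = n_sites, samples_per_site = samples_per_site,
                 n_loci = n_loci, missing_rate = missing_rate,
                 intercept = intercept, env_coefs = env_coefs,
                 geo_effect = geo_effect, freq_scale = freq_scale,
                 phenotype = phenotype, future = future, seed = seed),
            class = "world_config")
}

# one Gaussian random field: smoothed seeded white noise, standardized
grf_layer <- function(n_rows, n_cols, corr_length) {
  pad <- ceiling(3 * corr_length)
  z <- matrix(stats::rnorm((n_rows + 2 * pad) * (n_cols + 2 * pad)),
              n_rows + 2 * pad, n_cols + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = corr_length)
  k <- k / sum(k)
  sm_rows <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm_rows, 1, function(row) stats::filter(row, k, sides = 2)))
  core <- sm[pad + seq_len(n_rows), pad + seq_len(n_cols)]
  (core - mean(core)) / stats::sd(core)
}

#' Generate current and future environmental raster stacks
#'
#' Each layer is a Gaussian random field (seeded white noise smoothed with a
#' Gaussian kernel of the configured correlation length), standardized to
#' mean 0 and sd 1. The future stack adds the configured per-layer shift
#' plus a north-south gradient. Deterministic per seed.
#'
#' @param cfg a `world_config`.
#' @return list with `current` and `future` `env_stack`s.
#' @export
generate_environment <- function(cfg) {
  if (cfg$corr_length >= min(cfg$n_rows, cfg$n_cols)) {
    stop("correlation length must be smaller than the grid extent")
  }
  set.seed(derive_seed(cfg$seed, "environment"))
  n_layers <- cfg$n_drivers + cfg$n_noise
  layers <- lapply(seq_len(n_layers), function(i)
    grf_layer(cfg$n_rows, cfg$n_cols, cfg$corr_length))
  names(layers) <- c(paste0("env", seq_len(cfg$n_drivers)),
                     if (cfg$n_noise > 0)
                       paste0("noise", seq_len(cfg$n_noise)))
  cur <- env_stack(layers, xll = cfg$xll, yll = cfg$yll,
                   cellsize = cfg$cellsize, scenario = "current")
  ns <- (row(layers[[1]]) - 1) / max(1, cfg$n_rows - 1)  # 0 north, 1 south
  fut_layers <- lapply(layers, function(m)
    m + cfg$future$shift + cfg$future$gradient * (0.5 - ns))
  fut <- env_stack(fut_layers, xll = cfg$xll, yll = cfg$yll,
                   cellsize = cfg$cellsize, scenario = "future")
  list(current = cur, future = fut)
}

#' Place sampling sites on the synthetic landscape
#'
#' Draws distinct cells uniformly at random and records cell-centre
#' coordinates and environmental values.
#'
#' @param cfg a `world_config`.
#' @param st the current `env_stack`.
#' @return a `site_table` with environmental columns.
#' @export
generate_sites <- function(cfg, st) {
  set.seed(derive_seed(cfg$seed, "sites"))
  d <- dim(st$layers[[1]])
  cells <- sample.int(d[1] * d[2], cfg$n_sites)
  rows <- (cells - 1) %% d[1] + 1
  cols <- (cells - 1) %/% d[1] + 1
  cc <- stack_coords(st)
  env <- as.data.frame(lapply(st$layers, function(m) m[cbind(rows, cols)]))
  site_table(site_id = sprintf("S%02d", seq_len(cfg$n_sites)),
             lat = cc$lat[rows], lon = cc$lon[cols], env = env)
}

# the generating linear predictor eta for all unordered site pairs
true_eta <- function(cfg, sites, geo = NULL) {
  ids <- sites$site_id
  S <- length(ids)
  ii <- rep(seq_len(S - 1), times = (S - 1):1)
  jj <- unlist(lapply(seq_len(S - 1), function(i) seq(i + 1, S)))
  eta <- rep(cfg$intercept, length(ii))
  bases <- list()
  for (k in seq_len(cfg$n_drivers)) {
    nm <- paste0("env", k)
    b <- build_ispline_basis(sites[[nm]], n_basis = 3, name = nm)
    I <- eval_ispline(b, sites[[nm]])
    eta <- eta + drop(abs(I[ii, , drop = FALSE] - I[jj, , drop = FALSE])
                      %*% cfg$env_coefs[[k]])
    bases[[nm]] <- b
  }
  geo <- geo %||% geographic_distance(sites)
  gd <- as.matrix(geo)[cbind(ii, jj)]
  ge <- cfg$geo_effect
  fgeo <- if (identical(ge$type, "threshold")) {
    # smooth flat-to-rising effect: zero value and slope at the threshold,
    # quadratic rise reaching max_effect at ref_km (and beyond)
    ge$max_effect * pmin(1, pmax(0, gd - ge$threshold_km) /
                           (ge$ref_km - ge$threshold_km))^2
  } else {
    gk <- geo_knots(gd, length(ge$coefs))
    gb <- structure(list(name = "geographic", n_basis = length(ge$coefs),
                         knots = gk, range = c(0, max(gd))),
                    class = "ispline_basis")
    drop(eval_ispline(gb, gd) %*% ge$coefs)
  }
  list(ii = ii, jj = jj, eta = eta + fgeo, eta_env = eta, f_geo = fgeo,
       distance_km = gd, bases = bases, geo = geo)
}

#' Generate genotypes with differentiation keyed to the true model
#'
#' Per locus, an ancestral frequency p0 ~ Uniform(0.1, 0.9); site
#' logit-scale deviations are drawn from a multivariate normal whose
#' covariance is `s^2 * exp(-eta_true)` for each site pair, so expected
#' differentiation grows monotonically with the generating linear
#' predictor. Site frequencies are logistic-transformed and genotypes drawn
#' Binomial(2, p); an optional missingness mask is applied.
#'
#' @param cfg a `world_config`.
#' @param sites a `site_table` from [generate_sites()].
#' @return list: `gm` (a `genotype_matrix`) and `truth` (a `truth_record`:
#'   per-pair eta and mu, driver identities, bases, sub-seeds).
#' @export
generate_genotypes <- function(cfg, sites) {
  te <- true_eta(cfg, sites)
  S <- nrow(sites)
  C <- matrix(0, S, S)
  C[cbind(te$ii, te$jj)] <- exp(-te$eta)
  C <- C + t(C)
  diag(C) <- 1
  C <- cfg$freq_scale^2 * C
  ch <- tryCatch(chol(C + diag(1e-8, S)), error = function(e) NULL)
  if (is.null(ch)) {
    # exp(-eta) is not guaranteed positive definite for arbitrary eta;
    # clip small/negative eigenvalues and reconstruct
    ei <- eigen(C, symmetric = TRUE)
    floor_ev <- 1e-6 * max(ei$values)
    if (min(ei$values) < -0.25 * max(ei$values)) {
      stop(sprintf(
        "pairwise covariance far from positive definite (eta range %.3g-%.3g)",
        min(te$eta), max(te$eta)))
    }
    vals <- pmax(ei$values, floor_ev)
    C <- ei$vectors %*% (vals * t(ei$vectors))
    ch <- chol(C + diag(1e-10, S))
  }
  set.seed(derive_seed(cfg$seed, "genotypes"))
  p0 <- stats::runif(cfg$n_loci, 0.1, 0.9)
  z <- matrix(stats::rnorm(S * cfg$n_loci), S, cfg$n_loci)
  dev <- t(ch) %*% z
  pfreq <- stats::plogis(sweep(dev, 2, stats::qlogis(p0), "+"))
  rng <- seq(cfg$samples_per_site[1], cfg$samples_per_site[2])
  n_per <- if (length(rng) == 1) rep(rng, S) else
    sample(rng, S, replace = TRUE)
  n_tot <- sum(n_per)
  calls <- matrix(NA_integer_, n_tot, cfg$n_loci)
  site_of <- rep(sites$site_id, n_per)
  row0 <- 0
  for (i in seq_len(S)) {
    calls[row0 + seq_len(n_per[i]), ] <- matrix(
      stats::rbinom(n_per[i] * cfg$n_loci, 2,
                    rep(pfreq[i, ], each = n_per[i])),
      n_per[i], cfg$n_loci)
    row0 <- row0 + n_per[i]
  }
  if (cfg$missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < cfg$missing_rate,
                 nrow(calls))] <- NA_integer_
  }
  loci <- data.frame(chrom = "chr1",
                     pos = seq(1, by = 301, length.out = cfg$n_loci),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("%s_t%02d", site_of,
                                            unlist(lapply(n_per, seq_len))),
                        site_id = site_of, stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, loci, samples)
  truth <- structure(list(
    site_ids = sites$site_id, ii = te$ii, jj = te$jj,
    eta = te$eta, mu = 1 - exp(-te$eta), eta_env = te$eta_env,
    f_geo = te$f_geo, distance_km = te$distance_km,
    drivers = paste0("env", seq_len(cfg$n_drivers)),
    env_coefs = cfg$env_coefs, geo_effect = cfg$geo_effect,
    bases = te$bases, p0 = p0, site_freq = pfreq,
    seed = cfg$seed), class = "truth_record")
  list(gm = gm, truth = truth)
}

#' Generate maternal half-sib phenotypes
#'
#' `y = mu + condition effect + site effect + line effect + residual`, with
#' effects drawn from the configured variance components. When the config
#' targets a neutral world and a realized Fst is supplied, the among-site
#' variance is set from the neutral half-sib relation
#' `sigma2_site = [2 F/(1-F)] * 4 sigma2_fam`, optionally inflated by
#' `site_inflation` to emulate divergent selection.
#'
#' @param cfg a `world_config`.
#' @param sites a `site_table` (or subset of its rows).
#' @param lines_per_site maternal lines per site (default 6).
#' @param seedlings_per_line replicate seedlings per line and condition
#'   (default 8).
#' @param conditions character vector of condition labels.
#' @param realized_fst multilocus Fst used for the neutral site variance.
#' @return phenotype data.frame (long format) with attribute `truth`
#'   (realized effects and the site variance used).
#' @export
generate_phenotypes <- function(cfg, sites, lines_per_site = 6,
                                seedlings_per_line = 8,
                                conditions = c("warm", "hot"),
                                realized_fst = NULL) {
  if (lines_per_site < 2 || seedlings_per_line < 2) {
    stop("need at least two lines per site and two seedlings per line")
  }
  phc <- cfg$phenotype
  s2_fam <- phc$sigma2_fam
  s2_site <- if (isTRUE(phc$neutral) && !is.null(realized_fst)) {
    (2 * realized_fst / (1 - realized_fst)) * 4 * s2_fam *
      (phc$site_inflation %||% 1)
  } else {
    phc$sigma2_site %||% 2
  }
  set.seed(derive_seed(cfg$seed, "phenotypes"))
  S <- nrow(sites)
  site_eff <- stats::rnorm(S, 0, sqrt(s2_site))
  rows <- list()
  k <- 0
  for (i in seq_len(S)) {
    line_eff <- stats::rnorm(lines_per_site, 0, sqrt(s2_fam))
    for (l in seq_len(lines_per_site)) {
      for (cond in conditions) {
        ce <- phc$condition_effect * (match(cond, conditions) - 1)
        res <- stats::rnorm(seedlings_per_line, 0, sqrt(phc$sigma2_res))
        k <- k + 1
        rows[[k]] <- data.frame(
          seedling_id = sprintf("%s_L%d_%s_%d", sites$site_id[i], l, cond,
                                seq_len(seedlings_per_line)),
          site_id = sites$site_id[i],
          maternal_line = paste0("L", l),
          condition = cond,
          block = rep_len(c("b1", "b2"), seedlings_per_line),
          trait = "height",
          value = 10 + ce + site_eff[i] + line_eff[l] + res,
          time_days = 35,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(sigma2_site = s2_site, sigma2_fam = s2_fam,
                             sigma2_res = phc$sigma2_res,
                             site_effects = site_eff)
  out
}

#' Write a genotype matrix as a minimal VCF
#'
#' VCF 4.2 with GT-only genotype fields; missing calls encoded `./.`.
#' Suitable for [load_genotypes()] round trips.
#'
#' @param gm a `genotype_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
generate_vcf_fixture <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gdmscape synthetic data",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples$sample_id),
                 collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  lines <- vapply(seq_len(ncol(gm$calls)), function(j) {
    g <- gm$calls[, j]
    gt <- ifelse(is.na(g), "./.", code[g + 1])
    paste(c(gm$loci$chrom[j], gm$loci$pos[j], ".", gm$loci$ref[j],
            gm$loci$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Generate a complete synthetic world
#'
#' Orchestrates environment, sites, genotypes and phenotypes; the returned
#' truth record suffices to recompute the generating eta and mu for any
#' site pair.
#'
#' @param cfg a `world_config`.
#' @param phenotype_sites number of sites entering the growth experiment
#'   (default 6).
#' @return list: `env` (current/future stacks), `sites`, `gm`, `truth`,
#'   `phenotypes`, `geo`.
#' @export
generate_world <- function(cfg, phenotype_sites = 6) {
  env <- generate_environment(cfg)
  sites <- generate_sites(cfg, env$current)
  g <- generate_genotypes(cfg, sites)
  geo <- geographic_distance(sites)
  set.seed(derive_seed(cfg$seed, "phenotype_sites"))
  ph_sites <- sites[sort(sample.int(nrow(sites),
                                    min(phenotype_sites, nrow(sites)))), ]
  fst <- multilocus_fst(g$gm, sites = ph_sites$site_id)
  ph <- generate_phenotypes(cfg, ph_sites,
                            realized_fst = max(fst$theta, 0.001))
  list(env = env, sites = sites, gm = g$gm, truth = g$truth,
       phenotypes = ph, geo = geo, phenotype_sites = ph_sites$site_id)
}
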