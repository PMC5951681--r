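#' Run configuration for the pipeline commands
#'
#' Plain list of input paths, stage parameters and the master seed. Every
#' stochastic stage derives its own seed deterministically from the master
#' seed and the stage name, and the configuration is written verbatim into
#' the output directory of each command.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed.
#' @param vcf,site_csv input paths (optional when simulating).
#' @param params named list of stage-parameter overrides; recognised names
#'   include `max_sample_missing`, `max_locus_missing`, `min_spacing_bp`,
#'   `mantel_n_perm`, `n_basis`, `deviance_floor`, `corr_ceiling`,
#'   `select_n_perm`, `cv_train_frac`, `cv_n_iter`, `qst_n_sim`.
#' @param world a `world_config` used by [cmd_simulate()].
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, vcf = NULL, site_csv = NULL,
                       params = list(), world = NULL) {
  defaults <- list(max_sample_missing = 0.60, max_locus_missing = 0.60,
                   min_spacing_bp = 300, mantel_n_perm = 9999,
                   n_basis = 3, deviance_floor = 0.05, corr_ceiling = 0.60,
                   select_n_perm = 1000, cv_train_frac = 0.70,
                   cv_n_iter = 1000, qst_n_sim = 10000)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameters: ",
                            paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(out_dir = out_dir, seed = seed, vcf = vcf,
                 site_csv = site_csv, params = defaults,
                 world = world %||% world_config(seed = seed)),
            class = "run_config")
}

prepare_out <- function(config, stage) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_lines <- c(sprintf("stage %s", stage),
                 sprintf("seed %d", config$seed),
                 sprintf("%s %s", names(config$params),
                         vapply(config$params, format, character(1))))
  writeLines(cfg_lines, file.path(config$out_dir,
                                  paste0("config_", stage, ".txt")))
  invisible(config$out_dir)
}

write_manifest <- function(config, stage, files) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("gdmscape")),
    seed = config$seed,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

num_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Simulate a synthetic dataset to disk
#'
#' Writes VCF, site CSV, environmental grids (current and future, ESRI
#' ASCII), phenotype CSV and the truth record.
#'
#' @param config a `run_config` with a `world` configuration.
#' @return file list, invisibly.
#' @export
cmd_simulate <- function(config) {
  out <- prepare_out(config, "simulate")
  cfg <- config$world
  world <- generate_world(cfg)
  files <- character(0)
  f <- file.path(out, "genotypes.vcf")
  generate_vcf_fixture(world$gm, f)
  files <- c(files, f)
  f <- file.path(out, "sites.csv")
  num_csv(as.data.frame(world$sites), f)
  files <- c(files, f)
  f <- file.path(out, "samples.csv")
  num_csv(world$gm$samples, f)
  files <- c(files, f)
  for (scen in c("current", "future")) {
    st <- world$env[[scen]]
    for (nm in names(st$layers)) {
      f <- file.path(out, sprintf("%s_%s.asc", scen, nm))
      write_ascii_grid(st, nm, f)
      files <- c(files, f)
    }
  }
  f <- file.path(out, "phenotypes.csv")
  num_csv(world$phenotypes, f)
  files <- c(files, f)
  f <- file.path(out, "truth.json")
  tr <- world$truth
  jsonlite::write_json(list(site_ids = tr$site_ids, eta = tr$eta,
                            mu = tr$mu, f_geo = tr$f_geo,
                            distance_km = tr$distance_km,
                            drivers = tr$drivers,
                            env_coefs = tr$env_coefs,
                            geo_effect = tr$geo_effect, seed = tr$seed),
                       f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  write_manifest(config, "simulate", files)
  invisible(files)
}

read_inputs <- function(config) {
  vcf <- config$vcf %||% file.path(config$out_dir, "genotypes.vcf")
  site_csv <- config$site_csv %||% file.path(config$out_dir, "sites.csv")
  sample_csv <- file.path(config$out_dir, "samples.csv")
  for (f in c(vcf, site_csv, sample_csv)) {
    if (!file.exists(f)) stop("missing input path: ", f)
  }
  sites_df <- utils::read.csv(site_csv, stringsAsFactors = FALSE)
  env_cols <- setdiff(names(sites_df), c("site_id", "lat", "lon"))
  sites <- site_table(sites_df$site_id, sites_df$lat, sites_df$lon,
                      env = sites_df[, env_cols, drop = FALSE])
  gm <- load_genotypes(vcf, utils::read.csv(sample_csv,
                                            stringsAsFactors = FALSE))
  list(gm = gm, sites = sites)
}

#' Population-genomic stage: distances, PCoA, Mantel, diversity, Fst
#' @param config a `run_config`.
#' @return file list, invisibly.
#' @export
cmd_popgen <- function(config) {
  out <- prepare_out(config, "popgen")
  p <- config$params
  inp <- read_inputs(config)
  gm <- filter_and_thin(inp$gm, p$max_sample_missing, p$max_locus_missing,
                        p$min_spacing_bp)
  files <- character(0)
  gdist <- genomic_distance_euclidean(gm)
  files <- c(files, write_pairwise_csv(gdist,
                                       file.path(out, "genomic_dist.csv")))
  ord <- pcoa(gdist, n_axes = 4)
  files <- c(files, num_csv(
    data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
               check.names = FALSE),
    file.path(out, "pcoa_samples.csv")))
  # sample-level geographic distances use site coordinates
  idx <- match(gm$samples$site_id, inp$sites$site_id)
  geo_samp <- geographic_distance(inp$sites$lat[idx], inp$sites$lon[idx],
                                  labels = gm$samples$sample_id)
  mt <- mantel_test(gdist, geo_samp, n_perm = p$mantel_n_perm,
                    transform_b = "log",
                    seed = derive_seed(config$seed, "mantel"))
  div <- site_diversity(gm)
  files <- c(files, num_csv(div, file.path(out, "diversity.csv")))
  fst <- pairwise_fst_wc(gm)
  files <- c(files, write_pairwise_csv(fst, file.path(out, "fst.csv")))
  sfst <- scale_unit_interval(fst)
  files <- c(files, write_pairwise_csv(sfst,
                                       file.path(out, "fst_scaled.csv")))
  geo <- geographic_distance(inp$sites)
  files <- c(files, write_pairwise_csv(geo, file.path(out, "geo_dist.csv")))
  ord_fst <- pcoa(pairwise_matrix(pmax(unclass(sfst), 0),
                                  labels = rownames(sfst),
                                  kind = "scaled_fst"), n_axes = 4)
  summary <- list(
    n_samples = nrow(gm$calls), n_loci = ncol(gm$calls),
    mean_fst = mean(lower_tri(fst)), sd_fst = stats::sd(lower_tri(fst)),
    max_fst = max(lower_tri(fst)),
    mantel_r = mt$r, mantel_r_squared = mt$r_squared,
    mantel_p = mt$p_value,
    pcoa_pct_axis12 = sum(ord$percent_variance[1:2]),
    pcoa_fst_pct_axis12 = sum(ord_fst$percent_variance[1:2]))
  f <- file.path(out, "popgen_summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  write_manifest(config, "popgen", files)
  invisible(files)
}

#' GDM stage: variable selection, final model, cross-validation, curves
#' @param config a `run_config`.
#' @param candidates candidate predictors (default: all env columns).
#' @return file list, invisibly.
#' @export
cmd_gdm <- function(config, candidates = NULL) {
  out <- prepare_out(config, "gdm")
  p <- config$params
  sfst <- read_pairwise_csv(file.path(out, "fst_scaled.csv"),
                            kind = "scaled_fst")
  geo <- read_pairwise_csv(file.path(out, "geo_dist.csv"),
                           kind = "geographic")
  sites_df <- utils::read.csv(config$site_csv %||%
                                file.path(out, "sites.csv"),
                              stringsAsFactors = FALSE)
  env_cols <- setdiff(names(sites_df), c("site_id", "lat", "lon"))
  sites <- site_table(sites_df$site_id, sites_df$lat, sites_df$lon,
                      env = sites_df[, env_cols, drop = FALSE])
  candidates <- candidates %||% env_cols
  sel <- select_variables(sites, candidates, sfst, geo,
                          deviance_floor = p$deviance_floor,
                          corr_ceiling = p$corr_ceiling,
                          n_perm = p$select_n_perm,
                          seed = derive_seed(config$seed, "select"),
                          n_basis = p$n_basis)
  retained <- attr(sel, "retained")
  files <- c(num_csv(as.data.frame(sel),
                     file.path(out, "variable_selection.csv")))
  if (length(retained) == 0) retained <- candidates[1]
  pt <- make_pair_table(sites, retained, sfst, geo, n_basis = p$n_basis)
  model <- fit_gdm(pt)
  files <- c(files, num_csv(cbind(pt$pairs, as.data.frame(pt$X)),
                            file.path(out, "pair_table.csv")))
  f <- file.path(out, "gdm_model.json")
  write_gdm_json(model, f)
  files <- c(files, f)
  files <- c(files, num_csv(spline_curves(model),
                            file.path(out, "spline_curves.csv")))
  cv <- cross_validate(sites, retained, sfst, geo,
                       train_frac = p$cv_train_frac,
                       n_iter = p$cv_n_iter,
                       seed = derive_seed(config$seed, "cv"),
                       n_basis = p$n_basis)
  f <- file.path(out, "cross_validation.json")
  jsonlite::write_json(list(mean_r = cv$mean_r, sd_r = cv$sd_r,
                            n_degenerate = cv$n_degenerate, r = cv$r),
                       f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  write_manifest(config, "gdm", files)
  invisible(files)
}

read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bases <- lapply(obj$bases, function(b)
    structure(list(name = b$name, n_basis = obj$n_basis, knots = b$knots,
                   range = b$range), class = "ispline_basis"))
  structure(list(intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 bases = bases, predictors = obj$predictors,
                 n_basis = obj$n_basis,
                 deviance_model = obj$deviance_model,
                 deviance_null = obj$deviance_null,
                 deviance_explained = obj$deviance_explained,
                 degenerate = FALSE, site_ids = obj$site_ids),
            class = "gdm_model")
}

#' Projection stage: composition map, vulnerability, seed-source map
#' @param config a `run_config`.
#' @param target c(lat, lon) restoration site; default = grid centre.
#' @return file list, invisibly.
#' @export
cmd_project <- function(config, target = NULL) {
  out <- prepare_out(config, "project")
  model <- read_model(file.path(out, "gdm_model.json"))
  env_preds <- setdiff(model$predictors, "geographic")
  load_stack <- function(scen) {
    lays <- lapply(env_preds, function(nm) {
      f <- file.path(out, sprintf("%s_%s.asc", scen, nm))
      if (!file.exists(f)) stop("missing input path: ", f)
      read_ascii_grid(f, name = nm, scenario = scen)$layers[[1]]
    })
    names(lays) <- env_preds
    hdr <- read_ascii_grid(file.path(out, sprintf("%s_%s.asc", scen,
                                                  env_preds[1])))
    env_stack(lays, xll = hdr$xll, yll = hdr$yll, cellsize = hdr$cellsize,
              scenario = scen)
  }
  cur <- load_stack("current")
  fut <- load_stack("future")
  proj <- transform_environment(model, cur)
  proj <- tryCatch(pca_rgb(proj), error = function(e) {
    # reduced-channel fallback: fewer than three transformed layers vary,
    # so rescale the available ones directly to colour channels
    lays <- proj$transformed$layers
    varying <- Filter(function(m) stats::sd(m, na.rm = TRUE) > 0, lays)
    if (length(varying) == 0) varying <- lays[1]
    src <- rep(varying, length.out = 3)
    dd <- dim(lays[[1]])
    proj$rgb <- array(NA_real_, c(dd[1], dd[2], 3))
    for (k in 1:3) {
      m <- src[[k]]
      rng <- range(m, na.rm = TRUE)
      proj$rgb[, , k] <- if (diff(rng) > 0)
        255 * (m - rng[1]) / diff(rng) else (m * 0 + 127.5)
    }
    proj
  })
  files <- character(0)
  d <- dim(proj$rgb)
  rgb_df <- data.frame(
    channel = rep(c("R", "G", "B"), each = d[1] * d[2]),
    value = as.numeric(proj$rgb))
  files <- c(files, num_csv(rgb_df, file.path(out, "composition_rgb.csv")))
  vuln <- genomic_vulnerability(model, cur, fut)
  vst <- env_stack(list(vulnerability = vuln), xll = cur$xll,
                   yll = cur$yll, cellsize = cur$cellsize)
  f <- file.path(out, "vulnerability.asc")
  write_ascii_grid(vst, "vulnerability", f)
  files <- c(files, f)
  cc <- stack_coords(cur)
  target <- target %||% c(stats::median(cc$lat), stats::median(cc$lon))
  fut_at_target <- extract_at(fut, target[1], target[2])
  ssm <- seed_source_map(model, target,
                         unlist(fut_at_target[env_preds]), cur)
  sst <- env_stack(list(seed_source = ssm), xll = cur$xll, yll = cur$yll,
                   cellsize = cur$cellsize)
  f <- file.path(out, "seed_source.asc")
  write_ascii_grid(sst, "seed_source", f)
  files <- c(files, f)
  write_manifest(config, "project", files)
  invisible(files)
}

#' Qst-Fst stage
#' @param config a `run_config`.
#' @return file list, invisibly.
#' @export
cmd_qstfst <- function(config) {
  out <- prepare_out(config, "qstfst")
  p <- config$params
  ph_f <- file.path(out, "phenotypes.csv")
  if (!file.exists(ph_f)) stop("missing input path: ", ph_f)
  ph <- utils::read.csv(ph_f, stringsAsFactors = FALSE)
  inp <- read_inputs(config)
  gm <- filter_and_thin(inp$gm, p$max_sample_missing, p$max_locus_missing,
                        p$min_spacing_bp)
  res <- qst_fst_test(ph, gm, trait = ph$trait[1],
                      condition = ph$condition[1],
                      n_sim = p$qst_n_sim,
                      seed = derive_seed(config$seed, "qstfst"))
  f <- file.path(out, "qst_fst.json")
  jsonlite::write_json(list(qst = res$qst, fst = res$fst,
                            delta = res$delta, p_value = res$p_value,
                            n_sim = res$n_sim,
                            sites = res$sites),
                       f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  f2 <- file.path(out, "qst_fst_null.csv")
  num_csv(data.frame(delta_null = res$null_delta), f2)
  write_manifest(config, "qstfst", c(f, f2))
  invisible(c(f, f2))
}
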