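#' Relative height increment
#'
#' Growth-rate metric: the difference between the natural logarithms of two
#' height measurements divided by the elapsed time in days. Values above
#' `outlier_threshold` (default 0.035 per day) are flagged as outliers but
#' never removed.
#'
#' @param h1,h2 heights at the two measurements (> 0, same units).
#' @param t1,t2 measurement times in days (t2 > t1).
#' @param outlier_threshold per-day rate above which values are flagged.
#' @return numeric vector of per-day rates with logical attribute `outlier`.
#' @export
relative_height_increment <- function(h1, h2, t1, t2,
                                      outlier_threshold = 0.035) {
  if (any(h1 <= 0 | h2 <= 0)) stop("heights must be positive")
  if (any(t2 <= t1)) stop("t2 must exceed t1")
  r <- (log(h2) - log(h1)) / (t2 - t1)
  attr(r, "outlier") <- r > outlier_threshold
  r
}

#' Specific leaf area
#'
#' Leaf area divided by dry mass; with area in mm^2 and mass in mg the
#' result is mm^2/mg.
#'
#' @param area leaf area (> 0).
#' @param mass dry mass (> 0).
#' @param units unit string carried on the result.
#' @return numeric vector with attribute `units`.
#' @export
specific_leaf_area <- function(area, mass, units = "mm^2/mg") {
  if (any(area <= 0 | mass <= 0)) stop("area and mass must be positive")
  structure(area / mass, units = units)
}

#' Nested variance components for a half-sib design
#'
#' Method-of-moments estimates of among-site, among-maternal-line (within
#' site) and residual variance from the nested random-effects ANOVA expected
#' mean squares, using the unbalanced-design coefficients. Negative
#' estimates are truncated to zero and flagged.
#'
#' @param ph phenotype data.frame with columns `site_id`, `maternal_line`,
#'   `trait`, `condition`, `value`.
#' @param trait trait name to analyse.
#' @param condition experimental condition to subset on (NULL = all rows).
#' @return a `var_components`: list with `sigma2_site`, `sigma2_fam`,
#'   `sigma2_res`, degrees of freedom, and `truncated` flags.
#' @export
nested_variance_components <- function(ph, trait = NULL, condition = NULL) {
  df <- ph
  if (!is.null(trait) && "trait" %in% names(df)) {
    df <- df[df$trait == trait, , drop = FALSE]
  }
  if (!is.null(condition) && "condition" %in% names(df)) {
    df <- df[df$condition == condition, , drop = FALSE]
  }
  df <- df[!is.na(df$value), , drop = FALSE]
  site <- factor(df$site_id)
  line <- factor(paste(df$site_id, df$maternal_line, sep = ":"))
  if (nlevels(site) < 2) stop("insufficient replication: need >= 2 sites")
  tab_line <- table(line)
  tab_site <- table(site)
  lines_per_site <- rowSums(table(site, droplevels(line)) > 0)
  if (any(lines_per_site < 2)) {
    stop("insufficient replication: need >= 2 maternal lines per site")
  }
  if (any(tab_line < 2)) {
    stop("insufficient replication: need >= 2 seedlings per maternal line")
  }
  y <- df$value
  N <- length(y)
  a <- nlevels(site)
  b_tot <- nlevels(line)
  # sums of squares
  grand <- mean(y)
  site_means <- tapply(y, site, mean)
  line_means <- tapply(y, line, mean)
  n_site <- as.numeric(tab_site)
  n_line <- as.numeric(tab_line)
  line_site <- tapply(as.integer(site), line, function(v) v[1])
  ss_site <- sum(n_site * (site_means - grand)^2)
  ss_line <- sum(n_line * (line_means - site_means[line_site])^2)
  ss_res <- sum((y - line_means[as.integer(line)])^2)
  df_site <- a - 1
  df_line <- b_tot - a
  df_res <- N - b_tot
  ms_site <- ss_site / df_site
  ms_line <- ss_line / df_line
  ms_res <- ss_res / df_res
  # unbalanced EMS coefficients
  sum_nij2_over_ni <- sum(tapply(n_line^2, line_site, sum) / n_site)
  c2 <- (N - sum_nij2_over_ni) / df_line
  c1 <- (sum_nij2_over_ni - sum(n_line^2) / N) / df_site
  c0 <- (N - sum(n_site^2) / N) / df_site
  s_res <- ms_res
  s_fam_raw <- (ms_line - ms_res) / c2
  s_fam <- max(0, s_fam_raw)
  s_site_raw <- (ms_site - ms_res - c1 * s_fam) / c0
  s_site <- max(0, s_site_raw)
  structure(list(sigma2_site = s_site, sigma2_fam = s_fam,
                 sigma2_res = s_res,
                 df = c(site = df_site, line = df_line, residual = df_res),
                 mean_squares = c(site = ms_site, line = ms_line,
                                  residual = ms_res),
                 ems_coef = c(c0 = c0, c1 = c1, c2 = c2),
                 truncated = c(site = s_site_raw < 0, fam = s_fam_raw < 0)),
            class = "var_components")
}

#' @export
print.var_components <- function(x, ...) {
  cat(sprintf(
    "variance components: site %.4g, line(site) %.4g, residual %.4g\n",
    x$sigma2_site, x$sigma2_fam, x$sigma2_res))
  invisible(x)
}

#' Qst for maternal half-sib families
#'
#' For offspring related as half-siblings through shared mothers the
#' additive variance is four times the maternal-line variance, so
#' `Qst = sigma2_site / (sigma2_site + 8 * sigma2_fam)`.
#'
#' @param vc a `var_components` (or list with `sigma2_site`, `sigma2_fam`).
#' @return Qst in [0, 1]; NA with an `undefined` attribute when both
#'   components are zero.
#' @export
qst_halfsib <- function(vc) {
  s <- vc$sigma2_site
  f <- vc$sigma2_fam
  if (s < 0 || f < 0) stop("variance components must be non-negative")
  if (s == 0 && f == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  s / (s + 8 * f)
}

#' Qst-Fst comparison with a simulated null distribution
#'
#' Computes observed `delta = Qst - Fst` for one trait under one condition,
#' with Fst the multilocus Weir-Cockerham estimate restricted to the
#' phenotyped sites. The null distribution of delta is simulated: per
#' replicate (a) bootstrap loci to draw F*; (b) set the neutral among-site
#' variance `sigma2_B* = [2 F*/(1 - F*)] * (4 * sigma2_fam_hat)`; (c) draw
#' the site and family components from their chi-squared sampling
#' distributions with the ANOVA degrees of freedom; (d) form
#' `delta* = Qst* - F*`. The two-tailed p-value is the +1-corrected
#' proportion of `|delta*| >= |delta|`.
#'
#' @param ph phenotype table (see [nested_variance_components()]).
#' @param gm a `genotype_matrix` containing the phenotyped sites.
#' @param trait,condition trait and condition to analyse.
#' @param n_sim null replicates (default 10000).
#' @param seed integer seed.
#' @param two_tailed two-tailed p (default TRUE; one-tailed tests
#'   Qst > Fst).
#' @return a `qst_fst_result`: observed Qst, Fst, delta, null sample, p.
#' @export
qst_fst_test <- function(ph, gm, trait = NULL, condition = NULL,
                         n_sim = 10000, seed = 1, two_tailed = TRUE) {
  if (n_sim < 100) warning("n_sim < 100 gives a coarse null distribution")
  vc <- nested_variance_components(ph, trait = trait, condition = condition)
  qst <- qst_halfsib(vc)
  df <- ph
  if (!is.null(trait) && "trait" %in% names(df)) {
    df <- df[df$trait == trait, , drop = FALSE]
  }
  sites <- intersect(unique(as.character(df$site_id)),
                     unique(gm$samples$site_id))
  if (length(sites) < 2) stop("phenotyped sites not present in genotypes")
  set.seed(derive_seed(seed, "qst_fst_boot"))
  fst <- multilocus_fst(gm, sites = sites, n_boot = n_sim)
  delta <- qst - fst$theta
  df_site <- vc$df[["site"]]
  df_line <- vc$df[["line"]]
  df_res <- vc$df[["residual"]]
  f_star <- pmin(pmax(fst$boot, 1e-6), 0.999)
  set.seed(derive_seed(seed, "qst_fst_chisq"))
  # the mean squares, not the component estimates, have chi-squared
  # sampling distributions; draw them and push each replicate through the
  # same method-of-moments (with truncation) as the observed estimate
  c0 <- vc$ems_coef[["c0"]]
  c1 <- vc$ems_coef[["c1"]]
  c2 <- vc$ems_coef[["c2"]]
  # null-constrained family variance: under the neutral null the site mean
  # square also estimates sigma2_fam (through the neutral relation), so
  # pool both strata with df weights; this stabilizes the null centres
  k_neutral <- 2 * fst$theta / (1 - fst$theta) * 4
  sf_line <- vc$sigma2_fam
  sf_site <- max(0, (vc$mean_squares[["site"]] - vc$sigma2_res) /
                   (c1 + c0 * k_neutral))
  sf_h0 <- (df_line * sf_line + df_site * sf_site) / (df_line + df_site)
  sigma_b_star <- (2 * f_star / (1 - f_star)) * (4 * sf_h0)
  ems_res <- vc$sigma2_res
  ems_line <- vc$sigma2_res + c2 * sf_h0
  ems_site <- vc$sigma2_res + c1 * sf_h0 + c0 * sigma_b_star
  ms_res_star <- ems_res * stats::rchisq(n_sim, df_res) / df_res
  ms_line_star <- ems_line * stats::rchisq(n_sim, df_line) / df_line
  ms_site_star <- ems_site * stats::rchisq(n_sim, df_site) / df_site
  fam_star <- pmax(0, (ms_line_star - ms_res_star) / c2)
  site_star <- pmax(0, (ms_site_star - ms_res_star - c1 * fam_star) / c0)
  qst_star <- ifelse(site_star + fam_star > 0,
                     site_star / (site_star + 8 * fam_star), 0)
  delta_star <- qst_star - f_star
  p <- if (two_tailed) {
    (1 + sum(abs(delta_star) >= abs(delta))) / (n_sim + 1)
  } else {
    (1 + sum(delta_star >= delta)) / (n_sim + 1)
  }
  structure(list(qst = qst, fst = fst$theta, delta = delta,
                 null_delta = delta_star, p_value = p, n_sim = n_sim,
                 seed = seed, two_tailed = two_tailed,
                 var_components = vc, sites = sites),
            class = "qst_fst_result")
}

#' @export
print.qst_fst_result <- function(x, ...) {
  cat(sprintf("Qst = %.3f, Fst = %.3f, Qst - Fst = %.3f, p = %.3g (%d sims)\n",
              x$qst, x$fst, x$delta, x$p_value, x$n_sim))
  invisible(x)
}

#' Sequential percent-variance partition of a trait
#'
#' Sequential (type I) sums-of-squares partition over experimental
#' condition, site, and maternal line within site, expressed as percent of
#' the total sum of squares. A fixed-effects approximation of a
#' mixed-model partition, with condition entered first; the order is part
#' of the contract.
#'
#' @param ph phenotype table with columns `condition`, `site_id`,
#'   `maternal_line`, `value` (optionally `trait`).
#' @param trait trait to subset on.
#' @return data.frame with columns `term` and `percent`.
#' @export
variance_partition <- function(ph, trait = NULL) {
  df <- ph
  if (!is.null(trait) && "trait" %in% names(df)) {
    df <- df[df$trait == trait, , drop = FALSE]
  }
  df <- df[!is.na(df$value), , drop = FALSE]
  df$condition <- factor(df$condition)
  df$site_id <- factor(df$site_id)
  df$line <- factor(paste(df$site_id, df$maternal_line, sep = ":"))
  fit <- stats::lm(value ~ condition + site_id + site_id:line, data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    # aliasing inside the nested line term is expected (lines are nested in
    # sites); any other aliased term means a rank-deficient design
    if (any(!grepl(":line", aliased))) {
      stop("rank-deficient design; aliased terms: ",
           paste(aliased[!grepl(":line", aliased)], collapse = ", "))
    }
  }
  # only the sequential sums of squares are used, so the F-test warning on
  # saturated fits is irrelevant here
  an <- suppressWarnings(stats::anova(fit))
  ss <- an[["Sum Sq"]]
  terms <- rownames(an)
  total <- sum(ss)
  out <- data.frame(
    term = c("condition", "site", "line_in_site", "residual"),
    percent = 100 * ss[match(c("condition", "site_id", "site_id:line",
                               "Residuals"), terms)] / total,
    stringsAsFactors = FALSE)
  out
}
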