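#' Build the site-pair table for generalized dissimilarity modelling
#'
#' One row per unordered site pair, holding the response d (scaled Fst in
#' [0,1]), the absolute I-spline basis differences |I_k(x_i) - I_k(x_j)| for
#' each environmental predictor, and the geographic basis columns: I_k
#' evaluated at the pairwise great-circle distance, with the basis built on
#' the observed distances but anchored at 0 km so that I_k(0) = 0.
#'
#' @param sites a `site_table` carrying the predictor columns.
#' @param predictors character vector of environmental column names.
#' @param response `pairwise_matrix` of kind "scaled_fst" labelled by site.
#' @param geo `pairwise_matrix` of kind "geographic" labelled by site.
#' @param n_basis I-splines per predictor (default 3).
#' @return a `gdm_pair_table`: list with `pairs` (data.frame), `X` (basis
#'   difference matrix), `d` (response), `bases` (list of `ispline_basis`).
#' @export
make_pair_table <- function(sites, predictors, response, geo, n_basis = 3) {
  stopifnot(inherits(sites, "data.frame"))
  ids <- sites$site_id
  if (!identical(rownames(response), ids) || !identical(rownames(geo), ids)) {
    response <- response[ids, ids]
    geo <- geo[ids, ids]
  }
  for (p in predictors) {
    if (!p %in% names(sites)) stop("predictor not in site table: ", p)
    if (anyNA(sites[[p]])) {
      stop("missing environmental value for predictor '", p, "' at site ",
           ids[which(is.na(sites[[p]]))[1]])
    }
  }
  S <- length(ids)
  ii <- rep(seq_len(S - 1), times = (S - 1):1)
  jj <- unlist(lapply(seq_len(S - 1), function(i) seq(i + 1, S)))
  bases <- list()
  X <- NULL
  for (p in predictors) {
    b <- build_ispline_basis(sites[[p]], n_basis = n_basis, name = p)
    I <- eval_ispline(b, sites[[p]])
    X <- cbind(X, abs(I[ii, , drop = FALSE] - I[jj, , drop = FALSE]))
    bases[[p]] <- b
  }
  gd <- as.matrix(geo)[cbind(ii, jj)]
  gk <- geo_knots(gd, n_basis)
  gb <- structure(list(name = "geographic", n_basis = n_basis, knots = gk,
                       quantiles = unique(gk), range = c(0, max(gd))),
                  class = "ispline_basis")
  X <- cbind(X, eval_ispline(gb, gd))
  bases[["geographic"]] <- gb
  d <- as.matrix(response)[cbind(ii, jj)]
  if (any(d < 0 | d > 1)) stop("response must lie in [0, 1]")
  structure(list(
    pairs = data.frame(site_a = ids[ii], site_b = ids[jj],
                       distance_km = gd, d = d, stringsAsFactors = FALSE),
    X = X, d = d, bases = bases, predictors = predictors,
    site_ids = ids, n_basis = n_basis),
    class = "gdm_pair_table")
}

# geographic knot vector: quantiles of observed pairwise distances with the
# lower bound anchored at 0 so the basis vanishes at zero distance
geo_knots <- function(gd, n_basis) {
  if (n_basis == 1) {
    q <- c(0, max(gd))
    return(c(q[1], q[1], q[2]))
  }
  probs <- seq(0, 1, length.out = n_basis)
  q <- unname(stats::quantile(gd, probs, type = 7))
  q[1] <- 0
  if (anyDuplicated(q)) q <- seq(0, max(gd), length.out = n_basis)
  c(q[1], q, q[n_basis])
}

#' Fit a generalized dissimilarity model
#'
#' Fits mu = 1 - exp(-eta), eta = beta0 + X beta with beta0, beta >= 0, by
#' Gauss-Newton iterations that each solve a non-negative least-squares
#' subproblem, minimizing the squared-error deviance D = sum((d - mu)^2).
#' Zero-initialized and deterministic; converges when the deviance improves
#' by less than `tol` or after `max_iter` iterations. Step-halving guards
#' against overshooting.
#'
#' @param pt a `gdm_pair_table`.
#' @param tol convergence tolerance on the deviance decrease (default 1e-10).
#' @param max_iter maximum Gauss-Newton iterations (default 100).
#' @return a `gdm_model`: intercept, coefficients, bases, deviances.
#' @export
fit_gdm <- function(pt, tol = 1e-10, max_iter = 100) {
  X <- cbind(`(Intercept)` = 1, pt$X)
  d <- pt$d
  if (nrow(X) < ncol(pt$X) + 1) {
    warning("fewer pairs than coefficients; fit may be non-unique")
  }
  p <- ncol(X)
  beta <- rep(0, p)
  eta <- drop(X %*% beta)
  mu <- 1 - exp(-eta)
  dev <- sum((d - mu)^2)
  d_null <- sum((d - mean(d))^2)
  degenerate <- FALSE
  if (all(d == 0) || d_null == 0) {
    degenerate <- TRUE
    model <- new_gdm_model(beta, pt, dev_model = 0, dev_null = 0,
                           degenerate = TRUE, n_iter = 0L)
    return(model)
  }
  for (it in seq_len(max_iter)) {
    w <- exp(-eta)                       # d mu / d eta
    A <- X * w
    z <- d - mu + w * eta
    fit <- pracma::lsqnonneg(A, z)
    beta_new <- fit$x
    # step-halving on the deviance
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      mu_try <- 1 - exp(-eta_try)
      dev_try <- sum((d - mu_try)^2)
      if (dev_try <= dev + 1e-15 || step < 1e-8) break
      step <- step / 2
    }
    improved <- dev - dev_try
    beta <- beta_try; eta <- eta_try; mu <- mu_try; dev <- dev_try
    if (improved < tol) break
  }
  if (it == max_iter && improved >= tol * 100) {
    warning("fit_gdm reached max_iter without full convergence")
  }
  new_gdm_model(beta, pt, dev_model = dev, dev_null = d_null,
                degenerate = FALSE, n_iter = it)
}

new_gdm_model <- function(beta, pt, dev_model, dev_null, degenerate, n_iter) {
  coefs <- beta[-1]
  names(coefs) <- colnames(pt$X)
  structure(list(
    intercept = unname(beta[1]),
    coefficients = coefs,
    bases = pt$bases,
    predictors = c(pt$predictors, "geographic"),
    n_basis = pt$n_basis,
    deviance_model = dev_model,
    deviance_null = dev_null,
    deviance_explained = if (degenerate || dev_null == 0) 0 else
      1 - dev_model / dev_null,
    degenerate = degenerate,
    n_iter = n_iter,
    site_ids = pt$site_ids),
    class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf(
    "gdm_model: %d predictors (+geography), deviance explained = %.1f%%%s\n",
    length(x$predictors) - 1, 100 * x$deviance_explained,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Deviance explained by a fitted GDM
#'
#' `1 - D_model / D_null`, where D_null is the deviance of the best
#' intercept-only fit to the same pairs (squared-error deviance on the
#' response scale).
#'
#' @param model a `gdm_model`.
#' @return fraction in (-Inf, 1]; 0 with a degenerate flag when D_null = 0.
#' @export
deviance_explained <- function(model) model$deviance_explained

# per-predictor partial response sum_k beta_pk I_k(x)
partial_response <- function(model, predictor, x) {
  b <- model$bases[[predictor]]
  if (is.null(b)) stop("unknown predictor: ", predictor)
  I <- eval_ispline(b, x)
  k <- model$n_basis
  coefs <- model$coefficients[paste0(predictor, "_I", seq_len(k))]
  out <- drop(I %*% coefs)
  attr(out, "n_clamped") <- attr(I, "n_clamped")
  out
}

#' Predict genomic dissimilarity between two environments
#'
#' Evaluates `1 - exp(-eta)` with eta the fitted intercept plus the partial
#' splines applied to the absolute differences in basis space, plus the
#' geographic spline at the supplied distance. Values outside the training
#' range are clamped (count available via `attr(, "n_clamped")`).
#'
#' @param model a `gdm_model`.
#' @param env_a,env_b named numeric vectors covering the model's
#'   environmental predictors.
#' @param geo_km great-circle distance between the two locations, km.
#' @param include_intercept include beta0 in eta (default TRUE).
#' @return predicted dissimilarity in [0, 1).
#' @export
predict_dissimilarity <- function(model, env_a, env_b, geo_km,
                                  include_intercept = TRUE) {
  env_preds <- setdiff(model$predictors, "geographic")
  eta <- if (include_intercept) model$intercept else 0
  n_clamped <- 0L
  for (p in env_preds) {
    if (!(p %in% names(env_a)) || !(p %in% names(env_b))) {
      stop("missing predictor value: ", p)
    }
    b <- model$bases[[p]]
    Ia <- eval_ispline(b, env_a[[p]])
    Ib <- eval_ispline(b, env_b[[p]])
    n_clamped <- n_clamped + attr(Ia, "n_clamped") + attr(Ib, "n_clamped")
    k <- model$n_basis
    coefs <- model$coefficients[paste0(p, "_I", seq_len(k))]
    eta <- eta + sum(coefs * abs(Ia - Ib))
  }
  g <- partial_response(model, "geographic", geo_km)
  n_clamped <- n_clamped + attr(g, "n_clamped")
  out <- 1 - exp(-(eta + as.numeric(g)))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Predicted dissimilarities among a set of sites
#'
#' Vectorized pair prediction used by cross-validation: builds basis
#' differences from a site table with the model's fitted bases and returns
#' predictions for all unordered pairs.
#'
#' @param model a `gdm_model`.
#' @param sites a `site_table`.
#' @param geo `pairwise_matrix` of distances labelled by `sites$site_id`.
#' @return data.frame site_a, site_b, mu.
#' @export
predict_pairs <- function(model, sites, geo) {
  ids <- sites$site_id
  S <- length(ids)
  ii <- rep(seq_len(S - 1), times = (S - 1):1)
  jj <- unlist(lapply(seq_len(S - 1), function(i) seq(i + 1, S)))
  eta <- rep(model$intercept, length(ii))
  k <- model$n_basis
  for (p in setdiff(model$predictors, "geographic")) {
    I <- eval_ispline(model$bases[[p]], sites[[p]])
    coefs <- model$coefficients[paste0(p, "_I", seq_len(k))]
    eta <- eta + drop(abs(I[ii, , drop = FALSE] - I[jj, , drop = FALSE])
                      %*% coefs)
  }
  gd <- as.matrix(geo)[ids, ids][cbind(ii, jj)]
  eta <- eta + as.numeric(partial_response(model, "geographic", gd))
  data.frame(site_a = ids[ii], site_b = ids[jj], mu = 1 - exp(-eta),
             stringsAsFactors = FALSE)
}

#' Partial spline curves of a fitted GDM
#'
#' Evaluates each predictor's partial response f_p(x) = sum_k beta_pk I_k(x)
#' on a grid over the training range (the geographic spline included).
#'
#' @param model a `gdm_model`.
#' @param n_points grid size per predictor (default 200).
#' @return data.frame with columns `predictor`, `x`, `f`.
#' @export
spline_curves <- function(model, n_points = 200) {
  out <- lapply(model$predictors, function(p) {
    b <- model$bases[[p]]
    x <- seq(b$range[1], b$range[2], length.out = n_points)
    data.frame(predictor = p, x = x,
               f = as.numeric(partial_response(model, p, x)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Serialize a fitted GDM to JSON
#' @param model a `gdm_model`.
#' @param path output path.
#' @export
write_gdm_json <- function(model, path) {
  obj <- list(
    package = "gdmscape",
    version = as.character(utils::packageVersion("gdmscape")),
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    n_basis = model$n_basis,
    predictors = model$predictors,
    bases = lapply(model$bases, function(b)
      list(name = b$name, knots = b$knots, range = b$range)),
    deviance_model = model$deviance_model,
    deviance_null = model$deviance_null,
    deviance_explained = model$deviance_explained,
    site_ids = model$site_ids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
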