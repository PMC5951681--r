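#' Permutation importance of GDM predictors
#'
#' For each environmental variable in turn: permute that variable's values
#' across sites, rebuild the pair table, refit, and compare deviance
#' explained with the full model. Importance is the mean percent drop in
#' deviance explained; the p-value is
#' `(1 + #\{permuted dev. explained >= full\}) / (n_perm + 1)`.
#'
#' @param sites a `site_table`.
#' @param predictors environmental predictors of the full model.
#' @param response `pairwise_matrix` (scaled Fst).
#' @param geo `pairwise_matrix` of distances.
#' @param n_perm permutations per variable (default 1000).
#' @param seed integer seed (reproducible).
#' @param n_basis I-splines per predictor.
#' @return data.frame: variable, importance (percent), p_value.
#' @export
permutation_importance <- function(sites, predictors, response, geo,
                                   n_perm = 1000, seed = 1, n_basis = 3) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  full <- fit_gdm(make_pair_table(sites, predictors, response, geo,
                                  n_basis = n_basis))
  de_full <- full$deviance_explained
  S <- nrow(sites)
  out <- lapply(seq_along(predictors), function(vi) {
    v <- predictors[vi]
    set.seed(derive_seed(seed, paste0("permimp_", v)))
    de_perm <- vapply(seq_len(n_perm), function(i) {
      s2 <- sites
      s2[[v]] <- s2[[v]][sample.int(S)]
      fit_gdm(make_pair_table(s2, predictors, response, geo,
                              n_basis = n_basis))$deviance_explained
    }, numeric(1))
    imp <- if (de_full > 0) 100 * mean(de_full - de_perm) / de_full else 0
    data.frame(variable = v, importance = imp,
               p_value = (1 + sum(de_perm >= de_full)) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "deviance_explained_full") <- de_full
  res
}

#' Sequential GDM variable selection
#'
#' Three stages, applied in order. Stage 1: drop candidates whose
#' single-variable model (variable + geography) explains less than
#' `deviance_floor` of the deviance. Stage 2: among surviving variables,
#' while any pair of site-value vectors has |Pearson r| above
#' `corr_ceiling`, drop the member of the most-correlated pair with the
#' lower single-variable deviance explained. Stage 3: permutation importance
#' on the joint model; variables with p above 0.05 or importance below
#' `importance_floor` are flagged for review, and removed only when
#' `auto_remove = TRUE`.
#'
#' @param sites a `site_table`.
#' @param candidates candidate environmental column names.
#' @param response,geo pairwise matrices (scaled Fst; distances).
#' @param deviance_floor single-variable deviance threshold (default 0.05).
#' @param corr_ceiling absolute Pearson correlation ceiling (default 0.60).
#' @param n_perm permutations for stage 3 (default 1000).
#' @param seed integer seed.
#' @param importance_floor percent-importance flag threshold (default 1).
#' @param auto_remove drop stage-3 flagged variables (default FALSE).
#' @param n_basis I-splines per predictor.
#' @return a `variable_selection_report`: data.frame of per-candidate fates
#'   plus the retained set.
#' @export
select_variables <- function(sites, candidates, response, geo,
                             deviance_floor = 0.05, corr_ceiling = 0.60,
                             n_perm = 1000, seed = 1,
                             importance_floor = 1, auto_remove = FALSE,
                             n_basis = 3) {
  stopifnot(length(candidates) >= 1)
  report <- data.frame(variable = candidates,
                       single_deviance = NA_real_,
                       stage_removed = "retained",
                       importance = NA_real_, p_value = NA_real_,
                       stringsAsFactors = FALSE)
  # stage 1: single-variable deviance (with geography)
  for (i in seq_along(candidates)) {
    de <- tryCatch(
      fit_gdm(make_pair_table(sites, candidates[i], response, geo,
                              n_basis = n_basis))$deviance_explained,
      error = function(e) NA_real_)
    report$single_deviance[i] <- de
  }
  drop1 <- is.na(report$single_deviance) |
    report$single_deviance < deviance_floor
  report$stage_removed[drop1] <- "low_deviance"
  surv <- report$variable[!drop1]
  # stage 2: greedy correlation screening on raw site values
  if (length(surv) >= 2) {
    repeat {
      cm <- abs(stats::cor(as.data.frame(sites[, surv, drop = FALSE])))
      diag(cm) <- 0
      if (max(cm) <= corr_ceiling) break
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- surv[ij]
      dev <- report$single_deviance[match(pair, report$variable)]
      loser <- pair[which.min(dev)]
      report$stage_removed[report$variable == loser] <- "correlated"
      surv <- setdiff(surv, loser)
      if (length(surv) < 2) break
    }
  }
  # stage 3: permutation importance on the joint model
  if (length(surv) >= 1) {
    pi_res <- permutation_importance(sites, surv, response, geo,
                                     n_perm = n_perm, seed = seed,
                                     n_basis = n_basis)
    idx <- match(pi_res$variable, report$variable)
    report$importance[idx] <- pi_res$importance
    report$p_value[idx] <- pi_res$p_value
    flagged <- pi_res$variable[pi_res$p_value > 0.05 |
                                 pi_res$importance < importance_floor]
    if (auto_remove && length(flagged)) {
      report$stage_removed[report$variable %in% flagged] <- "permutation"
      surv <- setdiff(surv, flagged)
    }
    attr(report, "flagged") <- flagged
  } else {
    attr(report, "flagged") <- character(0)
  }
  attr(report, "retained") <- surv
  class(report) <- c("variable_selection_report", "data.frame")
  report
}

#' Site-level cross-validation of a GDM
#'
#' Each iteration holds out a random fraction of sites, fits on the training
#' pairs, predicts dissimilarities among the held-out sites only, and
#' records the Pearson correlation between predicted and observed values.
#' Iterations whose held-out response is constant are counted as degenerate
#' and excluded from the mean.
#'
#' @param sites a `site_table` (>= 7 sites).
#' @param predictors environmental predictors.
#' @param response,geo pairwise matrices.
#' @param train_frac fraction of sites used for training (default 0.70).
#' @param n_iter iterations (default 1000).
#' @param seed integer seed.
#' @param n_basis I-splines per predictor.
#' @return list with `mean_r`, `sd_r`, `r` (per-iteration, NA where
#'   degenerate), `n_degenerate`.
#' @export
cross_validate <- function(sites, predictors, response, geo,
                           train_frac = 0.70, n_iter = 1000, seed = 1,
                           n_basis = 3) {
  S <- nrow(sites)
  n_train <- ceiling(train_frac * S)
  if (S - n_train < 2) stop("fewer than two test sites per iteration")
  ids <- sites$site_id
  resp <- as.matrix(response)[ids, ids]
  set.seed(derive_seed(seed, "cross_validate"))
  r <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    tr <- sort(sample.int(S, n_train))
    te <- setdiff(seq_len(S), tr)
    sites_tr <- sites[tr, , drop = FALSE]
    sites_te <- sites[te, , drop = FALSE]
    fit <- tryCatch(
      fit_gdm(make_pair_table(sites_tr, predictors,
                              response[ids[tr], ids[tr]],
                              geo[ids[tr], ids[tr]], n_basis = n_basis)),
      error = function(e) NULL)
    if (is.null(fit)) next
    pred <- predict_pairs(fit, sites_te, geo)
    obs <- resp[cbind(match(pred$site_a, ids), match(pred$site_b, ids))]
    if (stats::sd(obs) == 0 || stats::sd(pred$mu) == 0) next
    r[i] <- stats::cor(pred$mu, obs)
  }
  ok <- !is.na(r)
  list(mean_r = mean(r[ok]), sd_r = stats::sd(r[ok]), r = r,
       n_degenerate = sum(!ok))
}
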