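test_that("I-spline bases are normalized, monotone, and integrate their M-splines", {
  set.seed(5)
  vals <- runif(20, 2, 9)
  b <- build_ispline_basis(vals, n_basis = 3, name = "x")
  expect_equal(as.numeric(eval_ispline(b, min(vals))), c(0, 0, 0))
  expect_equal(as.numeric(eval_ispline(b, max(vals))), c(1, 1, 1))
  # monotone non-decreasing on a fine grid
  g <- seq(min(vals), max(vals), length.out = 400)
  I <- eval_ispline(b, g)
  expect_true(all(diff(I[, 1]) >= -1e-12))
  expect_true(all(diff(I[, 2]) >= -1e-12))
  expect_true(all(diff(I[, 3]) >= -1e-12))
  # quadrature oracle: I_k(x) = integral of M_k up to x
  for (k in 1:3) {
    t3 <- b$knots[k:(k + 2)]
    for (x in c(3.2, 5.5, 8.1)) {
      q <- integrate(gdmscape:::mspline2_one, lower = min(vals), upper = x,
                     t1 = t3[1], t2 = t3[2], t3 = t3[3],
                     rel.tol = 1e-10, subdivisions = 400L)$value
      expect_equal(as.numeric(eval_ispline(b, x))[k], q, tolerance = 1e-8)
    }
  }
  # K = 1 and K = 4 variants keep the normalization contract
  for (K in c(1, 4)) {
    bk <- build_ispline_basis(vals, n_basis = K)
    expect_equal(as.numeric(eval_ispline(bk, min(vals))), rep(0, K))
    expect_equal(as.numeric(eval_ispline(bk, max(vals))), rep(1, K))
  }
  expect_error(build_ispline_basis(rep(1, 10)), "constant")
  # clamping is counted
  expect_equal(attr(eval_ispline(b, c(0, 5, 100)), "n_clamped"), 2)
})

test_that("pair table enumerates unordered pairs with non-negative basis differences", {
  sites <- make_sites(3)
  resp <- pairwise_matrix(as.matrix(dist(1:3)) / 10,
                          labels = sites$site_id, kind = "scaled_fst")
  geo <- geographic_distance(sites)
  pt <- make_pair_table(sites, c("env1", "env2"), resp, geo)
  expect_equal(nrow(pt$pairs), 3)
  expect_true(all(pt$X >= 0))
  # identical environments and zero distance: all-zero row
  sites2 <- make_sites(4)
  sites2$env1[2] <- sites2$env1[1]
  sites2$env2[2] <- sites2$env2[1]
  sites2$lat[2] <- sites2$lat[1]
  sites2$lon[2] <- sites2$lon[1]
  resp2 <- pairwise_matrix(matrix(0.1, 4, 4), labels = sites2$site_id,
                           kind = "scaled_fst")
  pt2 <- make_pair_table(sites2, c("env1", "env2"), resp2,
                         geographic_distance(sites2))
  row12 <- pt2$pairs$site_a == sites2$site_id[1] &
    pt2$pairs$site_b == sites2$site_id[2]
  expect_equal(as.numeric(pt2$X[row12, ]), rep(0, ncol(pt2$X)))
  # literal nested-loop construction oracle
  sites3 <- make_sites(4, seed = 77)
  resp3 <- pairwise_matrix(as.matrix(dist(rnorm(4))) / 5,
                           labels = sites3$site_id, kind = "scaled_fst")
  geo3 <- geographic_distance(sites3)
  pt3 <- make_pair_table(sites3, c("env1", "env2"), resp3, geo3)
  r <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    r <- r + 1
    expect_equal(pt3$pairs$site_a[r], sites3$site_id[i])
    expect_equal(pt3$pairs$site_b[r], sites3$site_id[j])
    for (p in c("env1", "env2")) {
      bI <- eval_ispline(pt3$bases[[p]], sites3[[p]])
      expect_equal(as.numeric(pt3$X[r, paste0(p, "_I", 1:3)]),
                   as.numeric(abs(bI[i, ] - bI[j, ])), tolerance = 1e-12)
    }
    expect_equal(
      as.numeric(pt3$X[r, paste0("geographic_I", 1:3)]),
      as.numeric(eval_ispline(pt3$bases$geographic, geo3[i, j])),
      tolerance = 1e-12)
  }
  # geographic basis vanishes at zero distance
  expect_equal(as.numeric(eval_ispline(pt3$bases$geographic, 0)),
               c(0, 0, 0))
  # missing env value errors with site and variable named
  sites_na <- make_sites(4)
  sites_na$env1[3] <- NA
  expect_error(make_pair_table(sites_na, c("env1"), resp2,
                               geographic_distance(sites_na)),
               "env1.*S03")
})

test_that("fit_gdm solves the constrained least-squares problem", {
  # all-zero response: degenerate flat model
  w0 <- make_known_world(S = 8)
  pt0 <- w0$pt
  pt0$d <- rep(0, nrow(pt0$pairs))
  m0 <- fit_gdm(pt0)
  expect_equal(m0$intercept, 0)
  expect_equal(unname(m0$coefficients), rep(0, length(m0$coefficients)))
  expect_true(m0$degenerate)
  expect_equal(deviance_explained(m0), 0)
  # noiseless self-consistency: predictions recover the generating mu
  w <- make_known_world(S = 12, noise_sd = 0)
  m <- fit_gdm(w$pt)
  mu_hat <- 1 - exp(-(m$intercept + drop(w$pt$X %*% m$coefficients)))
  expect_lt(max(abs(mu_hat - w$mu_true)), 1e-6)
  expect_true(all(m$coefficients >= 0))
  expect_gt(deviance_explained(m), 0.999)
  # response outside [0,1] rejected at pair-table construction
  resp_bad <- matrix(1.5, 3, 3); diag(resp_bad) <- 0
  sites3 <- make_sites(3)
  expect_error(make_pair_table(sites3, "env1",
                               pairwise_matrix(resp_bad,
                                               labels = sites3$site_id,
                                               kind = "fst"),
                               geographic_distance(sites3)), "0, 1")
})

test_that("fit_gdm matches a dense grid search on a 1-predictor toy problem", {
  # 6 pairs, K = 1, single predictor, no geography in the generating truth
  sites <- make_sites(4, n_env = 1, seed = 31)
  x <- c(0, 0.2, 0.5, 0.55, 0.8, 1.0)      # basis differences, one column
  d <- 1 - exp(-(0.15 + 0.9 * x)) + c(0.01, -0.02, 0.015, -0.01, 0.02, 0)
  pt <- list(X = matrix(x, ncol = 1, dimnames = list(NULL, "env1_I1")),
             d = d, pairs = data.frame(d = d), bases = list(),
             predictors = "env1", site_ids = sites$site_id, n_basis = 1)
  class(pt) <- "gdm_pair_table"
  m <- fit_gdm(pt)
  grid <- seq(0, 3, by = 1e-3)
  dev_best <- Inf; best <- c(NA, NA)
  for (b0 in grid) {
    mu <- 1 - exp(-(b0 + outer(grid, x)))
    devs <- rowSums(sweep(-mu, 2, d, "+")^2)
    i <- which.min(devs)
    if (devs[i] < dev_best) { dev_best <- devs[i]; best <- c(b0, grid[i]) }
  }
  expect_lt(abs(m$deviance_model - dev_best), 1e-5)
  expect_lt(abs(m$intercept - best[1]), 2e-3)
  expect_lt(abs(unname(m$coefficients) - best[2]), 2e-3)
})

test_that("predictions respect the link, the intercept, and monotonicity", {
  w <- make_known_world(S = 10, noise_sd = 0.01)
  m <- fit_gdm(w$pt)
  env_preds <- c("env1", "env2")
  ea <- c(env1 = w$sites$env1[1], env2 = w$sites$env2[1])
  # identical environments at zero distance: only the intercept survives
  expect_equal(as.numeric(predict_dissimilarity(m, ea, ea, 0)),
               1 - exp(-m$intercept), tolerance = 1e-12)
  # zeroed model predicts zero
  m0 <- m
  m0$intercept <- 0
  m0$coefficients[] <- 0
  eb <- c(env1 = w$sites$env1[5], env2 = w$sites$env2[5])
  expect_equal(as.numeric(predict_dissimilarity(m0, ea, eb, 300)), 0)
  # increasing a single env difference never decreases the prediction
  set.seed(8)
  for (rep in 1:20) {
    base_val <- runif(1, min(w$sites$env1), max(w$sites$env1))
    deltas <- sort(runif(3, 0, diff(range(w$sites$env1))))
    preds <- vapply(deltas, function(dl) {
      as.numeric(predict_dissimilarity(
        m, c(env1 = base_val, env2 = 0),
        c(env1 = min(base_val + dl, max(w$sites$env1)), env2 = 0), 100))
    }, numeric(1))
    expect_true(all(diff(preds) >= -1e-12))
  }
  # missing predictor errors
  expect_error(predict_dissimilarity(m, ea[1], eb, 10), "missing predictor")
})

test_that("deviance explained tracks the generating signal fraction", {
  # perfect fit
  w <- make_known_world(S = 12, noise_sd = 0)
  expect_gt(deviance_explained(fit_gdm(w$pt)), 0.999)
  # intercept-only data
  wi <- make_known_world(S = 8)
  pti <- wi$pt
  set.seed(2)
  pti$d <- rep(0.3, nrow(pti$pairs)) + rnorm(nrow(pti$pairs), 0, 1e-6)
  mi <- fit_gdm(pti)
  expect_lt(abs(deviance_explained(mi)), 0.05)
  # simulation oracle: deviance explained ~ generating R^2 at ~500 pairs
  wbig <- make_known_world(S = 33, noise_sd = 0.03)   # 528 pairs
  r2_gen <- var(wbig$mu_true) /
    (var(wbig$mu_true) + 0.03^2)
  de <- deviance_explained(fit_gdm(wbig$pt))
  expect_lt(abs(de - r2_gen), 0.05)
})

test_that("spline curves start at zero, are monotone, and top out at the coefficient sum", {
  w <- make_known_world(S = 14, noise_sd = 0.01)
  m <- fit_gdm(w$pt)
  curves <- spline_curves(m, n_points = 150)
  for (p in m$predictors) {
    cv <- curves[curves$predictor == p, ]
    expect_equal(cv$f[1], 0)
    expect_true(all(diff(cv$f) >= -1e-12))
    expect_equal(cv$f[nrow(cv)],
                 sum(m$coefficients[paste0(p, "_I", 1:3)]),
                 tolerance = 1e-12)
  }
})

test_that("training deviance explained never drops when a predictor is added", {
  for (seed in 1:6) {
    w <- make_known_world(S = 10, seed = seed * 13, noise_sd = 0.05)
    m1 <- fit_gdm(make_pair_table(w$sites, "env1", w$response, w$geo))
    m2 <- fit_gdm(make_pair_table(w$sites, c("env1", "env2"), w$response,
                                  w$geo))
    expect_gte(deviance_explained(m2), deviance_explained(m1) - 1e-8)
  }
})

test_that("prediction is invariant to predictor and pair order", {
  w <- make_known_world(S = 9, noise_sd = 0.02)
  m_a <- fit_gdm(make_pair_table(w$sites, c("env1", "env2"), w$response,
                                 w$geo))
  m_b <- fit_gdm(make_pair_table(w$sites, c("env2", "env1"), w$response,
                                 w$geo))
  pa <- predict_pairs(m_a, w$sites, w$geo)
  pb <- predict_pairs(m_b, w$sites, w$geo)
  expect_equal(pa$mu, pb$mu, tolerance = 1e-6)
  # site order permutation leaves pairwise predictions unchanged
  perm <- sample(nrow(w$sites))
  sites_p <- w$sites[perm, ]
  m_c <- fit_gdm(make_pair_table(sites_p, c("env1", "env2"),
                                 w$response, w$geo))
  pc <- predict_pairs(m_c, w$sites, w$geo)
  expect_equal(pa$mu, pc$mu, tolerance = 1e-6)
})

test_that("permutation importance flags informative and noise variables correctly", {
  w <- make_known_world(S = 14, noise_sd = 0.005,
                        coefs = list(c(0.4, 0.3, 0.3), c(0, 0, 0)))
  # env2 carries no signal by construction
  pi_res <- permutation_importance(w$sites, c("env1", "env2"),
                                   w$response, w$geo, n_perm = 60, seed = 4)
  expect_gt(pi_res$importance[pi_res$variable == "env1"], 20)
  expect_lt(pi_res$p_value[pi_res$variable == "env1"], 0.05)
  expect_lt(pi_res$importance[pi_res$variable == "env2"], 10)
  expect_gt(pi_res$p_value[pi_res$variable == "env2"], 0.05)
  # determinism under a fixed seed
  pi2 <- permutation_importance(w$sites, c("env1", "env2"), w$response,
                                w$geo, n_perm = 60, seed = 4)
  expect_identical(pi_res, pi2)
  expect_error(permutation_importance(w$sites, "env1", w$response, w$geo,
                                      n_perm = 0), "n_perm")
})

test_that("variable selection applies its three stages in order", {
  # no true geographic effect, so a useless variable's single-variable
  # model (variable + geography) cannot ride on the geographic signal
  w <- make_known_world(S = 16, noise_sd = 0.01,
                        coefs = list(c(0.4, 0.3, 0.3), c(0.3, 0.2, 0.2)),
                        geo_coefs = c(0, 0, 0))
  sites <- w$sites
  # a duplicated (perfectly correlated) predictor and a pure-noise one
  sites$env1_dup <- sites$env1 + 1
  set.seed(99)
  sites$noisevar <- rnorm(nrow(sites))
  sel <- select_variables(sites, c("env1", "env2", "env1_dup", "noisevar"),
                          w$response, w$geo, n_perm = 30, seed = 2)
  fate <- setNames(sel$stage_removed, sel$variable)
  expect_true(fate[["noisevar"]] %in% c("low_deviance"))
  expect_equal(fate[["env1"]], "retained")
  expect_equal(fate[["env2"]], "retained")
  # one of the duplicated pair must fall to the correlation rule
  expect_equal(fate[["env1_dup"]], "correlated")
  expect_setequal(attr(sel, "retained"), c("env1", "env2"))
  # no survivors after stage 1 gives an empty retained set, not an error
  sites_null <- make_sites(10, seed = 1234)
  set.seed(55)
  resp_null <- matrix(0, 10, 10)
  resp_null[lower.tri(resp_null)] <- runif(45)
  resp_null <- resp_null + t(resp_null)
  sel0 <- select_variables(
    sites_null, "env1",
    pairwise_matrix(resp_null, labels = sites_null$site_id,
                    kind = "scaled_fst"),
    geographic_distance(sites_null),
    deviance_floor = 0.99, n_perm = 5, seed = 1)
  expect_length(attr(sel0, "retained"), 0)
})

test_that("cross-validation recovers a noiseless world and is seed-stable", {
  w <- make_smooth_world(S = 30, noise_sd = 0)
  cv <- cross_validate(w$sites, c("env1", "env2"), w$response, w$geo,
                       n_iter = 100, seed = 3)
  expect_gt(cv$mean_r, 0.99)
  cv2 <- cross_validate(w$sites, c("env1", "env2"), w$response, w$geo,
                        n_iter = 100, seed = 3)
  expect_identical(cv$r, cv2$r)
  # shuffled response: mean r near zero
  set.seed(10)
  v <- lower_tri(w$response)
  shuf <- matrix(0, 30, 30)
  shuf[lower.tri(shuf)] <- sample(v)
  shuf <- shuf + t(shuf)
  cv0 <- cross_validate(w$sites, c("env1", "env2"),
                        pairwise_matrix(shuf, labels = w$sites$site_id,
                                        kind = "scaled_fst"),
                        w$geo, n_iter = 50, seed = 6)
  expect_lt(abs(cv0$mean_r), 0.25)
  expect_error(cross_validate(make_sites(5), "env1", w$response, w$geo),
               "test sites")
})

test_that("model JSON serialization round-trips predictions", {
  w <- make_known_world(S = 10, noise_sd = 0.02)
  m <- fit_gdm(w$pt)
  f <- tempfile(fileext = ".json")
  write_gdm_json(m, f)
  m2 <- gdmscape:::read_model(f)
  ea <- c(env1 = w$sites$env1[2], env2 = w$sites$env2[2])
  eb <- c(env1 = w$sites$env1[7], env2 = w$sites$env2[7])
  expect_equal(as.numeric(predict_dissimilarity(m2, ea, eb, 123)),
               as.numeric(predict_dissimilarity(m, ea, eb, 123)),
               tolerance = 1e-12)
})
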