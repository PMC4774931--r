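# toy 1-covariate world: presences sit at high covariate values
toy_training <- function(n_bg = 25, pres_cells = NULL,
                         feature_spec = "linear") {
  vals <- matrix(seq(0, 1, length.out = n_bg), nrow = sqrt(n_bg))
  st <- toy_stack(list(vals * 10 + 15))
  cc <- cellCentres(st$grid)
  bg <- occ(lon = cc$x, lat = cc$y)
  if (is.null(pres_cells)) pres_cells <- order(as.vector(vals),
                                               decreasing = TRUE)[1:8]
  pres <- occ(lon = cc$x[pres_cells], lat = cc$y[pres_cells])
  assembleTraining(pres, bg, st, feature_spec = feature_spec)
}

test_that("training assembly counts points and scales features to background [0,1]", {
  spec <- small_spec(seed = 21)
  st <- generateClimateStack(spec)
  cc <- cellCentres(spec$grid)
  set.seed(1)
  bg_i <- sample(nrow(cc), 90); pr_i <- sample(nrow(cc), 10)
  bg <- occ(lon = cc$x[bg_i], lat = cc$y[bg_i])
  pres <- occ(lon = cc$x[pr_i], lat = cc$y[pr_i])
  tr <- assembleTraining(pres, bg, st)
  expect_equal(tr$n_presence + tr$n_background, 100)
  # per feature, the background spans exactly [0, 1]
  expect_equal(unname(apply(tr$X_background, 2, min)), rep(0, 16))
  expect_equal(unname(apply(tr$X_background, 2, max)), rep(1, 16))
  # scaling equals direct background min/max of the covariates
  cov_bg <- habfoot:::covariates_at(st, bg$lon, bg$lat)
  expect_equal(tr$scaling$min, unname(apply(cov_bg, 2, min)))
  expect_equal(tr$scaling$max, unname(apply(cov_bg, 2, max)))

  # an off-grid presence is dropped and logged
  pres2 <- occ(lon = c(cc$x[pr_i], -1e6), lat = c(cc$y[pr_i], -1e6))
  tr2 <- assembleTraining(pres2, bg, st)
  expect_equal(unname(tr2$dropped["presence"]), 1)
  expect_equal(tr2$n_presence, 10)
  # everything off-grid is fatal
  expect_error(assembleTraining(occ(lon = -1e6, lat = -1e6), bg, st),
               "off-grid")
})

test_that("no contrast between presences and background shrinks all coefficients to zero", {
  n_bg <- 25
  vals <- matrix(seq(0, 1, length.out = n_bg), 5)
  st <- toy_stack(list(vals))
  cc <- cellCentres(st$grid)
  pts <- occ(lon = cc$x, lat = cc$y)
  tr <- assembleTraining(pts, pts, st)
  m <- fitMaxent(tr, beta = 1)
  expect_true(all(abs(m$lambda) < 1e-6))
  # the fitted distribution is uniform over background
  q <- habfoot:::gibbs_q(m$lambda, tr$X_background)
  expect_equal(q, rep(1 / n_bg, n_bg))
})

test_that("presences at high covariate values give a positive linear coefficient", {
  tr <- toy_training()
  m <- fitMaxent(tr, beta = 1)
  expect_gt(m$lambda[["lin_annual_mean_temp"]], 0)
})

test_that("coefficients match an independent brute-force penalized-likelihood search", {
  # two informative covariates on a 25-cell landscape, linear features only;
  # the remaining constant covariates provably stay at zero
  v1 <- matrix(seq(0, 1, length.out = 25), 5)
  v2 <- matrix(rep(seq(0, 1, length.out = 5), each = 5), 5)
  st <- toy_stack(list(v1 * 8 + 18, v2 * 500 + 300))
  cc <- cellCentres(st$grid)
  bg <- occ(lon = cc$x, lat = cc$y)
  pres_cells <- which(as.vector(v1) + as.vector(v2) >= 1.2)
  pres <- occ(lon = cc$x[pres_cells], lat = cc$y[pres_cells])
  tr <- assembleTraining(pres, bg, st, feature_spec = "linear")
  m <- fitMaxent(tr, beta = 1)

  # independent oracle: rescale covariates from scratch, evaluate the
  # penalized objective directly, grid-search with refinement
  f_bg <- cbind((as.vector(v1) - min(v1)) / diff(range(v1)),
                (as.vector(v2) - min(v2)) / diff(range(v2)))
  f_pr <- f_bg[pres_cells, ]
  mcount <- nrow(f_pr)
  beta_j <- pmax(apply(f_pr, 2, sd), 0.05) / sqrt(mcount)
  obj <- function(l1, l2) {
    eta <- f_bg %*% c(l1, l2)
    log(sum(exp(eta))) - mean(f_pr %*% c(l1, l2)) +
      beta_j[1] * abs(l1) + beta_j[2] * abs(l2)
  }
  centre <- c(0, 0); step <- 1; span <- 20
  for (round in 1:7) {
    g1 <- seq(centre[1] - span * step, centre[1] + span * step, by = step)
    g2 <- seq(centre[2] - span * step, centre[2] + span * step, by = step)
    vals <- outer(g1, g2, Vectorize(obj))
    ix <- arrayInd(which.min(vals), dim(vals))
    centre <- c(g1[ix[1]], g2[ix[2]])
    step <- step / 4; span <- 6
  }
  expect_lt(abs(m$lambda[["lin_annual_mean_temp"]] - centre[1]), 1e-3)
  expect_lt(abs(m$lambda[["lin_temp_seasonality"]] - centre[2]), 1e-3)
  expect_true(all(abs(m$lambda[setdiff(names(m$lambda),
    c("lin_annual_mean_temp", "lin_temp_seasonality"))]) < 1e-8))
})

test_that("the fitted Gibbs distribution is normalized over background", {
  tr <- toy_training(feature_spec = c("linear", "quadratic"))
  m <- fitMaxent(tr, beta = 1)
  total <- sum(exp(tr$X_background %*% m$lambda - m$logZ))
  expect_lt(abs(total - 1), 1e-6)
  expect_gt(m$entropy, 0)
})

test_that("stronger regularization never inflates a coefficient", {
  tr <- toy_training()
  fits <- lapply(c(0.5, 1, 2, 4), function(b) fitMaxent(tr, beta = b))
  for (k in 2:length(fits))
    expect_true(all(abs(fits[[k]]$lambda) <= abs(fits[[k - 1]]$lambda) + 1e-8))
})

test_that("a featureless model scores exactly 0.5 and prediction is rank-monotone in q", {
  vals <- matrix(seq(0, 1, length.out = 25), 5)
  st <- toy_stack(list(vals))
  cc <- cellCentres(st$grid)
  pts <- occ(lon = cc$x, lat = cc$y)
  m0 <- fitMaxent(assembleTraining(pts, pts, st), beta = 1)
  p0 <- predictSuitability(m0, st)
  expect_equal(as.vector(p0$values), rep(0.5, 25))

  tr <- toy_training(feature_spec = c("linear", "quadratic"))
  m <- fitMaxent(tr, beta = 0.5)
  st <- toy_stack(list(matrix(seq(0, 1, length.out = 25), 5) * 10 + 15))
  p <- predictSuitability(m, st)
  # raw density and logistic output rank cells identically
  cov <- sapply(m$scaling$covariate, function(nm) as.vector(st$layers[[nm]]))
  f <- habfoot:::make_features(cov, m$scaling, m$feature_spec)
  logq <- drop(f %*% m$lambda)
  expect_equal(order(logq), order(as.vector(p$values)))
})

test_that("no-data climate cells stay no-data in the suitability surface", {
  vals <- matrix(seq(0, 1, length.out = 25), 5)
  vals[2, 2] <- NA
  st <- toy_stack(list(vals))
  cc <- cellCentres(st$grid)
  ok <- !is.na(as.vector(vals))
  pts <- occ(lon = cc$x[ok], lat = cc$y[ok])
  m <- fitMaxent(assembleTraining(pts, pts, st), beta = 1)
  p <- predictSuitability(m, st)
  expect_true(is.na(p$values[2, 2]))
  expect_false(anyNA(p$values[-(5 + 2)]))
})

test_that("model serialization round-trips through JSON", {
  tr <- toy_training(feature_spec = c("linear", "quadratic"))
  m <- fitMaxent(tr, beta = 1)
  f <- withr::local_tempfile(fileext = ".json")
  writeEnvelopeModel(m, f)
  back <- readEnvelopeModel(f)
  expect_equal(back$lambda, m$lambda)
  expect_equal(back$logZ, m$logZ)
  expect_equal(back$entropy, m$entropy)
  expect_equal(back$scaling, m$scaling)
  # reloaded model predicts identically
  st <- toy_stack(list(matrix(seq(0, 1, length.out = 25), 5) * 10 + 15))
  expect_equal(predictSuitability(back, st)$values,
               predictSuitability(m, st)$values)
})

test_that("AUC matches pairwise enumeration, handles ties, and is transform-invariant", {
  g <- grid_geometry(6, 1, 250)
  mk_suit <- function(scores) structure(list(
    values = matrix(scores, 1, 6), grid = g, provenance = "test"),
    class = "suitability_raster")
  at <- function(cols) occ(lon = (cols - 0.5) * 250, lat = rep(125, length(cols)))

  # 3 presences {0.9, 0.8, 0.4} vs 3 background {0.7, 0.3, 0.1}: 8 of 9 pairs
  s <- mk_suit(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.1))
  expect_equal(evaluateAUC(s, at(1:3), at(4:6)), 8 / 9)
  # perfect separation and all-ties
  expect_equal(evaluateAUC(mk_suit(c(1, 1, 1, 0, 0, 0)), at(1:3), at(4:6)), 1)
  expect_equal(evaluateAUC(mk_suit(rep(0.4, 6)), at(1:3), at(4:6)), 0.5)
  expect_error(evaluateAUC(s, at(integer(0)), at(4:6)))

  # random <=10-point sets against a double-loop oracle
  g10 <- grid_geometry(10, 1, 250)
  mk10 <- function(scores) structure(list(
    values = matrix(c(scores, rep(0, 10 - length(scores))), 1, 10),
    grid = g10, provenance = "test"), class = "suitability_raster")
  at10 <- function(cols) occ(lon = (cols - 0.5) * 250,
                             lat = rep(125, length(cols)))
  set.seed(99)
  for (rep in 1:10) {
    np <- sample(2:5, 1); nb <- sample(2:5, 1)
    scores <- round(runif(np + nb), 1)     # ties likely
    a <- evaluateAUC(mk10(scores), at10(1:np), at10((np + 1):(np + nb)))
    pairs <- outer(scores[1:np], scores[(np + 1):(np + nb)],
                   function(p, b) (p > b) + 0.5 * (p == b))
    expect_equal(a, mean(pairs))
    # invariance under a strictly monotone transform
    s2 <- mk10(plogis(5 * (scores - 0.3)))
    expect_equal(evaluateAUC(s2, at10(1:np), at10((np + 1):(np + nb))), a)
  }
})

test_that("thresholding is inclusive and preserves no-data", {
  g <- grid_geometry(4, 4, 250)
  v <- matrix(0.5, 4, 4)
  s <- structure(list(values = v, grid = g, provenance = ""),
                 class = "suitability_raster")
  expect_true(all(thresholdEnvelope(s, 0.5)$values == 1L))
  v2 <- matrix(runif(16), 4, 4); v2[1, 1] <- NA
  s2 <- structure(list(values = v2, grid = g, provenance = ""),
                  class = "suitability_raster")
  expect_true(all(thresholdEnvelope(s2, 0)$values[-1] == 1L))
  expect_true(is.na(thresholdEnvelope(s2, 0)$values[1, 1]))
  for (tau in c(0.2, 0.6)) {
    b <- thresholdEnvelope(s2, tau)
    expect_equal(sum(b$values, na.rm = TRUE), sum(v2 >= tau, na.rm = TRUE))
  }
  expect_error(thresholdEnvelope(s2, 1.5), "tau")
})
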