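#' Presence-background maximum-entropy climate envelope
#'
#' The envelope model is the classic presence-background Maxent: over the
#' background points (here a target-group background, so observation bias
#' cancels between presences and background) fit the Gibbs distribution
#' `q(x) = exp(sum_j lambda_j f_j(x)) / Z` that maximises the penalized
#' log-likelihood of the presences,
#' `mean_pres(lambda . f) - log Z - sum_j beta_j |lambda_j|`.
#' This is convex; it is solved by proximal-gradient (ISTA with backtracking
#' line search) to a subgradient-optimality tolerance. Features are linear
#' and quadratic transforms of the eight climate covariates, min-max scaled
#' to \[0, 1\] using background statistics and clamped. The logistic output
#' `p = c q / (1 + c q)` with `c = exp(H)` (H the entropy of the fitted
#' distribution) maps the raw density to a \[0, 1\] suitability score; a
#' featureless model scores exactly 0.5 everywhere.
#'
#' @name envelope
NULL

# -- feature construction -------------------------------------------------

# raw covariate matrix (points x covariates) -> feature matrix under a
# fixed background min-max scaling, clamped to [0,1]
make_features <- function(cov, scaling, feature_spec) {
  lin <- sapply(seq_len(nrow(scaling)), function(j) {
    rng <- scaling$max[j] - scaling$min[j]
    v <- if (rng > 0) (cov[, j] - scaling$min[j]) / rng else rep(0.5, nrow(cov))
    pmin(pmax(v, 0), 1)
  })
  lin <- matrix(lin, nrow = nrow(cov))
  out <- NULL; nms <- character()
  if ("linear" %in% feature_spec) {
    out <- cbind(out, lin)
    nms <- c(nms, paste0("lin_", scaling$covariate))
  }
  if ("quadratic" %in% feature_spec) {
    out <- cbind(out, lin^2)
    nms <- c(nms, paste0("quad_", scaling$covariate))
  }
  colnames(out) <- nms
  out
}

covariates_at <- function(stack, x, y) {
  m <- sapply(stack$layer_names, function(nm)
    raster_values_at(stack$layers[[nm]], stack$grid, x, y))
  matrix(m, ncol = length(stack$layer_names),
         dimnames = list(NULL, stack$layer_names))
}

#' Assemble the Maxent training set
#'
#' Extracts the climate covariates at the presence and background points,
#' drops (and counts) points off-grid or on no-data cells, min-max scales
#' each covariate to \[0, 1\] using the *background* minima/maxima, and
#' builds the requested feature matrix for both sides. When `decimals` is
#' given, background points are first deduplicated by the same rounded
#' coordinate key used to thin the presences.
#'
#' @param presences a `thinned_occurrences` or [occurrenceSet()]
#' @param background a `background_set` or [occurrenceSet()]
#' @param stack a `climate_stack`
#' @param feature_spec subset of `c("linear", "quadratic")`
#' @param decimals optional rounding level for background deduplication
#' @param degree_size coordinate units per degree for the deduplication
#'   rounding (see [thinByRounding()])
#' @return a `training_set`: presence/background feature matrices, the
#'   scaling table, and retained/dropped counts
#' @export
assembleTraining <- function(presences, background, stack,
                             feature_spec = c("linear", "quadratic"),
                             decimals = NULL, degree_size = 1) {
  pres <- if (inherits(presences, "thinned_occurrences")) presences$retained
          else presences
  bg <- if (inherits(background, "background_set")) background$points
        else background
  if (!is.null(decimals))
    bg <- thinByRounding(bg, decimals, degree_size = degree_size)$retained
  if (nrow(pres) == 0 || nrow(bg) == 0)
    stop("presences and background must be non-empty", call. = FALSE)

  keep_on_grid <- function(occ) {
    cov <- covariates_at(stack, occ$lon, occ$lat)
    ok <- stats::complete.cases(cov)
    list(cov = cov[ok, , drop = FALSE], dropped = sum(!ok))
  }
  p <- keep_on_grid(pres); b <- keep_on_grid(bg)
  if (nrow(p$cov) == 0 || nrow(b$cov) == 0)
    stop("all points fell off-grid or on no-data cells", call. = FALSE)

  scaling <- data.frame(covariate = stack$layer_names,
                        min = unname(apply(b$cov, 2, min)),
                        max = unname(apply(b$cov, 2, max)),
                        stringsAsFactors = FALSE)
  structure(list(
    X_presence = make_features(p$cov, scaling, feature_spec),
    X_background = make_features(b$cov, scaling, feature_spec),
    scaling = scaling, feature_spec = feature_spec,
    n_presence = nrow(p$cov), n_background = nrow(b$cov),
    dropped = c(presence = p$dropped, background = b$dropped)),
    class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d presences + %d background, %d features (%s)\n",
              x$n_presence, x$n_background, ncol(x$X_presence),
              paste(x$feature_spec, collapse = "+")))
  invisible(x)
}

# -- fitting --------------------------------------------------------------

gibbs_q <- function(lambda, X) {
  eta <- drop(X %*% lambda)
  eta <- eta - max(eta)                 # log-sum-exp stabilisation
  e <- exp(eta)
  e / sum(e)
}

maxent_negll <- function(lambda, X_bg, p_hat) {
  eta <- drop(X_bg %*% lambda)
  m <- max(eta)
  log(sum(exp(eta - m))) + m - sum(lambda * p_hat)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Fit the penalized maximum-entropy model
#'
#' Minimises `log Z(lambda) - lambda . p_hat + sum_j beta_j |lambda_j|`
#' (p_hat the presence feature means) by proximal gradient with backtracking
#' line search. Per-feature penalty weights follow the Maxent default shape,
#' `beta_j = beta * sd_j(presences) / sqrt(n_presences)` (with a small floor
#' on the sd so constant features stay penalized). Convergence is declared
#' when the L1 subgradient-optimality residual falls below `tol` in max
#' norm; non-convergence within `max_iter` raises an error carrying the last
#' iterate.
#'
#' @param training a [assembleTraining()] result
#' @param beta global regularization multiplier (default 1)
#' @param seed recorded in the model (the fit itself is deterministic)
#' @param tol optimality tolerance (default 1e-6)
#' @param max_iter iteration cap (default 10000)
#' @return an `envelope_model` with coefficients, scaling, normalizer,
#'   entropy and provenance
#' @export
fitMaxent <- function(training, beta = 1, seed = 1L,
                      tol = 1e-6, max_iter = 10000) {
  X_p <- training$X_presence; X_b <- training$X_background
  if (nrow(X_p) < 2) stop("need at least 2 presences", call. = FALSE)
  p_hat <- colMeans(X_p)
  m <- nrow(X_p)
  sd_p <- apply(X_p, 2, stats::sd)
  beta_j <- beta * pmax(sd_p, 0.05) / sqrt(m)

  J <- ncol(X_b)
  lambda <- rep(0, J)
  L <- 1                                # local Lipschitz estimate
  g <- maxent_negll(lambda, X_b, p_hat)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- gibbs_q(lambda, X_b)
    grad <- drop(crossprod(X_b, q)) - p_hat
    # subgradient optimality residual
    resid <- ifelse(lambda != 0, abs(grad + beta_j * sign(lambda)),
                    pmax(abs(grad) - beta_j, 0))
    if (max(resid) < tol) { converged <- TRUE; break }
    repeat {                            # backtracking proximal step
      cand <- soft_threshold(lambda - grad / L, beta_j / L)
      d <- cand - lambda
      g_cand <- maxent_negll(cand, X_b, p_hat)
      if (g_cand <= g + sum(grad * d) + 0.5 * L * sum(d * d) + 1e-12) break
      L <- L * 2
    }
    lambda <- cand; g <- g_cand
    L <- max(L / 1.5, 1e-4)             # allow the step size to recover
  }
  if (!converged)
    stop(sprintf(paste0("maxent did not converge in %d iterations ",
                        "(residual %.3g); last iterate: %s"),
                 max_iter, max(resid),
                 paste(signif(lambda, 4), collapse = ", ")), call. = FALSE)

  q <- gibbs_q(lambda, X_b)
  eta <- drop(X_b %*% lambda)
  logZ <- log(sum(exp(eta - max(eta)))) + max(eta)
  H <- -sum(q * log(q))
  structure(list(feature_spec = training$feature_spec,
                 feature_names = colnames(X_b),
                 lambda = stats::setNames(lambda, colnames(X_b)),
                 scaling = training$scaling,
                 logZ = logZ, entropy = H,
                 beta = beta, beta_j = stats::setNames(beta_j, colnames(X_b)),
                 n_presence = training$n_presence,
                 n_background = training$n_background,
                 iterations = it, seed = as.integer(seed)),
            class = "envelope_model")
}

#' @export
print.envelope_model <- function(x, ...) {
  cat(sprintf(paste0("envelope_model: %d features (%s), beta %.3g, ",
                     "entropy %.4f, %d iterations\n"),
              length(x$lambda), paste(x$feature_spec, collapse = "+"),
              x$beta, x$entropy, x$iterations))
  nz <- x$lambda[x$lambda != 0]
  cat(sprintf("  %d non-zero coefficients\n", length(nz)))
  invisible(x)
}

#' Serialise / reload an envelope model (JSON)
#'
#' @param model an `envelope_model`
#' @param path file path
#' @export
writeEnvelopeModel <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeEnvelopeModel
#' @export
readEnvelopeModel <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$scaling <- as.data.frame(m$scaling, stringsAsFactors = FALSE)
  m$lambda <- stats::setNames(as.numeric(m$lambda), m$feature_names)
  m$beta_j <- stats::setNames(as.numeric(m$beta_j), m$feature_names)
  structure(m, class = "envelope_model")
}

# -- prediction, evaluation, thresholding ---------------------------------

#' Predict the suitability surface
#'
#' Evaluates the fitted density `q(x) = exp(lambda . f(x)) / Z` on every
#' valid grid cell (Z is the background normalizer frozen at fit time) and
#' applies the logistic transform `p = c q / (1 + c q)`, `c = exp(H)`.
#' No-data cells stay no-data.
#'
#' @param model an `envelope_model`
#' @param stack the `climate_stack` to predict over (layer names must cover
#'   the model's covariates)
#' @return a `suitability_raster` with values in \[0, 1\]
#' @export
predictSuitability <- function(model, stack) {
  if (!all(model$scaling$covariate %in% stack$layer_names))
    stop("stack is missing covariates required by the model", call. = FALSE)
  g <- stack$grid
  cov <- sapply(model$scaling$covariate, function(nm) as.vector(stack$layers[[nm]]))
  cov <- matrix(cov, ncol = nrow(model$scaling))
  ok <- stats::complete.cases(cov)
  p <- rep(NA_real_, nrow(cov))
  if (any(ok)) {
    f <- make_features(cov[ok, , drop = FALSE], model$scaling, model$feature_spec)
    logq <- drop(f %*% model$lambda) - model$logZ
    cq <- exp(model$entropy + logq)
    p[ok] <- cq / (1 + cq)
  }
  structure(list(values = matrix(p, g$height, g$width), grid = g,
                 provenance = sprintf("maxent logistic (c=exp(H), H=%.6f)",
                                      model$entropy)),
            class = "suitability_raster")
}

#' @export
print.suitability_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("suitability_raster: %dx%d, range [%.3f, %.3f]\n  %s\n",
              x$grid$height, x$grid$width, min(v), max(v), x$provenance))
  invisible(x)
}

#' Rank-based AUC of a suitability surface
#'
#' The probability that a randomly chosen presence point outscores a
#' randomly chosen background point, ties counting one half — computed from
#' midranks, which is exactly the pairwise enumeration. Points off-grid or
#' on no-data cells are ignored.
#'
#' @param suit a `suitability_raster`
#' @param presences,background occurrence sets (or `background_set`)
#' @return AUC in \[0, 1\]
#' @export
evaluateAUC <- function(suit, presences, background) {
  pres <- if (inherits(presences, "thinned_occurrences")) presences$retained
          else presences
  bg <- if (inherits(background, "background_set")) background$points
        else background
  sp <- raster_values_at(suit$values, suit$grid, pres$lon, pres$lat)
  sb <- raster_values_at(suit$values, suit$grid, bg$lon, bg$lat)
  sp <- sp[!is.na(sp)]; sb <- sb[!is.na(sb)]
  if (length(sp) == 0 || length(sb) == 0)
    stop("AUC undefined: need scores on both sides", call. = FALSE)
  r <- rank(c(sp, sb))                  # midranks handle ties as 1/2
  (sum(r[seq_along(sp)]) - length(sp) * (length(sp) + 1) / 2) /
    (length(sp) * length(sb))
}

#' Clip a suitability surface at a threshold
#'
#' Inclusive: a cell scoring exactly the threshold is suitable. No-data
#' stays no-data.
#'
#' @param suit a `suitability_raster`
#' @param tau threshold in \[0, 1\] (default 0.5)
#' @return a [binary_raster()]
#' @export
thresholdEnvelope <- function(suit, tau = 0.5) {
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]", call. = FALSE)
  binary_raster((suit$values >= tau) * 1L, suit$grid,
                provenance = sprintf("envelope >= %.3g", tau))
}
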