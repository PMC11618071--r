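#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km (via \pkg{geosphere}).
#' Vectorized over point pairs.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance(s), km.
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

# full pairwise haversine distance matrix (km); n x n
pairwiseKm <- function(lon, lat) {
  geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000 *
    (6371 / 6378.137)
}

#' Moran's I of residuals in distance bins (correlogram)
#'
#' Fits (or accepts) a smooth spatial baseline, then computes Moran's I of
#' the residuals per distance bin with binary weights
#' `w_ij = 1 iff d_ij` falls in the bin:
#' `I = (n / sum(W)) * sum_ij w_ij z_i z_j / sum_i z_i^2`. The null
#' expectation `-1/(n-1)` is reported alongside. Bins without pairs give
#' `NA`.
#'
#' The default baseline is a thin-plate smooth of the coordinates plus
#' univariate smooths of any covariates (`mgcv::gam`); alternatively pass
#' precomputed `baseline` predictions.
#'
#' @param lon,lat point coordinates (>= 30 points).
#' @param values response at the points.
#' @param covariates optional data.frame of additional smooth terms.
#' @param breaks increasing bin edges in km (default 0-1,000 km in 50 km
#'   bins).
#' @param baseline optional numeric vector of baseline predictions; when
#'   given, no GAM is fitted.
#' @return data.frame: `bin_lo, bin_hi, n_pairs, moran_i, expectation`.
#' @export
residualCorrelogram <- function(lon, lat, values, covariates = NULL,
                                breaks = seq(0, 1000, by = 50),
                                baseline = NULL) {
  n <- length(values)
  if (any(diff(breaks) <= 0)) stop("breaks must be increasing")
  if (is.null(baseline)) {
    if (n < 30) stop("need at least 30 points to fit the smooth baseline")
    dat <- data.frame(.y = values, .lon = lon, .lat = lat)
    terms <- "s(.lon, .lat)"
    if (!is.null(covariates)) {
      cn <- colnames(covariates)
      dat <- cbind(dat, covariates)
      terms <- c(terms, sprintf("s(%s)", cn))
    }
    fit <- mgcv::gam(stats::as.formula(paste(".y ~", paste(terms, collapse = " + "))),
                     data = dat)
    baseline <- stats::fitted(fit)
  }
  z <- values - baseline
  if (stats::sd(z) == 0) stop("zero-variance residuals")
  z <- z - mean(z)
  D <- pairwiseKm(lon, lat)
  s_zz <- sum(z^2)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L])
  out$n_pairs <- NA_integer_
  out$moran_i <- NA_real_
  cross <- tcrossprod(z)
  for (b in seq_len(nrow(out))) {
    W <- D > out$bin_lo[b] & D <= out$bin_hi[b]
    diag(W) <- FALSE
    sw <- sum(W)
    out$n_pairs[b] <- sw / 2
    if (sw > 0) out$moran_i[b] <- (n / sw) * sum(cross[W]) / s_zz
  }
  out$expectation <- -1 / (n - 1)
  out
}

#' Buffer-zone thinning: random-order greedy spatial subsample
#'
#' Visits points in random order and accepts a point iff it lies strictly
#' more than `minDistKm` from every previously accepted point, stopping at
#' `targetN` or when all points have been visited. All pairwise distances
#' of the output exceed `minDistKm`. If `targetN` cannot be reached a
#' smaller set is returned with a message.
#'
#' @param lon,lat candidate coordinates.
#' @param minDistKm minimum pairwise distance, km (> 0; default 50).
#' @param targetN desired subsample size (default all that fit).
#' @return integer indices into the input, in acceptance order.
#' @export
bufferSubsample <- function(lon, lat, minDistKm = 50, targetN = Inf) {
  stopifnot(minDistKm > 0)
  n <- length(lon)
  order <- sample.int(n)
  acc <- integer(0)
  for (i in order) {
    if (length(acc) >= targetN) break
    if (length(acc) == 0L ||
        all(haversineKm(lon[i], lat[i], lon[acc], lat[acc]) > minDistKm))
      acc <- c(acc, i)
  }
  if (is.finite(targetN) && length(acc) < targetN)
    message("buffer thinning exhausted at ", length(acc),
            " points (target ", targetN, ")")
  acc
}

#' Default random-forest hyperparameter grid (240 combinations)
#'
#' Tree count, features per split (as a fraction of predictors), maximum
#' depth (0 = unlimited) and minimum leaf size; values sized for
#' desk-scale training data.
#'
#' @return data.frame of 240 rows.
#' @export
defaultParamGrid <- function() {
  expand.grid(num_trees = c(50, 100, 150, 200, 250),
              mtry_frac = c(0.3, 0.5, 0.8, 1),
              max_depth = c(0, 4, 8, 16),
              min_node = c(3, 5, 10))
}

fitRanger <- function(data, response, features, params, seed = NULL,
                      importance = "none") {
  mtry <- max(1L, round(params$mtry_frac * length(features)))
  ranger::ranger(
    dependent.variable.name = response,
    data = data[, c(response, features), drop = FALSE],
    num.trees = params$num_trees, mtry = mtry,
    max.depth = params$max_depth, min.node.size = params$min_node,
    importance = importance, seed = seed, num.threads = 1L
  )
}

#' Randomized grid search for one ensemble member
#'
#' Draws `nDraws` hyperparameter sets from the grid without replacement
#' (all sets when `nDraws` exceeds the grid) and scores each by k-fold
#' cross-validated R^2 (`1 - SSE/SST` per fold, averaged; folds split
#' randomly by row). The winner is refitted on the full subset with
#' permutation importance enabled.
#'
#' @param data training rows (one member's buffer-thinned subsample).
#' @param response response column name.
#' @param features predictor column names.
#' @param paramGrid hyperparameter grid (default [defaultParamGrid()]).
#' @param nDraws random draws from the grid (default 48).
#' @param cvFolds folds (default 10; requires `nrow(data) >= 10 * cvFolds`).
#' @return list(fit, params, cv_r2).
#' @export
gridSearchMember <- function(data, response, features,
                             paramGrid = defaultParamGrid(),
                             nDraws = 48, cvFolds = 10) {
  n <- nrow(data)
  if (n < 10 * cvFolds)
    stop("need at least ", 10 * cvFolds, " rows for ", cvFolds, "-fold CV")
  if (stats::var(data[[response]]) == 0) stop("degenerate (constant) response")
  draws <- if (nDraws >= nrow(paramGrid)) seq_len(nrow(paramGrid))
           else sample.int(nrow(paramGrid), nDraws)
  fold <- sample(rep_len(seq_len(cvFolds), n))
  best <- NULL
  for (d in draws) {
    p <- paramGrid[d, ]
    r2 <- numeric(cvFolds)
    for (k in seq_len(cvFolds)) {
      tr <- data[fold != k, , drop = FALSE]
      te <- data[fold == k, , drop = FALSE]
      fit <- fitRanger(tr, response, features, p, seed = d * 1000L + k)
      pred <- stats::predict(fit, te[, features, drop = FALSE])$predictions
      sse <- sum((te[[response]] - pred)^2)
      sst <- sum((te[[response]] - mean(te[[response]]))^2)
      r2[k] <- 1 - sse / sst
    }
    score <- mean(r2)
    if (is.null(best) || score > best$cv_r2)
      best <- list(params = p, cv_r2 = score)
  }
  best$fit <- fitRanger(data, response, features, best$params,
                        seed = 1L, importance = "permutation")
  best[c("fit", "params", "cv_r2")]
}

#' Train a buffer-zone bootstrap ensemble
#'
#' Repeats, for each of `nMembers` members: an independent random-order
#' buffer thinning of the training points (pairwise distance >
#' `minDistKm`), then a randomized hyperparameter grid search with k-fold
#' cross-validation on the thinned subsample. Rows with missing response
#' or covariates are dropped (counted in metadata). Fully reproducible
#' from `seed` (member seeds derived with [deriveSeed()]).
#'
#' @param pixels data.frame with `lon`, `lat`, the response and covariate
#'   columns.
#' @param response response column name (default `"cwd"`).
#' @param features covariate column names.
#' @param nMembers ensemble size (default 200).
#' @param minDistKm buffer distance, km (default 50).
#' @param subsampleTarget target size of each member's subsample
#'   (default 2000).
#' @param nDraws,cvFolds,paramGrid grid-search controls.
#' @param seed master integer seed.
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(pixels, response = "cwd", features,
                          nMembers = 200, minDistKm = 50,
                          subsampleTarget = 2000, nDraws = 48,
                          cvFolds = 10, paramGrid = defaultParamGrid(),
                          seed = 1L) {
  cols <- c(response, features)
  ok <- stats::complete.cases(pixels[, c("lon", "lat", cols)])
  nDropped <- sum(!ok)
  if (nDropped) message(nDropped, " rows with missing values dropped")
  d <- pixels[ok, , drop = FALSE]
  if (nrow(d) < 10 * cvFolds) stop("too few complete rows to train")
  members <- vector("list", nMembers)
  for (m in seq_len(nMembers)) {
    set.seed(deriveSeed(seed, paste0("member", m)))
    idx <- bufferSubsample(d$lon, d$lat, minDistKm, subsampleTarget)
    mem <- gridSearchMember(d[idx, , drop = FALSE], response, features,
                            paramGrid, nDraws, cvFolds)
    mem$indices <- which(ok)[idx]
    members[[m]] <- mem
  }
  new("EnsembleModel", members = members, features = features,
      minDistKm = minDistKm, seed = as.integer(seed),
      meta = list(response = response, subsampleTarget = subsampleTarget,
                  nDraws = nDraws, cvFolds = cvFolds,
                  gridSize = nrow(paramGrid), nDroppedRows = nDropped))
}

#' @rdname trainEnsemble
#' @param x an `EnsembleModel`.
#' @export
memberCvR2 <- function(x) vapply(x@members, `[[`, numeric(1), "cv_r2")

setMethod("show", "EnsembleModel", function(object) {
  r2 <- memberCvR2(object)
  cat("EnsembleModel:", length(object@members), "members,",
      length(object@features), "features; buffer >", object@minDistKm, "km\n")
  cat(sprintf("  member CV R2: median %.3f [%.3f, %.3f]\n",
              stats::median(r2), min(r2), max(r2)))
})

#' Ensemble prediction with pixel-wise uncertainty
#'
#' Predicts every non-masked pixel of a covariate stack with each member
#' and returns the ensemble mean map and the coefficient-of-variation map
#' (population standard deviation divided by the mean). Pixels with
#' non-positive ensemble mean get `NA` CV (counted); masked pixels
#' propagate nodata.
#'
#' @param model an [EnsembleModel-class].
#' @param stack a [RasterGrid-class] carrying all training features.
#' @return a [RasterGrid-class] with layers `mean` and `cv`; attribute
#'   `n_cv_undefined` counts positive-mask pixels with undefined CV.
#' @export
predictEnsemble <- function(model, stack) {
  missing <- setdiff(model@features, layerNames(stack))
  if (length(missing))
    stop("stack lacks training feature(s): ", paste(missing, collapse = ", "))
  mask <- rasterMask(stack)
  idx <- which(mask)
  X <- as.data.frame(lapply(model@features,
                            function(nm) rasterLayer(stack, nm)[idx]))
  names(X) <- model@features
  P <- vapply(model@members,
              function(m) stats::predict(m$fit, X)$predictions,
              numeric(nrow(X)))
  mu <- rowMeans(P)
  sdpop <- sqrt(rowMeans((P - mu)^2))
  cv <- ifelse(mu > 0, sdpop / mu, NA_real_)
  mmean <- matrix(NA_real_, nrow(mask), ncol(mask))
  mcv <- mmean
  mmean[idx] <- mu
  mcv[idx] <- cv
  out <- RasterGrid(list(mean = mmean, cv = mcv), xmin = stack@xmin,
                    ymax = stack@ymax, res = stack@res,
                    mask = mask & !is.na(mmean))
  # cv layer may have extra NAs where mean <= 0; keep the shared mask on
  # 'mean' and record the count
  out@layers$cv <- mcv
  attr(out, "n_cv_undefined") <- sum(mu <= 0)
  out
}
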