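#' Fit a bivariate PCA convex-hull model of the training covariate space
#'
#' Standardizes the training covariates (centring and unit scaling),
#' eigendecomposes their correlation structure and retains the smallest
#' number of leading principal components whose cumulative explained
#' variance exceeds `varThreshold` (at least 2, so bivariate hulls exist).
#' A 2-D convex hull of the training scores is stored for every pair of
#' retained PCs (`choose(k, 2)` hulls).
#'
#' Constant columns carry no information and are dropped with a warning.
#'
#' @param X numeric matrix or data.frame of training covariates (>= 3
#'   rows, no missing values).
#' @param varThreshold cumulative explained-variance threshold
#'   (default 0.90).
#' @return a [HullModel-class].
#' @export
fitHullModel <- function(X, varThreshold = 0.90) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 training rows")
  if (anyNA(X)) stop("training covariates contain missing values")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(X)
  Z <- sweep(sweep(X, 2L, ctr), 2L, sds, "/")
  eg <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  share <- cumsum(ev) / sum(ev)
  k <- max(2L, which(share > varThreshold)[1L])
  k <- min(k, ncol(Z))
  scores <- Z %*% eg$vectors[, seq_len(k), drop = FALSE]
  hulls <- list()
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      pts <- scores[, c(i, j), drop = FALSE]
      h <- grDevices::chull(pts)
      hulls[[length(hulls) + 1L]] <-
        list(i = i, j = j, vertices = pts[h, , drop = FALSE])
    }
  }
  new("HullModel", center = ctr, scale = sds,
      rotation = eg$vectors, eigenvalues = ev, k = as.integer(k),
      hulls = hulls, features = colnames(X), varThreshold = varThreshold)
}

setMethod("show", "HullModel", function(object) {
  share <- sum(object@eigenvalues[seq_len(object@k)]) / sum(object@eigenvalues)
  cat("HullModel:", length(object@features), "features ->", object@k,
      sprintf("PCs (%.1f%% variance), %d bivariate hulls\n",
              100 * share, length(object@hulls)))
})

# vectorized point-in-convex-polygon; boundary counts as inside.
# vertices as returned by chull (consistently oriented).
pointsInHull <- function(px, py, vertices) {
  nv <- nrow(vertices)
  if (nv < 3L) {
    # degenerate hull (collinear training points): inside iff on the segment
    return(rep(FALSE, length(px)))
  }
  # orientation from the signed area
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  area2 <- sum(vx * c(vy[-1L], vy[1L]) - c(vx[-1L], vx[1L]) * vy)
  s <- sign(area2)
  inside <- rep(TRUE, length(px))
  for (e in seq_len(nv)) {
    x1 <- vx[e]; y1 <- vy[e]
    x2 <- vx[e %% nv + 1L]; y2 <- vy[e %% nv + 1L]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    inside <- inside & (s * cross >= 0)
    if (!any(inside)) break
  }
  inside
}

#' Classify points against the training hulls
#'
#' Projects new points with the *training* centring, scaling and
#' eigenvectors and returns, per point, the fraction of bivariate hulls
#' containing it (boundary counts as inside).
#'
#' @param model a [HullModel-class].
#' @param X matrix or data.frame with the training features as columns.
#' @return numeric vector of hull-coverage fractions in `[0, 1]`.
#' @export
classifyPoints <- function(model, X) {
  X <- as.data.frame(X)
  missing <- setdiff(model@features, colnames(X))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  M <- as.matrix(X[, model@features, drop = FALSE])
  Z <- sweep(sweep(M, 2L, model@center), 2L, model@scale, "/")
  scores <- Z %*% model@rotation[, seq_len(model@k), drop = FALSE]
  counts <- rep(0L, nrow(Z))
  for (h in model@hulls)
    counts <- counts + pointsInHull(scores[, h$i], scores[, h$j], h$vertices)
  counts / max(1L, length(model@hulls))
}

#' Interpolation-versus-extrapolation classification of a raster stack
#'
#' Applies [classifyPoints()] to every non-masked pixel and returns the
#' hull-coverage fraction map, the binary interpolation mask (fraction at
#' least `insideThreshold`) and the global share of non-masked pixels
#' flagged as interpolation.
#'
#' @param model a [HullModel-class].
#' @param stack a [RasterGrid-class] with all training features.
#' @param insideThreshold per-pixel fraction above which a pixel counts as
#'   interpolation (default 0.95).
#' @return list(grid = [RasterGrid-class] with layers `fraction` and
#'   `interpolation` (0/1), `interpolation_share` = fraction of valid
#'   pixels classified as interpolation).
#' @export
classifyGrid <- function(model, stack, insideThreshold = 0.95) {
  missing <- setdiff(model@features, layerNames(stack))
  if (length(missing))
    stop("stack lacks feature(s): ", paste(missing, collapse = ", "))
  mask <- rasterMask(stack)
  idx <- which(mask)
  X <- as.data.frame(lapply(model@features,
                            function(nm) rasterLayer(stack, nm)[idx]))
  names(X) <- model@features
  frac <- classifyPoints(model, X)
  fm <- matrix(NA_real_, nrow(mask), ncol(mask))
  im <- fm
  fm[idx] <- frac
  im[idx] <- as.numeric(frac >= insideThreshold)
  list(grid = RasterGrid(list(fraction = fm, interpolation = im),
                         xmin = stack@xmin, ymax = stack@ymax,
                         res = stack@res, mask = mask),
       interpolation_share = mean(frac >= insideThreshold))
}
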