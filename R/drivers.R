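#' Predictor screening: correlation clustering then iterative VIF
#'
#' First removes near-duplicate predictors by complete-linkage hierarchical
#' clustering on `1 - |r|` (clusters with pairwise `|r| > corCut` keep one
#' representative, the first by column order). Then iteratively computes
#' variance inflation factors `VIF_j = 1/(1 - R2_j)` from regressing each
#' predictor on the others and drops the largest-VIF predictor until all
#' fall below the threshold. Exactly collinear columns are caught by the
#' clustering step (|r| = 1) or dropped with a warning.
#'
#' @param X data.frame or matrix of numeric predictors (>= 2 columns,
#'   more rows than columns).
#' @param threshold VIF threshold (default 5).
#' @param corCut absolute-correlation cut for the pre-clustering
#'   (default 0.95).
#' @return list(retained, vifs, removed_cluster, removed_vif).
#' @export
vifScreen <- function(X, threshold = 5, corCut = 0.95) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2L, nrow(X) > ncol(X))
  keep <- colnames(X)
  removed_cluster <- character(0)
  if (ncol(X) >= 2L) {
    cm <- abs(stats::cor(X))
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "complete")
    grp <- stats::cutree(hc, h = 1 - corCut)
    reps <- tapply(colnames(X), grp, `[`, 1L)
    removed_cluster <- setdiff(colnames(X), reps)
    keep <- colnames(X)[colnames(X) %in% reps]
  }
  removed_vif <- character(0)
  vifOne <- function(j, cols) {
    r2 <- summary(stats::lm(
      stats::reformulate(cols[cols != j], response = j),
      data = X))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(keep) < 2L) break
    vifs <- vapply(keep, vifOne, numeric(1), cols = keep)
    if (max(vifs) < threshold) break
    worst <- keep[which.max(vifs)]
    removed_vif <- c(removed_vif, worst)
    keep <- setdiff(keep, worst)
  }
  vifs <- if (length(keep) >= 2L)
    vapply(keep, vifOne, numeric(1), cols = keep)
  else stats::setNames(rep(1, length(keep)), keep)
  list(retained = keep, vifs = vifs,
       removed_cluster = removed_cluster, removed_vif = removed_vif)
}

#' One observation per grid cell
#'
#' Assigns each row to the geographic cell of size `cellDeg` containing it
#' and uniformly samples exactly one row per occupied cell.
#'
#' @param lon,lat row coordinates.
#' @param cellDeg cell size in degrees (default 0.25).
#' @return integer row indices of the subsample.
#' @export
bootstrapGridSubsample <- function(lon, lat, cellDeg = 0.25) {
  cell <- paste(floor(lon / cellDeg), floor(lat / cellDeg), sep = ",")
  idx <- split(seq_along(lon), cell)
  out <- vapply(idx, function(v)
    if (length(v) == 1L) v else v[sample.int(length(v), 1L)], integer(1))
  unname(sort(out))
}

#' Bootstrapped variable importance and standardized partial regression
#'
#' Repeats `nBoot` times: draw a spatially thinned subsample (one row per
#' `cellDeg` grid cell), fit (a) a random-forest regressor with
#' permutation importance (mean decrease in out-of-bag accuracy) and (b)
#' an ordinary least squares regression on the z-scored response and
#' predictors, recording the standardized coefficients. Aggregates mean
#' and SD across bootstraps and ranks predictors by mean importance.
#' Bootstraps with fewer than `10 * p` rows are skipped and counted.
#'
#' @param data data.frame with `lon`, `lat`, the response and predictors.
#' @param response response column name.
#' @param predictors predictor column names (after [vifScreen()]).
#' @param nBoot bootstrap replicates (default 100).
#' @param cellDeg thinning cell size, degrees (default 0.25).
#' @param numTrees forest size per bootstrap (default 100).
#' @param seed integer seed.
#' @return list(importance, coefficients, n_skipped); the tables carry
#'   `variable, mean, sd, top1_freq` (importance) and `variable, mean, sd`
#'   (coefficients), ordered by mean importance / |coefficient|.
#' @export
importanceBootstrap <- function(data, response, predictors, nBoot = 100,
                                cellDeg = 0.25, numTrees = 100, seed = 1L) {
  p <- length(predictors)
  imp <- matrix(NA_real_, nBoot, p, dimnames = list(NULL, predictors))
  coefs <- imp
  skipped <- 0L
  for (b in seq_len(nBoot)) {
    set.seed(deriveSeed(seed, paste0("boot", b)))
    idx <- bootstrapGridSubsample(data$lon, data$lat, cellDeg)
    d <- data[idx, c(response, predictors), drop = FALSE]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (nrow(d) < 10 * p) {
      skipped <- skipped + 1L
      next
    }
    rf <- ranger::ranger(dependent.variable.name = response, data = d,
                         num.trees = numTrees, importance = "permutation",
                         seed = deriveSeed(seed, paste0("rf", b)),
                         num.threads = 1L)
    imp[b, ] <- rf$variable.importance[predictors]
    z <- as.data.frame(scale(d))
    fit <- stats::lm(stats::reformulate(predictors, response = response),
                     data = z)
    coefs[b, ] <- stats::coef(fit)[predictors]
  }
  used <- stats::complete.cases(imp)
  if (!any(used)) stop("every bootstrap was skipped")
  top1 <- apply(imp[used, , drop = FALSE], 1L, which.max)
  importance <- data.frame(
    variable = predictors,
    mean = colMeans(imp[used, , drop = FALSE]),
    sd = apply(imp[used, , drop = FALSE], 2L, stats::sd),
    top1_freq = as.numeric(table(factor(top1, levels = seq_len(p)))) /
      sum(used),
    row.names = NULL)
  importance <- importance[order(-importance$mean), ]
  coefficients <- data.frame(
    variable = predictors,
    mean = colMeans(coefs[used, , drop = FALSE]),
    sd = apply(coefs[used, , drop = FALSE], 2L, stats::sd),
    row.names = NULL)
  coefficients <- coefficients[order(-abs(coefficients$mean)), ]
  rownames(importance) <- rownames(coefficients) <- NULL
  list(importance = importance, coefficients = coefficients,
       n_skipped = skipped)
}

# closed-form univariate regression SSE of y ~ x (with intercept)
regressSSE <- function(x, y) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0) return(list(sse = syy, slope = NA_real_,
                            intercept = mean(y), df = n - 1L))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(sse = syy - sxy^2 / sxx, slope = slope,
       intercept = mean(y) - slope * mean(x), df = n - 2L)
}

partitionNode <- function(d, response, disturbanceVar, candidates, minNode,
                          alpha, probs, nodeId, depth) {
  n <- nrow(d)
  y <- d[[response]]
  x <- d[[disturbanceVar]]
  base <- regressSSE(x, y)
  node <- list(id = nodeId, n = n, depth = depth,
               intercept = base$intercept, slope = base$slope,
               split_var = NA_character_, split_threshold = NA_real_,
               p_adjusted = NA_real_, children = NULL)
  if (is.na(base$slope)) {
    node$flag <- "constant-disturbance"
    return(node)
  }
  if (n < 2 * minNode) return(node)
  best <- NULL
  nScanned <- 0L
  for (v in candidates) {
    cuts <- unique(stats::quantile(d[[v]], probs = probs, names = FALSE))
    for (t in cuts) {
      left <- d[[v]] <= t
      nl <- sum(left); nr <- n - nl
      if (nl < minNode || nr < minNode) next
      nScanned <- nScanned + 1L
      sseL <- regressSSE(x[left], y[left])$sse
      sseR <- regressSSE(x[!left], y[!left])$sse
      sse_split <- sseL + sseR
      if (is.null(best) || sse_split < best$sse_split)
        best <- list(var = v, threshold = t, sse_split = sse_split)
    }
  }
  if (is.null(best)) return(node)
  Fstat <- ((base$sse - best$sse_split) / 2) / (best$sse_split / (n - 4))
  p <- stats::pf(Fstat, 2, n - 4, lower.tail = FALSE)
  # Bonferroni over every scanned (candidate, threshold) pair: the best
  # split was selected from the whole grid, so correcting only over the
  # candidates would not control the per-node error rate
  p_adj <- min(1, p * nScanned)
  if (p_adj > alpha) return(node)
  node$split_var <- best$var
  node$split_threshold <- best$threshold
  node$p_adjusted <- p_adj
  left <- d[[best$var]] <= best$threshold
  node$children <- list(
    partitionNode(d[left, , drop = FALSE], response, disturbanceVar,
                  candidates, minNode, alpha, probs, nodeId * 2L, depth + 1L),
    partitionNode(d[!left, , drop = FALSE], response, disturbanceVar,
                  candidates, minNode, alpha, probs, nodeId * 2L + 1L,
                  depth + 1L)
  )
  node
}

#' Model-based recursive partitioning of a disturbance effect
#'
#' At each node, fits the univariate regression of the response on the
#' disturbance variable; then, for each candidate covariate, scans split
#' thresholds on a quantile grid, refits the regression separately in both
#' children and takes the (covariate, threshold) minimizing the split SSE.
#' The split is accepted iff the F test
#' `F = ((SSE_pooled - SSE_split)/2) / (SSE_split/(n - 4))`, Bonferroni
#' adjusted over every scanned (covariate, threshold) pair, is significant
#' at `alpha` and both children hold at least `minNode` rows; accepted
#' splits recurse. Leaves report the local intercept and slope of the
#' disturbance effect.
#'
#' @param data data.frame with response, disturbance and candidate
#'   columns.
#' @param response response column name (default `"cwd"`).
#' @param disturbanceVar disturbance regressor (must not be a candidate).
#' @param candidates covariates screened as split variables (the paper's
#'   workflow uses the top four by forest importance).
#' @param minNode minimum rows per node; default `max(500, 3%% of n)`.
#' @param alpha significance level after Bonferroni adjustment
#'   (default 0.01).
#' @param probs quantile grid of candidate thresholds (default deciles).
#' @return a [PartitionTree-class].
#' @export
partitionDisturbance <- function(data, response = "cwd", disturbanceVar,
                                 candidates,
                                 minNode = max(500, ceiling(0.03 * nrow(data))),
                                 alpha = 0.01,
                                 probs = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(disturbanceVar %in% names(data),
            all(candidates %in% names(data)),
            !disturbanceVar %in% candidates)
  d <- data[stats::complete.cases(
    data[, c(response, disturbanceVar, candidates)]), , drop = FALSE]
  root <- partitionNode(d, response, disturbanceVar, candidates,
                        minNode, alpha, probs, 1L, 0L)
  new("PartitionTree", root = root, disturbanceVar = disturbanceVar,
      candidates = candidates, minNode = as.integer(minNode),
      alpha = alpha, n = nrow(d))
}

collectLeaves <- function(node, path = "") {
  if (is.null(node$children)) {
    return(list(data.frame(id = node$id, depth = node$depth, n = node$n,
                           intercept = node$intercept, slope = node$slope,
                           path = path, stringsAsFactors = FALSE)))
  }
  c(collectLeaves(node$children[[1L]],
                  sprintf("%s%s%s <= %.4g", path,
                          if (nzchar(path)) " & " else "",
                          node$split_var, node$split_threshold)),
    collectLeaves(node$children[[2L]],
                  sprintf("%s%s%s > %.4g", path,
                          if (nzchar(path)) " & " else "",
                          node$split_var, node$split_threshold)))
}

#' Leaves of a partition tree as a table
#' @param tree a [PartitionTree-class].
#' @return data.frame: `id, depth, n, intercept, slope, path`.
#' @export
partitionLeaves <- function(tree) {
  out <- do.call(rbind, collectLeaves(tree@root))
  rownames(out) <- NULL
  out
}

renderNode <- function(node, disturbanceVar, indent = "") {
  if (is.null(node$children)) {
    sprintf("%s* leaf (n = %d): %s = %.4f %+.4f x %s\n", indent, node$n,
            "response", node$intercept, node$slope, disturbanceVar)
  } else {
    paste0(
      sprintf("%s%s <= %.4g (p_adj = %.3g, n = %d)\n", indent,
              node$split_var, node$split_threshold, node$p_adjusted, node$n),
      renderNode(node$children[[1L]], disturbanceVar, paste0(indent, "  ")),
      sprintf("%s%s > %.4g\n", indent, node$split_var, node$split_threshold),
      renderNode(node$children[[2L]], disturbanceVar, paste0(indent, "  "))
    )
  }
}

setMethod("show", "PartitionTree", function(object) {
  cat("PartitionTree on", object@disturbanceVar, "| n =", object@n,
      "| minNode =", object@minNode, "| alpha =", object@alpha, "\n")
  cat(renderNode(object@root, object@disturbanceVar))
})

#' Serialize a partition tree to JSON
#' @param tree a [PartitionTree-class].
#' @param file optional path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
partitionTreeJson <- function(tree, file = NULL) {
  payload <- list(disturbance_var = tree@disturbanceVar,
                  candidates = tree@candidates, min_node = tree@minNode,
                  alpha = tree@alpha, n = tree@n, root = tree@root)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
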