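test_that("haversineKm reproduces textbook great-circle distances", {
  expect_equal(haversineKm(10, 20, 10, 20), 0)
  # one degree of longitude at the equator: 2*pi*R/360
  expect_equal(haversineKm(0, 0, 1, 0), 2 * pi * 6371 / 360,
               tolerance = 1e-4)
  # antipodal points: pi*R
  expect_equal(haversineKm(0, 0, 180, 0), pi * 6371, tolerance = 1e-4)
})

test_that("Moran's I matches the brute-force double sum on hand-set points", {
  lon <- c(0, 0.2, 0.4, 0.6)
  lat <- c(0, 0, 0, 0)
  z <- c(1.2, -0.4, 0.7, -1.5)
  # direct check on 4 points with one wide bin and precomputed residuals
  cg <- residualCorrelogram(lon, lat, z, baseline = rep(0, length(z)),
                            breaks = c(0, 100))
  n <- 4
  zc <- z - mean(z)
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    haversineKm(lon[i], lat[i], lon[j], lat[j]))
  W <- D > 0 & D <= 100; diag(W) <- FALSE
  manual <- (n / sum(W)) * sum(W * outer(zc, zc)) / sum(zc^2)
  expect_equal(cg$moran_i[1L], manual, tolerance = 1e-12)
  expect_equal(cg$expectation[1L], -1 / 3)
  # empty bin is reported as missing
  cg2 <- residualCorrelogram(lon, lat, z, baseline = rep(0, 4),
                             breaks = c(500, 1000))
  expect_true(is.na(cg2$moran_i[1L]))
})

test_that("correlogram recovers planted short-range autocorrelation", {
  set.seed(14)
  n <- 400
  lon <- stats::runif(n, 0, 6); lat <- stats::runif(n, 0, 6)
  # spatial noise with ~30 km range: nearest-neighbour kernel smoothing
  base <- stats::rnorm(n)
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    haversineKm(lon[i], lat[i], lon[j], lat[j]))
  K <- exp(-(D / 30)^2)
  val <- as.numeric(K %*% base / rowSums(K)) + stats::rnorm(n, 0, 0.05)
  cg <- residualCorrelogram(lon, lat, val, baseline = rep(mean(val), n),
                            breaks = c(0, 30, 100, 200, 400))
  expect_gt(cg$moran_i[1L], 0.3)                  # strong at short range
  expect_lt(abs(cg$moran_i[4L]), 0.1)             # near null far away
  # i.i.d. residuals: I stays within a Monte-Carlo envelope of -1/(n-1)
  set.seed(15)
  iid <- stats::rnorm(n)
  cgi <- residualCorrelogram(lon, lat, iid, baseline = rep(0, n),
                             breaks = c(0, 100))
  perm <- replicate(200, {
    zp <- sample(iid)
    residualCorrelogram(lon, lat, zp, baseline = rep(0, n),
                        breaks = c(0, 100))$moran_i[1L]
  })
  expect_gt(cgi$moran_i[1L], stats::quantile(perm, 0.005))
  expect_lt(cgi$moran_i[1L], stats::quantile(perm, 0.995))
})

test_that("the default GAM baseline absorbs the smooth trend", {
  w <- smallWorld()
  tab <- worldTraitTable(w)
  recs <- communityRecords(w@plots, tab)
  cov <- extractCovariates(w@landscape, recs$lon, recs$lat,
                           c("temperature", "soil_moisture"))
  cg <- residualCorrelogram(recs$lon, recs$lat, recs$cwd, covariates = cov,
                            breaks = c(0, 100, 300))
  expect_true(all(is.finite(cg$moran_i)))
  expect_lt(max(abs(cg$moran_i)), 0.5)  # trend removed, no runaway structure
})

test_that("bufferSubsample follows the greedy acceptance rule", {
  # all points mutually > 50 km apart are all retained, any order
  lon <- c(0, 1, 2); lat <- c(0, 0, 0)  # ~111 km spacing
  for (s in 1:5) {
    set.seed(s)
    expect_setequal(bufferSubsample(lon, lat, 50), 1:3)
  }
  # collinear points at 0, 40, 80 km visited in order (1, 2, 3) -> {1, 3}
  km <- 2 * pi * 6371 / 360
  lon2 <- c(0, 40, 80) / km; lat2 <- c(0, 0, 0)
  s <- which(vapply(1:200, function(s) {
    set.seed(s); identical(sample.int(3), 1:3)
  }, logical(1)))[1L]
  set.seed(s)
  expect_equal(sort(bufferSubsample(lon2, lat2, 50)), c(1L, 3L))
  # duplicate coordinates: exactly one survives
  set.seed(1)
  dup <- bufferSubsample(c(0, 0, 5), c(0, 0, 0), 50)
  expect_equal(length(dup), 2L)
  expect_equal(sum(dup %in% 1:2), 1L)
  # unreachable target returns a smaller set with a notice
  set.seed(1)
  expect_message(short <- bufferSubsample(lon2, lat2, 50, targetN = 3),
                 "exhausted")
  expect_lt(length(short), 3L)
})

test_that("grid search finds learnable signal and stays honest on noise", {
  set.seed(22)
  n <- 600
  d <- data.frame(x1 = stats::runif(n), x2 = stats::runif(n))
  d$y <- sin(2 * pi * d$x1) + (2 * d$x2 - 1)^2 + stats::rnorm(n, 0, 0.1)
  grid <- defaultParamGrid()
  set.seed(23)
  m <- gridSearchMember(d, "y", c("x1", "x2"), paramGrid = grid,
                        nDraws = 6, cvFolds = 5)
  expect_gt(m$cv_r2, 0.8)
  # pure noise: cross-validated R2 stays near or below zero
  d$y <- stats::rnorm(n)
  set.seed(24)
  m0 <- gridSearchMember(d, "y", c("x1", "x2"), paramGrid = grid,
                         nDraws = 6, cvFolds = 5)
  expect_lt(m0$cv_r2, 0.1)
  # nDraws beyond the grid size evaluates each combination once
  tiny <- expand.grid(num_trees = 50, mtry_frac = c(0.5, 1),
                      max_depth = 0, min_node = 5)
  set.seed(25)
  mt <- gridSearchMember(d[1:80, ], "y", c("x1", "x2"), paramGrid = tiny,
                         nDraws = 10, cvFolds = 5)
  expect_true(nrow(merge(mt$params, tiny)) == 1L)
  expect_error(gridSearchMember(d[1:20, ], "y", c("x1", "x2"),
                                cvFolds = 10), "rows")
})

test_that("small ensembles are reproducible and respect the buffer invariant", {
  w <- smallWorld()
  tab <- worldTraitTable(w)
  recs <- communityRecords(w@plots, tab)
  px <- aggregateToPixels(recs, res = rasterRes(w@landscape),
                          xmin = w@landscape@xmin, ymax = w@landscape@ymax)
  d <- cbind(px, extractCovariates(w@landscape, px$lon, px$lat,
                                   c("temperature", "soil_moisture",
                                     "disturbance")))
  feats <- c("temperature", "soil_moisture", "disturbance")
  tiny <- expand.grid(num_trees = 60, mtry_frac = c(0.5, 1),
                      max_depth = c(0, 6), min_node = 5)
  em1 <- trainEnsemble(d, "cwd", feats, nMembers = 2, minDistKm = 40,
                       subsampleTarget = 150, nDraws = 4, cvFolds = 5,
                       paramGrid = tiny, seed = 99)
  em2 <- trainEnsemble(d, "cwd", feats, nMembers = 2, minDistKm = 40,
                       subsampleTarget = 150, nDraws = 4, cvFolds = 5,
                       paramGrid = tiny, seed = 99)
  expect_identical(lapply(em1@members, `[[`, "indices"),
                   lapply(em2@members, `[[`, "indices"))
  expect_equal(memberCvR2(em1), memberCvR2(em2))
  # buffer invariant: every member's subsample pairwise > minDistKm
  for (m in em1@members) {
    pts <- d[m$indices, ]
    D <- outer(seq_len(nrow(pts)), seq_len(nrow(pts)), function(i, j)
      haversineKm(pts$lon[i], pts$lat[i], pts$lon[j], pts$lat[j]))
    expect_gt(min(D[upper.tri(D)]), 40)
  }
  # prediction: mean map is member-permutation invariant; cv arithmetic
  pred <- predictEnsemble(em1, w@landscape)
  emr <- em1; emr@members <- rev(emr@members)
  predr <- predictEnsemble(emr, w@landscape)
  expect_equal(rasterLayer(pred, "mean"), rasterLayer(predr, "mean"))
  expect_error(predictEnsemble(em1, generateLandscape(8, 8, seed = 1,
    params = list())), NA)
})

test_that("predictEnsemble computes population-sd CV and propagates nodata", {
  # two constant members predicting 0.4 and 0.6: mean 0.5, cv = 0.1/0.5
  w <- smallWorld()
  constMember <- function(v) {
    d <- data.frame(y = rep(v, 60) + stats::rnorm(60, 0, 1e-12),
                    temperature = stats::runif(60))
    list(fit = ranger::ranger(y ~ temperature, data = d, num.trees = 5,
                              seed = 1, num.threads = 1L),
         params = list(), indices = 1:60, cv_r2 = 0)
  }
  em <- new("EnsembleModel",
            members = list(constMember(0.4), constMember(0.6)),
            features = "temperature", minDistKm = 50, seed = 1L,
            meta = list())
  pred <- predictEnsemble(em, w@landscape)
  msk <- rasterMask(w@landscape)
  expect_equal(unique(round(rasterLayer(pred, "mean")[msk], 10)), 0.5)
  expect_equal(unique(round(rasterLayer(pred, "cv")[msk], 10)), 0.2)
  expect_true(all(is.na(rasterLayer(pred, "mean")[!msk])))
  expect_true(all(is.na(rasterLayer(pred, "cv")[!msk])))
  # identical members give a zero cv map
  em0 <- new("EnsembleModel",
             members = list(constMember(0.4), constMember(0.4)),
             features = "temperature", minDistKm = 50, seed = 1L,
             meta = list())
  p0 <- predictEnsemble(em0, w@landscape)
  expect_lt(max(rasterLayer(p0, "cv")[msk]), 1e-9)
})
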