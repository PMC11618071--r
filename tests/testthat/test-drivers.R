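test_that("vifScreen computes VIFs and drops collinear predictors", {
  set.seed(51)
  n <- 300
  # orthogonal-ish predictors: all VIFs ~ 1, nothing dropped
  X <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n),
                  c = stats::rnorm(n))
  vs <- vifScreen(X)
  expect_setequal(vs$retained, c("a", "b", "c"))
  expect_true(all(vs$vifs < 1.2))
  # planted r = 0.9 pair: VIF = 1/(1-0.81) > 5, one dropped
  z <- stats::rnorm(n)
  X2 <- data.frame(a = z,
                   b = 0.9 * z + sqrt(1 - 0.81) * stats::rnorm(n),
                   c = stats::rnorm(n))
  # check the closed form on the raw pair before screening
  r <- stats::cor(X2$a, X2$b)
  vif_ab <- 1 / (1 - summary(stats::lm(a ~ b, X2))$r.squared)
  expect_equal(vif_ab, 1 / (1 - r^2), tolerance = 1e-10)
  vs2 <- vifScreen(X2, threshold = 5)
  expect_equal(length(vs2$removed_vif), 1L)
  expect_true(all(vs2$vifs < 5))
  # duplicated column removed at the clustering step
  X3 <- data.frame(a = z, a2 = z, b = stats::rnorm(n))
  vs3 <- vifScreen(X3)
  expect_equal(vs3$removed_cluster, "a2")
})

test_that("bootstrapGridSubsample keeps one observation per occupied cell", {
  lon <- c(0.01, 0.02, 0.03, 1.3, 2.6)
  lat <- c(0.01, 0.02, 0.03, 1.3, 2.6)
  set.seed(52)
  idx <- bootstrapGridSubsample(lon, lat, cellDeg = 0.25)
  expect_equal(length(idx), 3L)        # 3 rows share one cell
  expect_equal(sum(idx %in% 1:3), 1L)
  # singleton cells all survive
  lon2 <- seq(0, 24.75, by = 0.26)[1:50]
  expect_equal(length(bootstrapGridSubsample(lon2, rep(0.1, 50))), 50L)
  # stochastic within multi-row cells
  picks <- replicate(30, {
    bootstrapGridSubsample(lon, lat, 0.25)[1L]
  })
  expect_gt(length(unique(picks)), 1L)
})

test_that("importanceBootstrap finds the planted dominant driver", {
  set.seed(53)
  n <- 900
  d <- data.frame(lon = stats::runif(n, 0, 8), lat = stats::runif(n, 0, 8))
  d$temperature <- stats::runif(n, 0, 25)
  d$noisevar <- stats::rnorm(n)
  d$moisture <- stats::runif(n)
  d$cwd <- 0.45 + 0.004 * d$temperature - 0.01 * d$moisture +
    stats::rnorm(n, 0, 0.02)
  ib <- importanceBootstrap(d, "cwd", c("temperature", "moisture", "noisevar"),
                            nBoot = 20, cellDeg = 0.25, seed = 3)
  expect_equal(ib$importance$variable[1L], "temperature")
  expect_gte(ib$importance$top1_freq[ib$importance$variable == "temperature"],
             0.9)
  # pure-noise predictor: importance within 2 sd of zero
  nv <- ib$importance[ib$importance$variable == "noisevar", ]
  expect_lt(nv$mean, 2 * nv$sd + 1e-12)
  # single-predictor standardized coefficient equals Pearson r
  ib1 <- importanceBootstrap(d, "cwd", "temperature", nBoot = 4,
                             cellDeg = 1e-5, seed = 4) # every row its own cell
  expect_equal(ib1$coefficients$mean[1L],
               stats::cor(d$cwd, d$temperature), tolerance = 1e-10)
})

test_that("importance rankings are stable between independent runs", {
  w <- smallWorld()
  tab <- worldTraitTable(w)
  recs <- communityRecords(w@plots, tab)
  d <- cbind(recs, extractCovariates(w@landscape, recs$lon, recs$lat,
                                     c("temperature", "soil_moisture",
                                       "disturbance")))
  preds <- c("temperature", "soil_moisture", "disturbance",
             "richness_scaled", "mean_dbh")
  r1 <- importanceBootstrap(d, "cwd", preds, nBoot = 15, seed = 11)
  r2 <- importanceBootstrap(d, "cwd", preds, nBoot = 15, seed = 999)
  k1 <- rank(-stats::setNames(r1$importance$mean, r1$importance$variable)[preds])
  k2 <- rank(-stats::setNames(r2$importance$mean, r2$importance$variable)[preds])
  tau <- stats::cor(k1, k2, method = "kendall")
  expect_gte(tau, 0.6)
})

test_that("partitionDisturbance recovers a planted slope reversal", {
  set.seed(54)
  n <- 4000
  d <- data.frame(temperature = stats::runif(n, 0, 25),
                  moisture = stats::runif(n),
                  disturbance = stats::runif(n))
  slope <- ifelse(d$temperature < 10, 0.02, -0.02)
  d$cwd <- 0.5 + slope * d$disturbance + stats::rnorm(n, 0, 0.02)
  pt <- partitionDisturbance(d, "cwd", "disturbance",
                             candidates = c("temperature", "moisture"),
                             minNode = 400, alpha = 0.01)
  expect_equal(pt@root$split_var, "temperature")
  expect_lt(abs(pt@root$split_threshold - 10), 1)
  leaves <- partitionLeaves(pt)
  cold <- leaves[grepl("temperature <=", leaves$path) &
                   !grepl("temperature >", leaves$path), ]
  warm <- leaves[grepl("temperature >", leaves$path) &
                   !grepl("temperature <=", leaves$path), ]
  expect_true(all(cold$slope > 0))
  expect_true(all(warm$slope < 0))
  expect_true(all(leaves$n >= 400))
})

test_that("homogeneous or tiny nodes yield a single-node tree", {
  set.seed(55)
  n <- 1500
  d <- data.frame(temperature = stats::runif(n, 0, 25),
                  disturbance = stats::runif(n))
  d$cwd <- 0.5 + 0.02 * d$disturbance + stats::rnorm(n, 0, 0.02)
  pt <- partitionDisturbance(d, "cwd", "disturbance",
                             candidates = "temperature",
                             minNode = 200, alpha = 0.01)
  expect_true(is.na(pt@root$split_var))
  expect_equal(nrow(partitionLeaves(pt)), 1L)
  # n below twice the minimum node size cannot split
  pt2 <- partitionDisturbance(d[1:300, ], "cwd", "disturbance",
                              candidates = "temperature", minNode = 300)
  expect_equal(nrow(partitionLeaves(pt2)), 1L)
  # constant disturbance: leaf flagged, slope undefined
  d3 <- d[1:600, ]; d3$disturbance <- 0.5
  pt3 <- partitionDisturbance(d3, "cwd", "disturbance",
                              candidates = "temperature", minNode = 100)
  expect_true(is.na(pt3@root$slope))
  expect_equal(pt3@root$flag, "constant-disturbance")
})

test_that("false-split rate under a homogeneous null stays within the bound", {
  set.seed(56)
  splits <- replicate(200, {
    n <- 700
    d <- data.frame(t1 = stats::runif(n), t2 = stats::runif(n),
                    disturbance = stats::runif(n))
    d$cwd <- 0.5 + 0.01 * d$disturbance + stats::rnorm(n, 0, 0.02)
    pt <- partitionDisturbance(d, "cwd", "disturbance",
                               candidates = c("t1", "t2"), minNode = 100,
                               alpha = 0.01)
    !is.na(pt@root$split_var)
  })
  # bound alpha * |candidates| = 0.02 plus Monte-Carlo slack at 120 draws
  expect_lte(mean(splits), 0.03)
})

test_that("partition trees serialize to JSON and text", {
  set.seed(57)
  n <- 900
  d <- data.frame(temperature = stats::runif(n, 0, 25),
                  disturbance = stats::runif(n))
  d$cwd <- 0.5 + ifelse(d$temperature < 12, 0.03, -0.03) * d$disturbance +
    stats::rnorm(n, 0, 0.02)
  pt <- partitionDisturbance(d, "cwd", "disturbance", "temperature",
                             minNode = 120)
  js <- jsonlite::fromJSON(partitionTreeJson(pt), simplifyVector = TRUE)
  expect_equal(js$n, n)
  expect_equal(js$disturbance_var, "disturbance")
  txt <- utils::capture.output(show(pt))
  expect_true(any(grepl("leaf", txt)))
})
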