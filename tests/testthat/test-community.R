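mkTable <- function() {
  buildTraitTable(data.frame(
    species = c("Quercus robur", "Quercus petraea", "Pinus sylvestris"),
    clade = c("angiosperm", "angiosperm", "gymnosperm"),
    wood_density = c(0.56, 0.58, 0.42)))
}

mkCensus <- function(species, dbh, plot_id = "p1", year = 2010,
                     area = 25, lat = 1, lon = 1, ...) {
  n <- length(species)
  data.frame(plot_id = rep(plot_id, n), lat = rep(lat, n),
             lon = rep(lon, n), area_m2 = rep(area, n),
             year = rep(year, n), species = species, dbh_cm = dbh, ...,
             stringsAsFactors = FALSE)
}

test_that("filterLatestCensus keeps the newest census and breaks ties by size", {
  p <- rbind(mkCensus("Quercus robur", c(10, 12), year = 1998),
             mkCensus("Quercus robur", c(10, 12, 14), year = 2010),
             mkCensus("Pinus sylvestris", 20, plot_id = "p2", year = 2005))
  out <- filterLatestCensus(p)
  expect_equal(sort(unique(out$year[out$plot_id == "p1"])), 2010)
  expect_equal(nrow(out[out$plot_id == "p2", ]), 1L)  # single census unchanged
  # tie on year: larger census wins (same-year censuses told apart by id)
  tie <- rbind(mkCensus(rep("Quercus robur", 30), rep(10, 30), year = 2000,
                        census_id = "c1"),
               mkCensus(rep("Pinus sylvestris", 12), rep(10, 12),
                        year = 2000, census_id = "c2"))
  expect_message(kept <- filterLatestCensus(tie), "tied")
  expect_equal(nrow(kept), 30L)
  expect_true(all(kept$species == "Quercus robur"))
})

test_that("assignWoodDensity prefers species, falls back to genus, else none", {
  tab <- mkTable()
  res <- assignWoodDensity(c("Quercus robur", "Quercus ilex", "Fagus spp"),
                           tab)
  expect_equal(res$level, c("species", "genus", "none"))
  expect_equal(res$density[1L], 0.56)
  expect_equal(res$density[2L], (0.56 + 0.58) / 2)  # genus over species means
  expect_true(is.na(res$density[3L]))
})

test_that("coverage filter drops below 75% and keeps the boundary", {
  tab <- mkTable()
  c7 <- mkCensus(c(rep("Quercus robur", 7), rep("Unknown tree", 3)),
                 rep(10, 10))
  expect_false(coverageFilter(c7, tab)$keep)          # 0.70 < 0.75
  c8 <- mkCensus(c(rep("Quercus robur", 8), rep("Unknown tree", 2)),
                 rep(10, 10))
  expect_true(coverageFilter(c8, tab)$keep)           # 0.80
  c34 <- mkCensus(c(rep("Quercus robur", 3), "Unknown tree"), rep(10, 4))
  expect_true(coverageFilter(c34, tab)$keep)          # exactly 0.75 kept
  expect_equal(coverageFilter(c34, tab)$coverage, 0.75)
  expect_message(e <- coverageFilter(mkCensus(character(0), numeric(0)), tab),
                 "empty")
  expect_false(e$keep)
})

test_that("computeCWD is the basal-area-weighted mean of Eq.-style weights", {
  tab <- mkTable()
  # one tree: CWD equals its density
  expect_equal(computeCWD(mkCensus("Quercus robur", 17), tab)$cwd, 0.56)
  # equal DBH: plain average
  r2 <- computeCWD(mkCensus(c("Quercus robur", "Pinus sylvestris"),
                            c(20, 20)), tab)
  expect_equal(r2$cwd, (0.56 + 0.42) / 2)
  expect_equal(r2$angiosperm_ratio, 0.5)
  # dbh {10,20,30} with wd {0.4,0.5,0.6}: weights prop to {100,400,900}
  tab3 <- buildTraitTable(data.frame(
    species = c("Aa aa", "Bb bb", "Cc cc"),
    wood_density = c(0.4, 0.5, 0.6)))
  r3 <- computeCWD(mkCensus(c("Aa aa", "Bb bb", "Cc cc"), c(10, 20, 30)),
                   tab3)
  expect_equal(r3$cwd, (0.4 * 100 + 0.5 * 400 + 0.6 * 900) / 1400)
  expect_equal(r3$cwd, 780 / 1400)
  # unmatched trees excluded, weights renormalized over matched only
  r4 <- computeCWD(mkCensus(c("Quercus robur", "Unknown tree"), c(10, 50)),
                   tab)
  expect_equal(r4$cwd, 0.56)
  expect_equal(r4$coverage_fraction, 0.5)
})

test_that("CWD is DBH-unit invariant and bounded by member densities", {
  tab <- worldTraitTable(smallWorld())
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    sp <- sample(speciesMeans(tab)$species, n, replace = TRUE)
    dbh <- stats::runif(n, 6, 60)
    c_cm <- mkCensus(sp, dbh)
    c_m <- mkCensus(sp, dbh / 100)           # same stems measured in metres
    expect_equal(computeCWD(c_cm, tab)$cwd, computeCWD(c_m, tab)$cwd)
    wds <- assignWoodDensity(sp, tab)$density
    cwd <- computeCWD(c_cm, tab)$cwd
    expect_gte(cwd, min(wds)); expect_lte(cwd, max(wds))
  }
})

test_that("richnessScaled applies the species-area exponent", {
  c1 <- mkCensus(paste("Sp", letters[1:5]), rep(10, 5), area = 25)
  expect_equal(richnessScaled(c1), 5)                     # reference area
  c2 <- mkCensus(paste("Sp", letters[1:16]), rep(10, 16), area = 16 * 25)
  expect_equal(richnessScaled(c2), 16 * (1 / 16)^0.25)    # = 8
  expect_equal(richnessScaled(c2, z = 0), 16)             # raw count
})

test_that("aggregateToPixels follows the half-open pixel convention", {
  rec <- data.frame(lon = c(0.1, 0.2, 1.5), lat = c(89.9, 89.95, 89.2),
                    cwd = c(0.4, 0.6, 0.9))
  px <- aggregateToPixels(rec, res = 1)
  expect_equal(nrow(px), 2L)
  one <- px[px$px_col == 180, ]          # floor((0.1 + 180)/1)
  expect_equal(one$cwd, 0.5)             # mean of the two co-located plots
  expect_equal(one$n_plots, 2L)
  # plot exactly on a cell edge goes to the cell whose interval starts there
  edge <- aggregateToPixels(data.frame(lon = 1, lat = 89, cwd = 1), res = 1)
  expect_equal(edge$px_col, 181)
  expect_equal(edge$px_row, 1)
  # aggregation then global mean differs from plot-level mean when pixel
  # plot counts are unequal, and agrees when they are equal
  expect_false(isTRUE(all.equal(mean(px$cwd), mean(rec$cwd))))
  rec_eq <- data.frame(lon = c(0.1, 1.5), lat = c(89.9, 89.2),
                       cwd = c(0.4, 0.6))
  px_eq <- aggregateToPixels(rec_eq, res = 1)
  expect_equal(mean(px_eq$cwd), mean(rec_eq$cwd))
})

test_that("biomeSummary recovers the generator's biome contrasts", {
  w <- smallWorld()
  tab <- worldTraitTable(w)
  recs <- communityRecords(w@plots, tab)
  px <- aggregateToPixels(recs, res = rasterRes(w@landscape),
                          xmin = w@landscape@xmin, ymax = w@landscape@ymax)
  bs <- biomeSummary(px, w@landscape)
  expect_true(all(bs$forest_type$group %in%
                    c("boreal", "temperate", "tropical", "dryland")))
  # truth: per-forest-type CWD means computed from the records directly
  bb <- extractCovariates(w@landscape, px$lon, px$lat, "biome")$biome
  for (ft in bs$forest_type$group) {
    code <- match(ft, c("boreal", "temperate", "tropical", "dryland"))
    truth <- px$cwd[!is.na(bb) & bb == code]
    row <- bs$forest_type[bs$forest_type$group == ft, ]
    expect_equal(row$mean, mean(truth), tolerance = 1e-12)
    expect_equal(row$n, length(truth))
  }
  # the planted warm > cold density ordering shows up in the summaries
  m <- stats::setNames(bs$forest_type$mean, bs$forest_type$group)
  expect_gt(m[["tropical"]], m[["boreal"]])
  # single-biome input: overall mean equals the biome mean
  one <- biomeSummary(px[which(bb == bb[!is.na(bb)][1L])[1:3], ],
                      w@landscape)
  expect_equal(nrow(one$biome), 1L)
})

test_that("temporal variance decomposition separates plot from year signal", {
  # identical CWD across years within plot, differing across plots
  rec <- data.frame(plot_id = rep(c("a", "b", "c"), each = 3),
                    year = rep(2000:2002, 3),
                    cwd = rep(c(0.4, 0.5, 0.6), each = 3))
  vd <- temporalVarianceDecomposition(rec)
  expect_gt(vd$fractions[["plot"]], 0.999)
  # planted sigma2_plot = 9, sigma2_year = 1, sigma2_res ~ 0
  set.seed(8)
  np <- 60; ny <- 8
  d <- expand.grid(plot_id = paste0("p", 1:np), year = 2000 + 1:ny)
  d$cwd <- stats::rnorm(np, 0, 3)[as.integer(factor(d$plot_id))] +
    stats::rnorm(ny, 0, 1)[as.integer(factor(d$year))] +
    stats::rnorm(nrow(d), 0, 0.01)
  vd2 <- temporalVarianceDecomposition(d)
  expect_lt(abs(vd2$fractions[["plot"]] - 0.9), 0.07)
  expect_lt(abs(vd2$fractions[["year"]] - 0.1), 0.07)
  expect_lt(vd2$fractions[["residual"]], 0.01)
  # single plot: plot component zero with warning
  expect_warning(
    v1 <- temporalVarianceDecomposition(
      data.frame(plot_id = "a", year = rep(2000:2005, each = 2),
                 cwd = stats::rnorm(12))), "single")
  expect_equal(unname(v1$fractions[["plot"]]), 0)
})
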