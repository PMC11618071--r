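#' Generate a two-clade ultrametric Yule phylogeny with synthetic taxonomy
#'
#' Simulates a pure-birth (Yule) tree for each of two labelled clades --
#' "angiosperm" and "gymnosperm" -- and joins them as the two children of
#' the root, rescaled to total depth 1. Tips receive synthetic binomial
#' labels (`Genus_spNN`) and a genus/family/order taxonomy built from
#' consecutive tips, so related taxa sit close together on the tree.
#'
#' @param nTips total number of tips (>= 3).
#' @param seed integer seed; identical seeds give identical trees.
#' @param angioFraction fraction of tips assigned to the angiosperm clade.
#' @return an `ape` `phylo` object with an attached `taxonomy` attribute
#'   (data.frame: species, genus, family, order, clade).
#' @export
generatePhylogeny <- function(nTips, seed = 1L, angioFraction = 0.75) {
  if (nTips < 3) stop("nTips must be >= 3")
  set.seed(deriveSeed(seed, "phylogeny"))
  nAng <- max(1L, min(nTips - 1L, round(nTips * angioFraction)))
  nGym <- nTips - nAng

  crown <- 0.6  # crown depth of each clade; stem fills to total depth 1
  subNewick <- function(n, prefix) {
    if (n == 1L) {
      return(sprintf("%s:%g", paste0(prefix, "TMP1"), 1))
    }
    tr <- ape::rphylo(n, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth * crown
    tr$tip.label <- paste0(prefix, "TMP", seq_len(n))
    nwk <- ape::write.tree(tr)
    sub(";$", sprintf(":%g", 1 - crown), nwk)
  }
  nwk <- sprintf("(%s,%s);", subNewick(nAng, "A"), subNewick(nGym, "G"))
  tree <- ape::read.tree(text = nwk)

  # taxonomy from consecutive tips within each clade
  tax <- do.call(rbind, lapply(c(angiosperm = "A", gymnosperm = "G"),
    function(p) {
      tips <- grep(paste0("^", p, "TMP"), tree$tip.label, value = TRUE)
      # keep tree (cladewise) order so taxa are phylogenetically clustered
      n <- length(tips)
      genus_sizes <- integer(0)
      while (sum(genus_sizes) < n)
        genus_sizes <- c(genus_sizes, sample(2:5, 1L))
      genus_id <- rep(seq_along(genus_sizes), genus_sizes)[seq_len(n)]
      ng <- max(genus_id)
      fam_sizes <- integer(0)
      while (sum(fam_sizes) < ng) fam_sizes <- c(fam_sizes, sample(2:4, 1L))
      fam_of_genus <- rep(seq_along(fam_sizes), fam_sizes)[seq_len(ng)]
      nf <- max(fam_of_genus)
      ord_sizes <- integer(0)
      while (sum(ord_sizes) < nf) ord_sizes <- c(ord_sizes, sample(2:3, 1L))
      ord_of_fam <- rep(seq_along(ord_sizes), ord_sizes)[seq_len(nf)]
      cl <- if (p == "A") "angiosperm" else "gymnosperm"
      pre <- if (p == "A") "Angio" else "Gymno"
      genus <- sprintf("%sgenus%03d", pre, genus_id)
      sp_idx <- stats::ave(genus_id, genus_id, FUN = seq_along)
      data.frame(
        old = tips,
        species = sprintf("%s_sp%02d", genus, sp_idx),
        genus = genus,
        family = sprintf("%sfam%02d", pre, fam_of_genus[genus_id]),
        order = sprintf("%sord%02d", pre, ord_of_fam[fam_of_genus[genus_id]]),
        clade = cl,
        stringsAsFactors = FALSE
      )
    }))
  rownames(tax) <- NULL
  tree$tip.label <- tax$species[match(tree$tip.label, tax$old)]
  tax$old <- NULL
  tree$node.label <- NULL
  attr(tree, "taxonomy") <- tax
  tree
}

#' Simulate wood densities under lambda-scaled Brownian motion
#'
#' Draws one trait value per tip from a multivariate normal whose mean is
#' the tip's clade mean and whose covariance is `sigma2` times the
#' Brownian (shared path length) matrix with off-diagonal entries scaled
#' by `lambdaTrue` (Pagel's lambda transform). The clade means are treated
#' as fixed ancestral states at the two clade origins, so deviations
#' accumulate independently within each clade (block-diagonal covariance
#' of within-clade shared paths); this pins the realized clade means near
#' their targets instead of letting the shared stem branches drift whole
#' clades coherently. Values are clipped to the span of real wood,
#' 0.05-1.5 g cm^-3; clipping slightly perturbs normality and is counted
#' in the `n_clipped` attribute.
#'
#' @param tree a phylogeny from [generatePhylogeny()] (or any `phylo` with
#'   a matching `taxonomy` supplied).
#' @param lambdaTrue phylogenetic signal in `[0, 1]`.
#' @param cladeMeans named vector of clade mean densities (g cm^-3), each
#'   in (0, 1.5]; defaults to the angiosperm/gymnosperm means 0.59/0.47.
#' @param sigma2 Brownian rate (trait variance per unit depth), > 0.
#' @param seed integer seed.
#' @param taxonomy data.frame with `species` and `clade`; defaults to the
#'   tree's attached taxonomy.
#' @return named numeric vector of densities, one per tip.
#' @export
simulateTraits <- function(tree, lambdaTrue = 0.9,
                           cladeMeans = c(angiosperm = 0.59, gymnosperm = 0.47),
                           sigma2 = 0.012, seed = 1L,
                           taxonomy = attr(tree, "taxonomy")) {
  if (lambdaTrue < 0 || lambdaTrue > 1) stop("lambdaTrue must be in [0, 1]")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (any(cladeMeans <= 0 | cladeMeans > 1.5))
    stop("clade means must lie in (0, 1.5] g cm^-3")
  if (is.null(taxonomy)) stop("tree carries no taxonomy; supply one")
  set.seed(deriveSeed(seed, "traits"))
  lab <- tree$tip.label
  clade <- taxonomy$clade[match(lab, taxonomy$species)]
  # block-diagonal within-clade Brownian covariance (clade roots as origins)
  C <- matrix(0, length(lab), length(lab), dimnames = list(lab, lab))
  for (cl in unique(clade)) {
    tips <- lab[clade == cl]
    if (length(tips) == 1L) {
      C[tips, tips] <- max(ape::node.depth.edgelength(tree))
    } else {
      sub <- ape::keep.tip(tree, tips)
      C[sub$tip.label, sub$tip.label] <- ape::vcv(sub)
    }
  }
  Cl <- lambdaTrue * C
  diag(Cl) <- diag(C)
  mu <- cladeMeans[clade]
  R <- chol(Cl)
  x <- as.numeric(mu + sqrt(sigma2) * crossprod(R, stats::rnorm(length(lab))))
  # pin clade sample means to their targets: the clade means are generator
  # parameters, so the realized clade contrast should not wander with the
  # Brownian draw (costs exact multivariate normality in one direction per
  # clade, negligible at the tip counts used here)
  for (cl in unique(clade)) {
    sel <- clade == cl
    if (sum(sel) > 1L) x[sel] <- x[sel] - mean(x[sel]) + cladeMeans[[cl]]
  }
  clipped <- sum(x < 0.05 | x > 1.5)
  x <- clip(x, 0.05, 1.5)
  names(x) <- lab
  attr(x, "n_clipped") <- clipped
  x
}

#' Default landscape generator parameters
#' @return named list of defaults accepted by [generateLandscape()].
#' @export
landscapeDefaults <- function() {
  list(
    xmin = -8, ymax = 8, res = 0.25,
    tMin = 0, tMax = 25,          # deg C, north (row 1) to south gradient
    tempNoiseSd = 1.5,            # deg C of smooth spatial noise
    noiseRange = 5,               # smoothing range of noise fields, cells
    maskFraction = 0.08,          # share of cells masked as nodata ("water")
    biomeTempSplit = c(boreal = 5, warm = 15),  # deg C thresholds
    biomeMoistSplit = 0.4         # moisture split tropical vs dryland
  )
}

#' Generate a synthetic landscape raster stack
#'
#' Builds congruent layers on one lattice: `temperature` (monotone
#' north-south gradient plus smooth noise, deg C), `soil_moisture` and
#' `disturbance` (smooth fields in (0, 1)), `gsv` (growing stock volume,
#' m^3 ha^-1, >= 0), `rmf` (root mass fraction in (0, 0.6)) and `biome`
#' (integer codes 1 boreal, 2 temperate, 3 tropical, 4 dryland from
#' temperature/moisture thresholds). A smooth-field threshold masks
#' `maskFraction` of cells as nodata, shared across all layers.
#'
#' @param nRows,nCols lattice dimensions, both >= 8.
#' @param params named list overriding [landscapeDefaults()].
#' @param seed integer seed.
#' @return a [RasterGrid-class].
#' @export
generateLandscape <- function(nRows = 64, nCols = 64, params = list(),
                              seed = 1L) {
  if (nRows < 8 || nCols < 8) stop("landscape must be at least 8 x 8")
  p <- utils::modifyList(landscapeDefaults(), params)
  set.seed(deriveSeed(seed, "landscape"))

  gradient <- matrix(rep(p$tMin + (seq_len(nRows) - 0.5) / nRows *
                           (p$tMax - p$tMin), nCols), nRows, nCols)
  temperature <- gradient
  if (p$tempNoiseSd > 0)
    temperature <- temperature + p$tempNoiseSd * smoothField(nRows, nCols, p$noiseRange)
  moisture <- stats::plogis(1.2 * smoothField(nRows, nCols, p$noiseRange))
  disturbance <- stats::plogis(1.5 * smoothField(nRows, nCols, p$noiseRange) - 0.3)
  gsv <- pmax(120 + 150 * moisture + 5 * temperature +
                40 * smoothField(nRows, nCols, p$noiseRange), 0)
  rmf <- clip(0.32 - 0.005 * temperature +
                0.04 * smoothField(nRows, nCols, p$noiseRange), 0.05, 0.55)

  biome <- matrix(2, nRows, nCols)                 # temperate default
  biome[temperature < p$biomeTempSplit[["boreal"]]] <- 1
  warm <- temperature >= p$biomeTempSplit[["warm"]]
  biome[warm & moisture >= p$biomeMoistSplit] <- 3  # tropical
  biome[warm & moisture < p$biomeMoistSplit] <- 4   # dryland

  maskField <- smoothField(nRows, nCols, p$noiseRange)
  valid <- maskField < stats::quantile(maskField, 1 - p$maskFraction)

  RasterGrid(list(temperature = temperature, soil_moisture = moisture,
                  disturbance = disturbance, gsv = gsv, rmf = rmf,
                  biome = biome),
             xmin = p$xmin, ymax = p$ymax, res = p$res, mask = valid)
}

#' Extract layer values at point coordinates
#'
#' @param grid a [RasterGrid-class].
#' @param lon,lat coordinate vectors.
#' @param layers layer names (default: all).
#' @return data.frame, one row per point; `NA` outside the grid or on
#'   masked cells.
#' @export
extractCovariates <- function(grid, lon, lat, layers = layerNames(grid)) {
  rc <- lonLatToCell(grid, lon, lat)
  idx <- cbind(rc$row, rc$col)
  out <- lapply(layers, function(nm) {
    v <- rep(NA_real_, nrow(rc))
    ok <- !is.na(rc$row)
    v[ok] <- rasterLayer(grid, nm)[idx[ok, , drop = FALSE]]
    v
  })
  names(out) <- layers
  as.data.frame(out)
}

#' Assemble tree-level inventory plots along the landscape gradient
#'
#' Places plots on random non-masked pixels and assembles each community by
#' inverse-distance trait filtering: species are sampled with weights
#' `1 / (|wd - target(T)| + eps)` where
#' `target(T) = baseWd * (1 + slope * T / 100)`, so the expected plot CWD
#' regresses on temperature with relative slope `slopePctPerDegC` (%/degC).
#' Gymnosperm sampling weight additionally decays with temperature
#' (`gymBase * exp(-gymDecay * T)`), creating the cold-to-warm shift from
#' gymnosperm- to angiosperm-dominated communities. DBH is truncated
#' lognormal (all trees > 5 cm; median ~19 cm), plot areas lognormal with
#' median 25 m^2, census years uniform over `years`.
#'
#' An optional planted disturbance interaction (`disturbanceEffect`) shifts
#' the target by `slopeCold * disturbance` below `threshold` deg C and by
#' `slopeWarm * disturbance` above it, for context-dependency recovery
#' experiments.
#'
#' @param world a [SyntheticWorld-class] (plots may be empty).
#' @param nPlots number of plots (>= 1).
#' @param slopePctPerDegC CWD-temperature slope encoded by the trait
#'   filter, percent per deg C.
#' @param seed integer seed.
#' @param baseWd filter target at 0 deg C (g cm^-3); the default (`NULL`)
#'   anchors the target band at the realized trait-pool mean so the
#'   mid-landscape target equals the mean simulated density.
#' @param epsFilter softening constant of the inverse-distance filter.
#' @param gymBase,gymDecay gymnosperm weight multiplier parameters.
#' @param meanTrees,minTrees Poisson mean and lower bound of trees per plot.
#' @param dbhMeanlog,dbhSdlog lognormal DBH parameters (cm scale).
#' @param areaMedian,areaSdlog lognormal plot-area parameters (m^2).
#' @param years candidate census years.
#' @param censusRepeatFraction fraction of plots given a second census year
#'   (community redrawn at the same location).
#' @param disturbanceEffect `NULL` or
#'   `list(threshold = 10, slopeCold = 0.02, slopeWarm = -0.02)`.
#' @return data.frame with one row per tree: `plot_id, lat, lon, area_m2,
#'   year, species, dbh_cm`.
#' @export
generatePlots <- function(world, nPlots, slopePctPerDegC = 0.5, seed = 1L,
                          baseWd = NULL, epsFilter = 0.005,
                          gymBase = 6, gymDecay = 0.25,
                          meanTrees = 40, minTrees = 10,
                          dbhMeanlog = log(19), dbhSdlog = 0.55,
                          areaMedian = 25, areaSdlog = 0.5,
                          years = 1995:2015, censusRepeatFraction = 0,
                          disturbanceEffect = NULL) {
  if (nPlots < 1) stop("nPlots must be >= 1")
  set.seed(deriveSeed(seed, "plots"))
  grid <- world@landscape
  tt <- world@traitTruth
  tax <- world@taxonomy
  gym <- tax$clade[match(names(tt), tax$species)] == "gymnosperm"

  tempLayer <- rasterLayer(grid, "temperature")
  if (is.null(baseWd)) {
    # anchor the filter target band at the realized trait-pool mean so the
    # encoded CWD-temperature gradient spans the community trait cloud for
    # any simulated trait draw
    tMid <- mean(tempLayer[rasterMask(grid)])
    baseWd <- mean(tt) / (1 + slopePctPerDegC * tMid / 100)
  }
  valid <- which(rasterMask(grid))
  d <- dim(grid)
  cells <- sample(valid, nPlots, replace = TRUE)
  row <- (cells - 1L) %% d[1L] + 1L
  col <- (cells - 1L) %/% d[1L] + 1L
  lon <- grid@xmin + (col - 1L + stats::runif(nPlots)) * grid@res
  lat <- grid@ymax - (row - 1L + stats::runif(nPlots)) * grid@res
  temp <- tempLayer[cbind(row, col)]
  dist <- rasterLayer(grid, "disturbance")[cbind(row, col)]
  area <- stats::rlnorm(nPlots, log(areaMedian), areaSdlog)
  year <- sample(years, nPlots, replace = TRUE)

  second <- stats::runif(nPlots) < censusRepeatFraction

  assemble <- function(i, yr) {
    target <- baseWd * (1 + slopePctPerDegC * temp[i] / 100)
    if (!is.null(disturbanceEffect)) {
      de <- disturbanceEffect
      target <- target + dist[i] *
        if (temp[i] < de$threshold) de$slopeCold else de$slopeWarm
    }
    w <- 1 / (abs(tt - target) + epsFilter)
    w[gym] <- w[gym] * gymBase * exp(-gymDecay * temp[i])
    n <- minTrees + stats::rpois(1L, max(0, meanTrees - minTrees))
    sp <- sample(names(tt), n, replace = TRUE, prob = w)
    # truncated lognormal: DBH strictly > 5 cm
    u <- stats::runif(n, stats::plnorm(5, dbhMeanlog, dbhSdlog), 1)
    dbh <- stats::qlnorm(u, dbhMeanlog, dbhSdlog)
    data.frame(plot_id = sprintf("plot%05d", i), lat = lat[i], lon = lon[i],
               area_m2 = area[i], year = yr, species = sp, dbh_cm = dbh,
               stringsAsFactors = FALSE)
  }

  out <- vector("list", nPlots + sum(second))
  for (i in seq_len(nPlots)) out[[i]] <- assemble(i, year[i])
  j <- nPlots
  for (i in which(second)) {
    j <- j + 1L
    yr2 <- sample(setdiff(years, year[i]), 1L)
    out[[j]] <- assemble(i, yr2)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a complete synthetic world with known ground truth
#'
#' Chains [generatePhylogeny()], [simulateTraits()], [generateLandscape()]
#' and [generatePlots()] under one master seed (stage seeds derived with
#' [deriveSeed()]) and records every generator parameter in `truthParams`,
#' which together with the seed fully determines the world.
#'
#' @param nTips,lambdaTrue,cladeMeans,sigma2 passed to the phylogeny/trait
#'   generators.
#' @param nRows,nCols,landscapeParams passed to [generateLandscape()].
#' @param nPlots,slopePctPerDegC,... passed to [generatePlots()].
#' @param seed master integer seed.
#' @return a [SyntheticWorld-class].
#' @export
makeSyntheticWorld <- function(nTips = 200, lambdaTrue = 0.9,
                               cladeMeans = c(angiosperm = 0.59,
                                              gymnosperm = 0.47),
                               sigma2 = 0.012,
                               nRows = 64, nCols = 64,
                               landscapeParams = list(),
                               nPlots = 2000, slopePctPerDegC = 0.5,
                               seed = 1L, ...) {
  tree <- generatePhylogeny(nTips, seed = deriveSeed(seed, "w-tree"))
  traits <- simulateTraits(tree, lambdaTrue, cladeMeans, sigma2,
                           seed = deriveSeed(seed, "w-traits"))
  land <- generateLandscape(nRows, nCols, landscapeParams,
                            seed = deriveSeed(seed, "w-land"))
  world <- new("SyntheticWorld", phylogeny = tree,
               taxonomy = attr(tree, "taxonomy"),
               traitTruth = traits, landscape = land,
               plots = data.frame(), truthParams = list())
  plots <- generatePlots(world, nPlots, slopePctPerDegC,
                         seed = deriveSeed(seed, "w-plots"), ...)
  world@plots <- plots
  world@truthParams <- c(
    list(seed = seed, nTips = nTips, lambdaTrue = lambdaTrue,
         cladeMeans = as.list(cladeMeans), sigma2 = sigma2,
         nRows = nRows, nCols = nCols, nPlots = nPlots,
         slopePctPerDegC = slopePctPerDegC,
         landscape = utils::modifyList(landscapeDefaults(), landscapeParams)),
    list(...)
  )
  validObject(world)
  world
}

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld:", length(object@traitTruth), "taxa,",
      length(unique(object@plots$plot_id)), "plots,",
      nrow(object@plots), "trees\n")
  cat("  landscape:", paste(dim(object@landscape), collapse = " x "),
      "cells; lambda_true =", object@truthParams$lambdaTrue,
      "; CWD-T slope =", object@truthParams$slopePctPerDegC, "%/degC\n")
})
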