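# Shared table I/O ------------------------------------------------------------

#' Read and write tab-separated tables
#'
#' Thin wrappers fixing the dialect used across the package: tab
#' separator, header row, no quoting, no row names, `.` decimal. Finite
#' values round-trip exactly (17 significant digits).
#'
#' @param file path.
#' @param x data.frame to write.
#' @return `readTsv`: a data.frame; `writeTsv`: `file`, invisibly.
#' @export
readTsv <- function(file) {
  utils::read.delim(file, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname readTsv
#' @export
writeTsv <- function(x, file) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) format(v, digits = 17, trim = TRUE,
                                              scientific = FALSE))
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a synthetic world to a directory of plain-text artifacts
#'
#' Plots as TSV (`plot_id, lat, lon, area_m2, year, species, dbh_cm`),
#' per-species trait records and taxonomy as TSV, the phylogeny as Newick,
#' each landscape layer as an ESRI ASCII grid and the generator truth
#' parameters as YAML.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(dir, f)
  writeTsv(world@plots, p("plots.tsv"))
  tax <- world@taxonomy
  traits <- data.frame(species = names(world@traitTruth),
                       genus = tax$genus[match(names(world@traitTruth),
                                               tax$species)],
                       clade = tax$clade[match(names(world@traitTruth),
                                               tax$species)],
                       wood_density = as.numeric(world@traitTruth),
                       source_id = "synthetic_truth")
  writeTsv(traits, p("traits.tsv"))
  writeTsv(tax, p("taxonomy.tsv"))
  ape::write.tree(world@phylogeny, p("tree.nwk"))
  for (nm in layerNames(world@landscape))
    writeAsciiGrid(world@landscape, nm, p(paste0(nm, ".asc")))
  yaml::write_yaml(world@truthParams, p("truth_params.yaml"))
  paths <- c("plots.tsv", "traits.tsv", "taxonomy.tsv", "tree.nwk",
             paste0(layerNames(world@landscape), ".asc"),
             "truth_params.yaml")
  invisible(file.path(dir, paths))
}

# Pipeline configuration -------------------------------------------------------

#' Default end-to-end pipeline configuration
#'
#' Every stage parameter of the pipeline with its default; unknown keys in
#' overrides are rejected. The demo scale (64 x 64 world, 500 plots, 10
#' ensemble members) runs end to end on one CPU in a few minutes.
#'
#' @param overrides named list of overrides, nested as in the defaults.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(overrides = list()) {
  defaults <- list(
    seed = 1L,
    world = list(nTips = 200, lambdaTrue = 0.9, sigma2 = 0.012,
                 nRows = 64, nCols = 64, nPlots = 500,
                 slopePctPerDegC = 0.5),
    community = list(threshold = 0.75, referenceArea = 25, z = 0.25),
    map = list(nMembers = 10, minDistKm = 50, subsampleTarget = 800,
               nDraws = 8, cvFolds = 10,
               features = c("temperature", "soil_moisture", "disturbance")),
    hulls = list(varThreshold = 0.90, insideThreshold = 0.95),
    drivers = list(nBoot = 25, cellDeg = 0.25, numTrees = 100,
                   nCandidates = 4),
    biomass = list(carbonFraction = 0.5, constantWd = 0.53)
  )
  checkKeys <- function(ov, def, path = "") {
    bad <- setdiff(names(ov), names(def))
    if (length(bad))
      stop("unknown config key(s): ",
           paste0(path, bad, collapse = ", "))
    for (nm in names(ov))
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]])))
        checkKeys(ov[[nm]], def[[nm]], paste0(path, nm, "$"))
  }
  checkKeys(overrides, defaults)
  utils::modifyList(defaults, overrides)
}

manifestRow <- function(files, stage, secs) {
  data.frame(file = basename(files), checksum = unname(tools::md5sum(files)),
             stage = stage, seconds = round(secs, 2),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline: simulate, traits, community, map, hulls,
#' drivers, biomass
#'
#' Executes every stage in order, writing plain-text artifacts under
#' `outDir` and returning a manifest (file, md5 checksum, stage, wall
#' seconds). A stage whose output files all exist is skipped unless
#' `force = TRUE`, so deleting an intermediate reruns only that stage and
#' everything downstream of a missing input fails with an error naming
#' the stage that should have produced it.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory.
#' @param force rerun stages whose outputs already exist.
#' @return manifest data.frame, invisibly written as `manifest.tsv`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, force = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outDir, f)
  need <- function(f, stage) {
    if (!file.exists(p(f)))
      stop("missing artifact '", f, "': run the '", stage, "' stage first")
    p(f)
  }
  manifest <- list()
  runStage <- function(stage, outputs, fun) {
    paths <- p(outputs)
    if (!force && all(file.exists(paths))) {
      message("stage ", stage, ": outputs exist, skipped")
      manifest[[stage]] <<- manifestRow(paths, stage, 0)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    fun()
    manifest[[stage]] <<- manifestRow(paths, stage,
                                      proc.time()[["elapsed"]] - t0)
    invisible(NULL)
  }
  seed <- config$seed
  landFiles <- paste0(c("temperature", "soil_moisture", "disturbance",
                        "gsv", "rmf", "biome"), ".asc")

  runStage("simulate",
           c("plots.tsv", "traits.tsv", "taxonomy.tsv", "tree.nwk",
             landFiles, "truth_params.yaml"), function() {
    w <- config$world
    world <- makeSyntheticWorld(nTips = w$nTips, lambdaTrue = w$lambdaTrue,
                                sigma2 = w$sigma2, nRows = w$nRows,
                                nCols = w$nCols, nPlots = w$nPlots,
                                slopePctPerDegC = w$slopePctPerDegC,
                                seed = seed)
    writeWorld(world, outDir)
  })

  runStage("traits", c("species_means.tsv", "genus_means.tsv"), function() {
    rec <- readTsv(need("traits.tsv", "simulate"))
    tab <- buildTraitTable(rec)
    writeTsv(speciesMeans(tab), p("species_means.tsv"))
    writeTsv(genusMeans(tab), p("genus_means.tsv"))
  })

  loadTraitTable <- function() {
    rec <- readTsv(need("traits.tsv", "simulate"))
    buildTraitTable(rec)
  }
  loadLandscape <- function() {
    files <- p(landFiles)
    names(files) <- sub("\\.asc$", "", landFiles)
    readAsciiStack(files)
  }

  runStage("community", c("community.tsv", "pixels.tsv"), function() {
    plots <- readTsv(need("plots.tsv", "simulate"))
    tab <- loadTraitTable()
    land <- loadLandscape()
    cc <- config$community
    latest <- filterLatestCensus(plots)
    recs <- communityRecords(latest, tab, cc$threshold, cc$referenceArea,
                             cc$z)
    writeTsv(recs, p("community.tsv"))
    px <- aggregateToPixels(recs, res = rasterRes(land),
                            xmin = land@xmin, ymax = land@ymax)
    writeTsv(px, p("pixels.tsv"))
  })

  pixelsWithCovariates <- function(land) {
    px <- readTsv(need("pixels.tsv", "community"))
    cov <- extractCovariates(land, px$lon, px$lat)
    cbind(px, cov)
  }

  runStage("map", c("cwd_mean.asc", "cwd_cv.asc", "map_model.yaml"),
           function() {
    land <- loadLandscape()
    d <- pixelsWithCovariates(land)
    mm <- config$map
    model <- trainEnsemble(d, response = "cwd", features = mm$features,
                           nMembers = mm$nMembers,
                           minDistKm = mm$minDistKm,
                           subsampleTarget = mm$subsampleTarget,
                           nDraws = mm$nDraws, cvFolds = mm$cvFolds,
                           seed = deriveSeed(seed, "map"))
    pred <- predictEnsemble(model, land)
    writeAsciiGrid(pred, "mean", p("cwd_mean.asc"))
    writeAsciiGrid(pred, "cv", p("cwd_cv.asc"))
    yaml::write_yaml(list(n_members = mm$nMembers,
                          features = mm$features,
                          min_dist_km = mm$minDistKm,
                          member_cv_r2 = memberCvR2(model),
                          seed = deriveSeed(seed, "map")),
                     p("map_model.yaml"))
  })

  runStage("hulls", c("hull_fraction.asc", "hull_interpolation.asc",
                      "hull_summary.json"), function() {
    land <- loadLandscape()
    d <- pixelsWithCovariates(land)
    hh <- config$hulls
    model <- fitHullModel(d[, config$map$features, drop = FALSE],
                          hh$varThreshold)
    cls <- classifyGrid(model, land, hh$insideThreshold)
    writeAsciiGrid(cls$grid, "fraction", p("hull_fraction.asc"))
    writeAsciiGrid(cls$grid, "interpolation", p("hull_interpolation.asc"))
    jsonlite::write_json(list(k = model@k, n_hulls = length(model@hulls),
                              interpolation_share = cls$interpolation_share),
                         p("hull_summary.json"), auto_unbox = TRUE)
  })

  runStage("drivers", c("importance.tsv", "coefficients.tsv",
                        "partition.json", "partition.txt"), function() {
    land <- loadLandscape()
    recs <- readTsv(need("community.tsv", "community"))
    cov <- extractCovariates(land, recs$lon, recs$lat,
                             c("temperature", "soil_moisture", "disturbance"))
    d <- cbind(recs, cov)
    dd <- config$drivers
    predictors <- c("temperature", "soil_moisture", "disturbance",
                    "angiosperm_ratio", "richness_scaled", "mean_dbh")
    set.seed(deriveSeed(seed, "drivers"))
    imp <- importanceBootstrap(d, "cwd", predictors, nBoot = dd$nBoot,
                               cellDeg = dd$cellDeg,
                               numTrees = dd$numTrees,
                               seed = deriveSeed(seed, "importance"))
    writeTsv(imp$importance, p("importance.tsv"))
    writeTsv(imp$coefficients, p("coefficients.tsv"))
    cand <- setdiff(imp$importance$variable, "disturbance")
    cand <- utils::head(cand, dd$nCandidates)
    tree <- partitionDisturbance(d, "cwd", "disturbance", cand,
                                 minNode = max(50, ceiling(0.03 * nrow(d))))
    partitionTreeJson(tree, p("partition.json"))
    writeLines(utils::capture.output(show(tree)), p("partition.txt"))
  })

  runStage("biomass", c("biomass_summary.json", "biomass_pct.asc"),
           function() {
    land <- loadLandscape()
    cwd <- readAsciiGrid(need("cwd_mean.asc", "map"), "cwd")
    stack <- RasterGrid(list(cwd = cwd@layers$cwd,
                             gsv = rasterLayer(land, "gsv"),
                             biome = rasterLayer(land, "biome"),
                             rmf = rasterLayer(land, "rmf")),
                        xmin = land@xmin, ymax = land@ymax,
                        res = rasterRes(land))
    bb <- config$biomass
    cfg <- biomassConfig(carbonFraction = bb$carbonFraction,
                         constantWd = bb$constantWd)
    cmp <- constantDensityComparison(stack, cfg)
    writeAsciiGrid(cmp$pct, "pct", p("biomass_pct.asc"))
    jsonlite::write_json(list(spatial_gtc = cmp$spatial_gtc,
                              universal_gtc = cmp$universal_gtc,
                              overall_pct = cmp$overall_pct,
                              biome_summary = cmp$biome_summary),
                         p("biomass_summary.json"), auto_unbox = TRUE,
                         digits = NA)
  })

  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  writeTsv(out, p("manifest.tsv"))
  out
}
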