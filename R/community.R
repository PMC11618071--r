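#' Keep only the latest census of every plot
#'
#' For each `plot_id`, retains the census (all tree rows) with the maximum
#' year; ties on year are broken toward the census with more trees (logged
#' via message).
#'
#' @param plots tree-level data.frame (`plot_id`, `year`, one row per tree;
#'   an optional `census_id` column distinguishes same-year censuses of one
#'   plot, otherwise `year` identifies the census).
#' @return the filtered tree-level data.frame.
#' @export
filterLatestCensus <- function(plots) {
  stopifnot(all(c("plot_id", "year") %in% names(plots)))
  cid <- if ("census_id" %in% names(plots)) plots$census_id else plots$year
  key <- paste(plots$plot_id, cid, sep = "\r")
  first <- !duplicated(key)
  cen <- data.frame(key = key[first], plot_id = plots$plot_id[first],
                    year = plots$year[first],
                    n = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  pick <- do.call(rbind, lapply(split(cen, cen$plot_id), function(d) {
    d <- d[d$year == max(d$year), , drop = FALSE]
    if (nrow(d) > 1L) {
      message("plot ", d$plot_id[1L], ": tied census years, keeping the ",
              "larger census (", max(d$n), " trees)")
      d <- d[which.max(d$n), , drop = FALSE]
    }
    d
  }))
  out <- plots[key %in% pick$key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign wood density to trees from a trait table
#'
#' Species-level match preferred; genus-level mean as fallback; `none`
#' when neither is available (a data outcome, not an error).
#'
#' @param species character vector of species binomials or genus tokens.
#' @param traitTable a [TraitTable-class].
#' @return data.frame `density`, `level` (`species`/`genus`/`none`),
#'   `clade`.
#' @export
assignWoodDensity <- function(species, traitTable) {
  sp <- speciesMeans(traitTable)
  ge <- genusMeans(traitTable)
  i_sp <- match(species, sp$species)
  gkey <- speciesToGenus(species)
  i_ge <- match(gkey, ge$genus)
  density <- ifelse(!is.na(i_sp), sp$mean_wd[i_sp],
                    ifelse(!is.na(i_ge), ge$mean_wd[i_ge], NA_real_))
  level <- ifelse(!is.na(i_sp), "species",
                  ifelse(!is.na(i_ge), "genus", "none"))
  clade <- ifelse(!is.na(i_sp), sp$clade[i_sp],
                  ifelse(!is.na(i_ge), ge$clade[i_ge], NA_character_))
  data.frame(density = density, level = level, clade = clade,
             stringsAsFactors = FALSE)
}

#' Coverage filter: drop plots where too few trees have wood density
#'
#' Coverage = matched individuals / total individuals. A census is dropped
#' iff coverage is strictly below the threshold (exactly 0.75 is kept
#' under the default).
#'
#' @param census tree rows of one plot.
#' @param traitTable a [TraitTable-class].
#' @param threshold minimum coverage fraction (default 0.75).
#' @return list(keep = logical, coverage = fraction).
#' @export
coverageFilter <- function(census, traitTable, threshold = 0.75) {
  if (nrow(census) == 0L) {
    message("empty census: dropped")
    return(list(keep = FALSE, coverage = NA_real_))
  }
  wd <- assignWoodDensity(census$species, traitTable)
  coverage <- mean(wd$level != "none")
  list(keep = coverage >= threshold, coverage = coverage)
}

#' Community-weighted wood density of one census
#'
#' CWD is the mean wood density of the census' matched trees weighted by
#' basal area `pi * (dbh/2)^2`; weights renormalize over matched trees
#' only (the >= 75% coverage filter guarantees they represent the plot).
#' The angiosperm ratio is the share of angiosperm individuals among
#' matched trees; mean DBH is the arithmetic mean over all trees.
#'
#' @param census tree rows of one plot (`species`, `dbh_cm`, plus plot
#'   metadata columns).
#' @param traitTable a [TraitTable-class].
#' @return one-row data.frame: `plot_id, lat, lon, year, area_m2, cwd,
#'   angiosperm_ratio, mean_dbh, coverage_fraction, n_trees`.
#' @export
computeCWD <- function(census, traitTable) {
  stopifnot(nrow(census) > 0L)
  wd <- assignWoodDensity(census$species, traitTable)
  m <- wd$level != "none"
  if (!any(m)) stop("no tree in the census has wood density information")
  ba <- pi * (census$dbh_cm[m] / 2)^2
  if (sum(ba) <= 0) stop("zero total basal area")
  cwd <- sum(wd$density[m] * ba) / sum(ba)
  meta <- function(col) if (col %in% names(census)) census[[col]][1L] else NA
  data.frame(
    plot_id = meta("plot_id"), lat = meta("lat"), lon = meta("lon"),
    year = meta("year"), area_m2 = meta("area_m2"),
    cwd = cwd,
    angiosperm_ratio = mean(wd$clade[m] == "angiosperm"),
    mean_dbh = mean(census$dbh_cm),
    coverage_fraction = mean(m),
    n_trees = nrow(census),
    stringsAsFactors = FALSE
  )
}

#' Arrhenius-scaled species richness
#'
#' Scales the observed species count to a reference plot area with the
#' species-area exponent `z`: `S_ref = S_obs * (referenceArea / area)^z`.
#' `z = 0` returns the raw count.
#'
#' @param census tree rows of one plot (needs `species`, `area_m2`).
#' @param referenceArea reference plot area, m^2 (default 25, the median
#'   inventory plot size).
#' @param z species-area exponent (default 0.25).
#' @return scaled species density (species per reference area).
#' @export
richnessScaled <- function(census, referenceArea = 25, z = 0.25) {
  area <- census$area_m2[1L]
  stopifnot(area > 0)
  length(unique(census$species)) * (referenceArea / area)^z
}

#' Community records for a whole plot table
#'
#' Applies the coverage filter and computes CWD, angiosperm ratio, scaled
#' richness and mean DBH for every census in a tree-level table. Censuses
#' failing the coverage filter (or empty after matching) are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param plots tree-level data.frame (multiple plots/censuses).
#' @param traitTable a [TraitTable-class].
#' @param threshold coverage threshold (default 0.75).
#' @param referenceArea,z richness scaling parameters.
#' @return data.frame of community records, one row per retained census.
#' @export
communityRecords <- function(plots, traitTable, threshold = 0.75,
                             referenceArea = 25, z = 0.25) {
  key <- paste(plots$plot_id, plots$year, sep = "\r")
  pieces <- split(seq_len(nrow(plots)), key)
  recs <- vector("list", length(pieces))
  dropped <- 0L
  for (i in seq_along(pieces)) {
    census <- plots[pieces[[i]], , drop = FALSE]
    cf <- coverageFilter(census, traitTable, threshold)
    if (!isTRUE(cf$keep)) {
      dropped <- dropped + 1L
      next
    }
    r <- computeCWD(census, traitTable)
    r$richness_scaled <- richnessScaled(census, referenceArea, z)
    recs[[i]] <- r
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no census passed the coverage filter")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Aggregate community records to pixels
#'
#' Pixel index uses the shared half-open, top-left-origin convention:
#' `col = floor((lon - xmin)/res)`, `row = floor((ymax - lat)/res)` (a plot
#' exactly on a cell edge belongs to the cell whose half-open interval
#' contains it). The pixel value of every numeric metric is the unweighted
#' mean over member plots; `n_plots` is retained.
#'
#' @param records community records (needs `lon`, `lat` plus metric
#'   columns).
#' @param res pixel size in degrees (default 30 arcsec = 1/120 degree).
#' @param xmin,ymax grid origin (default the global -180/90).
#' @param metrics columns to average (default: all numeric metrics
#'   present).
#' @return data.frame: `px_row, px_col, lon, lat` (pixel centres), the
#'   averaged metrics and `n_plots`.
#' @export
aggregateToPixels <- function(records, res = 30 / 3600,
                              xmin = -180, ymax = 90,
                              metrics = intersect(c("cwd", "angiosperm_ratio",
                                                    "richness_scaled",
                                                    "mean_dbh"),
                                                  names(records))) {
  col <- floor((records$lon - xmin) / res)
  row <- floor((ymax - records$lat) / res)
  key <- paste(row, col, sep = ",")
  groups <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    d <- records[idx, , drop = FALSE]
    v <- vapply(metrics, function(m) mean(d[[m]]), numeric(1))
    r <- floor((ymax - d$lat[1L]) / res)
    cc <- floor((d$lon[1L] - xmin) / res)
    cbind(data.frame(px_row = r, px_col = cc,
                     lon = xmin + (cc + 0.5) * res,
                     lat = ymax - (r + 0.5) * res),
          as.data.frame(as.list(v)), n_plots = length(idx))
  }))
  rownames(out) <- NULL
  out
}

#' Per-biome and per-forest-type summaries of pixel records
#'
#' Looks up the biome code of each pixel on a categorical raster and
#' summarises a metric by biome and by forest type through a grouping map
#' (biome code -> forest type). Records on unclassified (masked) pixels
#' are excluded and counted.
#'
#' @param pixels pixel records (needs `lon`, `lat` and the metric column).
#' @param biomeGrid a [RasterGrid-class] with a `biome` layer.
#' @param grouping named character vector biome code -> forest type;
#'   default maps the synthetic codes 1-4 to boreal/temperate/tropical/
#'   dryland.
#' @param metric column to summarise (default `"cwd"`).
#' @return list(biome = data.frame, forest_type = data.frame,
#'   n_unclassified = count); each table has mean, sd, n.
#' @export
biomeSummary <- function(pixels, biomeGrid,
                         grouping = c("1" = "boreal", "2" = "temperate",
                                      "3" = "tropical", "4" = "dryland"),
                         metric = "cwd") {
  b <- extractCovariates(biomeGrid, pixels$lon, pixels$lat, "biome")$biome
  ok <- !is.na(b)
  n_uncl <- sum(!ok)
  d <- pixels[ok, , drop = FALSE]
  b <- as.character(b[ok])
  summarise <- function(group) {
    g <- split(d[[metric]], group)
    data.frame(group = names(g),
               mean = vapply(g, mean, numeric(1)),
               sd = vapply(g, stats::sd, numeric(1)),
               n = vapply(g, length, numeric(1)), row.names = NULL)
  }
  ft <- grouping[b]
  list(biome = summarise(b),
       forest_type = summarise(ft),
       n_unclassified = n_uncl)
}

#' Temporal versus spatial variance decomposition of repeated censuses
#'
#' Two-way crossed random-effects model (REML via \pkg{lme4}) of CWD with
#' plot and census year as random intercepts; returns variance fractions
#' for plot, year and residual. A single year (or single plot) fixes that
#' component at 0 with a warning.
#'
#' @param records community records with `plot_id`, `year`, `cwd`.
#' @return list with `components` and `fractions` named
#'   `plot, year, residual`.
#' @export
temporalVarianceDecomposition <- function(records) {
  stopifnot(all(c("plot_id", "year", "cwd") %in% names(records)))
  d <- records
  d$.plot <- factor(d$plot_id)
  d$.year <- factor(d$year)
  terms <- character(); zero <- character()
  if (nlevels(d$.plot) > 1L) terms <- c(terms, "(1 | .plot)") else zero <- c(zero, "plot")
  if (nlevels(d$.year) > 1L) terms <- c(terms, "(1 | .year)") else zero <- c(zero, "year")
  if (length(zero))
    warning("single-category component(s) fixed at 0: ",
            paste(zero, collapse = ", "))
  if (!length(terms)) stop("need variation in plot or year")
  f <- stats::as.formula(paste("cwd ~ 1 +", paste(terms, collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(f, data = d,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  comp <- c(plot = get(".plot"), year = get(".year"),
            residual = get("Residual"))
  list(components = comp, fractions = comp / sum(comp))
}
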