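#' @import methods
NULL

setOldClass("phylo")
setOldClass("ranger")

#' RasterGrid: congruent named single-band layers on a geographic lattice
#'
#' A minimal in-memory raster stack: named numeric matrices sharing one
#' north-up geographic (EPSG:4326) lattice and one nodata mask. Rows run
#' north to south, columns west to east; a cell with top-left corner
#' (lon0, lat0) covers the half-open box \code{[lon0, lon0 + res)} in
#' longitude and \code{(lat0 - res, lat0]} in latitude, so cell indices are
#' \code{col = floor((lon - xmin)/res) + 1} and
#' \code{row = floor((ymax - lat)/res) + 1}.
#'
#' Cells where \code{rasterMask(x)} is \code{FALSE} are nodata and carry
#' \code{NA} in every layer.
#'
#' @slot layers named list of numeric matrices, all with identical dimensions.
#' @slot xmin western edge (decimal degrees).
#' @slot ymax northern edge (decimal degrees).
#' @slot res cell size (decimal degrees), shared by both axes.
#' @slot mask logical matrix; \code{TRUE} marks a valid (non-nodata) cell.
#' @slot crs coordinate reference tag; always geographic WGS84 here.
#'
#' @seealso [RasterGrid()], [rasterLayer()], [writeAsciiGrid()]
#' @export
setClass("RasterGrid",
  representation(
    layers = "list",
    xmin = "numeric",
    ymax = "numeric",
    res = "numeric",
    mask = "matrix",
    crs = "character"
  ),
  prototype(crs = "EPSG:4326")
)

setValidity("RasterGrid", function(object) {
  msgs <- character()
  if (length(object@layers) == 0L) msgs <- c(msgs, "at least one layer required")
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    msgs <- c(msgs, "layers must be uniquely named")
  dims <- dim(object@mask)
  for (nm in names(object@layers)) {
    l <- object@layers[[nm]]
    if (!is.matrix(l) || !is.numeric(l))
      msgs <- c(msgs, sprintf("layer '%s' is not a numeric matrix", nm))
    else if (!identical(dim(l), dims))
      msgs <- c(msgs, sprintf("layer '%s' dimensions differ from mask", nm))
    else if (any(!is.na(l[!object@mask])))
      msgs <- c(msgs, sprintf("layer '%s' has values on masked cells", nm))
  }
  if (!is.logical(object@mask)) msgs <- c(msgs, "mask must be logical")
  if (object@res <= 0) msgs <- c(msgs, "res must be positive")
  if (length(msgs)) msgs else TRUE
})

#' TraitTable: species- and genus-level wood density lookup
#'
#' Built by [buildTraitTable()]. Species means are arithmetic means over a
#' species' records; genus means average the genus' species means (not the
#' raw records), so heavily sampled species do not dominate.
#'
#' @slot species data.frame with columns \code{species, genus, clade,
#'   mean_wd, n_records}.
#' @slot genus data.frame with columns \code{genus, clade, mean_wd,
#'   n_species, n_records}.
#' @slot nRejected number of input records dropped by validation.
#' @export
setClass("TraitTable",
  representation(species = "data.frame", genus = "data.frame",
                 nRejected = "integer"),
  prototype(nRejected = 0L)
)

setValidity("TraitTable", function(object) {
  msgs <- character()
  need_sp <- c("species", "genus", "clade", "mean_wd", "n_records")
  need_ge <- c("genus", "clade", "mean_wd", "n_species", "n_records")
  if (!all(need_sp %in% names(object@species)))
    msgs <- c(msgs, "species table lacks required columns")
  if (!all(need_ge %in% names(object@genus)))
    msgs <- c(msgs, "genus table lacks required columns")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(object@species$species)) msgs <- c(msgs, "duplicate species keys")
  if (anyDuplicated(object@genus$genus)) msgs <- c(msgs, "duplicate genus keys")
  orphan <- setdiff(unique(object@species$genus), object@genus$genus)
  if (length(orphan))
    msgs <- c(msgs, "every genus with a species mean must have a genus mean")
  if (length(msgs)) msgs else TRUE
})

#' EnsembleModel: buffer-bootstrap ensemble of random-forest regressors
#'
#' @slot members list; each member holds the fitted \code{ranger} handle,
#'   the hyperparameters drawn by the grid search, the training-row indices
#'   of its buffer-thinned subsample and its tenfold cross-validated R2.
#' @slot features covariate names the members were trained on.
#' @slot minDistKm minimum pairwise distance (km) enforced within each
#'   member's subsample.
#' @slot seed integer seed the ensemble was trained from.
#' @slot meta bookkeeping (subsample target, grid size, dropped rows).
#' @export
setClass("EnsembleModel",
  representation(members = "list", features = "character",
                 minDistKm = "numeric", seed = "integer", meta = "list")
)

setValidity("EnsembleModel", function(object) {
  msgs <- character()
  if (length(object@members) < 1L) msgs <- c(msgs, "at least one member required")
  ok <- vapply(object@members, function(m)
    all(c("fit", "params", "indices", "cv_r2") %in% names(m)), logical(1))
  if (!all(ok)) msgs <- c(msgs, "members must carry fit, params, indices, cv_r2")
  if (length(msgs)) msgs else TRUE
})

#' HullModel: bivariate principal-component convex hulls of training data
#'
#' Stores the centring/scaling vectors and eigenvectors of the training
#' covariates together with the 2-D convex hull of the training points in
#' every pair of retained principal components. New points are classified
#' by projecting them with the *training* transform and counting how many
#' hulls contain them.
#'
#' @slot center,scale per-feature centring and scaling vectors.
#' @slot rotation eigenvector matrix (features x PCs).
#' @slot eigenvalues variances of all PCs.
#' @slot k number of retained PCs (smallest set explaining more than the
#'   variance threshold).
#' @slot hulls list over PC pairs; each element has \code{i, j} and the
#'   hull \code{vertices} in counter-clockwise order.
#' @slot features training feature names.
#' @slot varThreshold the cumulative-variance threshold used.
#' @export
setClass("HullModel",
  representation(center = "numeric", scale = "numeric", rotation = "matrix",
                 eigenvalues = "numeric", k = "integer", hulls = "list",
                 features = "character", varThreshold = "numeric")
)

setValidity("HullModel", function(object) {
  msgs <- character()
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  nh <- if (object@k >= 2L) choose(object@k, 2L) else 0L
  if (length(object@hulls) != nh)
    msgs <- c(msgs, sprintf("expected %d hulls for k = %d", nh, object@k))
  if (length(msgs)) msgs else TRUE
})

#' PartitionTree: linear-model tree for disturbance context-dependency
#'
#' Recursive partition of a univariate regression of community wood density
#' on a disturbance variable; splits on environmental covariates where the
#' regression is unstable. Leaves carry per-node intercept and slope.
#'
#' @slot root recursive node list (split variable/threshold, p-value,
#'   per-node coefficients, children).
#' @slot disturbanceVar name of the disturbance regressor.
#' @slot candidates covariates screened as split variables.
#' @slot minNode minimum observations per node.
#' @slot alpha significance level for accepting a split
#'   (Bonferroni-adjusted over candidates).
#' @slot n number of observations at the root.
#' @export
setClass("PartitionTree",
  representation(root = "list", disturbanceVar = "character",
                 candidates = "character", minNode = "integer",
                 alpha = "numeric", n = "integer")
)

#' SyntheticWorld: self-contained synthetic study system with known truth
#'
#' Bundles a two-clade phylogeny, simulated wood densities, a landscape
#' raster stack, tree-level inventory plots assembled along the landscape's
#' temperature gradient, and the full generator parameter record
#' (\code{truthParams}) that, with the seed, determines every output.
#'
#' @slot phylogeny an \code{ape} \code{phylo} tree with clade annotations.
#' @slot taxonomy data.frame mapping species to genus, family, order, clade.
#' @slot traitTruth named numeric vector of true wood densities (g cm^-3).
#' @slot landscape a [RasterGrid-class] with layers temperature (deg C),
#'   soil_moisture (fraction), disturbance (0-1), gsv (m^3 ha^-1),
#'   rmf (fraction), biome (categorical code).
#' @slot plots tree-level table (plot_id, lat, lon, area_m2, year, species,
#'   dbh_cm), one row per tree.
#' @slot truthParams list of all generator parameters, including the seed.
#' @export
setClass("SyntheticWorld",
  representation(phylogeny = "phylo", taxonomy = "data.frame",
                 traitTruth = "numeric", landscape = "RasterGrid",
                 plots = "data.frame", truthParams = "list")
)

setValidity("SyntheticWorld", function(object) {
  msgs <- character()
  missing_sp <- setdiff(unique(object@plots$species), names(object@traitTruth))
  if (length(missing_sp))
    msgs <- c(msgs, sprintf("%d plot species absent from traitTruth", length(missing_sp)))
  if (length(msgs)) msgs else TRUE
})
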