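#' Canonicalize raw taxon names
#'
#' Rule-based cleaner for messy binomials: collapses whitespace, capitalizes
#' the genus, lower-cases the epithet, strips authority strings (tokens with
#' capitals, initials or punctuation after the epithet) and infraspecific
#' rank markers (`var.`, `subsp.`, `ssp.`, `f.`, `cv.`), then applies an
#' optional user synonym map. A single-word input returns a genus-only
#' token. Inputs without any alphabetic content yield `NA` (rejected
#' record; callers count these, they are not fatal).
#'
#' @param raw character vector of raw names.
#' @param synonymMap optional named character vector mapping canonical
#'   names to their accepted replacement (applied last).
#' @return character vector of canonical binomials (`"Genus epithet"`),
#'   genus-only tokens (`"Genus"`), or `NA` for rejected input.
#' @export
normalizeName <- function(raw, synonymMap = NULL) {
  rank_markers <- c("var", "subsp", "ssp", "f", "cv", "aff", "cf")
  one <- function(x) {
    if (is.na(x)) return(NA_character_)
    x <- gsub("[[:space:]]+", " ", trimws(x))
    if (!grepl("[A-Za-z]", x)) return(NA_character_)
    toks <- strsplit(x, " ", fixed = TRUE)[[1L]]
    toks <- toks[toks != ""]
    alpha1 <- grepl("^[A-Za-z][A-Za-z-]*$", toks[1L])
    if (!alpha1) return(NA_character_)
    genus <- paste0(toupper(substr(toks[1L], 1, 1)),
                    tolower(substr(toks[1L], 2, nchar(toks[1L]))))
    if (length(toks) == 1L) return(genus)
    ep <- toks[2L]
    ep_clean <- tolower(ep)
    # epithet must be plainly alphabetic and not a rank marker or authority
    if (!grepl("^[a-z][a-z-]*$", ep_clean) ||
        sub("\\.$", "", ep_clean) %in% rank_markers)
      return(genus)
    paste(genus, ep_clean)
  }
  out <- vapply(raw, one, character(1), USE.NAMES = FALSE)
  if (!is.null(synonymMap)) {
    hit <- out %in% names(synonymMap)
    out[hit] <- unname(synonymMap[out[hit]])
  }
  out
}

# split a species key ("Genus epithet" or "Genus_epithet") into its genus
speciesToGenus <- function(species) {
  vapply(strsplit(species, "[ _]"), `[`, character(1), 1L)
}

#' Build species- and genus-level wood density lookup tables
#'
#' Species mean = arithmetic mean of that species' records. Genus mean =
#' mean of the genus' *species means* (each species counted once), so
#' heavily sampled species do not dominate their genus. Records with
#' densities outside (0, 2) g cm^-3 are rejected and counted.
#'
#' @param records data.frame with columns `species` (canonical binomial or
#'   genus-only token), `wood_density` (g cm^-3) and optionally `genus`,
#'   `clade`, `source_id`. Genus is derived from the species key when
#'   absent; genus-only records (no epithet) are rejected for table
#'   building and counted.
#' @return a [TraitTable-class].
#' @export
buildTraitTable <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("species", "wood_density") %in% names(records)))
  rec <- records
  if (!"genus" %in% names(rec)) rec$genus <- speciesToGenus(rec$species)
  if (!"clade" %in% names(rec)) rec$clade <- "unknown"
  ok <- !is.na(rec$species) & !is.na(rec$wood_density) &
    rec$wood_density > 0 & rec$wood_density < 2 &
    grepl("[ _]", rec$species)          # species-level (binomial) records only
  nRejected <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no valid trait records")

  sp_mean <- stats::aggregate(wood_density ~ species, rec, mean)
  sp_n <- stats::aggregate(wood_density ~ species, rec, length)
  first <- rec[!duplicated(rec$species), c("species", "genus", "clade")]
  species <- merge(merge(sp_mean, sp_n, by = "species",
                         suffixes = c("", ".n")), first, by = "species")
  names(species)[names(species) == "wood_density"] <- "mean_wd"
  names(species)[names(species) == "wood_density.n"] <- "n_records"
  species <- species[order(species$species),
                     c("species", "genus", "clade", "mean_wd", "n_records")]

  ge_mean <- stats::aggregate(mean_wd ~ genus, species, mean)
  ge_nsp <- stats::aggregate(species ~ genus, species, length)
  ge_nrec <- stats::aggregate(n_records ~ genus, species, sum)
  ge_clade <- stats::aggregate(clade ~ genus, species,
                               function(x) names(sort(table(x),
                                                      decreasing = TRUE))[1L])
  genus <- Reduce(function(a, b) merge(a, b, by = "genus"),
                  list(ge_mean, ge_clade, ge_nsp, ge_nrec))
  names(genus)[names(genus) == "species"] <- "n_species"
  genus <- genus[order(genus$genus),
                 c("genus", "clade", "mean_wd", "n_species", "n_records")]
  rownames(species) <- rownames(genus) <- NULL
  new("TraitTable", species = species, genus = genus,
      nRejected = as.integer(nRejected))
}

setMethod("show", "TraitTable", function(object) {
  cat("TraitTable:", nrow(object@species), "species means,",
      nrow(object@genus), "genus means",
      sprintf("(%d records rejected)\n", object@nRejected))
})

#' @rdname buildTraitTable
#' @param x a `TraitTable`.
#' @export
speciesMeans <- function(x) x@species

#' @rdname buildTraitTable
#' @export
genusMeans <- function(x) x@genus

#' Between-source concordance of species-level wood density
#'
#' For every pair of sources sharing at least three species, regresses
#' source B's species means on source A's (ordinary least squares) and
#' reports the shared-species count, slope and R^2 = 1 - SSE/SST. Pairs
#' with fewer than three shared species are skipped with a notice.
#'
#' @param records data.frame with `species`, `wood_density`, `source_id`.
#' @return data.frame: `source_a, source_b, n_shared, slope, r2`.
#' @export
sourceConcordance <- function(records) {
  stopifnot(all(c("species", "wood_density", "source_id") %in% names(records)))
  sp <- stats::aggregate(wood_density ~ species + source_id, records, mean)
  sources <- sort(unique(sp$source_id))
  if (length(sources) < 2L) stop("need at least two sources")
  out <- list()
  for (i in seq_along(sources)) for (j in seq_along(sources)) {
    if (j <= i) next
    a <- sp[sp$source_id == sources[i], ]
    b <- sp[sp$source_id == sources[j], ]
    m <- merge(a, b, by = "species", suffixes = c("_a", "_b"))
    if (nrow(m) < 3L) {
      message("skipping pair ", sources[i], "/", sources[j],
              ": only ", nrow(m), " shared species")
      next
    }
    fit <- stats::lm(wood_density_b ~ wood_density_a, data = m)
    sse <- sum(stats::residuals(fit)^2)
    sst <- sum((m$wood_density_b - mean(m$wood_density_b))^2)
    out[[length(out) + 1L]] <- data.frame(
      source_a = sources[i], source_b = sources[j], n_shared = nrow(m),
      slope = unname(stats::coef(fit)[2L]), r2 = 1 - sse / sst)
  }
  if (!length(out)) stop("no source pair shares >= 3 species")
  do.call(rbind, out)
}

#' Nested taxonomic variance decomposition of trait records
#'
#' Fits the nested random-effects model
#' `wd = mu + a_family + b_genus(family) + c_species(genus) + e` by REML
#' (through \pkg{lme4}) and returns the variance components and their
#' fractions of the total. A level with a single category is fixed at 0
#' with a warning; negative components cannot occur under REML's bounded
#' optimisation.
#'
#' @param records data.frame with `family`, `genus`, `species`,
#'   `wood_density`.
#' @return list with `components` and `fractions`, each named
#'   `family, genus_within_family, species_within_genus, residual`;
#'   fractions sum to 1.
#' @export
taxonomicVarianceDecomposition <- function(records) {
  stopifnot(all(c("family", "genus", "species", "wood_density") %in%
                  names(records)))
  rec <- records[!is.na(records$wood_density), , drop = FALSE]
  # explicit nesting so repeated labels across parents cannot alias
  rec$.fam <- factor(rec$family)
  rec$.gen <- factor(paste(rec$family, rec$genus, sep = "/"))
  rec$.sp <- factor(paste(rec$family, rec$genus, rec$species, sep = "/"))
  terms <- character()
  zero <- character()
  for (lv in c(".fam", ".gen", ".sp")) {
    if (nlevels(rec[[lv]]) > 1L) terms <- c(terms, sprintf("(1 | %s)", lv))
    else zero <- c(zero, lv)
  }
  if (length(zero))
    warning("level(s) with a single category fixed at 0: ",
            paste(zero, collapse = ", "))
  if (!length(terms)) stop("need at least two categories at some level")
  f <- stats::as.formula(paste("wood_density ~ 1 +",
                               paste(terms, collapse = " + ")))
  # boundary fits (a component at ~0) trigger harmless optimizer chatter
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(f, data = rec,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  comp <- c(family = get(".fam"),
            genus_within_family = get(".gen"),
            species_within_genus = get(".sp"),
            residual = get("Residual"))
  list(components = comp, fractions = comp / sum(comp))
}
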