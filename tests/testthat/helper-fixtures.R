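# shared fixtures, all generated in code

# trait records table derived from a synthetic world's truth
worldTraitRecords <- function(world) {
  tax <- world@taxonomy
  tt <- world@traitTruth
  data.frame(species = names(tt),
             genus = tax$genus[match(names(tt), tax$species)],
             family = tax$family[match(names(tt), tax$species)],
             order = tax$order[match(names(tt), tax$species)],
             clade = tax$clade[match(names(tt), tax$species)],
             wood_density = as.numeric(tt),
             source_id = "synthetic_truth",
             stringsAsFactors = FALSE)
}

worldTraitTable <- function(world) buildTraitTable(worldTraitRecords(world))

# small world cached per session to keep the unit suite fast
smallWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeSyntheticWorld(nTips = 80, nRows = 24, nCols = 24,
                                   nPlots = 250, seed = 404)
    cache
  }
})

# fixed 5-tip tree used by the brute-force covariance and likelihood oracles
fiveTipTree <- function() {
  ape::read.tree(text = "((A:1,B:1):2,(C:1.5,(D:0.5,E:0.5):1):1.5);")
}

# independent path-walk oracle for shared branch lengths: walks edges from
# each tip to the root and sums lengths of common edges
pathWalkCovariance <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parentOf <- function(node) {
    i <- which(tree$edge[, 2L] == node)
    if (length(i) == 0L) NULL else list(parent = tree$edge[i, 1L],
                                        len = tree$edge.length[i])
  }
  edgesToRoot <- function(tip) {
    out <- list()
    node <- tip
    repeat {
      p <- parentOf(node)
      if (is.null(p)) break
      out[[length(out) + 1L]] <- c(node, p$parent, p$len)
      node <- p$parent
    }
    out
  }
  paths <- lapply(seq_len(n), edgesToRoot)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ei <- vapply(paths[[i]], function(e) paste(e[1L], e[2L]), character(1))
    ej <- vapply(paths[[j]], function(e) paste(e[1L], e[2L]), character(1))
    shared <- intersect(ei, ej)
    C[i, j] <- sum(vapply(paths[[i]][ei %in% shared], `[`, numeric(1), 3L))
  }
  C
}

# independent profiled-likelihood grid search for Pagel's lambda
lambdaGridOracle <- function(tree, traits, step = 1e-3) {
  C <- ape::vcv(tree)
  y <- traits[rownames(C)]
  n <- length(y)
  ll <- function(lam) {
    V <- lam * C
    diag(V) <- diag(C)
    Vi <- solve(V)
    mu <- sum(Vi %*% y) / sum(Vi)
    q <- drop(t(y - mu) %*% Vi %*% (y - mu))
    s2 <- q / n
    -0.5 * (n * log(2 * pi * s2) + determinant(V)$modulus + n)
  }
  grid <- seq(0, 1, by = step)
  vals <- vapply(grid, ll, numeric(1))
  grid[which.max(vals)]
}

# ray-casting (crossing-number) point-in-polygon oracle, independent of the
# half-plane implementation; boundary handled by nudging is avoided by the
# tests using interior/exterior points
rayCastInPolygon <- function(px, py, vx, vy) {
  nv <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
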