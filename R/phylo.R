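#' Brownian covariance matrix of a phylogeny
#'
#' Tip-by-tip matrix of shared root-to-tip path lengths (the expected trait
#' covariance, up to a rate constant, under Brownian motion); the diagonal
#' holds root-to-tip distances. Zero-length terminal branches make the
#' matrix singular; a diagonal jitter can be requested for downstream
#' solves.
#'
#' @param tree an `ape` `phylo` with branch lengths.
#' @param jitter nonnegative value added to the diagonal (default 0).
#' @return symmetric positive semi-definite matrix with tip labels.
#' @export
brownianCovariance <- function(tree, jitter = 0) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv(tree)
  term <- tree$edge[, 2L] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0))
    warning("zero-length terminal branches: covariance is singular; ",
            "consider the 'jitter' argument")
  if (jitter > 0) diag(C) <- diag(C) + jitter
  C
}

# profiled multivariate-normal log-likelihood machinery shared by lambda
# and K. V must be positive definite.
profiledLogLik <- function(V, y) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  logdet <- 2 * sum(log(diag(R)))
  one <- rep(1, n)
  Vi1 <- backsolve(R, forwardsolve(t(R), one))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  mu <- sum(Viy) / sum(Vi1)
  q <- sum((y - mu) * backsolve(R, forwardsolve(t(R), y - mu)))
  s2 <- q / n
  if (s2 <= 0) return(list(ll = -Inf))
  list(ll = -0.5 * (n * log(2 * pi * s2) + logdet + n), mu = mu, s2 = s2)
}

lambdaTransform <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

# largest lambda keeping C(lambda) positive definite (>= 1 for ultrametric
# trees); bisection on Cholesky success over [1, 2]
lambdaMax <- function(C) {
  pd <- function(l) !is.null(tryCatch(chol(lambdaTransform(C, l)),
                                      error = function(e) NULL))
  if (!pd(1)) return(1)
  lo <- 1; hi <- 2
  if (pd(hi)) return(hi)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (pd(mid)) lo <- mid else hi <- mid
  }
  lo
}

matchTraits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be named by tip label")
  miss <- setdiff(tree$tip.label, names(traits))
  extra <- setdiff(names(traits), tree$tip.label)
  if (length(miss) || length(extra))
    stop("tip/trait label mismatch; missing traits: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...",
         "; unmatched traits: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) " ...")
  traits[tree$tip.label]
}

#' Pagel's lambda by maximum likelihood
#'
#' Scales the off-diagonal of the Brownian covariance by lambda (diagonal
#' unchanged) and maximises the multivariate-normal likelihood over
#' `[0, lambda_max]`, profiling the ancestral mean and rate analytically at
#' each lambda; `lambda_max` is the largest value keeping the covariance
#' positive definite (>= 1 for ultrametric trees). Optimisation is
#' golden-section (via `optimize`) with tolerance 1e-6. The p-value is a
#' likelihood-ratio test against lambda = 0 (chi-squared, 1 df).
#'
#' @param tree `phylo` with >= 4 tips.
#' @param traits named numeric vector matched to tip labels.
#' @return object of class `SignalResult`: `statistic` (lambda-hat),
#'   `logLik`, `logLik0`, `p.value`, `n`, `method`.
#' @export
pagelsLambda <- function(tree, traits) {
  y <- matchTraits(tree, traits)
  if (length(y) < 4L) stop("need at least 4 tips with trait values")
  if (stats::sd(y) == 0) stop("constant trait: likelihood is degenerate")
  C <- brownianCovariance(tree)
  lmax <- lambdaMax(C)
  obj <- function(l) profiledLogLik(lambdaTransform(C, l), y)$ll
  opt <- stats::optimize(obj, c(0, lmax), maximum = TRUE, tol = 1e-6)
  # optimize can miss boundary optima; check the ends explicitly
  cand <- c(opt$maximum, 0, lmax)
  lls <- c(opt$objective, obj(0), obj(lmax))
  best <- which.max(lls)
  ll0 <- lls[2L]
  lr <- max(0, 2 * (lls[best] - ll0))
  res <- list(statistic = c(lambda = unname(cand[best])),
              logLik = lls[best], logLik0 = ll0,
              p.value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
              n = length(y), lambda_max = lmax,
              method = "Pagel's lambda (ML, profiled mean and rate)")
  class(res) <- "SignalResult"
  res
}

#' @export
print.SignalResult <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %s = %.4f, n = %d, p = %.4g\n",
              names(x$statistic), x$statistic, x$n, x$p.value))
  invisible(x)
}

#' Blomberg's K with a contrast-variance permutation test
#'
#' K compares the observed ratio of the mean squared deviation from the
#' phylogenetically corrected mean (MSE0) to the phylogenetically weighted
#' mean squared error (MSE) against its Brownian expectation
#' `(tr(C) - n / sum(C^-1)) / (n - 1)`; K = 1 is the Brownian baseline,
#' K << 1 means less signal than Brownian motion. Significance comes from
#' tip permutations: the variance of phylogenetically independent
#' contrasts is recomputed for each shuffled trait vector and the p-value
#' is the (+1-smoothed) fraction of permutations with contrast variance at
#' most the observed one.
#'
#' @param tree `phylo` with >= 4 tips.
#' @param traits named numeric vector matched to tip labels.
#' @param nPerm number of permutations (>= 99; default 999).
#' @return `SignalResult` with `statistic` (K), `p.value`, `n`.
#' @export
blombergsK <- function(tree, traits, nPerm = 999) {
  y <- matchTraits(tree, traits)
  n <- length(y)
  if (n < 4L) stop("need at least 4 tips with trait values")
  if (nPerm < 99) stop("nPerm must be >= 99")
  if (stats::sd(y) == 0) stop("constant trait")
  C <- brownianCovariance(tree)
  R <- tryCatch(chol(C), error = function(e)
    stop("singular Brownian covariance; rerun brownianCovariance with jitter"))
  solveC <- function(v) backsolve(R, forwardsolve(t(R), v))
  one <- rep(1, n)
  Ci1 <- solveC(one)
  a <- sum(solveC(y)) / sum(Ci1)          # phylogenetically corrected mean
  dev <- y - a
  mse0 <- sum(dev^2) / (n - 1)
  mse <- sum(dev * solveC(dev)) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci1)) / (n - 1)
  K <- (mse0 / mse) / expected

  picvar <- function(v) stats::var(ape::pic(v, tree))
  obs <- picvar(y)
  perm <- replicate(nPerm, picvar(stats::setNames(sample(y), names(y))))
  p <- (sum(perm <= obs) + 1) / (nPerm + 1)
  res <- list(statistic = c(K = unname(K)), p.value = p, n = n,
              nPerm = nPerm, contrast_var = obs,
              method = "Blomberg's K (contrast-variance permutation test)")
  class(res) <- "SignalResult"
  res
}

#' Order-level trait conservatism randomization test
#'
#' For each taxonomic order, the observed mean trait over its descendant
#' tips is compared with a null built from `nRand` random shuffles of the
#' whole trait vector across all tips. The two-tailed p-value uses the
#' (r + 1)/(n + 1) convention on inclusive ranks:
#' `p = min(1, 2 * min(p_low, p_high))` with
#' `p_high = (#\{null >= obs\} + 1)/(nRand + 1)` and symmetrically for
#' `p_low`. Orders with fewer than `minSpecies` tips are reported but
#' flagged `"untested"`.
#'
#' @param tree `phylo`.
#' @param traits named numeric vector matched to tip labels.
#' @param orderMap named character vector (species -> order) covering all
#'   tips, or a data.frame with `species` and `order` columns.
#' @param nRand number of randomizations (>= 99; default 999).
#' @param minSpecies minimum tips for an order to be tested (default 50).
#' @param alpha significance level for the direction flag (default 0.05).
#' @return data.frame: `order, n_species, mean_wd, p_value, flag` where
#'   flag is `untested`, `higher`, `lower` or `ns`.
#' @export
orderConservatismTest <- function(tree, traits, orderMap, nRand = 999,
                                  minSpecies = 50, alpha = 0.05) {
  if (is.data.frame(orderMap))
    orderMap <- stats::setNames(orderMap$order, orderMap$species)
  y <- matchTraits(tree, traits)
  if (nRand < 99) stop("nRand must be >= 99")
  uncovered <- setdiff(names(y), names(orderMap))
  if (length(uncovered))
    stop("orderMap does not cover all tips: ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  ord <- factor(orderMap[names(y)])
  counts <- table(ord)
  # indicator matrix scaled to compute all order means in one product
  M <- outer(ord, factor(levels(ord), levels = levels(ord)), `==`) * 1
  M <- sweep(M, 2L, as.numeric(counts), "/")
  obs <- as.numeric(crossprod(M, y))
  perm <- matrix(NA_real_, nRand, nlevels(ord))
  for (r in seq_len(nRand)) perm[r, ] <- crossprod(M, sample(y))
  p_high <- (colSums(perm >= rep(obs, each = nRand)) + 1) / (nRand + 1)
  p_low <- (colSums(perm <= rep(obs, each = nRand)) + 1) / (nRand + 1)
  p <- pmin(1, 2 * pmin(p_low, p_high))
  tested <- as.numeric(counts) >= minSpecies
  flag <- ifelse(!tested, "untested",
                 ifelse(p <= alpha & p_high < p_low, "higher",
                        ifelse(p <= alpha & p_low < p_high, "lower", "ns")))
  data.frame(order = levels(ord), n_species = as.integer(counts),
             mean_wd = obs,
             p_value = ifelse(tested, p, NA_real_),
             flag = flag, row.names = NULL)
}
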