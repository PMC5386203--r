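#' @include AllClasses.R
NULL

.degrees <- function(x) {
  if (is(x, "GPANetwork")) as.integer(igraph::degree(asIgraph(x)))
  else if (inherits(x, "igraph")) as.integer(igraph::degree(x))
  else as.integer(x)
}

#' Complementary cumulative degree distribution
#'
#' `P_c(k)`, the fraction of nodes with degree at least `k`, evaluated at
#' every observed degree. Non-increasing, with value 1 at the minimum
#' observed degree.
#'
#' @param x a [GPANetwork-class], an `igraph` graph, or an integer vector of
#'   degrees.
#' @return a data frame with columns `k` (ascending observed degrees) and
#'   `ccdf`.
#' @export
#' @examples
#' degreeCCDF(c(1, 1, 2, 3))  # 1, 0.5, 0.25
degreeCCDF <- function(x) {
  deg <- .degrees(x)
  if (!length(deg)) stop("empty network")
  k <- sort(unique(deg))
  ccdf <- vapply(k, function(kk) mean(deg >= kk), numeric(1))
  data.frame(k = k, ccdf = ccdf)
}

# Hurwitz zeta(s, a) = sum_{k>=0} (a + k)^(-s), s > 1, by Euler-Maclaurin.
hurwitzZeta <- function(s, a) {
  stopifnot(s > 1, a > 0)
  K <- 64
  head <- sum((a + seq_len(K) - 1)^(-s))
  b <- a + K
  head + b^(1 - s) / (s - 1) + 0.5 * b^(-s) + s * b^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * b^(-s - 3) / 720
}

# Discrete power-law tail CCDF P(K >= k | K >= kmin) at the given k values.
.plTailCCDF <- function(k, gamma, kmin) {
  z0 <- hurwitzZeta(gamma, kmin)
  vapply(k, function(kk) hurwitzZeta(gamma, kk), numeric(1)) / z0
}

# Discrete MLE of the exponent on the tail k >= kmin.
.plMLE <- function(tail, kmin) {
  S <- sum(log(tail))
  n <- length(tail)
  opt <- optimize(function(g) -(-g * S - n * log(hurwitzZeta(g, kmin))),
                  interval = c(1.01, 8))
  opt$minimum
}

# KS distance between the empirical and fitted tail CCDFs.
.plKS <- function(tail, gamma, kmin) {
  k <- sort(unique(tail))
  emp <- vapply(k, function(kk) mean(tail >= kk), numeric(1))
  max(abs(emp - .plTailCCDF(k, gamma, kmin)))
}

# Sample n draws from the discrete power law p(k) ~ k^(-gamma), k >= kmin.
.rplDiscrete <- function(n, gamma, kmin) {
  kmax <- min(1e6, max(1e4, ceiling(kmin * 1e6^(1 / (gamma - 1)))))
  ks <- seq.int(kmin, kmax)
  pmf <- ks^(-gamma)
  sample(ks, n, replace = TRUE, prob = pmf)
}

#' Fit a discrete power law to a degree sample
#'
#' Maximum-likelihood fit of `p(k) ~ k^(-gamma)` for `k >= k_min`, with the
#' scaling-region cutoff `k_min` selected by scanning the observed degrees
#' and minimizing the Kolmogorov-Smirnov distance between the empirical and
#' fitted tail distributions. Optionally a semi-parametric bootstrap
#' goodness-of-fit p-value: surrogate samples draw tail values from the
#' fitted law and body values from the empirical body, are refitted in full,
#' and `p` is the fraction of surrogate KS distances at least as large as
#' the observed one (the conventional acceptance threshold is `p > 0.1`).
#'
#' @param x a network or integer degree sample (all degrees >= 1); samples
#'   of at least ~50 values are recommended.
#' @param kMinCandidates optional integer vector of cutoffs to scan
#'   (default: all observed degrees leaving a tail of at least `minTail`
#'   values and two distinct degrees).
#' @param minTail smallest admissible tail sample size (default 8).
#' @param gof if `TRUE`, compute the bootstrap goodness-of-fit p-value.
#' @param nBoot number of bootstrap surrogates (default 100).
#' @return a [PowerLawFit-class].
#' @export
#' @examples
#' set.seed(1)
#' net <- growNetwork(gpaParams(500, m = 3, beta = 2 / 3, lambda = 1,
#'                              seed = 7))
#' fitPowerLaw(net)
fitPowerLaw <- function(x, kMinCandidates = NULL, minTail = 8L,
                        gof = FALSE, nBoot = 100L) {
  deg <- .degrees(x)
  if (!length(deg)) stop("empty degree sample")
  if (any(deg < 1L)) stop("all degrees must be >= 1")
  if (length(unique(deg)) < 2L)
    stop("power-law fit impossible: all degrees are equal")
  cands <- if (is.null(kMinCandidates)) sort(unique(deg)) else
    sort(unique(as.integer(kMinCandidates)))
  cands <- cands[vapply(cands, function(km) {
    tail <- deg[deg >= km]
    length(tail) >= max(2L, minTail) && length(unique(tail)) >= 2L
  }, logical(1))]
  if (!length(cands)) stop("no admissible k_min candidate")
  fits <- lapply(cands, function(km) {
    tail <- deg[deg >= km]
    g <- .plMLE(tail, km)
    list(kmin = km, gamma = g, ks = .plKS(tail, g, km),
         ntail = length(tail))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
  pval <- NA_real_
  if (gof) {
    n <- length(deg)
    body <- deg[deg < best$kmin]
    ptail <- best$ntail / n
    ksb <- vapply(seq_len(nBoot), function(b) {
      ntl <- rbinom(1, n, ptail)
      surr <- c(if (ntl > 0) .rplDiscrete(ntl, best$gamma, best$kmin),
                if (n - ntl > 0) sample(body, n - ntl, replace = TRUE))
      f <- tryCatch(fitPowerLaw(surr, minTail = minTail),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f@ksTail
    }, numeric(1))
    pval <- mean(ksb >= best$ks, na.rm = TRUE)
  }
  new("PowerLawFit", gammaHat = best$gamma, kMin = as.integer(best$kmin),
      ksTail = best$ks, nTail = as.integer(best$ntail), gofPvalue = pval)
}

#' Per-degree clustering spectrum
#'
#' Local clustering of node `s` is the probability that two neighbours of
#' `s` are themselves connected, `2 T_s / (k_s (k_s - 1))` with `T_s` the
#' number of triangles at `s`. The profile averages it over nodes of equal
#' degree; nodes of degree < 2 (undefined coefficient) are excluded from
#' both the profile and the mean.
#'
#' @param x a [GPANetwork-class] or an `igraph` graph.
#' @return a [ClusteringProfile-class].
#' @export
clusteringProfile <- function(x) {
  g <- if (is(x, "GPANetwork")) asIgraph(x) else x
  if (!inherits(g, "igraph")) stop("need a GPANetwork or igraph object")
  if (igraph::vcount(g) == 0L) stop("empty network")
  deg <- igraph::degree(g)
  lc <- igraph::transitivity(g, type = "local")
  ok <- deg >= 2
  prof <- data.frame(
    k = sort(unique(deg[ok])),
    cbar = as.numeric(tapply(lc[ok], deg[ok], mean)),
    nNodes = as.integer(table(deg[ok])))
  new("ClusteringProfile", profile = prof,
      meanClustering = mean(lc[ok]))
}

#' Kolmogorov-Smirnov statistic of angles against uniformity
#'
#' The supremum distance `rho` between the empirical distribution function
#' of the angles and the uniform CDF `theta / (2*pi)`, taking both sides of
#' every jump. `rho` near 0 indicates homogeneous similarity coordinates
#' (the `Lambda -> Inf` regime); values near 1 indicate strong angular
#' clustering.
#'
#' @param x a [GPANetwork-class] or a numeric vector of angles.
#' @return the KS statistic, in `[0, 1]`.
#' @export
#' @examples
#' ksUniform(pi)  # 0.5
ksUniform <- function(x) {
  ang <- if (is(x, "GPANetwork")) nodeAngles(x) else x
  n <- length(ang)
  if (!n) stop("empty angle set")
  u <- sort(reduceAngle(ang)) / (2 * pi)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}
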