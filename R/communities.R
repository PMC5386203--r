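#' @include AllClasses.R geometry.R
NULL

.angles <- function(x) {
  if (is(x, "GPANetwork")) nodeAngles(x) else reduceAngle(as.numeric(x))
}

#' Critical angular gap
#'
#' The expected value of the largest of `n` circular gaps between `n`
#' points placed uniformly at random on the circle: gaps are approximately
#' exponential with rate `n / (2*pi)`, so the expected maximum is
#' `(2*pi / n) * H_n` with `H_n` the n-th harmonic number
#' (mode `"exact_harmonic"`), approximated by
#' `(2*pi / n) * (ln n + gamma_Euler)` (mode `"approx"`, the default). Gaps
#' larger than this threshold mark boundaries between soft communities.
#'
#' @param n number of nodes (>= 1).
#' @param mode `"approx"` or `"exact_harmonic"`.
#' @return the critical gap, strictly decreasing in `n` for `n >= 2`.
#' @export
#' @examples
#' criticalGap(100)                           # 0.325605
#' criticalGap(100, mode = "exact_harmonic")  # 0.325933
criticalGap <- function(n, mode = c("approx", "exact_harmonic")) {
  mode <- match.arg(mode)
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  eulerGamma <- 0.57721566490153286
  if (mode == "approx") (2 * pi / n) * (log(n) + eulerGamma)
  else (2 * pi / n) * sum(1 / seq_len(n))
}

#' Circular gaps between consecutive angles
#'
#' Sorts the angles and returns the `n` circular gaps between consecutive
#' points, including the wrap-around gap; a single angle yields one gap of
#' `2*pi`. The gaps sum to `2*pi` and are also returned rescaled by the
#' critical gap.
#'
#' @param x a [GPANetwork-class] or a numeric vector of angles.
#' @param thetaC critical gap used for rescaling (default: [criticalGap()]
#'   of the sample size, approximate mode).
#' @return a [GapSequence-class].
#' @export
#' @examples
#' circularGaps(c(0, pi))  # gaps pi, pi
circularGaps <- function(x, thetaC = criticalGap(length(.angles(x)))) {
  ang <- .angles(x)
  n <- length(ang)
  if (!n) stop("empty angle set")
  s <- sort(ang)
  gaps <- if (n == 1L) 2 * pi else c(diff(s), 2 * pi - s[n] + s[1])
  new("GapSequence", sortedAngles = s, gaps = gaps, thetaC = thetaC,
      rescaledGaps = gaps / thetaC)
}

#' Detect soft communities from angular coordinates
#'
#' A soft community is a maximal run of circularly consecutive nodes whose
#' internal gaps do not exceed the critical gap: the circle is cut at every
#' gap strictly greater than `thetaC` and the runs between cuts are the
#' communities. With no qualifying gap (or a single one, which cuts the
#' circle into one arc) the whole network is a single community.
#' Communities are ordered by their smallest member angle; the run spanning
#' the `2*pi -> 0` wrap is one community.
#'
#' @param x a [GPANetwork-class] or a numeric vector of angles.
#' @param thetaC critical gap (> 0); default: [criticalGap()] of the sample
#'   size in approximate mode.
#' @return a [CommunityPartition-class]; node indices refer to the input
#'   order.
#' @export
#' @examples
#' p <- detectCommunities(c(0, 0.1, 0.2, 3.0, 3.1, 3.2))
#' nCommunities(p)   # 2
#' communitySizes(p) # 3 3
detectCommunities <- function(x, thetaC = criticalGap(length(.angles(x)))) {
  ang <- .angles(x)
  n <- length(ang)
  if (!n) stop("empty angle set")
  if (length(thetaC) != 1L || !is.finite(thetaC) || thetaC <= 0)
    stop("thetaC must be a single positive value")
  ord <- order(ang)
  s <- ang[ord]
  gaps <- if (n == 1L) 2 * pi else c(diff(s), 2 * pi - s[n] + s[1])
  cuts <- which(gaps > thetaC)  # gap i follows sorted node i
  if (length(cuts) <= 1L) {
    bg <- if (length(cuts)) rep(gaps[cuts], 2) else c(NA_real_, NA_real_)
    part <- new("CommunityPartition", thetaC = thetaC,
                communities = list(seq_len(n)), sizes = n,
                boundingGaps = matrix(bg, 1, 2), membership = rep(1L, n),
                nC = 1L, n = n)
    return(part)
  }
  k <- length(cuts)
  # block j runs from sorted position cuts[j-1] + 1 to cuts[j]; block 1
  # wraps: from cuts[k] + 1 around 2*pi to cuts[1], so it owns the smallest
  # angle and blocks come out ordered by smallest member angle.
  starts <- c(cuts[k] + 1L, cuts[-k] + 1L)
  starts[starts > n] <- starts[starts > n] - n
  ends <- cuts
  membership <- integer(n)
  communities <- vector("list", k)
  bounding <- matrix(0, k, 2)
  for (j in seq_len(k)) {
    pos <- if (starts[j] <= ends[j]) seq.int(starts[j], ends[j])
           else c(seq.int(starts[j], n), seq_len(ends[j]))
    ids <- ord[pos]
    communities[[j]] <- sort(ids)
    membership[ids] <- j
    gl <- if (j == 1L) cuts[k] else cuts[j - 1L]
    bounding[j, ] <- c(gaps[gl], gaps[ends[j]])
  }
  new("CommunityPartition", thetaC = thetaC, communities = communities,
      sizes = lengths(communities), boundingGaps = bounding,
      membership = membership, nC = k, n = n)
}

#' Community separation and its network mean
#'
#' The separation of a community is the average of its two bounding gaps
#' rescaled by the critical gap, `S = (g_left + g_right) / (2 * thetaC)`;
#' by construction `S >= 1` for every detected community. The mean
#' separation is the expected separation of the community a randomly chosen
#' node belongs to, i.e. the size-weighted average
#' `S_bar = sum(n_i * S_i) / sum(n_i)`. Values close to 1 mean blurred
#' community boundaries; large values mean narrow, well-separated
#' communities.
#'
#' @param partition a [CommunityPartition-class] with at least two
#'   communities.
#' @return a list with `S` (per-community separations, in community order)
#'   and `mean` (the size-weighted mean separation).
#' @export
#' @examples
#' p <- detectCommunities(c(0, 0.1, 0.2, 3.0, 3.1, 3.2))
#' communitySeparation(p)$mean  # 1.185749
communitySeparation <- function(partition) {
  stopifnot(is(partition, "CommunityPartition"))
  if (partition@nC < 2L)
    stop("separation undefined: a single community has no bounding gaps")
  S <- rowSums(partition@boundingGaps) / (2 * partition@thetaC)
  list(S = S, mean = sum(partition@sizes * S) / sum(partition@sizes))
}

#' Sample autocorrelation of the circular gap sequence
#'
#' Standard biased sample autocorrelation of the gap series in circular
#' order, normalized to 1 at lag 0. Slow decay indicates long-range
#' correlations in node placement (small `Lambda`); white-noise-like decay
#' indicates near-Poisson placement (large `Lambda`).
#'
#' @param x a [GapSequence-class], a [GPANetwork-class], or a numeric vector
#'   of gaps.
#' @param maxLag largest lag (default 20); the series must have at least
#'   `maxLag + 2` values.
#' @return a data frame with columns `lag` (0..`maxLag`) and `acf`.
#' @export
gapAutocorrelation <- function(x, maxLag = 20L) {
  gaps <- if (is(x, "GapSequence")) x@gaps
          else if (is(x, "GPANetwork")) circularGaps(x)@gaps
          else as.numeric(x)
  n <- length(gaps)
  if (n < maxLag + 2L) stop("need at least maxLag + 2 gaps")
  if (stats::var(gaps) == 0)
    stop("autocorrelation undefined: zero gap variance")
  a <- acf(gaps, lag.max = maxLag, plot = FALSE, demean = TRUE)
  data.frame(lag = 0:maxLag, acf = as.numeric(a$acf))
}

#' CCDF of soft-community sizes
#'
#' Fraction of communities with size at least `s`, evaluated at every
#' observed size; non-increasing with value 1 at the smallest size.
#'
#' @param partition a [CommunityPartition-class].
#' @return a data frame with columns `size` and `ccdf`.
#' @export
communitySizeCCDF <- function(partition) {
  stopifnot(is(partition, "CommunityPartition"))
  sz <- partition@sizes
  s <- sort(unique(sz))
  data.frame(size = s,
             ccdf = vapply(s, function(ss) mean(sz >= ss), numeric(1)))
}
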