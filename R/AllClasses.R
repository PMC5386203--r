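#' @include gpanet-package.R
NULL

setClassUnion("integerOrNA", c("integer", "logical"))

#' Generation controls for a GPA network
#'
#' Holds the four model parameters (target size `n`, links per new node `m`,
#' popularity-fading speed `beta`, initial attractiveness `Lambda`) plus the
#' distance mode used for attractiveness disks and linking, and the RNG seed.
#' `Lambda` is stored as a per-birth-time vector so that time-varying
#' schedules are supported; the implied degree exponent is
#' `gamma = 1 + 1/beta`.
#'
#' @slot n target node count (>= 1).
#' @slot m links established by every new node (>= 1).
#' @slot beta popularity-fading speed, in (0, 1].
#' @slot lambda numeric vector of length `n`, `Lambda(t)` for t = 1..n.
#' @slot distanceMode `"approx"` (printed hyperbolic-distance formula) or
#'   `"exact"` (law of cosines at curvature -1).
#' @slot seed integer RNG seed, or `NA`.
#' @seealso [gpaParams()], [growNetwork()]
#' @export
setClass("GPAParams",
  representation(n = "integer", m = "integer", beta = "numeric",
                 lambda = "numeric", distanceMode = "character",
                 seed = "integerOrNA"))

setValidity("GPAParams", function(object) {
  msg <- NULL
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    msg <- c(msg, "n must be a single integer >= 1")
  if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
    msg <- c(msg, "m must be a single integer >= 1")
  if (length(object@beta) != 1L || !is.finite(object@beta) ||
      object@beta <= 0 || object@beta > 1)
    msg <- c(msg, "beta must lie in (0, 1]")
  if (length(object@lambda) != object@n)
    msg <- c(msg, "lambda must have one value per birth time")
  if (any(!is.finite(object@lambda)) || any(object@lambda < 0))
    msg <- c(msg, "lambda values must be finite and >= 0")
  if (!object@distanceMode %in% c("approx", "exact"))
    msg <- c(msg, "distanceMode must be 'approx' or 'exact'")
  if (is.null(msg)) TRUE else msg
})

#' A network grown by geometric preferential attachment
#'
#' Node records are implicit in birth order: node `t` (t = 1..n) has angular
#' coordinate `angles[t]` and radial coordinate `2 ln t` at birth, updated by
#' popularity fading as the network grows. Edges are undirected pairs of
#' 1-based birth-time ids, without self-loops or duplicates.
#'
#' @slot angles numeric vector, angular coordinates in `[0, 2*pi)`, birth order.
#' @slot edges two-column integer matrix of undirected edges.
#' @slot chosenAttract integer vector, the attractiveness `A_t(theta_t)` of the
#'   selected candidate position at each birth time (simulation provenance).
#' @slot params the [GPAParams-class] the network was grown with.
#' @seealso [growNetwork()], [asIgraph()], [nodeAngles()]
#' @export
setClass("GPANetwork",
  representation(angles = "numeric", edges = "matrix",
                 chosenAttract = "integer", params = "GPAParams"))

setValidity("GPANetwork", function(object) {
  msg <- NULL
  n <- length(object@angles)
  if (any(!is.finite(object@angles)) ||
      any(object@angles < 0) || any(object@angles >= 2 * pi))
    msg <- c(msg, "angles must be finite and lie in [0, 2*pi)")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  else if (nrow(e)) {
    if (any(e < 1L) || any(e > n)) msg <- c(msg, "edge endpoints out of range")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
  }
  if (is.null(msg)) TRUE else msg
})

#' Circular angular gaps of a point set on the similarity circle
#'
#' For `n` angles there are `n` circular gaps between consecutive sorted
#' angles (including the wrap-around gap); they sum to `2*pi`. `gaps[i]` is
#' the gap following `sortedAngles[i]` counter-clockwise. Rescaled gaps are
#' `gaps / thetaC` where `thetaC` is the critical gap for `n` points.
#'
#' @slot sortedAngles angles in increasing order.
#' @slot gaps circular gaps, same length as `sortedAngles`.
#' @slot thetaC critical gap used for rescaling.
#' @slot rescaledGaps `gaps / thetaC`.
#' @seealso [circularGaps()], [criticalGap()]
#' @export
setClass("GapSequence",
  representation(sortedAngles = "numeric", gaps = "numeric",
                 thetaC = "numeric", rescaledGaps = "numeric"))

setValidity("GapSequence", function(object) {
  msg <- NULL
  if (length(object@gaps) != length(object@sortedAngles))
    msg <- c(msg, "number of gaps must equal number of angles")
  if (any(object@gaps < 0)) msg <- c(msg, "gaps must be >= 0")
  if (abs(sum(object@gaps) - 2 * pi) > 1e-9)
    msg <- c(msg, "gaps must sum to 2*pi")
  if (is.null(msg)) TRUE else msg
})

#' Soft-community partition from angular gaps
#'
#' Nodes are split at every angular gap strictly greater than the critical
#' gap `thetaC`; maximal runs of circularly consecutive nodes form the soft
#' communities. Communities are ordered by their smallest member angle; the
#' block spanning the 2*pi -> 0 wrap is a single community.
#'
#' @slot thetaC critical gap used for splitting.
#' @slot communities list of integer vectors of node indices (input order).
#' @slot sizes community sizes `n_i`.
#' @slot boundingGaps `nC x 2` matrix of (left, right) bounding gaps; `NA`
#'   when a single community covers the whole circle without a splitting gap.
#' @slot membership integer community id per node (input order).
#' @slot nC number of communities.
#' @slot n number of nodes.
#' @seealso [detectCommunities()], [communitySeparation()]
#' @export
setClass("CommunityPartition",
  representation(thetaC = "numeric", communities = "list", sizes = "integer",
                 boundingGaps = "matrix", membership = "integer",
                 nC = "integer", n = "integer"))

setValidity("CommunityPartition", function(object) {
  msg <- NULL
  if (sum(object@sizes) != object@n)
    msg <- c(msg, "community sizes must sum to n")
  if (length(object@communities) != object@nC)
    msg <- c(msg, "nC must match the number of community blocks")
  ids <- sort(unlist(object@communities))
  if (!identical(ids, seq_len(object@n)))
    msg <- c(msg, "communities must be disjoint and cover all nodes")
  bg <- object@boundingGaps
  if (object@nC >= 2L && any(!is.na(bg) & bg <= object@thetaC))
    msg <- c(msg, "bounding gaps must exceed thetaC when nC >= 2")
  if (is.null(msg)) TRUE else msg
})

#' Discrete power-law fit of a degree distribution
#'
#' Result of the discrete maximum-likelihood fit with the lower cutoff
#' `kMin` selected by minimizing the Kolmogorov-Smirnov distance on the
#' fitted tail.
#'
#' @slot gammaHat fitted exponent (> 1).
#' @slot kMin selected tail cutoff degree.
#' @slot ksTail KS distance between empirical and fitted tail.
#' @slot nTail number of observations with degree >= `kMin`.
#' @slot gofPvalue bootstrap goodness-of-fit p-value, `NA` unless requested.
#' @seealso [fitPowerLaw()]
#' @export
setClass("PowerLawFit",
  representation(gammaHat = "numeric", kMin = "integer", ksTail = "numeric",
                 nTail = "integer", gofPvalue = "numeric"))

setValidity("PowerLawFit", function(object) {
  msg <- NULL
  if (object@gammaHat <= 1) msg <- c(msg, "gammaHat must exceed 1")
  if (object@kMin < 1L) msg <- c(msg, "kMin must be >= 1")
  if (object@ksTail < 0 || object@ksTail > 1)
    msg <- c(msg, "ksTail must lie in [0, 1]")
  if (object@nTail < 2L) msg <- c(msg, "nTail must be >= 2")
  if (is.null(msg)) TRUE else msg
})

#' Per-degree clustering spectrum
#'
#' Mean local clustering coefficient for each degree `k >= 2` plus the mean
#' over all eligible nodes. Nodes of degree < 2, for which the local
#' coefficient is undefined, are excluded.
#'
#' @slot profile data frame with columns `k`, `cbar`, `nNodes`.
#' @slot meanClustering average local clustering over nodes of degree >= 2.
#' @seealso [clusteringProfile()]
#' @export
setClass("ClusteringProfile",
  representation(profile = "data.frame", meanClustering = "numeric"))

#' Monte-Carlo sample bank for the Lambda likelihood
#'
#' Immutable precomputation reused across all Lambda values: the observed
#' attractiveness `A_t(theta_t)` for t = 2..n0 and, for each of the `N`
#' Monte-Carlo candidate paths, the sum of candidate attractivenesses over
#' the truncated path, `S_t^(j) = sum_i A_t(phi_i^(j))`. These are the
#' sufficient statistics of the bank for the likelihood estimator.
#'
#' @slot n0 number of first nodes used.
#' @slot N number of Monte-Carlo sample paths.
#' @slot beta popularity-fading speed assumed for radial reconstruction.
#' @slot distanceMode distance mode used for attractiveness disks.
#' @slot seed RNG seed the candidate paths were drawn with (or `NA`).
#' @slot observedAttract integer vector `A_t(theta_t)`, t = 2..n0.
#' @slot sumAttract `(n0-1) x N` matrix of per-path attractiveness sums.
#' @seealso [buildSampleBank()], [logLikelihoodLambda()]
#' @export
setClass("MCSampleBank",
  representation(n0 = "integer", N = "integer", beta = "numeric",
                 distanceMode = "character", seed = "integerOrNA",
                 observedAttract = "integer", sumAttract = "matrix"))

setValidity("MCSampleBank", function(object) {
  msg <- NULL
  if (object@n0 < 2L) msg <- c(msg, "n0 must be >= 2")
  if (object@N < 1L) msg <- c(msg, "N must be >= 1")
  if (length(object@observedAttract) != object@n0 - 1L)
    msg <- c(msg, "observedAttract must have n0 - 1 entries")
  if (!all(dim(object@sumAttract) == c(object@n0 - 1L, object@N)))
    msg <- c(msg, "sumAttract must be (n0 - 1) x N")
  tmax <- seq.int(2L, object@n0) - 1L
  if (any(object@observedAttract < 0L) ||
      any(object@observedAttract > tmax))
    msg <- c(msg, "observed attractiveness must lie in [0, t - 1]")
  if (is.null(msg)) TRUE else msg
})

#' Estimated log-likelihood profile of the initial attractiveness
#'
#' Monte-Carlo log-likelihood estimates (up to a shared additive constant)
#' over a grid of Lambda values, with the argmax `lambdaHat`.
#'
#' @slot grid ascending Lambda values (>= 0).
#' @slot loglik estimated log-likelihood per grid point.
#' @slot lambdaHat maximizer (smallest grid value on ties).
#' @slot settings list with elements `N`, `n0`, `seed`, `beta`,
#'   `distanceMode`.
#' @seealso [estimateLambda()], [temporalLambda()]
#' @export
setClass("LambdaLikelihood",
  representation(grid = "numeric", loglik = "numeric", lambdaHat = "numeric",
                 settings = "list"))

setValidity("LambdaLikelihood", function(object) {
  msg <- NULL
  if (is.unsorted(object@grid, strictly = TRUE))
    msg <- c(msg, "grid must be strictly ascending")
  if (any(object@grid < 0)) msg <- c(msg, "grid values must be >= 0")
  if (length(object@loglik) != length(object@grid))
    msg <- c(msg, "loglik must match the grid length")
  if (object@lambdaHat < min(object@grid) ||
      object@lambdaHat > max(object@grid))
    msg <- c(msg, "lambdaHat must lie within the grid range")
  if (is.null(msg)) TRUE else msg
})
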