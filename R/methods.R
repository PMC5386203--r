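#' @include AllGenerics.R
NULL

#' Accessors for GPANetwork objects
#'
#' `nNodes` returns the node count, `nodeAngles` the angular coordinates in
#' birth order, `edgeMatrix` the two-column edge matrix of birth-time ids,
#' and `nodeRadii` the radial coordinates of nodes 1..`time` updated to the
#' given time by popularity fading.
#'
#' @param x a [GPANetwork-class].
#' @param time evaluation time for the radial coordinates (default: the
#'   full network size).
#' @return numeric or integer vectors; a matrix for `edgeMatrix`.
#' @name GPANetwork-accessors
NULL

#' @rdname GPANetwork-accessors
setMethod("nNodes", "GPANetwork", function(x) length(x@angles))

#' @rdname GPANetwork-accessors
setMethod("nodeAngles", "GPANetwork", function(x) x@angles)

#' @rdname GPANetwork-accessors
setMethod("edgeMatrix", "GPANetwork", function(x) x@edges)

#' @rdname GPANetwork-accessors
setMethod("nodeRadii", "GPANetwork", function(x, time = nNodes(x)) {
  stopifnot(time >= 1, time <= nNodes(x))
  updatedRadius(seq_len(time), time, x@params@beta)
})

#' @rdname asIgraph
setMethod("asIgraph", "GPANetwork", function(x) {
  igraph::make_graph(edges = as.vector(t(x@edges)), n = nNodes(x),
                     directed = FALSE)
})

setMethod("show", "GPAParams", function(object) {
  lam <- unique(object@lambda)
  lam_txt <- if (length(lam) == 1L) format(lam) else
    sprintf("schedule [%s .. %s]", format(object@lambda[1]),
            format(object@lambda[object@n]))
  cat(sprintf(
    "GPAParams: n=%d, m=%d, beta=%.4g (gamma=%.4g), Lambda=%s, mode=%s\n",
    object@n, object@m, object@beta, 1 + 1 / object@beta, lam_txt,
    object@distanceMode))
  invisible(object)
})

setMethod("show", "GPANetwork", function(object) {
  cat(sprintf("GPANetwork: %d nodes, %d edges\n", nNodes(object),
              nrow(object@edges)))
  show(object@params)
  invisible(object)
})

setMethod("show", "GapSequence", function(object) {
  cat(sprintf(
    "GapSequence: %d circular gaps (sum %.6f), thetaC = %.6f, max/thetaC = %.3f\n",
    length(object@gaps), sum(object@gaps), object@thetaC,
    max(object@rescaledGaps)))
  invisible(object)
})

#' Accessors for CommunityPartition objects
#'
#' @param x a [CommunityPartition-class].
#' @return `nCommunities`: integer count; `communitySizes`: integer vector;
#'   `communityMembers`: list of node-index vectors; `communityMembership`:
#'   integer community id per node; `boundingGaps`: `nC x 2` matrix;
#'   `thetaC`: the critical gap used.
#' @name CommunityPartition-accessors
NULL

#' @rdname CommunityPartition-accessors
setMethod("nCommunities", "CommunityPartition", function(x) x@nC)

#' @rdname CommunityPartition-accessors
setMethod("communitySizes", "CommunityPartition", function(x) x@sizes)

#' @rdname CommunityPartition-accessors
setMethod("communityMembers", "CommunityPartition", function(x) x@communities)

#' @rdname CommunityPartition-accessors
setMethod("communityMembership", "CommunityPartition", function(x) {
  x@membership
})

#' @rdname CommunityPartition-accessors
setMethod("boundingGaps", "CommunityPartition", function(x) x@boundingGaps)

#' @rdname CommunityPartition-accessors
setMethod("thetaC", "CommunityPartition", function(x) x@thetaC)

setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf(
    "CommunityPartition: %d nodes in %d soft communities (thetaC = %.6f)\n",
    object@n, object@nC, object@thetaC))
  if (object@nC <= 10L)
    cat("  sizes:", paste(object@sizes, collapse = ", "), "\n")
  else
    cat(sprintf("  sizes: median %d, largest %d\n",
                as.integer(stats::median(object@sizes)), max(object@sizes)))
  invisible(object)
})

#' Accessors for PowerLawFit objects
#'
#' @param x a [PowerLawFit-class].
#' @return `gammaHat`: the fitted exponent; `kMin`: the tail cutoff degree.
#' @name PowerLawFit-accessors
NULL

#' @rdname PowerLawFit-accessors
setMethod("gammaHat", "PowerLawFit", function(x) x@gammaHat)

#' @rdname PowerLawFit-accessors
setMethod("kMin", "PowerLawFit", function(x) x@kMin)

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: gamma = %.3f for k >= %d (n_tail = %d, KS = %.4f%s)\n",
    object@gammaHat, object@kMin, object@nTail, object@ksTail,
    if (is.na(object@gofPvalue)) ""
    else sprintf(", GOF p = %.3f", object@gofPvalue)))
  invisible(object)
})

setMethod("show", "ClusteringProfile", function(object) {
  cat(sprintf(
    "ClusteringProfile: %d degree classes, mean clustering = %.4f\n",
    nrow(object@profile), object@meanClustering))
  invisible(object)
})

setMethod("show", "MCSampleBank", function(object) {
  cat(sprintf(
    "MCSampleBank: n0 = %d nodes, N = %d Monte-Carlo paths (beta = %.4g, %s)\n",
    object@n0, object@N, object@beta, object@distanceMode))
  invisible(object)
})

#' Accessors for LambdaLikelihood objects
#'
#' @param x a [LambdaLikelihood-class].
#' @return `lambdaHat`: the maximum-likelihood estimate; `lambdaGrid`: the
#'   Lambda grid; `logLikValues`: the estimated log-likelihood per grid
#'   point (up to a shared additive constant).
#' @name LambdaLikelihood-accessors
NULL

#' @rdname LambdaLikelihood-accessors
setMethod("lambdaHat", "LambdaLikelihood", function(x) x@lambdaHat)

#' @rdname LambdaLikelihood-accessors
setMethod("lambdaGrid", "LambdaLikelihood", function(x) x@grid)

#' @rdname LambdaLikelihood-accessors
setMethod("logLikValues", "LambdaLikelihood", function(x) x@loglik)

setMethod("show", "LambdaLikelihood", function(object) {
  cat(sprintf(
    "LambdaLikelihood: Lambda-hat = %.4g on grid [%g, %g] (%d points; n0 = %d, N = %d)\n",
    object@lambdaHat, min(object@grid), max(object@grid),
    length(object@grid), object@settings$n0, object@settings$N))
  invisible(object)
})
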