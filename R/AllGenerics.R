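#' @include AllClasses.R
NULL

#' Convert a GPA network to an igraph object
#'
#' @param x a [GPANetwork-class].
#' @return an undirected `igraph` graph on `nNodes(x)` vertices whose vertex
#'   ids are birth times.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname GPANetwork-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname GPANetwork-accessors
#' @export
setGeneric("nodeAngles", function(x) standardGeneric("nodeAngles"))

#' @rdname GPANetwork-accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname GPANetwork-accessors
#' @export
setGeneric("nodeRadii", function(x, time = nNodes(x)) {
  standardGeneric("nodeRadii")
})

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("communitySizes", function(x) standardGeneric("communitySizes"))

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("communityMembers", function(x) standardGeneric("communityMembers"))

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("communityMembership", function(x) {
  standardGeneric("communityMembership")
})

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("boundingGaps", function(x) standardGeneric("boundingGaps"))

#' @rdname CommunityPartition-accessors
#' @export
setGeneric("thetaC", function(x) standardGeneric("thetaC"))

#' @rdname PowerLawFit-accessors
#' @export
setGeneric("gammaHat", function(x) standardGeneric("gammaHat"))

#' @rdname PowerLawFit-accessors
#' @export
setGeneric("kMin", function(x) standardGeneric("kMin"))

#' @rdname LambdaLikelihood-accessors
#' @export
setGeneric("lambdaHat", function(x) standardGeneric("lambdaHat"))

#' @rdname LambdaLikelihood-accessors
#' @export
setGeneric("lambdaGrid", function(x) standardGeneric("lambdaGrid"))

#' @rdname LambdaLikelihood-accessors
#' @export
setGeneric("logLikValues", function(x) standardGeneric("logLikValues"))
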