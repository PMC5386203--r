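#' @include AllClasses.R geometry.R
NULL

#' Read and write undirected edge lists
#'
#' Tab-separated files with two integer node-id columns per line and `#`
#' comments. Reading deduplicates (undirected) edges and rejects self-loops
#' with the offending line number; writing a [GPANetwork-class] or a
#' two-column matrix round-trips to the identical edge set.
#'
#' @param path file path.
#' @param x a [GPANetwork-class] or a two-column integer edge matrix.
#' @return `readEdgeList`: a two-column integer matrix; `writeEdgeList`:
#'   `path`, invisibly.
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) return(matrix(integer(0), 0, 2))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed edge line ", lineno[bad[1]], ": expected two columns")
  e <- suppressWarnings(
    matrix(as.integer(unlist(fields)), ncol = 2, byrow = TRUE))
  bad <- which(is.na(e[, 1]) | is.na(e[, 2]))
  if (length(bad))
    stop("malformed edge line ", lineno[bad[1]], ": non-integer node id")
  loops <- which(e[, 1] == e[, 2])
  if (length(loops))
    stop("self-loop at line ", lineno[loops[1]])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' @rdname readEdgeList
#' @export
writeEdgeList <- function(x, path) {
  e <- if (is(x, "GPANetwork")) edgeMatrix(x) else as.matrix(x)
  stopifnot(ncol(e) == 2L)
  write.table(e, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write hyperbolic coordinate tables
#'
#' Tab-separated tables with a header naming the columns `node` and `theta`
#' (radians), and optionally `r` (radial coordinate) and `birth` (birth
#' time). Angles are reduced to `[0, 2*pi)` on read; rows are returned in
#' birth order when birth times are present, otherwise in file order. When a
#' coordinate table lacks birth times they can be assigned afterwards with
#' [birthTimesFromDegree()].
#'
#' @param path file path.
#' @param x a [GPANetwork-class] or a data frame with at least columns
#'   `node` and `theta`.
#' @param digits significant digits written (default 15, which round-trips
#'   doubles to well beyond 12 significant digits).
#' @return `readCoordinates`: a data frame with columns `node`, `theta` and
#'   any optional columns present; `writeCoordinates`: `path`, invisibly.
#' @export
readCoordinates <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
  if (!"theta" %in% names(tab)) stop("coordinate table must name a 'theta' column")
  if (!"node" %in% names(tab)) stop("coordinate table must name a 'node' column")
  if (any(!is.finite(tab$theta))) stop("theta values must be finite")
  if (anyDuplicated(tab$node)) stop("node ids must be unique")
  tab$theta <- reduceAngle(tab$theta)
  if ("birth" %in% names(tab)) {
    if (!identical(sort(as.integer(tab$birth)), seq_len(nrow(tab))))
      stop("birth times must form a permutation of 1..n")
    tab <- tab[order(tab$birth), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' @rdname readCoordinates
#' @export
writeCoordinates <- function(x, path, digits = 15) {
  tab <- if (is(x, "GPANetwork")) {
    data.frame(node = seq_len(nNodes(x)), theta = nodeAngles(x),
               r = nodeRadii(x), birth = seq_len(nNodes(x)))
  } else as.data.frame(x)
  stopifnot(all(c("node", "theta") %in% names(tab)))
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a community partition as TSV
#'
#' Two columns: node id (input order) and community id.
#'
#' @param partition a [CommunityPartition-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writePartition <- function(partition, path) {
  stopifnot(is(partition, "CommunityPartition"))
  write.table(data.frame(node = seq_len(partition@n),
                         community = partition@membership),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Lambda schedule
#'
#' Two-column TSV `(t, lambda)` with optional header, interpreted as a step
#' function of birth time.
#'
#' @param path file path.
#' @return a data frame with columns `t` and `lambda`, suitable as the
#'   `lambdaSchedule` argument of [gpaParams()].
#' @export
readLambdaSchedule <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (is.character(tab[[1]])) tab <- tab[-1, , drop = FALSE]  # header row
  if (ncol(tab) < 2L) stop("schedule must have two columns: t, lambda")
  data.frame(t = as.numeric(tab[[1]]), lambda = as.numeric(tab[[2]]))
}
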