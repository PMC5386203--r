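#' @include AllClasses.R simulator.R
NULL

#' Precompute the Monte-Carlo sample bank for the Lambda likelihood
#'
#' The likelihood of the observed angular coordinates involves, at every
#' birth time t, an integral over the t-1 candidate positions that were
#' rejected; it is estimated by Monte Carlo with `N` independent candidate
#' paths of uniform angles. The bank precomputes every attractiveness the
#' estimator needs exactly once — the observed `A_t(theta_t)` and the
#' per-path sums of candidate attractivenesses — so that the likelihood can
#' then be evaluated at any number of Lambda values at negligible cost.
#' Radial coordinates are reconstructed from birth order as `r_t = 2 ln t`
#' with popularity fading `beta`, exactly as in the simulator.
#'
#' @param x a [GPANetwork-class] or a numeric vector of angular coordinates
#'   ordered by birth time.
#' @param n0 number of first nodes to use (>= 2; the likelihood rarely needs
#'   the whole network).
#' @param N number of Monte-Carlo sample paths.
#' @param beta popularity-fading speed used to reconstruct radii (taken from
#'   the network's parameters when `x` is a [GPANetwork-class]).
#' @param distanceMode `"approx"` or `"exact"` attractiveness disks.
#' @param seed integer RNG seed for the candidate paths, or `NULL`.
#' @return an immutable [MCSampleBank-class].
#' @export
buildSampleBank <- function(x, n0 = min(500L, length(.angles(x))), N = 100L,
                            beta = 2 / 3,
                            distanceMode = c("approx", "exact"),
                            seed = NULL) {
  distanceMode <- match.arg(distanceMode)
  if (is(x, "GPANetwork")) {
    beta <- x@params@beta
    distanceMode <- x@params@distanceMode
  }
  ang <- .angles(x)
  n0 <- as.integer(n0)
  N <- as.integer(N)
  if (n0 < 2L) stop("n0 must be >= 2")
  if (n0 > length(ang)) stop("n0 exceeds the number of coordinates")
  if (!is.null(seed)) set.seed(seed)
  cand <- matrix(runif(N * n0, 0, 2 * pi), nrow = N, ncol = n0)
  bank <- gpa_mc_bank(ang[seq_len(n0)], beta, distanceMode == "exact", cand)
  new("MCSampleBank", n0 = n0, N = N, beta = beta,
      distanceMode = distanceMode,
      seed = if (is.null(seed)) NA else as.integer(seed),
      observedAttract = bank$obsA, sumAttract = bank$sumA)
}

#' Monte-Carlo estimate of the Lambda log-likelihood
#'
#' Estimates, up to an additive constant shared by all Lambda values,
#' `l(Lambda) = sum_t [ ln(A_t(theta_t) + Lambda) - ln( (1/N) sum_j
#' D_t^(j)(Lambda) ) ]` for t = 2..n0, where the Monte-Carlo denominator
#' treats the observed position as one of the t candidates:
#' `D_t^(j) = (A_t(theta_t) + Lambda) + sum_i (A_t(phi_i^(j)) + Lambda)`.
#' The Monte-Carlo average is taken before the logarithm
#' (`average = "mean-then-log"`, the estimator's reference form, with a
#' small second-order bias in 1/N); an average-of-logs variant is available
#' behind the `average` flag. At `Lambda = 0` the value is `-Inf` whenever
#' some observed attractiveness is zero (such a choice has probability zero
#' under the pure density-following model); this is reported, not an error.
#'
#' @param lambda numeric vector of Lambda values (>= 0).
#' @param bank an [MCSampleBank-class].
#' @param average `"mean-then-log"` (default) or `"log-then-mean"`.
#' @return estimated log-likelihood, one value per element of `lambda`.
#' @export
logLikelihoodLambda <- function(lambda, bank,
                                average = c("mean-then-log",
                                            "log-then-mean")) {
  average <- match.arg(average)
  stopifnot(is(bank, "MCSampleBank"))
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("lambda values must be finite and >= 0")
  obsA <- bank@observedAttract
  tt <- seq.int(2L, bank@n0)
  vapply(lambda, function(lam) {
    num <- log(obsA + lam)
    D <- obsA + bank@sumAttract + tt * lam  # (n0-1) x N, columns recycled
    den <- if (average == "mean-then-log") log(rowMeans(D))
           else rowMeans(log(D))
    sum(num - den)
  }, numeric(1))
}

#' Maximum-likelihood estimate of the initial attractiveness
#'
#' Builds one Monte-Carlo sample bank from the first `n0` coordinates and
#' evaluates the estimated log-likelihood on a grid of Lambda values,
#' returning the profile and its maximizer (ties resolved to the smallest
#' Lambda). With `refine = TRUE` a golden-section search
#' ([stats::optimize()]) sharpens the estimate inside the grid interval
#' bracketing the maximum; the profile is smooth and unimodal, so the coarse
#' grid brackets reliably. The flatter the profile around its maximum, the
#' less information the data carry about Lambda — large true values are
#' intrinsically harder to pin down.
#'
#' @inheritParams buildSampleBank
#' @param grid ascending nonnegative Lambda values to profile over.
#' @param refine if `TRUE`, refine the maximizer within the bracketing
#'   interval.
#' @param average estimator variant, see [logLikelihoodLambda()].
#' @return a [LambdaLikelihood-class].
#' @export
#' @examples
#' \donttest{
#' net <- growNetwork(gpaParams(300, lambda = 0, seed = 11))
#' est <- estimateLambda(net, n0 = 100, N = 50, seed = 12)
#' lambdaHat(est)
#' }
estimateLambda <- function(x, grid = seq(0, 3, by = 0.1),
                           n0 = min(500L, length(.angles(x))), N = 100L,
                           beta = 2 / 3,
                           distanceMode = c("approx", "exact"), seed = NULL,
                           refine = FALSE,
                           average = c("mean-then-log", "log-then-mean")) {
  if (!length(grid) || is.unsorted(grid, strictly = TRUE) || any(grid < 0))
    stop("grid must be nonempty, strictly ascending, and >= 0")
  bank <- buildSampleBank(x, n0 = n0, N = N, beta = beta,
                          distanceMode = distanceMode, seed = seed)
  ll <- logLikelihoodLambda(grid, bank, average = average)
  i <- which.max(ll)  # first maximum = smallest Lambda on ties
  lhat <- grid[i]
  if (refine && length(grid) > 2L) {
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- optimize(function(l) logLikelihoodLambda(l, bank,
                                                    average = average),
                    interval = c(lo, hi), maximum = TRUE)
    if (opt$objective > ll[i]) lhat <- opt$maximum
  }
  new("LambdaLikelihood", grid = as.numeric(grid), loglik = ll,
      lambdaHat = lhat,
      settings = list(N = bank@N, n0 = bank@n0, seed = bank@seed,
                      beta = bank@beta, distanceMode = bank@distanceMode))
}

#' Temporal profile of the Lambda estimate over growing prefixes
#'
#' Re-runs the maximum-likelihood estimation independently on the subgraphs
#' made of the first `t` nodes for each checkpoint `t`, pretending Lambda is
#' constant within each prefix. A profile that decreases with `t` indicates
#' a decaying initial attractiveness; a flat profile (up to statistical
#' fluctuation) supports a constant one.
#'
#' @inheritParams estimateLambda
#' @param checkpoints ascending prefix sizes, each >= 2 and at most the
#'   number of available coordinates.
#' @return a data frame with columns `t`, `lambdaHat`, plus the per-prefix
#'   [LambdaLikelihood-class] objects as attribute `"profiles"`.
#' @export
temporalLambda <- function(x, checkpoints, grid = seq(0, 3, by = 0.1),
                           N = 100L, beta = 2 / 3,
                           distanceMode = c("approx", "exact"),
                           seed = NULL) {
  ang <- .angles(x)
  checkpoints <- as.integer(checkpoints)
  if (is.unsorted(checkpoints, strictly = TRUE) || any(checkpoints < 2L))
    stop("checkpoints must be strictly ascending and >= 2")
  if (max(checkpoints) > length(ang))
    stop("checkpoint exceeds the number of available nodes")
  ests <- lapply(seq_along(checkpoints), function(k) {
    estimateLambda(x, grid = grid, n0 = checkpoints[k], N = N, beta = beta,
                   distanceMode = distanceMode,
                   seed = if (is.null(seed)) NULL else seed + k)
  })
  out <- data.frame(t = checkpoints,
                    lambdaHat = vapply(ests, lambdaHat, numeric(1)))
  attr(out, "profiles") <- ests
  out
}

#' Assign birth times from degree ranks
#'
#' When real data carry no timestamps, node birth times are assigned as the
#' ranks in decreasing degree order (rank 1 = highest degree), with ties
#' broken by ascending node id — older nodes are assumed to have had more
#' time to accumulate links. The result is a permutation of 1..n.
#'
#' @param x a [GPANetwork-class], an `igraph` graph, or an integer degree
#'   vector.
#' @return integer vector of birth times, one per node.
#' @export
#' @examples
#' birthTimesFromDegree(c(5, 5, 3))  # 1 2 3
birthTimesFromDegree <- function(x) {
  deg <- .degrees(x)
  if (!length(deg)) stop("empty network")
  births <- integer(length(deg))
  births[order(-deg, seq_along(deg))] <- seq_along(deg)
  births
}
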