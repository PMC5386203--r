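#' @include AllClasses.R geometry.R
NULL

#' Construct generation controls for a GPA network
#'
#' The model has three parameters: the number of links `m` established by
#' every new node (controls the mean degree, which tends to `2m`), the
#' popularity-fading speed `beta` (controls the degree exponent
#' `gamma = 1 + 1/beta`), and the initial attractiveness `lambda` (controls
#' the heterogeneity of the angular node density and hence community
#' separation; `lambda = Inf` is approximated by a very large value and
#' reduces the model to uniformly random angles).
#'
#' @param n target node count.
#' @param m links per new node.
#' @param beta popularity-fading speed in (0, 1].
#' @param lambda constant initial attractiveness (>= 0), ignored when
#'   `lambdaSchedule` is given.
#' @param lambdaSchedule optional time-varying schedule: either a numeric
#'   vector of length `n` (`Lambda(t)` per birth time) or a two-column data
#'   frame `(t, lambda)` interpreted as a step function (value at birth time
#'   `t` is the schedule entry with the largest `t` not exceeding it).
#' @param distanceMode `"approx"` (default; the large-radius distance
#'   formula, under which linking reproduces the popularity-similarity
#'   ranking exactly) or `"exact"`.
#' @param seed integer RNG seed or `NULL`.
#' @return a validated [GPAParams-class] object.
#' @export
#' @examples
#' gpaParams(1000, m = 3, beta = 2 / 3, lambda = 1, seed = 42)
gpaParams <- function(n, m = 3, beta = 2 / 3, lambda = 1,
                      lambdaSchedule = NULL,
                      distanceMode = c("approx", "exact"), seed = NULL) {
  distanceMode <- match.arg(distanceMode)
  n <- as.integer(n)
  if (is.null(lambdaSchedule)) {
    if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
      stop("lambda must be a single finite value >= 0")
    lam <- rep(as.numeric(lambda), n)
  } else if (is.data.frame(lambdaSchedule)) {
    ts <- as.numeric(lambdaSchedule[[1]])
    vs <- as.numeric(lambdaSchedule[[2]])
    if (is.unsorted(ts, strictly = TRUE) || ts[1] > 1)
      stop("schedule times must be strictly increasing and start at t <= 1")
    f <- stats::stepfun(ts[-1], vs)
    lam <- f(seq_len(n))
  } else {
    lam <- as.numeric(lambdaSchedule)
    if (length(lam) != n) stop("lambda schedule vector must have length n")
  }
  new("GPAParams", n = n, m = as.integer(m), beta = as.numeric(beta),
      lambda = lam, distanceMode = distanceMode,
      seed = if (is.null(seed)) NA else as.integer(seed))
}

#' Grow a geometric preferential attachment network
#'
#' Nodes appear one at a time, t = 1, 2, .... For each new node: (a) `t`
#' candidate angles are drawn uniformly on `[0, 2*pi)`; (b) the
#' attractiveness `A_t(phi_i)` of each candidate is the number of existing
#' nodes within hyperbolic distance `r_t = 2 ln t` of the point
#' `(r_t, phi_i)`; (c) candidate `i` is selected with probability
#' `(A_t(phi_i) + Lambda) / sum_j (A_t(phi_j) + Lambda)` (uniformly if all
#' weights vanish). Radial coordinates of existing nodes are updated by
#' popularity fading, and the new node links to its `m` hyperbolically
#' closest predecessors (to all of them when `t <= m`). Identical seeds give
#' bit-identical networks.
#'
#' @param params a [GPAParams-class], or missing to build one from `...`.
#' @param ... passed to [gpaParams()] when `params` is missing.
#' @return a [GPANetwork-class] with
#'   `m * (m - 1) / 2 + m * (n - m)` edges (for `n >= m`).
#' @export
#' @examples
#' net <- growNetwork(gpaParams(200, m = 3, beta = 2 / 3, lambda = 1,
#'                              seed = 1))
#' nNodes(net)
#' nrow(edgeMatrix(net))  # 3 + 3 * 197
growNetwork <- function(params, ...) {
  if (missing(params)) params <- gpaParams(...)
  stopifnot(is(params, "GPAParams"))
  validObject(params)
  if (!is.na(params@seed)) set.seed(params@seed)
  res <- gpa_grow(params@n, params@m, params@beta, params@lambda,
                  params@distanceMode == "exact")
  new("GPANetwork", angles = res$angles, edges = res$edges,
      chosenAttract = res$chosenA, params = params)
}

#' Attractiveness of a candidate location
#'
#' The attractiveness `A_t(phi)` of location `phi` for a node born at time
#' `t` is the number of existing nodes `s < t` lying within hyperbolic
#' distance `r_t` of the point `(r_t, phi)`, with the radii of existing
#' nodes updated to time `t`. Disk membership is inclusive (`<= r_t`). This
#' is a direct (brute-force) reference implementation; the growth loop
#' computes the same counts by range counting.
#'
#' @param phi numeric vector of candidate angles.
#' @param thetas angles of the existing nodes, in birth order
#'   (`theta_1 .. theta_{t-1}`).
#' @param t birth time of the new node; defaults to `length(thetas) + 1`.
#' @param beta popularity-fading speed.
#' @param distanceMode `"approx"` or `"exact"`.
#' @return integer vector of counts, one per candidate, each in `[0, t-1]`.
#' @export
#' @examples
#' attractiveness(0, thetas = c(0, pi), beta = 2 / 3,
#'                distanceMode = "exact")  # 1
attractiveness <- function(phi, thetas, t = length(thetas) + 1L,
                           beta = 2 / 3, distanceMode = c("approx", "exact")) {
  distanceMode <- match.arg(distanceMode)
  t <- as.integer(t)
  if (t < 1L || length(thetas) != t - 1L)
    stop("state must contain exactly the nodes 1..t-1")
  if (t == 1L) return(rep(0L, length(phi)))
  rt <- birthRadius(t)
  rs <- updatedRadius(seq_len(t - 1L), t, beta)
  phi <- reduceAngle(phi)
  vapply(phi, function(p) {
    dth <- angularDistance(p, thetas)
    if (distanceMode == "approx") {
      # dtheta = 0 gives distance -Inf, inside any disk
      d <- ifelse(dth == 0, -Inf, rs + rt + 2 * log(dth / 2))
    } else {
      d <- hyperbolicDistance(rep(rt, t - 1L), p, rs, thetas, mode = "exact")
    }
    sum(d <= rt)
  }, integer(1))
}

#' Sample the angular coordinate of a new node
#'
#' One step of the angular placement rule: draw `t` uniform candidates,
#' weight each by its attractiveness plus `lambda`, and select one
#' proportionally (uniformly when all weights are zero, the `Lambda = 0`
#' degenerate case). Consumes exactly `t + 1` uniform variates, matching the
#' growth loop's RNG discipline.
#'
#' @inheritParams attractiveness
#' @param lambda initial attractiveness (>= 0).
#' @param details if `TRUE`, also return the candidates and their
#'   attractivenesses.
#' @return the selected angle, or (with `details`) a list with elements
#'   `angle`, `candidates`, `attract`, `pick`.
#' @export
sampleAngle <- function(thetas, lambda, t = length(thetas) + 1L,
                        beta = 2 / 3, distanceMode = c("approx", "exact"),
                        details = FALSE) {
  distanceMode <- match.arg(distanceMode)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single finite value >= 0")
  t <- as.integer(t)
  cand <- runif(t, 0, 2 * pi)
  u <- runif(1)
  A <- attractiveness(cand, thetas, t = t, beta = beta,
                      distanceMode = distanceMode)
  w <- A + lambda
  W <- sum(w)
  pick <- if (W <= 0) min(floor(u * t) + 1L, t) else
    findInterval(u * W, cumsum(w), left.open = TRUE) + 1L
  if (details)
    list(angle = cand[pick], candidates = cand, attract = A, pick = pick)
  else cand[pick]
}

#' Probability that a new node is a follower
#'
#' The angular placement rule decomposes into a mixture: with probability
#' `p_f = sum(A) / (sum(A) + t * Lambda)` the node follows the node-density
#' field (pure preferential attachment to geometry, `Lambda = 0`), otherwise
#' it picks uniformly among its `t` candidate positions. Since the mean
#' attractiveness of a uniform location is approximately 1, `p_f` is
#' approximately `1 / (1 + Lambda)`.
#'
#' @param lambda initial attractiveness (>= 0).
#' @param attract integer vector of candidate attractivenesses
#'   `A_t(phi_1) .. A_t(phi_t)`.
#' @return the follower probability, in `[0, 1]`.
#' @export
#' @examples
#' followerProbability(1, rep(1, 10))  # 10 / (10 + 10) = 0.5
followerProbability <- function(lambda, attract) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single finite value >= 0")
  sA <- sum(attract)
  denom <- sA + length(attract) * lambda
  if (denom == 0)
    stop("follower probability undefined: zero attractiveness and lambda")
  sA / denom
}
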