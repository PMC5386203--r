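#' @include gpanet-package.R
NULL

#' Reduce angles to the canonical interval [0, 2*pi)
#'
#' All angular arithmetic in the package uses this single convention.
#'
#' @param theta numeric vector of angles in radians (any finite reals).
#' @return angles reduced modulo `2*pi` into `[0, 2*pi)`.
#' @export
#' @examples
#' reduceAngle(7)        # 7 - 2*pi
#' reduceAngle(-0.1)     # 2*pi - 0.1
reduceAngle <- function(theta) {
  if (any(!is.finite(theta))) stop("angles must be finite")
  r <- theta %% (2 * pi)
  # guard against r == 2*pi from floating-point rounding of tiny negatives
  r[r >= 2 * pi] <- 0
  r
}

#' Angular distance on the similarity circle
#'
#' The angular separation `pi - |pi - |theta_a - theta_b||`, i.e. the length
#' of the shorter arc between the two angles. Inputs are reduced modulo
#' `2*pi` first; the result is symmetric and lies in `[0, pi]`.
#'
#' @param thetaA,thetaB numeric vectors of angles in radians (recycled).
#' @return angular distances in `[0, pi]`.
#' @export
#' @examples
#' angularDistance(0, pi)              # pi
#' angularDistance(0.1, 2 * pi - 0.1)  # 0.2
angularDistance <- function(thetaA, thetaB) {
  d <- abs(reduceAngle(thetaA) - reduceAngle(thetaB))
  pi - abs(pi - d)
}

#' Radial coordinate of a node at birth
#'
#' A node born at time `t` appears at hyperbolic radius `r_t = 2 ln t`, so
#' the disk of occupied radii expands logarithmically as the network grows.
#'
#' @param t positive integer birth times.
#' @return radial coordinates `2 ln t` (0 for `t = 1`).
#' @export
#' @examples
#' birthRadius(1)    # 0
#' birthRadius(100)  # 9.21034
birthRadius <- function(t) {
  if (any(!is.finite(t)) || any(t < 1)) stop("birth times must be >= 1")
  2 * log(t)
}

#' Radial coordinate after popularity fading
#'
#' As the network grows, old nodes drift outward: at time `t >= s` the node
#' born at `s` sits at `r_s(t) = beta * r_s + (1 - beta) * r_t`. With
#' `beta = 1` there is no fading; the result always lies in `[r_s, r_t]`.
#'
#' @param s birth times.
#' @param t current times, `t >= s` (recycled against `s`).
#' @param beta popularity-fading speed in (0, 1].
#' @return updated radial coordinates.
#' @export
#' @examples
#' updatedRadius(10, 100, 2 / 3)  # 6.140227
updatedRadius <- function(s, t, beta) {
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]")
  if (any(!is.finite(s)) || any(!is.finite(t)) || any(s < 1))
    stop("times must be finite and >= 1")
  if (any(s > t)) stop("birth time s must not exceed current time t")
  beta * birthRadius(s) + (1 - beta) * birthRadius(t)
}

#' Hyperbolic distance between points in polar coordinates
#'
#' Distance between points `(r1, theta1)` and `(r2, theta2)` in the
#' hyperbolic plane of curvature -1. Mode `"exact"` evaluates the hyperbolic
#' law of cosines `cosh x = cosh r1 cosh r2 - sinh r1 sinh r2 cos(dtheta)`
#' via the cancellation-free form
#' `cosh x = cosh(r1 - r2) + 2 sinh r1 sinh r2 sin^2(dtheta/2)`, switching
#' to a logarithmic asymptotic when the radii are large enough to overflow
#' `cosh`, and returning `|r1 - r2|` exactly when the angular separation is
#' below 1e-9. Mode `"approx"` is the large-radius expansion
#' `x ~ r1 + r2 + 2 ln(dtheta / 2)`, which diverges at `dtheta = 0` and, for
#' nodes with radii built from birth times, ranks candidates identically to
#' the popularity-similarity score `s^beta * dtheta`.
#'
#' @param r1,r2 nonnegative radial coordinates (recycled).
#' @param theta1,theta2 angles in radians (recycled).
#' @param mode `"exact"` (default) or `"approx"`.
#' @return nonnegative distances (`"approx"` may be negative at small radii,
#'   where the expansion is a poor approximation).
#' @export
#' @examples
#' hyperbolicDistance(3, 0, 5, 0)            # 2 (radial geodesic)
#' hyperbolicDistance(5, 0, 5, pi)           # 10
#' hyperbolicDistance(5, 0, 5, 2, mode = "approx")  # 10
hyperbolicDistance <- function(r1, theta1, r2, theta2,
                               mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  if (any(!is.finite(r1)) || any(!is.finite(r2)) || any(r1 < 0) || any(r2 < 0))
    stop("radial coordinates must be finite and >= 0")
  dth <- angularDistance(theta1, theta2)
  k <- max(length(r1), length(r2), length(dth))
  r1 <- rep_len(r1, k); r2 <- rep_len(r2, k); dth <- rep_len(dth, k)
  if (mode == "approx") {
    if (any(dth == 0))
      stop("approximate distance diverges at zero angular separation; ",
           "use the exact mode or handle coincident angles")
    return(r1 + r2 + 2 * log(dth / 2))
  }
  x <- numeric(k)
  tiny <- dth < 1e-9
  x[tiny] <- abs(r1[tiny] - r2[tiny])
  big <- !tiny & (r1 + r2 > 350)  # cosh would overflow; asymptotic form
  if (any(big)) {
    xa <- r1[big] + r2[big] + 2 * log(sin(dth[big] / 2))
    x[big] <- pmax(xa, abs(r1[big] - r2[big]))
  }
  rest <- !tiny & !big
  if (any(rest)) {
    s2 <- sin(dth[rest] / 2)
    arg <- cosh(r1[rest] - r2[rest]) +
      2 * sinh(r1[rest]) * sinh(r2[rest]) * s2 * s2
    x[rest] <- acosh(pmax(arg, 1))
  }
  x
}
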