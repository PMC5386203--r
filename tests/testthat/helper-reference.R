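# Brute-force pure-R reference implementation of the growth model, consuming
# the RNG stream in the same order as the compiled core (per node t: t
# candidate angles, then one selection variate). Used for bit-exact
# cross-validation of the fast range-counting path.
refGrow <- function(n, m, beta, lambda, distanceMode = "approx",
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- rep_len(lambda, n)
  angles <- numeric(n)
  edges <- NULL
  for (t in seq_len(n)) {
    cand <- runif(t) * (2 * pi)
    u <- runif(1)
    A <- attractiveness(cand, angles[seq_len(t - 1)], t = t, beta = beta,
                        distanceMode = distanceMode)
    w <- A + lambda[t]
    W <- sum(w)
    pick <- if (W <= 0) min(floor(u * t) + 1, t) else
      which(u * W <= cumsum(w))[1]
    angles[t] <- cand[pick]
    K <- min(m, t - 1)
    if (K > 0) {
      s <- seq_len(t - 1)
      rt <- birthRadius(t)
      rs <- updatedRadius(s, t, beta)
      dth <- angularDistance(angles[s], angles[t])
      key <- if (distanceMode == "approx") {
        ifelse(dth == 0, -Inf, rs + 2 * log(dth / 2))
      } else {
        hyperbolicDistance(rs, angles[s], rep(rt, t - 1), angles[t])
      }
      sel <- s[order(key, s)][seq_len(K)]
      edges <- rbind(edges, cbind(sel, t))
    }
  }
  list(angles = angles, edges = edges)
}

# canonical form of an undirected edge matrix, for set comparison
canonEdges <- function(e) {
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- NULL
  storage.mode(e) <- "integer"
  e
}

# independent sampler of the discrete power law p(k) ~ k^(-gamma), k >= kmin,
# by direct normalization of the pmf over a truncated support
rPowerLawOracle <- function(n, gamma, kmin, kmax = 2e5) {
  ks <- seq.int(kmin, kmax)
  sample(ks, n, replace = TRUE, prob = ks^(-gamma))
}

toyAngles <- c(0.0, 0.1, 0.2, 3.0, 3.1, 3.2)
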