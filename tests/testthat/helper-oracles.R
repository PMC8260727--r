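# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# Harrell's C by explicit enumeration of all comparable pairs:
# a pair is comparable when the shorter observed time ends in an event;
# concordant when the earlier event carries the higher risk score, tied
# scores count one half.
oracle_cindex <- function(risk, time, event) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- i; b <- j
      if (time[b] < time[a] || (time[b] == time[a] && event[b] == 1 && event[a] == 0)) {
        a <- j; b <- i
      }
      if (event[a] != 1) next                       # earlier subject censored
      if (time[a] == time[b] && event[b] == 1) next # tied event times
      den <- den + 1
      if (risk[a] > risk[b]) num <- num + 1
      else if (risk[a] == risk[b]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Negative log partial likelihood for a single covariate (no tied event
# times), maximized by golden-section search: the brute-force Cox oracle.
oracle_cox_beta <- function(time, event, x) {
  neg_logpl <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk_set <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk_set])))
    }
    -ll
  }
  stats::optimize(neg_logpl, c(-10, 10), tol = 1e-10)$minimum
}

# Hand product-limit estimator at observed event times.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (k in seq_along(et)) {
    n_risk <- sum(time >= et[k])
    d <- sum(time == et[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = et, survival = surv)
}

# Vertex-level measurement oracle for a polygon over a straight baseline
# along the x axis (baseline spanning beyond the polygon): radial distance
# is the largest vertex height above the axis, footprint width the x-range
# of the vertex projections.
oracle_measure_straight <- function(poly) {
  list(r = max(poly[, 2]), w = diff(range(poly[, 1])))
}

# Random upper-chain polygon on a straight baseline with known truth.
random_protrusion <- function(x0 = 0, height, width, k = sample(1:9, 1)) {
  xt <- x0 + sort(runif(k, 0.02, 0.98)) * width
  yt <- runif(k, 0.2, 0.95) * height
  yt[sample(k, 1)] <- height
  rbind(c(x0, 0), cbind(xt, yt), c(x0 + width, 0))
}

# 2D rigid transform helper for invariance tests.
rigid_transform <- function(pts, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(pts %*% t(R), 2, -shift)
}
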