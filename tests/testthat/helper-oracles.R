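# Independent oracles used across the suite.

# Circumcenter via the barycentric closed form (weights a^2 (b^2 + c^2 - a^2)
# etc.), algebraically independent of the package's linear-system solve.
circumcircle_oracle <- function(p1, p2, p3) {
  a2 <- sum((p2 - p3)^2)
  b2 <- sum((p1 - p3)^2)
  c2 <- sum((p1 - p2)^2)
  w <- c(a2 * (b2 + c2 - a2), b2 * (c2 + a2 - b2), c2 * (a2 + b2 - c2))
  center <- (w[1] * p1 + w[2] * p2 + w[3] * p3) / sum(w)
  list(center = center, radius = sqrt(sum((p1 - center)^2)))
}

# Dense-grid OLS slope of the analytic logistic over the 20-80% window,
# computed from first principles (no lm, no package code).
logistic_ols_slope_oracle <- function(k, t0 = 0, dt = 1e-3) {
  thalf <- log(4) / k            # time from midpoint to 80% closure
  tt <- seq(t0 - thalf, t0 + thalf, by = dt)
  cc <- 100 / (1 + exp(-k * (tt - t0)))
  tc <- tt - mean(tt)
  sum(tc * (cc - mean(cc))) / sum(tc^2)
}

# Build a noiseless ring_trace directly from a closure law.
make_closure_trace <- function(times, closure, asymmetry = NA_real_,
                               id = "t") {
  ring_trace(time_min = times, closure_pct = closure,
             asymmetry_pct = asymmetry, trace_id = id)
}

logistic_trace <- function(k, t0, dt, span = c(1, 99), id = "logi") {
  t_of_c <- function(c) t0 + log(c / (100 - c)) / k
  tt <- seq(t_of_c(span[1]), t_of_c(span[2]), by = dt)
  make_closure_trace(tt, logistic_closure(tt, k, t0), id = id)
}
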