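# Independent oracles used across the suite.  These deliberately solve the
# same problems as the package by different routes (fixed-point iteration,
# Newton's method, discrete-time simulation, brute-force grids) so that
# agreement is informative.

# Damped fixed-point iteration of the implicit random-predator equation.
# The forward map Ne -> n0 (1 - exp(a (Ne h - T))) has derivative
# n0 a h exp(.) > 1 at the root whenever consumption is handling-limited,
# where the root is repelling and no amount of under-relaxation helps.
# The logarithmic rearrangement
#     Ne = (T + log(1 - Ne / n0) / a) / h
# has a strictly negative derivative -1 / (a h (n0 - Ne)), so the damped
# iteration with lambda = 1 / (1 + |g'|) is a contraction everywhere.
# (For h = 0 the equation is explicit and no iteration is needed.)
fixed_point_rogers <- function(n0, a, h, T = 1, tol = 1e-12, max_iter = 100000L) {
  if (a == 0 || n0 == 0) return(0)
  if (h == 0) return(n0 * (1 - exp(-a * T)))
  upper <- min(n0 * (1 - 1e-12), T / h)
  ne <- upper / 2
  for (i in seq_len(max_iter)) {
    target <- (T + log1p(-ne / n0) / a) / h
    target <- min(max(target, 0), upper)
    if (abs(target - ne) <= tol) return(ne)
    d <- 1 / (a * h * (n0 - ne))
    lambda <- 1 / (1 + d)
    ne <- ne + lambda * (target - ne)
  }
  ne
}

# Newton iteration on f(w) = w * exp(w) - x (first order, not Halley)
newton_w0 <- function(x, tol = 1e-14) {
  w <- if (x > 1) log(x) else x / (1 + x)
  for (i in 1:200) {
    f <- w * exp(w) - x
    if (abs(f) <= tol * max(1, abs(x))) break
    w <- w - f / (exp(w) * (w + 1))
  }
  w
}

# Discrete-time (tau-leap) oracle for the event-based trial simulation,
# vectorised over replicates: per step of width dt, each free predator
# captures with the exact exponential hazard 1 - exp(-a * remaining * dt),
# after which searching is blocked for the handling time h.
tau_leap_trials <- function(nrep, n0, a, h, T = 1, dt = 5e-4) {
  remaining <- rep(n0, nrep)
  busy_until <- numeric(nrep)
  steps <- ceiling(T / dt)
  for (s in seq_len(steps)) {
    t <- (s - 1) * dt
    active <- t >= busy_until & remaining > 0
    pr <- 1 - exp(-a * remaining * dt)
    cap <- active & (stats::runif(nrep) < pr)
    if (any(cap)) {
      remaining[cap] <- remaining[cap] - 1L
      busy_until[cap] <- t + dt / 2 + h
    }
  }
  n0 - remaining
}

# Brute-force refining grid search for a 2-parameter binomial-logit NLL.
# Each level re-centres the grid at the incumbent minimum and halves the
# half-width, so the search can slide along a correlated (b0, b1) valley
# instead of zooming prematurely.
grid_logit_2par <- function(eaten, n0, xcov, b0_range, b1_range,
                            levels = 24L, width = 25L) {
  nll <- function(b0, b1) {
    p <- stats::plogis(b0 + b1 * xcov)
    -sum(stats::dbinom(eaten, n0, p, log = TRUE))
  }
  c0 <- mean(b0_range); hw0 <- diff(b0_range) / 2
  c1 <- mean(b1_range); hw1 <- diff(b1_range) / 2
  for (l in seq_len(levels)) {
    g0 <- seq(c0 - hw0, c0 + hw0, length.out = width)
    g1 <- seq(c1 - hw1, c1 + hw1, length.out = width)
    vals <- outer(g0, g1, Vectorize(nll))
    k <- arrayInd(which.min(vals), dim(vals))
    c0 <- g0[k[1]]
    c1 <- g1[k[2]]
    hw0 <- hw0 / 2
    hw1 <- hw1 / 2
  }
  c(b0 = c0, b1 = c1)
}

# single-group design shorthand used by the simulation-heavy tests
one_sex_design <- function(replicates = 6L) {
  trial_design(replicates = replicates, sexes = "M")
}

one_sex_params <- function(a, h) {
  list(M = group_params(a = a, h = h))
}
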