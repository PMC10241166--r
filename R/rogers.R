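#' Expected consumption under the Rogers Type II random-predator model
#'
#' The random predator equation without prey replacement gives the number
#' of prey eaten \eqn{N_e} from an initial density \eqn{N_0} implicitly:
#' \deqn{N_e = N_0 (1 - e^{a (N_e h - T)})}
#' where \eqn{a} is the attack rate, \eqn{h} the handling time and
#' \eqn{T} the trial duration.  The unique root in \eqn{[0, N_0]} has the
#' closed form
#' \deqn{N_e = N_0 - W_0(a h N_0 e^{-a (T - h N_0)}) / (a h)}
#' with \eqn{W_0} the principal Lambert W branch.  When \eqn{h = 0} the
#' model collapses to \eqn{N_0 (1 - e^{-aT})} (depletion-only Type I) and
#' when \eqn{a = 0} no prey are eaten.
#'
#' The solution always satisfies \eqn{0 \le N_e \le \min(N_0, T/h)}:
#' handling time caps what one predator can process in the available time.
#'
#' @param n0 initial prey density (non-negative; vectorised).
#' @param a attack rate, per unit prey per unit time (\eqn{\ge 0}).
#' @param h handling time per prey (\eqn{\ge 0}).
#' @param T trial duration (> 0; the experimental convention is to fit
#'   with \code{T = 1} so that \code{a} and \code{h} are expressed per
#'   trial).
#' @return numeric vector of expected numbers of prey consumed.
#' @examples
#' rogers_predict(16, a = 1, h = 0, T = 1)      # 16 * (1 - exp(-1))
#' rogers_predict(c(1, 2, 4, 6, 10, 16), a = 2.5, h = 0.08)
#' @export
rogers_predict <- function(n0, a, h, T = 1) {
  if (!is.numeric(n0) || any(n0 < 0)) stop("`n0` must be non-negative")
  if (length(a) != 1L || !is.finite(a) || a < 0) stop("`a` must be a single finite value >= 0")
  if (length(h) != 1L || !is.finite(h) || h < 0) stop("`h` must be a single finite value >= 0")
  if (length(T) != 1L || !is.finite(T) || T <= 0) stop("`T` must be a single finite value > 0")

  if (a == 0) return(numeric(length(n0)) * n0)
  if (h == 0) return(n0 * (1 - exp(-a * T)))

  # log of the Lambert argument; switch to the log-domain solver when the
  # argument itself would overflow
  L <- log(a * h * n0) - a * (T - h * n0)
  w <- numeric(length(n0))
  zero <- n0 == 0
  big <- !zero & L > 700
  if (any(big)) w[big] <- .lambert_w0_explog(L[big])
  ord <- !zero & !big
  if (any(ord)) w[ord] <- lambert_w0(exp(L[ord]))
  ne <- n0 - w / (a * h)
  pmin(pmax(ne, 0), n0)
}

#' Negative log-likelihood of the Rogers Type II model
#'
#' Each trial contributes a binomial likelihood for the number of prey
#' eaten out of those offered, with success probability
#' \code{rogers_predict(n0, a, h, T) / n0}.  Parameters enter on the log
#' scale so the surface is smooth and unconstrained.
#'
#' Probabilities are clamped to \code{[eps, 1 - eps]} (default
#' \code{eps = 1e-9}) to keep the log finite at the parameter-space
#' boundary.
#'
#' @param log_a,log_h log attack rate and log handling time.
#' @param trials data frame of foraging trials with columns \code{n0},
#'   \code{eaten} and (optionally) \code{duration_T} (defaults to 1).
#' @param eps probability clamp.
#' @return the negative log-likelihood (a single number).
#' @export
nll_type2 <- function(log_a, log_h, trials, eps = 1e-9) {
  if (!is.finite(log_a) || !is.finite(log_h)) stop("parameters must be finite")
  trials <- .as_trials(trials)
  obj <- .nll_builder(trials$n0, trials$eaten, trials$duration_T, eps = eps)
  obj(c(log_a, log_h))
}

# Lean Lambert W0 for strictly positive arguments on the likelihood hot
# path: no input checks, no clamping, identical Halley update.
.w0_pos <- function(z) {
  w <- log1p(z)
  big <- z > 4
  if (any(big)) {
    lz <- log(z[big])
    w[big] <- lz - log(lz)
  }
  for (i in seq_len(30L)) {
    ew <- exp(w)
    f <- w * ew - z
    if (all(abs(f) <= 1e-12 * (1 + z))) break
    w <- w - f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
  }
  w
}

# Fast closure used by the optimisers: consumption counts are aggregated
# over the unique (n0, T) cells so each evaluation costs one Lambert solve
# per distinct density rather than per trial, and the Rogers solution is
# inlined without the user-facing argument checks (its agreement with
# rogers_predict() is under test).
.nll_builder <- function(n0, eaten, Tdur, eps = 1e-9, fix_h = FALSE) {
  key <- paste(n0, Tdur)
  uk <- !duplicated(key)
  un0 <- n0[uk]
  uT <- Tdur[uk]
  idx <- match(key, key[uk])
  sum_eaten <- as.numeric(tapply(eaten, idx, sum))
  sum_uneaten <- as.numeric(tapply(n0 - eaten, idx, sum))
  const <- sum(lchoose(n0, eaten))

  function(par) {
    a <- exp(par[1L])
    h <- if (fix_h) 0 else exp(par[2L])
    if (!is.finite(a) || !is.finite(h)) return(1e10)
    if (a == 0 || h == 0) {
      ne <- un0 * (1 - exp(-a * uT))
    } else {
      L <- log(a * h * un0) - a * (uT - h * un0)
      w <- if (max(L) > 700) {
        # near-overflow region: defer to the guarded public solver
        return({
          p <- vapply(seq_along(un0), function(i)
            rogers_predict(un0[i], a, h, uT[i]) / un0[i], 0)
          p[p < eps] <- eps
          p[p > 1 - eps] <- 1 - eps
          v <- -(const + sum(sum_eaten * log(p)) + sum(sum_uneaten * log1p(-p)))
          if (is.finite(v)) v else 1e10
        })
      } else .w0_pos(exp(L))
      ne <- un0 - w / (a * h)
      ne[ne < 0] <- 0
      over <- ne > un0
      ne[over] <- un0[over]
    }
    p <- ne / un0
    p[p < eps] <- eps
    p[p > 1 - eps] <- 1 - eps
    nll <- -(const + sum(sum_eaten * log(p)) + sum(sum_uneaten * log1p(-p)))
    if (!is.finite(nll)) 1e10 else nll
  }
}

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = 2\,\mathrm{NLL} + 2k + \frac{2k(k+1)}{n - k - 1}}
#'
#' @param nll negative log-likelihood at the optimum.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed \code{k + 1}.
#' @return the AICc value.
#' @examples
#' aicc(10, 2, 12)  # 25.333...
#' @export
aicc <- function(nll, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  2 * nll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# coerce and sanity-check a trials table (internal; full user-facing
# validation with row-level messages lives in validate_trials())
.as_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("`trials` must be a data frame")
  if (nrow(trials) == 0L) stop("`trials` is empty")
  need <- c("n0", "eaten")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("`trials` lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(trials$duration_T)) trials$duration_T <- 1
  if (any(trials$eaten < 0 | trials$eaten > trials$n0)) {
    stop("`eaten` must lie in [0, n0] for every trial")
  }
  trials
}
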