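#' Principal branch of the Lambert W function
#'
#' Solves \eqn{w e^w = x} for the principal (upper) branch \eqn{W_0},
#' defined for \eqn{x \ge -1/e}.  This is the function that turns the
#' implicit Rogers random-predator equation into a closed form, so it sits
#' on the hot path of every functional-response fit.
#'
#' The implementation uses a branch-point series / logarithmic initial
#' guess followed by Halley iteration, which converges to full double
#' precision in at most a handful of steps.  The residual
#' \eqn{|w e^w - x|} is driven below \code{1e-12} (relative for large
#' arguments).
#'
#' @param x numeric vector, each element \eqn{\ge -1/e} (values within
#'   rounding error below the branch point are clamped to it).
#' @return numeric vector \code{w} with \code{w * exp(w) == x}.
#' @examples
#' lambert_w0(0)            # 0
#' lambert_w0(exp(1))       # 1
#' lambert_w0(1)            # 0.567143...
#' @export
lambert_w0 <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (anyNA(x)) stop("`x` contains missing values")
  branch <- -exp(-1)
  if (any(x < branch - 1e-12)) {
    stop("lambert_w0 is defined only for x >= -1/e = ", format(branch))
  }
  x <- pmax(x, branch)

  w <- numeric(length(x))
  # initial guesses by region
  lo <- x < 0.5                       # branch-point series region
  if (any(lo)) {
    p <- sqrt(2 * (exp(1) * x[lo] + 1))
    w[lo] <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  }
  mid <- !lo & x <= exp(1) + 1
  if (any(mid)) w[mid] <- log1p(x[mid]) * 0.8
  hi <- x > exp(1) + 1
  if (any(hi)) {
    lx <- log(x[hi])
    w[hi] <- lx - log(lx)
  }

  # Halley iteration on f(w) = w e^w - x
  for (i in seq_len(40L)) {
    ew <- exp(w)
    f <- w * ew - x
    done <- abs(f) <= 1e-13 * pmax(1, abs(x))
    if (all(done)) break
    denom <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    step <- f / denom
    step[done] <- 0
    w <- w - step
  }
  w
}

# W0 of exp(L) for large L, used to keep rogers_predict finite when the
# exponential argument of the implicit equation overflows a double.
# Asymptotic expansion w = L - log L + log L / L, refined by Halley on
# g(w) = w + log(w) - L (exact rearrangement for w > 0).
.lambert_w0_explog <- function(L) {
  w <- L - log(L) + log(L) / L
  for (i in seq_len(20L)) {
    g <- w + log(w) - L
    if (all(abs(g) <= 1e-13 * pmax(1, abs(L)))) break
    w <- w - g * w / (w + 1)
  }
  w
}
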