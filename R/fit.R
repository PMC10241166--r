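#' Maximum-likelihood fit of the Rogers Type II functional response
#'
#' Minimises [nll_type2()] over \code{(log a, log h)}; optimising on the
#' log scale enforces positivity without constraints.  Starting values
#' come from a depletion-only (Type I) pre-fit for the attack rate and
#' \code{h0 = T / max(eaten)} for the handling time, unless supplied.
#' The variance-covariance matrix is the inverse numerical Hessian on the
#' log-parameter scale.
#'
#' Datasets in which no prey were ever eaten, or in which every trial
#' ended with all prey eaten, carry no information about \code{(a, h)}
#' jointly; these raise an error rather than returning a boundary
#' estimate.
#'
#' @param trials data frame of foraging trials (columns \code{n0},
#'   \code{eaten}, optional \code{duration_T}); typically one sex/group.
#' @param init optional numeric \code{c(a, h)} starting values on the
#'   natural scale.
#' @param control list passed to [stats::optim()] (Nelder-Mead); the
#'   default uses \code{reltol = 1e-12} so refits from different starts
#'   agree tightly.
#' @param hessian compute the Hessian/vcov (disable inside bootstrap
#'   loops for speed).
#' @return an object of class \code{fr_fit} with elements \code{a_hat},
#'   \code{h_hat}, \code{log_likelihood}, \code{aicc}, \code{n_trials},
#'   \code{converged}, \code{vcov} (log scale) and \code{response}
#'   (\code{"type2"}).
#' @examples
#' set.seed(1)
#' tr <- generate_trials(seed = 1)
#' fit_type2(tr[tr$sex == "M", ])
#' @export
fit_type2 <- function(trials, init = NULL, control = list(), hessian = TRUE) {
  trials <- .as_trials(trials)
  .fit_fr(trials$n0, trials$eaten, trials$duration_T,
          init = init, fix_h = FALSE, control = control, hessian = hessian)
}

#' Type I (depletion-only) comparator fit
#'
#' Same likelihood as [fit_type2()] with the handling time fixed at zero,
#' i.e. \eqn{N_e = N_0(1 - e^{-aT})}: prey deplete but consumption is
#' never handling-limited.  Used as the AICc comparator when deciding the
#' response type.
#'
#' @inheritParams fit_type2
#' @return an object of class \code{fr_fit} with \code{h_hat = 0} and
#'   \code{response = "type1"}.
#' @export
fit_type1 <- function(trials, init = NULL, control = list(), hessian = TRUE) {
  trials <- .as_trials(trials)
  .fit_fr(trials$n0, trials$eaten, trials$duration_T,
          init = init, fix_h = TRUE, control = control, hessian = hessian)
}

.fit_fr <- function(n0, eaten, Tdur, init = NULL, fix_h = FALSE,
                    control = list(), hessian = TRUE, polish = TRUE) {
  n <- length(n0)
  if (length(unique(n0)) < 2L) stop("need trials at >= 2 distinct prey densities")
  if (all(eaten == 0)) {
    stop("non-identifiable: no prey were eaten in any trial")
  }
  if (all(eaten == n0)) {
    stop("degenerate: every trial consumed all prey offered; ",
         "attack rate and handling time are not jointly identifiable")
  }

  # starting values: Type-I slope for a, duration / max(eaten) for h
  if (is.null(init)) {
    prop <- sum(eaten) / sum(n0)
    prop <- min(max(prop, 0.02), 0.98)
    Tbar <- mean(Tdur)
    a0 <- -log(1 - prop) / Tbar
    h0 <- Tbar / max(max(eaten), 1)
    init <- c(a0, max(h0, 1e-3))
  } else {
    if (any(init <= 0)) stop("`init` must be positive on the natural scale")
  }

  obj <- .nll_builder(n0, eaten, Tdur, fix_h = fix_h)
  ctrl <- utils::modifyList(list(reltol = 1e-12, maxit = 2000L), control)

  if (fix_h) {
    opt <- stats::optim(log(init[1L]), function(p) obj(p), method = "Brent",
                        lower = log(1e-8), upper = log(1e4))
    par <- opt$par
    k <- 1L
  } else {
    opt <- stats::optim(log(init), obj, method = "Nelder-Mead", control = ctrl)
    if (polish) {
      # Newton refinement from the simplex optimum pins the last digits,
      # so refits from any start agree to ~1e-8
      par_p <- opt$par
      for (it in 1:4) {
        g <- .cd_grad(obj, par_p)
        H <- try(stats::optimHess(par_p, obj), silent = TRUE)
        if (inherits(H, "try-error")) break
        step <- try(solve(H, g), silent = TRUE)
        if (inherits(step, "try-error") || !all(is.finite(step))) break
        cand <- par_p - step
        if (obj(cand) <= obj(par_p) + 1e-12) par_p <- cand
        if (sqrt(sum(step^2)) < 1e-10) break
      }
      if (obj(par_p) <= opt$value) {
        opt$par <- par_p
        opt$value <- obj(par_p)
      }
    }
    par <- opt$par
    k <- 2L
  }

  conv <- opt$convergence == 0L && is.finite(opt$value)
  vc <- matrix(NA_real_, k, k)
  if (hessian && conv) {
    H <- try(stats::optimHess(par, obj), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vc_try <- try(solve(H), silent = TRUE)
      if (!inherits(vc_try, "try-error") && all(is.finite(vc_try))) vc <- vc_try
    }
  }
  dimnames(vc) <- if (k == 2L) list(c("log_a", "log_h"), c("log_a", "log_h")) else
    list("log_a", "log_a")

  structure(list(
    a_hat = exp(par[1L]),
    h_hat = if (fix_h) 0 else exp(par[2L]),
    log_likelihood = -opt$value,
    aicc = aicc(opt$value, k = k, n = n),
    n_trials = n,
    converged = conv,
    vcov = vc,
    response = if (fix_h) "type1" else "type2"
  ), class = "fr_fit")
}

#' @export
print.fr_fit <- function(x, ...) {
  cat("Functional response fit (", x$response, "), n = ", x$n_trials,
      " trials\n", sep = "")
  cat(sprintf("  attack rate    a = %.4f\n", x$a_hat))
  cat(sprintf("  handling time  h = %.4f\n", x$h_hat))
  cat(sprintf("  logLik = %.3f   AICc = %.3f   converged: %s\n",
              x$log_likelihood, x$aicc, x$converged))
  invisible(x)
}

#' Functional-response type determination
#'
#' Logistic regression of the proportion of prey eaten on prey density.
#' A significantly negative first-order density term indicates a
#' decelerating (Type II) response.  The default linear predictor uses
#' density alone: with the usual half-dozen density levels a raw
#' quadratic term is almost collinear with the linear one and wrecks the
#' power of the first-order test.  Set \code{order = 2} to add the
#' quadratic term (useful when screening for sigmoid, Type III,
#' responses, where the signature is a positive linear and negative
#' quadratic term); the quadratic term is then kept regardless of its
#' significance and the linear term is still the one read out.
#'
#' @param trials data frame of trials (needs \code{n0}, \code{eaten}).
#' @param order 1 (default) for a linear-only model, 2 for
#'   linear + quadratic density terms.
#' @return list with \code{first_order_coef}, \code{z}, \code{p},
#'   \code{type} (\code{"type2"} if the linear term is significantly
#'   negative at 0.05, else \code{"not type2"}) and the underlying
#'   \code{glm} fit.
#' @export
type_test <- function(trials, order = 1L) {
  trials <- .as_trials(trials)
  if (length(unique(trials$n0)) < 3L) stop("need >= 3 distinct prey densities")
  trials$.dens <- trials$n0
  fml <- if (order >= 2L) {
    cbind(eaten, n0 - eaten) ~ .dens + I(.dens^2)
  } else {
    cbind(eaten, n0 - eaten) ~ .dens
  }
  fit <- stats::glm(fml, family = stats::binomial(), data = trials)
  if (!fit$converged) warning("type_test logistic regression did not converge")
  sm <- summary(fit)$coefficients
  co <- sm[".dens", ]
  list(
    first_order_coef = unname(co["Estimate"]),
    z = unname(co["z value"]),
    p = unname(co["Pr(>|z|)"]),
    type = if (co["Estimate"] < 0 && co["Pr(>|z|)"] < 0.05) "type2" else "not type2",
    fit = fit
  )
}

# central-difference gradient used by the Newton polish
.cd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h * (1 + abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, 0)
}
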