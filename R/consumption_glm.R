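#' Binomial GLM of the proportion of prey consumed
#'
#' Fits a binomial-logit model of \code{(eaten, uneaten)} on initial prey
#' density, consumer sex, a centred morphology term (crusher-claw height
#' or carapace width — never both, they are too collinear to share a
#' model) and the sex-by-morphology interaction:
#' \deqn{logit(p) = b_0 + b_1 N_0 + b_2 [male] + b_3 m_c + b_4 [male] m_c}
#' Morphology is centred at the dataset mean, so the sex main effect is
#' the log-odds contrast between the sexes at mean morphology.
#'
#' @param trials trials data frame with both sexes and finite morphology.
#' @param morphology_term \code{"claw"} (crusher-claw height) or
#'   \code{"carapace"} (carapace width).
#' @param center optional centring constant; defaults to the mean of the
#'   chosen morphology column (stored in the fit and reused by
#'   [predict_proportion()] and by bootstrap refits).
#' @return object of class \code{consumption_glm}: list with
#'   \code{coefficients}, \code{vcov}, \code{deviance},
#'   \code{dispersion} (Pearson chi-square / df), \code{converged},
#'   \code{center}, \code{morphology_term}, \code{sex_levels} and
#'   \code{glm} (the underlying fit).
#' @examples
#' tr <- generate_logit_trials(seed = 3)
#' fit <- fit_consumption_glm(tr)
#' coef_table(fit)
#' @export
fit_consumption_glm <- function(trials, morphology_term = c("claw", "carapace"),
                                center = NULL) {
  morphology_term <- match.arg(morphology_term)
  trials <- .as_trials(trials)
  col <- paste0(morphology_term, "_mm")
  if (is.null(trials[[col]])) stop("`trials` lacks column ", col)
  if (!all(is.finite(trials[[col]]))) stop("non-finite morphology values")
  sexes <- sort(unique(trials$sex))
  if (length(sexes) < 2L) stop("both sexes must be present")
  if (is.null(center)) center <- mean(trials[[col]])

  d <- data.frame(eaten = trials$eaten, uneaten = trials$n0 - trials$eaten,
                  density = trials$n0,
                  sex = factor(trials$sex, levels = sexes),
                  morph_c = trials[[col]] - center)
  fit <- stats::glm(cbind(eaten, uneaten) ~ density + sex + morph_c + sex:morph_c,
                    family = stats::binomial(), data = d)
  if (!fit$converged) warning("consumption GLM did not converge")
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  structure(list(
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    deviance = stats::deviance(fit),
    dispersion = pearson / fit$df.residual,
    converged = fit$converged,
    center = center,
    morphology_term = morphology_term,
    sex_levels = sexes,
    glm = fit
  ), class = "consumption_glm")
}

#' Coefficient table of a consumption GLM
#'
#' @param fit a \code{consumption_glm}.
#' @return data frame with estimate, SE, z and p per term.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "consumption_glm"))
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients / se
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.consumption_glm <- function(x, ...) {
  cat("Binomial-logit consumption model (morphology term:",
      x$morphology_term, "centred at", sprintf("%.3f", x$center), "mm)\n")
  print(coef_table(x), digits = 4)
  cat(sprintf("deviance %.2f, dispersion %.2f, converged: %s\n",
              x$deviance, x$dispersion, x$converged))
  invisible(x)
}

#' Predicted proportion of prey consumed
#'
#' Inverse-logit of the linear predictor at the supplied covariates,
#' using the centring constant stored in the fit, so raw morphology
#' values can be supplied directly.
#'
#' @param fit a \code{consumption_glm} (full or slim bootstrap refit).
#' @param density initial prey density.
#' @param sex sex label (one of the fit's levels).
#' @param morphology_value raw morphology value (mm) on the scale of the
#'   fit's morphology term.
#' @return predicted proportion(s) in (0, 1); vectorised over
#'   \code{density}.
#' @export
predict_proportion <- function(fit, density, sex, morphology_value) {
  stopifnot(inherits(fit, "consumption_glm"))
  if (!sex %in% fit$sex_levels) {
    stop("unknown sex level '", sex, "'; fit has: ",
         paste(fit$sex_levels, collapse = ", "))
  }
  m <- morphology_value - fit$center
  male <- as.numeric(sex == fit$sex_levels[2L])
  b <- fit$coefficients
  eta <- b[[1L]] + b[["density"]] * density +
    b[[paste0("sex", fit$sex_levels[2L])]] * male +
    b[["morph_c"]] * m +
    b[[paste0("sex", fit$sex_levels[2L], ":morph_c")]] * male * m
  stats::plogis(eta)
}

#' Bootstrap refits of the consumption GLM
#'
#' Nonparametric resampling of trials with replacement, stratified by
#' sex-by-density cell (preserving the design), refitting the GLM per
#' iteration.  Every refit reuses the original fit's centring constant
#' so that bootstrap and original predictions are on the same covariate
#' scale.  Failed or non-converged refits are dropped and counted.
#'
#' @param trials trials data frame.
#' @param n_iter bootstrap iterations.
#' @param seed integer seed.
#' @param morphology_term as in [fit_consumption_glm()].
#' @param identity_resample testing hook: every refit uses the original
#'   data.
#' @return list with \code{fit} (original \code{consumption_glm}),
#'   \code{boot} (list of slim \code{consumption_glm} refits),
#'   \code{n_failed}, \code{seed}.
#' @export
bootstrap_glm <- function(trials, n_iter = 2000L, seed = 1L,
                          morphology_term = c("claw", "carapace"),
                          identity_resample = FALSE) {
  morphology_term <- match.arg(morphology_term)
  trials <- .as_trials(trials)
  if (n_iter < 1L) stop("`n_iter` must be >= 1")
  orig <- fit_consumption_glm(trials, morphology_term)
  strata <- split(seq_len(nrow(trials)), interaction(trials$sex, trials$n0))
  strata <- strata[lengths(strata) > 0L]

  set.seed(as.integer(seed))
  boots <- vector("list", n_iter)
  failed <- 0L
  for (b in seq_len(n_iter)) {
    idx <- if (identity_resample) seq_len(nrow(trials)) else
      unlist(lapply(strata, function(s) s[sample.int(length(s), length(s),
                                                     replace = TRUE)]),
             use.names = FALSE)
    ft <- try(suppressWarnings(
      fit_consumption_glm(trials[idx, , drop = FALSE], morphology_term,
                          center = orig$center)), silent = TRUE)
    if (inherits(ft, "try-error") || !ft$converged) {
      failed <- failed + 1L
      next
    }
    ft$glm <- NULL   # keep refits slim
    boots[[b]] <- ft
  }
  list(fit = orig, boot = Filter(Negate(is.null), boots),
       n_failed = failed, seed = as.integer(seed))
}
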