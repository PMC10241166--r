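#' Sexual-dimorphism summary and test for one trait
#'
#' Mean of the trait by sex, male minus female difference in mm, the
#' percentage difference relative to the female mean, and the p-value of
#' the two-group linear model \code{trait ~ sex}.
#'
#' @param morph morphology table with columns \code{sex} (containing
#'   \code{"F"}/\code{"M"} levels, female first alphabetically),
#'   \code{claw_mm}, \code{carapace_mm}.
#' @param trait \code{"claw"} or \code{"carapace"}.
#' @return list with \code{mean_by_sex}, \code{diff_mm},
#'   \code{pct_diff}, \code{p}, \code{n_by_sex}.
#' @examples
#' m <- generate_morphology(100, seed = 2)
#' dimorphism_stats(m, "claw")
#' @export
dimorphism_stats <- function(morph, trait = c("claw", "carapace")) {
  trait <- match.arg(trait)
  col <- paste0(trait, "_mm")
  if (is.null(morph[[col]]) || is.null(morph$sex)) {
    stop("`morph` needs columns sex and ", col)
  }
  sexes <- sort(unique(morph$sex))
  if (length(sexes) != 2L) stop("exactly two sexes required")
  y <- morph[[col]]
  g <- factor(morph$sex, levels = sexes)
  mns <- tapply(y, g, mean)
  diff_mm <- unname(mns[2L] - mns[1L])
  fit <- stats::lm(y ~ g)
  p <- summary(fit)$coefficients[2L, 4L]
  list(mean_by_sex = mns,
       diff_mm = diff_mm,
       pct_diff = 100 * diff_mm / unname(mns[1L]),
       p = unname(p),
       n_by_sex = table(g))
}

#' Movement metrics of one track
#'
#' Path length (sum of consecutive Euclidean distances), proportion of
#' time in motion (steps whose displacement rate exceeds the
#' stationarity threshold), and average moving speed (path length /
#' moving time).  With no moving steps the speed is undefined and
#' returned as \code{NA} with \code{speed_defined = FALSE}.
#'
#' @param track data frame of one animal's ordered points with columns
#'   \code{t} (s), \code{x}, \code{y} (cm); at least two points,
#'   strictly increasing timestamps.
#' @param threshold stationarity threshold, cm/s: a step counts as
#'   moving when its displacement rate exceeds this.  The default
#'   0.5 cm/s separates station-keeping jitter from genuine travel at
#'   typical sampling intervals of about a second.
#' @return list with \code{path_length_cm}, \code{prop_time_moving},
#'   \code{speed_cm_per_s}, \code{speed_defined}.
#' @export
track_metrics <- function(track, threshold = 0.5) {
  if (nrow(track) < 2L) stop("a track needs at least two points")
  dt <- diff(track$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  d <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  path <- sum(d)
  moving <- d / dt > threshold
  t_total <- sum(dt)
  t_moving <- sum(dt[moving])
  if (t_moving > 0) {
    list(path_length_cm = path,
         prop_time_moving = t_moving / t_total,
         speed_cm_per_s = path / t_moving,
         speed_defined = TRUE)
  } else {
    list(path_length_cm = path,
         prop_time_moving = 0,
         speed_cm_per_s = NA_real_,
         speed_defined = FALSE)
  }
}

#' Movement metrics for every animal in a track set
#'
#' @param tracks output of [generate_tracks()] (or any table with
#'   \code{id}, \code{sex}, \code{carapace_mm}, \code{claw_mm},
#'   \code{t}, \code{x}, \code{y}).
#' @param threshold stationarity threshold, cm/s.
#' @return data frame, one row per animal.
#' @export
track_metrics_table <- function(tracks, threshold = 0.5) {
  out <- lapply(split(tracks, tracks$id), function(tr) {
    m <- track_metrics(tr, threshold)
    data.frame(id = tr$id[1L], sex = tr$sex[1L],
               carapace_mm = tr$carapace_mm[1L], claw_mm = tr$claw_mm[1L],
               path_length_cm = m$path_length_cm,
               prop_time_moving = m$prop_time_moving,
               speed_cm_per_s = m$speed_cm_per_s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Linear models of movement metrics on sex and body size
#'
#' For each metric (path length, proportion of time moving, speed), an
#' ordinary least-squares fit of \code{metric ~ sex * trait}, returning
#' the coefficient table.
#'
#' @param metrics output of [track_metrics_table()].
#' @param trait \code{"carapace"} or \code{"claw"}.
#' @return named list of coefficient data frames (term, estimate, se,
#'   t, p), one per metric; rows with undefined speed are dropped from
#'   the speed model.
#' @export
behaviour_lm <- function(metrics, trait = c("carapace", "claw")) {
  trait <- match.arg(trait)
  col <- paste0(trait, "_mm")
  mk <- function(y) {
    d <- data.frame(y = metrics[[y]],
                    sex = factor(metrics$sex),
                    size = metrics[[col]])
    d <- d[is.finite(d$y), , drop = FALSE]
    fit <- stats::lm(y ~ sex * size, data = d)
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
               t = sm[, 3L], p = sm[, 4L], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  list(path_length = mk("path_length_cm"),
       prop_time_moving = mk("prop_time_moving"),
       speed = mk("speed_cm_per_s"))
}

#' Prey-size selectivity contrasts
#'
#' Linear model of prey length on sex crossed with outcome (consumed vs
#' not consumed), followed by pairwise contrasts of consumed vs
#' not-consumed mean lengths within each sex (Tukey adjustment via
#' emmeans).  A non-significant within-sex contrast means that sex ate
#' prey of the sizes it was offered, i.e. no size selectivity.
#'
#' @param prey per-prey table with columns \code{sex}, \code{length_mm},
#'   \code{consumed} (logical), e.g. from [generate_prey_sizes()].
#' @return list with \code{model} (the lm), \code{contrasts} (data
#'   frame of within-sex consumed minus not-consumed contrasts with
#'   adjusted p-values) and \code{offered_by_sex} (data frame of
#'   between-sex contrasts of offered sizes).
#' @export
prey_size_contrasts <- function(prey) {
  need <- c("sex", "length_mm", "consumed")
  if (!all(need %in% names(prey))) {
    stop("`prey` needs columns: ", paste(need, collapse = ", "))
  }
  d <- data.frame(length_mm = prey$length_mm,
                  sex = factor(prey$sex),
                  outcome = factor(ifelse(prey$consumed, "consumed",
                                          "not_consumed"),
                                   levels = c("not_consumed", "consumed")))
  fit <- stats::lm(length_mm ~ sex * outcome, data = d)
  emm <- emmeans::emmeans(fit, ~ outcome | sex)
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  # sex margin averages over the outcome factor; the emmeans interaction
  # note is expected and unhelpful here
  emm_sex <- suppressMessages(emmeans::emmeans(fit, ~ sex))
  ctr_sex <- as.data.frame(emmeans::contrast(emm_sex, method = "pairwise",
                                             adjust = "tukey"))
  list(model = fit, contrasts = ctr, offered_by_sex = ctr_sex)
}

#' Population sex-ratio estimates from trapping records
#'
#' Per-period proportion of females, per-site mean over periods, and two
#' labelled tests of site-level deviation from an even (0.5) sex ratio:
#' an exact binomial test on the pooled counts and a one-sample t-test
#' of the per-period proportions.
#'
#' @param catches data frame with columns \code{site}, \code{period},
#'   \code{males}, \code{females} (counts, males + females >= 1).
#' @return list with \code{per_period} (data frame with
#'   \code{prop_female}) and \code{per_site} (data frame with
#'   \code{mean_prop_female}, \code{n_periods}, \code{pooled_females},
#'   \code{pooled_total}, \code{p_pooled_binomial},
#'   \code{p_per_period_t}).
#' @export
sexratio_estimates <- function(catches) {
  need <- c("site", "period", "males", "females")
  if (!all(need %in% names(catches))) {
    stop("`catches` needs columns: ", paste(need, collapse = ", "))
  }
  if (any(catches$males < 0 | catches$females < 0)) stop("counts must be >= 0")
  tot <- catches$males + catches$females
  if (any(tot < 1)) stop("each period needs at least one animal")
  per_period <- cbind(catches, prop_female = catches$females / tot)

  per_site <- do.call(rbind, lapply(split(per_period, per_period$site),
    function(s) {
      pf <- s$prop_female
      pooled_f <- sum(s$females)
      pooled_n <- sum(s$females + s$males)
      p_pool <- stats::binom.test(pooled_f, pooled_n, p = 0.5)$p.value
      p_t <- if (length(pf) > 1L && stats::sd(pf) > 0) {
        stats::t.test(pf, mu = 0.5)$p.value
      } else {
        NA_real_
      }
      data.frame(site = s$site[1L],
                 mean_prop_female = mean(pf),
                 n_periods = nrow(s),
                 pooled_females = pooled_f,
                 pooled_total = pooled_n,
                 p_pooled_binomial = p_pool,
                 p_per_period_t = p_t,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_site) <- NULL
  list(per_period = per_period, per_site = per_site)
}
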