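#' Experimental design of a functional-response trial grid
#'
#' Describes a fully crossed density-by-group design.  The default mirrors
#' a standard laboratory layout for decapod foraging trials: six prey
#' densities (1, 2, 4, 6, 10, 16), two sexes, six replicates per cell, and
#' trial duration normalised to \code{T = 1} so fitted rates are per
#' trial.
#'
#' @param densities strictly positive integer initial prey counts.
#' @param replicates replicates per density-by-group cell (>= 1).
#' @param sexes group labels.
#' @param duration_T dimensionless trial duration.
#' @return list of class \code{trial_design}.
#' @examples
#' d <- trial_design()
#' nrow(expand.grid(d$densities, d$sexes)) * d$replicates  # 72 trials
#' @export
trial_design <- function(densities = c(1, 2, 4, 6, 10, 16), replicates = 6L,
                         sexes = c("F", "M"), duration_T = 1) {
  if (any(densities <= 0) || any(densities != round(densities))) {
    stop("`densities` must be strictly positive integers")
  }
  if (replicates < 1L) stop("`replicates` must be >= 1")
  if (duration_T <= 0) stop("`duration_T` must be > 0")
  structure(list(densities = as.integer(densities),
                 replicates = as.integer(replicates),
                 sexes = as.character(sexes),
                 duration_T = duration_T),
            class = "trial_design")
}

#' Per-group generating parameters
#'
#' Attack rate and handling time of the Rogers model plus the moments of
#' the (truncated-normal) morphology distributions for one group.
#'
#' @param a attack rate (> 0 unless deliberately degenerate; >= 0 allowed).
#' @param h handling time (>= 0).
#' @param claw_mean,claw_sd crusher-claw height moments, mm.
#' @param carapace_mean,carapace_sd carapace width moments, mm.
#' @return list of class \code{group_params}.
#' @export
group_params <- function(a, h, claw_mean = 15, claw_sd = 2.5,
                         carapace_mean = 66, carapace_sd = 5) {
  if (!is.finite(a) || a < 0) stop("`a` must be finite and >= 0")
  if (!is.finite(h) || h < 0) stop("`h` must be finite and >= 0")
  if (claw_sd < 0 || carapace_sd < 0) stop("standard deviations must be >= 0")
  structure(list(a = a, h = h, claw_mean = claw_mean, claw_sd = claw_sd,
                 carapace_mean = carapace_mean, carapace_sd = carapace_sd),
            class = "group_params")
}

#' Default sex-specific generating parameters
#'
#' Females: lower attack rate, longer handling time, smaller claws;
#' males: the reverse.  Morphology moments follow published summaries of
#' green crabs used in foraging trials (female carapace 64.9 +/- 5.6 mm,
#' claw 13.8 +/- 2.4 mm; male carapace 67.1 +/- 5.0 mm, claw
#' 17.4 +/- 3.1 mm).  The (a, h) pairs are chosen so that the implied
#' functional response ratios (a/h of roughly 14 vs 27) and the male
#' minus female differences in maximum consumption and handling time sit
#' where sex-comparative crab studies report them.
#'
#' @return named list of [group_params()], one per sex.
#' @export
crab_defaults <- function() {
  list(
    F = group_params(a = 1.8, h = 0.13, claw_mean = 13.8, claw_sd = 2.4,
                     carapace_mean = 64.9, carapace_sd = 5.6),
    M = group_params(a = 2.7, h = 0.10, claw_mean = 17.4, claw_sd = 3.1,
                     carapace_mean = 67.1, carapace_sd = 5.0)
  )
}

# truncated-normal draw by reject-and-redraw below `lower`
.rtnorm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Simulate foraging trials
#'
#' Generates one trial per design cell and replicate.  Two stochastic
#' mechanisms are available:
#' \describe{
#'   \item{\code{expectation_binomial}}{the number eaten is
#'     \eqn{Binomial(N_0, p)} with \eqn{p = N_e / N_0} from
#'     [rogers_predict()] — exactly the likelihood assumption of the
#'     Rogers fit.}
#'   \item{\code{event_based}}{a continuous-time simulation: search times
#'     are exponential with rate \eqn{a \times} remaining prey, and each
#'     capture is followed by a handling period \code{h} during which the
#'     search clock is paused.  A capture whose search completes before
#'     \code{T} counts as consumed even if its handling overruns the
#'     trial (set \code{count_overrun_handling = FALSE} to require the
#'     handling period to finish in time).}
#' }
#' Each simulated animal also receives a carapace width and crusher-claw
#' height drawn from its group's truncated-normal morphology
#' distribution.
#'
#' @param design a [trial_design()].
#' @param params named list of [group_params()], one per group label in
#'   the design.
#' @param mode \code{"expectation_binomial"} or \code{"event_based"}.
#' @param seed integer seed; the dataset is a deterministic function of
#'   it.
#' @param count_overrun_handling see above (event-based mode only).
#' @return data frame with columns \code{trial_id}, \code{sex},
#'   \code{carapace_mm}, \code{claw_mm}, \code{n0}, \code{eaten},
#'   \code{duration_T}.
#' @examples
#' tr <- generate_trials(seed = 42)
#' aggregate(eaten ~ sex + n0, tr, mean)
#' @export
generate_trials <- function(design = trial_design(), params = crab_defaults(),
                            mode = c("expectation_binomial", "event_based"),
                            seed = 1L, count_overrun_handling = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "trial_design"))
  miss <- setdiff(design$sexes, names(params))
  if (length(miss)) stop("no parameters for group(s): ", paste(miss, collapse = ", "))
  for (g in design$sexes) {
    p <- params[[g]]
    if (!all(is.finite(c(p$a, p$h)))) stop("non-finite parameters for group ", g)
  }
  set.seed(as.integer(seed))

  grid <- expand.grid(rep = seq_len(design$replicates),
                      n0 = design$densities,
                      sex = design$sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  eaten <- integer(n)
  carapace <- claw <- numeric(n)
  Tdur <- design$duration_T

  for (g in design$sexes) {
    ii <- which(grid$sex == g)
    p <- params[[g]]
    carapace[ii] <- .rtnorm(length(ii), p$carapace_mean, p$carapace_sd)
    claw[ii] <- .rtnorm(length(ii), p$claw_mean, p$claw_sd)
    if (mode == "expectation_binomial") {
      pe <- vapply(grid$n0[ii], function(d)
        rogers_predict(d, p$a, p$h, Tdur) / d, 0)
      eaten[ii] <- stats::rbinom(length(ii), grid$n0[ii], pe)
    } else {
      eaten[ii] <- vapply(grid$n0[ii], function(d)
        .sim_event_trial(d, p$a, p$h, Tdur, count_overrun_handling), 0L)
    }
  }

  data.frame(trial_id = seq_len(n),
             sex = grid$sex,
             carapace_mm = carapace,
             claw_mm = claw,
             n0 = grid$n0,
             eaten = eaten,
             duration_T = Tdur,
             stringsAsFactors = FALSE)
}

# one continuous-time trial: exponential search, handling blocks search
.sim_event_trial <- function(n0, a, h, Tdur, count_overrun = TRUE) {
  if (a <= 0) return(0L)
  elapsed <- 0
  remaining <- n0
  eaten <- 0L
  while (remaining > 0L) {
    s <- stats::rexp(1L, rate = a * remaining)
    if (elapsed + s > Tdur) break
    if (!count_overrun && elapsed + s + h > Tdur) break
    eaten <- eaten + 1L
    remaining <- remaining - 1L
    elapsed <- elapsed + s + h
  }
  eaten
}

#' Simulate trials whose consumption follows a binomial-logit model
#'
#' Companion generator for checking the consumption GLM: the proportion
#' eaten follows \code{plogis(b0 + b_dens * n0 + b_sex * [male] +
#' b_claw * claw_c + b_sexclaw * [male] * claw_c)} where \code{claw_c} is
#' claw height centred at the overall generating mean.  Morphology is
#' drawn as in [generate_trials()].
#'
#' @param design a [trial_design()].
#' @param coefs named numeric vector with elements \code{intercept},
#'   \code{density}, \code{sex}, \code{claw}, \code{sex_claw} (logit
#'   scale).
#' @param params named list of [group_params()] supplying morphology
#'   moments.
#' @param seed integer seed.
#' @return data frame with the same columns as [generate_trials()].
#' @export
generate_logit_trials <- function(design = trial_design(),
                                  coefs = c(intercept = 0, density = -0.7,
                                            sex = 0.3, claw = 0.6,
                                            sex_claw = -0.5),
                                  params = crab_defaults(), seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  need <- c("intercept", "density", "sex", "claw", "sex_claw")
  if (!all(need %in% names(coefs))) {
    stop("`coefs` needs elements: ", paste(need, collapse = ", "))
  }
  set.seed(as.integer(seed))
  grid <- expand.grid(rep = seq_len(design$replicates),
                      n0 = design$densities,
                      sex = design$sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  carapace <- claw <- numeric(n)
  for (g in design$sexes) {
    ii <- which(grid$sex == g)
    p <- params[[g]]
    carapace[ii] <- .rtnorm(length(ii), p$carapace_mean, p$carapace_sd)
    claw[ii] <- .rtnorm(length(ii), p$claw_mean, p$claw_sd)
  }
  claw_center <- mean(vapply(params[design$sexes], `[[`, 0, "claw_mean"))
  male <- as.numeric(grid$sex == design$sexes[length(design$sexes)])
  eta <- coefs[["intercept"]] + coefs[["density"]] * grid$n0 +
    coefs[["sex"]] * male + coefs[["claw"]] * (claw - claw_center) +
    coefs[["sex_claw"]] * male * (claw - claw_center)
  eaten <- stats::rbinom(n, grid$n0, stats::plogis(eta))
  data.frame(trial_id = seq_len(n), sex = grid$sex, carapace_mm = carapace,
             claw_mm = claw, n0 = grid$n0, eaten = eaten,
             duration_T = design$duration_T, stringsAsFactors = FALSE)
}

#' Simulate per-prey sizes for a set of trials
#'
#' Offered prey lengths are uniform on \code{size_range} (default
#' 25–40 mm, a typical clam-length window), with an optional additive
#' per-sex offset to emulate unbalanced random assignment.  Consumption
#' is size-blind: the eaten prey of each trial are a simple random subset
#' of those offered.
#'
#' @param trials a trials data frame ([generate_trials()] output).
#' @param size_range length-2 numeric, mm.
#' @param sex_offset named numeric of per-sex additive shifts in offered
#'   length (mm), e.g. \code{c(F = 1.4, M = -1.4)}.
#' @param seed integer seed.
#' @return data frame with columns \code{trial_id}, \code{sex},
#'   \code{length_mm}, \code{consumed} (logical).
#' @export
generate_prey_sizes <- function(trials, size_range = c(25, 40),
                                sex_offset = c(F = 0, M = 0), seed = 1L) {
  trials <- .as_trials(trials)
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nrow(trials)), function(i) {
    n0 <- trials$n0[i]
    off <- sex_offset[[trials$sex[i]]]
    if (is.null(off)) off <- 0
    len <- stats::runif(n0, size_range[1L], size_range[2L]) + off
    consumed <- logical(n0)
    if (trials$eaten[i] > 0) consumed[sample.int(n0, trials$eaten[i])] <- TRUE
    data.frame(trial_id = trials$trial_id[i], sex = trials$sex[i],
               length_mm = len, consumed = consumed, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a morphology survey
#'
#' Per-animal carapace width and crusher-claw height from per-group
#' normals truncated at zero.  Claw is linked to carapace through a
#' linear model parameterised by the correlation \code{rho}, so the
#' marginal claw moments still match the group parameters while claw and
#' carapace are positively correlated as in real crabs.
#'
#' @param n_per_sex animals per group (>= 1).
#' @param params named list of [group_params()].
#' @param rho within-group claw–carapace correlation in [0, 1).
#' @param seed integer seed.
#' @return data frame with \code{sex}, \code{carapace_mm},
#'   \code{claw_mm}.
#' @export
generate_morphology <- function(n_per_sex, params = crab_defaults(),
                                rho = 0.7, seed = 1L) {
  if (any(n_per_sex < 1)) stop("`n_per_sex` must be >= 1")
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)")
  set.seed(as.integer(seed))
  if (length(n_per_sex) == 1L) {
    n_per_sex <- stats::setNames(rep(n_per_sex, length(params)), names(params))
  }
  out <- lapply(names(n_per_sex), function(g) {
    p <- params[[g]]
    n <- n_per_sex[[g]]
    carapace <- .rtnorm(n, p$carapace_mean, p$carapace_sd)
    if (p$claw_sd == 0) {
      claw <- rep(p$claw_mean, n)
    } else {
      slope <- if (p$carapace_sd > 0) rho * p$claw_sd / p$carapace_sd else 0
      resid_sd <- p$claw_sd * sqrt(1 - rho^2)
      claw <- p$claw_mean + slope * (carapace - p$carapace_mean) +
        stats::rnorm(n, 0, resid_sd)
      bad <- which(claw < 0)
      while (length(bad)) {
        claw[bad] <- p$claw_mean + slope * (carapace[bad] - p$carapace_mean) +
          stats::rnorm(length(bad), 0, resid_sd)
        bad <- bad[claw[bad] < 0]
      }
    }
    data.frame(sex = g, carapace_mm = carapace, claw_mm = claw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Movement-simulation settings
#'
#' Parameters of the two-state (move/pause) correlated random walk used
#' by [generate_tracks()].  Defaults describe a crab exploring a
#' 61 x 41 cm arena for 5 minutes, sampled once per second.
#'
#' @param speed named per-sex moving speed, cm/s.
#' @param p_move named per-sex stationary probability of being in the
#'   moving state.
#' @param persist probability of staying in the moving state from one
#'   step to the next (state persistence).
#' @param turn_sd standard deviation of the per-step turning angle,
#'   radians.
#' @param dt sampling interval, seconds (the interval between tracked
#'   points; must be supplied to match whatever frame subsampling
#'   produced the data).
#' @param duration track duration, seconds.
#' @param arena arena width and height, cm.
#' @return list of class \code{track_params}.
#' @export
track_params <- function(speed = c(F = 2.5, M = 2.5),
                         p_move = c(F = 0.5, M = 0.5),
                         persist = 0.8, turn_sd = 0.6, dt = 1,
                         duration = 300, arena = c(61, 41)) {
  if (any(arena <= 0)) stop("arena dimensions must be positive")
  if (dt <= 0 || duration <= 0) stop("`dt` and `duration` must be positive")
  if (any(p_move < 0 | p_move > 1)) stop("`p_move` must be in [0, 1]")
  structure(list(speed = speed, p_move = p_move, persist = persist,
                 turn_sd = turn_sd, dt = dt, duration = duration,
                 arena = arena), class = "track_params")
}

#' Simulate movement tracks
#'
#' Two-state correlated random walk inside a rectangular arena: each
#' animal alternates between a moving state (constant speed, correlated
#' heading) and a pause state, with reflecting walls.  Each animal also
#' gets morphology from \code{params} so the track metrics can be
#' regressed on carapace width.
#'
#' @param n_per_sex animals per sex.
#' @param move_params a [track_params()].
#' @param params named list of [group_params()] for morphology.
#' @param seed integer seed.
#' @return data frame with \code{id}, \code{sex}, \code{carapace_mm},
#'   \code{claw_mm}, \code{t} (s), \code{x}, \code{y} (cm).
#' @export
generate_tracks <- function(n_per_sex = 16L, move_params = track_params(),
                            params = crab_defaults(), seed = 1L) {
  stopifnot(inherits(move_params, "track_params"))
  set.seed(as.integer(seed))
  mp <- move_params
  n_steps <- floor(mp$duration / mp$dt)
  id <- 0L
  out <- list()
  for (g in names(mp$speed)) {
    pg <- params[[g]]
    for (k in seq_len(n_per_sex)) {
      id <- id + 1L
      carapace <- .rtnorm(1L, pg$carapace_mean, pg$carapace_sd)
      claw <- .rtnorm(1L, pg$claw_mean, pg$claw_sd)
      pm <- mp$p_move[[g]]
      # two-state chain with stationary P(move) = pm and persistence; when
      # the implied pause-to-move rate saturates at 1, persistence is
      # raised instead so the stationary distribution is always honoured
      p_stay_move <- mp$persist
      if (pm <= 0) {
        p_stay_move <- 0; p_go_move <- 0
      } else if (pm >= 1) {
        p_stay_move <- 1; p_go_move <- 1
      } else {
        p_go_move <- pm * (1 - p_stay_move) / (1 - pm)
        if (p_go_move > 1) {
          p_go_move <- 1
          p_stay_move <- 1 - (1 - pm) / pm
        }
      }
      moving <- stats::runif(1L) < pm
      theta <- stats::runif(1L, 0, 2 * pi)
      x <- stats::runif(1L, 0, mp$arena[1L])
      y <- stats::runif(1L, 0, mp$arena[2L])
      xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
      xs[1L] <- x; ys[1L] <- y
      step_len <- mp$speed[[g]] * mp$dt
      for (s in seq_len(n_steps)) {
        moving <- if (moving) stats::runif(1L) < p_stay_move else
          stats::runif(1L) < p_go_move
        if (moving) {
          theta <- theta + stats::rnorm(1L, 0, mp$turn_sd)
          x <- x + step_len * cos(theta)
          y <- y + step_len * sin(theta)
          # reflect off walls
          if (x < 0) { x <- -x; theta <- pi - theta }
          if (x > mp$arena[1L]) { x <- 2 * mp$arena[1L] - x; theta <- pi - theta }
          if (y < 0) { y <- -y; theta <- -theta }
          if (y > mp$arena[2L]) { y <- 2 * mp$arena[2L] - y; theta <- -theta }
        }
        xs[s + 1L] <- x; ys[s + 1L] <- y
      }
      out[[id]] <- data.frame(id = id, sex = g, carapace_mm = carapace,
                              claw_mm = claw, t = seq(0, by = mp$dt,
                                                      length.out = n_steps + 1L),
                              x = xs, y = ys, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate trapping-survey catch records
#'
#' Per trapping period, the number of females is binomial with the given
#' female proportion; males are the remainder.
#'
#' @param n_periods number of trapping periods.
#' @param catch_sizes integer catches per period (recycled; default a
#'   reproducible spread of 20–120 animals).
#' @param female_proportion probability that an animal is female, in
#'   [0, 1]; either a single value or one per site.
#' @param sites site labels assigned to periods in rotation.
#' @param seed integer seed.
#' @return data frame with \code{site}, \code{period}, \code{males},
#'   \code{females}.
#' @export
generate_catches <- function(n_periods = 42L, catch_sizes = NULL,
                             female_proportion = 0.5,
                             sites = c("siteA", "siteB", "siteC", "siteD"),
                             seed = 1L) {
  if (any(female_proportion < 0 | female_proportion > 1)) {
    stop("`female_proportion` must be in [0, 1]")
  }
  set.seed(as.integer(seed))
  if (is.null(catch_sizes)) {
    catch_sizes <- sample(20:120, n_periods, replace = TRUE)
  }
  catch_sizes <- rep_len(as.integer(catch_sizes), n_periods)
  if (any(catch_sizes < 1L)) stop("catch sizes must be >= 1")
  site <- rep_len(sites, n_periods)
  q <- if (length(female_proportion) == length(sites)) {
    stats::setNames(female_proportion, sites)[site]
  } else {
    rep_len(female_proportion, n_periods)
  }
  females <- stats::rbinom(n_periods, catch_sizes, q)
  data.frame(site = site, period = seq_len(n_periods),
             males = catch_sizes - females, females = females,
             stringsAsFactors = FALSE)
}
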