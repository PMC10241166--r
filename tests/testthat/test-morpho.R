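test_that("dimorphism_stats reproduces survey-scale claw dimorphism", {
  # two sexes pinned exactly at published survey means (claw sd = 0)
  prm <- list(F = group_params(1, .1, claw_mean = 11.48, claw_sd = 0),
              M = group_params(1, .1, claw_mean = 16.71, claw_sd = 0))
  m <- generate_morphology(c(F = 197, M = 175), prm, seed = 1)
  ds <- suppressWarnings(dimorphism_stats(m, "claw"))  # zero-variance lm
  expect_equal(ds$diff_mm, 5.23, tolerance = 1e-9)
  expect_equal(ds$pct_diff, 100 * 5.23 / 11.48, tolerance = 1e-9)  # 45.56%
  expect_identical(as.integer(ds$n_by_sex), c(197L, 175L))
})

test_that("dimorphism_stats on identical groups finds nothing", {
  prm <- list(F = group_params(1, .1, claw_mean = 14, claw_sd = 1),
              M = group_params(1, .1, claw_mean = 14, claw_sd = 1))
  m <- generate_morphology(300, prm, seed = 2)
  ds <- dimorphism_stats(m, "claw")
  expect_lt(abs(ds$diff_mm), 0.3)
  expect_gt(ds$p, 0.01)
})

test_that("dimorphism percentage is scale-invariant and p matches permutation", {
  m <- generate_morphology(10, seed = 3)
  ds_mm <- dimorphism_stats(m, "carapace")
  m_cm <- m
  m_cm$carapace_mm <- m_cm$carapace_mm / 10
  expect_equal(dimorphism_stats(m_cm, "carapace")$pct_diff, ds_mm$pct_diff,
               tolerance = 1e-12)

  # permutation oracle for the two-group p-value on a 10-animal toy set
  y <- m$carapace_mm
  g <- m$sex
  obs <- abs(diff(tapply(y, g, mean)))
  set.seed(4)
  perm <- replicate(20000, {
    gs <- sample(g)
    abs(diff(tapply(y, gs, mean)))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(ds_mm$p - p_perm), 0.08)
})

test_that("track metrics handle stationary and straight-line tracks", {
  still <- data.frame(t = 0:9, x = rep(1, 10), y = rep(2, 10))
  m <- track_metrics(still)
  expect_identical(m$path_length_cm, 0)
  expect_identical(m$prop_time_moving, 0)
  expect_false(m$speed_defined)
  expect_true(is.na(m$speed_cm_per_s))

  line <- data.frame(t = 0:5, x = seq(0, 10, by = 2), y = 0)
  m2 <- track_metrics(line)   # 10 cm in 5 s, always moving
  expect_equal(m2$path_length_cm, 10, tolerance = 1e-12)
  expect_identical(m2$prop_time_moving, 1)
  expect_equal(m2$speed_cm_per_s, 2, tolerance = 1e-12)
  expect_error(track_metrics(line[1, ]), "two points")
  expect_error(track_metrics(data.frame(t = c(0, 0), x = 1:2, y = 1:2)),
               "increasing")
})

test_that("path length is rigid-motion invariant and speed*time = path", {
  set.seed(5)
  tr <- data.frame(t = 0:30, x = cumsum(stats::rnorm(31)),
                   y = cumsum(stats::rnorm(31)))
  m <- track_metrics(tr, threshold = 0.3)
  th <- 0.83
  rot <- data.frame(t = tr$t,
                    x = cos(th) * tr$x - sin(th) * tr$y + 12,
                    y = sin(th) * tr$x + cos(th) * tr$y - 5)
  m_rot <- track_metrics(rot, threshold = 0.3)
  expect_equal(m_rot$path_length_cm, m$path_length_cm, tolerance = 1e-10)
  expect_equal(m_rot$prop_time_moving, m$prop_time_moving, tolerance = 1e-12)
  expect_equal(m$speed_cm_per_s * m$prop_time_moving * 30, m$path_length_cm,
               tolerance = 1e-10)
})

test_that("behaviour_lm recovers an injected sex effect and a null", {
  tp <- track_params(speed = c(F = 2, M = 3.2), p_move = c(F = 0.5, M = 0.5),
                     duration = 400)
  met <- track_metrics_table(generate_tracks(14, tp, seed = 6))
  lm_out <- behaviour_lm(met, "carapace")
  sp <- lm_out$speed
  expect_identical(sp$term[1], "(Intercept)")
  sexrow <- sp[sp$term == "sexM", ]
  # injected speed gap of 1.2 cm/s: detectable sign at least
  expect_gt(sexrow$estimate + 2 * sexrow$se, 0)

  # null data: no sex term anywhere near significance in path length
  tp0 <- track_params(duration = 400)
  met0 <- track_metrics_table(generate_tracks(14, tp0, seed = 7))
  lm0 <- behaviour_lm(met0, "carapace")
  expect_gt(lm0$path_length[lm0$path_length$term == "sexM", "p"], 0.01)
})

test_that("behaviour_lm equals the normal-equations solution on a toy set", {
  toy <- data.frame(id = 1:6, sex = rep(c("F", "M"), each = 3),
                    carapace_mm = c(60, 64, 68, 61, 65, 70),
                    claw_mm = 12:17,
                    path_length_cm = c(100, 140, 120, 180, 210, 260),
                    prop_time_moving = c(.4, .5, .45, .6, .62, .7),
                    speed_cm_per_s = c(2, 2.2, 2.1, 2.8, 3, 3.3))
  out <- behaviour_lm(toy, "carapace")$path_length
  X <- cbind(1, toy$sex == "M", toy$carapace_mm,
             (toy$sex == "M") * toy$carapace_mm)
  beta <- solve(t(X) %*% X, t(X) %*% toy$path_length_cm)
  expect_equal(out$estimate, drop(beta), tolerance = 1e-8)
})

test_that("prey-size contrasts: size-blind consumption is null, selectivity is not", {
  tr <- generate_trials(trial_design(replicates = 12), seed = 8)
  prey <- generate_prey_sizes(tr, seed = 9)
  psc <- prey_size_contrasts(prey)
  expect_true(all(psc$contrasts$p.value > 0.05))

  # inject selectivity: consumed prey are the smallest offered
  sel <- prey
  sel <- do.call(rbind, lapply(split(sel, sel$trial_id), function(d) {
    k <- sum(d$consumed)
    d$consumed <- rank(d$length_mm, ties.method = "first") <= k
    d
  }))
  psc_sel <- prey_size_contrasts(sel)
  expect_true(any(psc_sel$contrasts$p.value < 0.05))

  # contrast arithmetic equals group-mean differences on the toy model
  est <- psc$contrasts$estimate
  mns <- tapply(prey$length_mm, list(prey$consumed, prey$sex), mean)
  expect_equal(sort(est), sort(c(mns["FALSE", "F"] - mns["TRUE", "F"],
                                 mns["FALSE", "M"] - mns["TRUE", "M"])),
               tolerance = 1e-9)
})

test_that("sex-ratio estimation: proportions, site means, bias tests", {
  even <- data.frame(site = "s1", period = 1:4, males = c(10, 20, 15, 5),
                     females = c(10, 20, 15, 5))
  sr <- sexratio_estimates(even)
  expect_true(all(sr$per_period$prop_female == 0.5))
  expect_identical(sr$per_site$mean_prop_female, 0.5)
  expect_identical(sr$per_site$p_pooled_binomial, 1)

  skew <- generate_catches(42, catch_sizes = 90, female_proportion = 0.41,
                           seed = 10)
  sr2 <- sexratio_estimates(skew)
  expect_equal(sr2$per_site$mean_prop_female,
               as.vector(tapply(sr2$per_period$prop_female,
                                sr2$per_period$site, mean)),
               tolerance = 1e-12)
  # pooled test has power against 0.41 at ~950 animals per site
  expect_true(all(sr2$per_site$p_pooled_binomial < 0.05))
  expect_error(sexratio_estimates(data.frame(site = "a", period = 1,
                                             males = 0, females = 0)),
               "at least one")
})
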