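test_that("generate_trials respects the design and conserves prey", {
  d <- trial_design()
  tr <- generate_trials(d, seed = 1)
  expect_identical(nrow(tr), 6L * 2L * 6L)
  expect_true(all(tr$eaten >= 0 & tr$eaten <= tr$n0))
  expect_identical(sort(unique(tr$n0)), c(1L, 2L, 4L, 6L, 10L, 16L))
  expect_identical(as.vector(table(tr$sex)), c(36L, 36L))
  # uneaten + eaten = n0 by construction
  expect_identical(tr$eaten + (tr$n0 - tr$eaten), tr$n0)
})

test_that("identical seeds give byte-identical datasets, different seeds differ", {
  a <- generate_trials(seed = 99)
  b <- generate_trials(seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$eaten, generate_trials(seed = 100)$eaten))
  m1 <- generate_morphology(50, seed = 7)
  expect_identical(m1, generate_morphology(50, seed = 7))
  t1 <- generate_tracks(2, seed = 3)
  expect_identical(t1, generate_tracks(2, seed = 3))
  c1 <- generate_catches(seed = 5)
  expect_identical(c1, generate_catches(seed = 5))
})

test_that("zero attack rate means nothing is ever eaten, either mode", {
  p0 <- list(F = group_params(0, 0.1), M = group_params(0, 0.1))
  for (mode in c("expectation_binomial", "event_based")) {
    tr <- generate_trials(params = p0, mode = mode, seed = 8)
    expect_true(all(tr$eaten == 0))
  }
})

test_that("binomial mode matches the h = 0 closed form in the mean", {
  d <- trial_design(densities = 16, replicates = 10000, sexes = "M")
  tr <- generate_trials(d, list(M = group_params(1, 0)), seed = 13)
  expected <- 16 * (1 - exp(-1))            # 10.11
  se <- stats::sd(tr$eaten) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$eaten) - expected), 3.5 * se + 1e-9)
})

test_that("binomial-mode means track rogers_predict across a parameter grid", {
  grid <- expand.grid(a = c(0.8, 2.5), h = c(0.05, 0.15), n0 = c(4, 16))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- trial_design(densities = g$n0, replicates = 3000, sexes = "M")
    tr <- generate_trials(d, list(M = group_params(g$a, g$h)), seed = 600 + i)
    mu <- rogers_predict(g$n0, g$a, g$h)
    se <- stats::sd(tr$eaten) / sqrt(nrow(tr))
    expect_lt(abs(mean(tr$eaten) - mu), 4 * se + 1e-9)
  }
})

test_that("event-based simulation agrees with an independent tau-leap oracle", {
  n0 <- 16; a <- 2.5; h <- 0.08; nrep <- 10000
  d <- trial_design(densities = n0, replicates = nrep, sexes = "M")
  tr <- generate_trials(d, list(M = group_params(a, h)), mode = "event_based",
                        seed = 17)
  set.seed(18)
  oracle <- tau_leap_trials(nrep, n0, a, h)
  se <- sqrt(stats::var(tr$eaten) / nrep + stats::var(oracle) / nrep)
  expect_lt(abs(mean(tr$eaten) - mean(oracle)), 3.5 * se)
})

test_that("handling-overrun captures are configurable", {
  # large h: the last capture usually overruns the trial end
  d <- trial_design(densities = 10, replicates = 400, sexes = "M")
  p <- list(M = group_params(3, 0.4))
  count <- generate_trials(d, p, mode = "event_based", seed = 21)
  strict <- generate_trials(d, p, mode = "event_based", seed = 21,
                            count_overrun_handling = FALSE)
  expect_gt(mean(count$eaten), mean(strict$eaten))
})

test_that("generate_trials validates its inputs", {
  expect_error(generate_trials(params = list(F = group_params(1, 0.1))),
               "no parameters")
  expect_error(trial_design(densities = c(0, 2)), "positive")
  expect_error(trial_design(replicates = 0), ">= 1")
  expect_error(group_params(a = NaN, h = 0.1), "finite")
})

test_that("morphology generator hits its moments and correlation", {
  prm <- list(F = group_params(1, 0.1, claw_mean = 11.48, claw_sd = 2.2,
                               carapace_mean = 58, carapace_sd = 7),
              M = group_params(1, 0.1, claw_mean = 16.71, claw_sd = 3.0,
                               carapace_mean = 67, carapace_sd = 6))
  m <- generate_morphology(10000, prm, rho = 0.7, seed = 23)
  for (g in c("F", "M")) {
    sub <- m[m$sex == g, ]
    p <- prm[[g]]
    se <- p$claw_sd / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$claw_mm) - p$claw_mean), 3 * se)
    expect_lt(abs(stats::sd(sub$claw_mm) - p$claw_sd), 0.1)
    ci <- stats::cor.test(sub$claw_mm, sub$carapace_mm)$conf.int
    expect_true(0.7 >= ci[1] - 0.02 && 0.7 <= ci[2] + 0.02)
  }
  # degenerate: zero claw spread pins every claw at the mean
  m0 <- generate_morphology(20, list(F = group_params(1, .1, claw_sd = 0),
                                     M = group_params(1, .1, claw_sd = 0)),
                            seed = 3)
  expect_true(all(m0$claw_mm[m0$sex == "F"] ==
                    m0$claw_mm[m0$sex == "F"][1]))
  expect_error(generate_morphology(0), ">= 1")
  expect_true(all(m$claw_mm >= 0) && all(m$carapace_mm >= 0))
})

test_that("track generator obeys its limiting behaviours", {
  # never moving: zero path, zero moving time
  still <- generate_tracks(2, track_params(p_move = c(F = 0, M = 0),
                                           duration = 60), seed = 5)
  met <- track_metrics_table(still)
  expect_true(all(met$path_length_cm == 0))
  expect_true(all(met$prop_time_moving == 0))
  expect_true(all(is.na(met$speed_cm_per_s)))

  # always moving at speed v for t seconds: path close to v * t (wall
  # reflections fold the sampled path slightly, so the bound is loose)
  always <- generate_tracks(3, track_params(p_move = c(F = 1, M = 1),
                                            speed = c(F = 2, M = 2),
                                            duration = 100), seed = 6)
  met2 <- track_metrics_table(always)
  expect_equal(met2$path_length_cm, rep(200, 6), tolerance = 0.05)
  expect_true(all(met2$prop_time_moving >= 0.98))
  expect_equal(met2$speed_cm_per_s, rep(2, 6), tolerance = 0.05)

  # configured per-sex speeds and move probabilities are recoverable
  tp <- track_params(speed = c(F = 1.5, M = 3), p_move = c(F = 0.3, M = 0.7),
                     duration = 600)
  tracks <- generate_tracks(12, tp, seed = 7)
  met3 <- track_metrics_table(tracks)
  for (g in c("F", "M")) {
    sub <- met3[met3$sex == g, ]
    expect_lt(abs(mean(sub$speed_cm_per_s) - tp$speed[[g]]), 0.1)
    expect_lt(abs(mean(sub$prop_time_moving) - tp$p_move[[g]]), 0.12)
  }
  # positions stay inside the arena
  expect_true(all(tracks$x >= 0 & tracks$x <= 61))
  expect_true(all(tracks$y >= 0 & tracks$y <= 41))
  expect_error(track_params(arena = c(-1, 41)), "positive")
})

test_that("catch generator reproduces its binomial structure", {
  all_f <- generate_catches(10, catch_sizes = 50, female_proportion = 1,
                            seed = 1)
  expect_true(all(all_f$males == 0))
  big <- generate_catches(40, catch_sizes = 5000, female_proportion = 0.5,
                          seed = 2)
  expect_lt(abs(sum(big$females) / sum(big$females + big$males) - 0.5), 0.01)

  q <- 0.41
  cc <- generate_catches(42, catch_sizes = 80, female_proportion = q, seed = 3)
  props <- cc$females / (cc$females + cc$males)
  se <- sqrt(q * (1 - q) / 80 / 42)
  expect_lt(abs(mean(props) - q), 3.5 * se)
  expect_error(generate_catches(female_proportion = 1.2), "\\[0, 1\\]")
})

test_that("prey sizes land in range, split by consumption, honour offsets", {
  tr <- generate_trials(seed = 44)
  prey <- generate_prey_sizes(tr, seed = 45)
  expect_identical(nrow(prey), sum(tr$n0))
  agg <- tapply(prey$consumed, prey$trial_id, sum)
  expect_identical(as.integer(agg[as.character(tr$trial_id)]), tr$eaten)
  expect_true(all(prey$length_mm >= 25 & prey$length_mm <= 40))
  off <- generate_prey_sizes(tr, sex_offset = c(F = 1.4, M = -1.4), seed = 46)
  gap <- mean(off$length_mm[off$sex == "F"]) - mean(off$length_mm[off$sex == "M"])
  expect_gt(gap, 1.5)
})
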