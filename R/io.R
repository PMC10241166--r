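#' Validate a foraging-trial dataset
#'
#' Reads a trials table from a CSV path or data frame and enforces the
#' trial invariants with row-level messages: required columns present,
#' \code{n0 >= 1} integral, \code{0 <= eaten <= n0}, positive duration,
#' finite morphology where supplied.
#'
#' @param x CSV path or data frame.
#' @return the validated data frame (with \code{duration_T} filled in if
#'   absent), or an error listing every offending row/column.
#' @export
validate_trials <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("no such file: ", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop("`x` must be a data frame or CSV path")
  problems <- character()
  need <- c("trial_id", "sex", "n0", "eaten")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(x$duration_T)) x$duration_T <- 1

  bad <- which(!is.finite(x$n0) | x$n0 < 1 | x$n0 != round(x$n0))
  if (length(bad)) {
    problems <- c(problems, paste0("row ", bad, ": n0 must be a positive integer"))
  }
  bad <- which(!is.finite(x$eaten) | x$eaten < 0 | x$eaten > x$n0)
  if (length(bad)) {
    problems <- c(problems, paste0("row ", bad, ": eaten must lie in [0, n0]"))
  }
  bad <- which(!is.finite(x$duration_T) | x$duration_T <= 0)
  if (length(bad)) {
    problems <- c(problems, paste0("row ", bad, ": duration_T must be > 0"))
  }
  for (col in intersect(c("claw_mm", "carapace_mm"), names(x))) {
    bad <- which(!is.finite(x[[col]]) | x[[col]] < 0)
    if (length(bad)) {
      problems <- c(problems, paste0("row ", bad, ": ", col,
                                     " must be finite and >= 0"))
    }
  }
  if (length(problems)) {
    stop("invalid trials table:\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "))
  }
  x
}

#' Pipeline configuration
#'
#' Bundles every tunable of a full analysis run.  One master seed
#' deterministically spawns per-stage seeds, so a stage can be re-run in
#' isolation and still match the full pipeline.
#'
#' @param seed master integer seed.
#' @param design a [trial_design()].
#' @param params named list of [group_params()].
#' @param mode trial-generation mode (see [generate_trials()]).
#' @param boot_iter bootstrap iterations for both the functional
#'   response and the GLM.
#' @param morphology_term \code{"claw"} or \code{"carapace"}.
#' @param q_step grid step of the sex-ratio sweep.
#' @param density_policy \code{"average"} or \code{"fixed"} (see
#'   [sexratio_sweep()]).
#' @param survey_n_per_sex animals per sex in the simulated morphology
#'   survey.
#' @param n_periods,female_proportion trapping-record settings (see
#'   [generate_catches()]).
#' @param trials_csv optional path to a real trials CSV; when supplied
#'   the simulation stage is skipped and the file is validated and used.
#' @return list of class \code{fr_config}.
#' @export
fr_config <- function(seed = 1L, design = trial_design(),
                      params = crab_defaults(),
                      mode = "expectation_binomial",
                      boot_iter = 2000L,
                      morphology_term = "claw",
                      q_step = 0.01,
                      density_policy = "average",
                      survey_n_per_sex = c(F = 197L, M = 175L),
                      n_periods = 42L,
                      female_proportion = 0.5,
                      trials_csv = NULL) {
  structure(list(seed = as.integer(seed), design = design, params = params,
                 mode = mode, boot_iter = as.integer(boot_iter),
                 morphology_term = morphology_term, q_step = q_step,
                 density_policy = density_policy,
                 survey_n_per_sex = survey_n_per_sex,
                 n_periods = as.integer(n_periods),
                 female_proportion = female_proportion,
                 trials_csv = trials_csv),
            class = "fr_config")
}

#' Write / read a pipeline configuration
#'
#' Lossless YAML round-trip of an [fr_config()].
#'
#' @param config an \code{fr_config}.
#' @param path file path.
#' @return \code{write_config} returns \code{path} invisibly;
#'   \code{read_config} returns the \code{fr_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fr_config"))
  x <- unclass(config)
  x$design <- unclass(x$design)
  x$params <- lapply(x$params, unclass)
  x$survey_n_per_sex <- as.list(x$survey_n_per_sex)  # keep names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$design <- do.call(trial_design, x$design)
  x$params <- lapply(x$params, function(p) do.call(group_params, p))
  if (!is.null(x$survey_n_per_sex)) x$survey_n_per_sex <- unlist(x$survey_n_per_sex)
  do.call(fr_config, x)
}

# per-stage seeds derived from the master seed (kept well inside 32-bit)
.stage_seed <- function(seed, k) (as.integer(seed) %% 20000000L) * 97L + k

#' Run the full analysis pipeline
#'
#' Simulates (or loads) foraging trials, determines the response type
#' per sex, fits the Rogers Type II model per sex, bootstraps, computes
#' the between-sex contrasts (consumption at the highest density,
#' maximum consumption, FRR ratio), fits and bootstraps the consumption
#' GLM, runs the sex-ratio sweep, and summarises a morphology survey and
#' trapping records.  With \code{out_dir} set, writes every stage table
#' as plain CSV plus a key/value \code{report.txt}; outputs are a
#' deterministic function of the config (identical config, identical
#' bytes).
#'
#' @param config an [fr_config()].
#' @param out_dir optional output directory (created if needed).
#' @return named list with all stage results, invisibly when writing.
#' @export
run_pipeline <- function(config = fr_config(), out_dir = NULL) {
  stopifnot(inherits(config, "fr_config"))
  sexes <- config$design$sexes

  trials <- if (!is.null(config$trials_csv)) {
    validate_trials(config$trials_csv)
  } else {
    generate_trials(config$design, config$params, mode = config$mode,
                    seed = .stage_seed(config$seed, 1L))
  }

  by_sex <- split(trials, trials$sex)
  types <- lapply(by_sex, function(tr) {
    tt <- type_test(tr)
    tt$fit <- NULL
    tt
  })
  fits <- lapply(by_sex, fit_type2)
  boots <- lapply(seq_along(sexes), function(i)
    stratified_bootstrap(by_sex[[sexes[i]]], n_iter = config$boot_iter,
                         seed = .stage_seed(config$seed, 1L + i)))
  names(boots) <- sexes

  nmax <- max(config$design$densities)
  contrasts <- list(
    consumption_at_max_density =
      group_difference_at_density(boots[[sexes[2L]]], boots[[sexes[1L]]],
                                  n0 = nmax, T = config$design$duration_T),
    frr_ratio = frr_ratio_contrast(boots[[sexes[2L]]], boots[[sexes[1L]]])
  )

  bg <- bootstrap_glm(trials, n_iter = config$boot_iter,
                      seed = .stage_seed(config$seed, 4L),
                      morphology_term = config$morphology_term)
  survey <- generate_morphology(config$survey_n_per_sex, config$params,
                                seed = .stage_seed(config$seed, 5L))
  dim_claw <- dimorphism_stats(survey, "claw")
  dim_cara <- dimorphism_stats(survey, "carapace")

  sweep <- sexratio_sweep(bg$fit, bg$boot,
                          claw_female = dim_claw$mean_by_sex[[1L]],
                          claw_male = dim_claw$mean_by_sex[[2L]],
                          q_grid = seq(0, 1, by = config$q_step),
                          densities = config$design$densities,
                          density_policy = config$density_policy)

  catches <- generate_catches(config$n_periods,
                              female_proportion = config$female_proportion,
                              seed = .stage_seed(config$seed, 6L))
  ratios <- sexratio_estimates(catches)

  res <- list(config = config, trials = trials, type_tests = types,
              fits = fits, boots = boots, contrasts = contrasts,
              glm = bg, survey = survey,
              dimorphism = list(claw = dim_claw, carapace = dim_cara),
              sweep = sweep, catches = catches, sexratios = ratios)
  if (!is.null(out_dir)) {
    .write_pipeline(res, out_dir)
    return(invisible(res))
  }
  res
}

.write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(res$trials, "trials.csv")
  sexes <- names(res$fits)
  fits_df <- do.call(rbind, lapply(sexes, function(g) {
    f <- res$fits[[g]]
    data.frame(sex = g, a_hat = f$a_hat, h_hat = f$h_hat,
               log_likelihood = f$log_likelihood, aicc = f$aicc,
               n_trials = f$n_trials, converged = f$converged)
  }))
  wcsv(fits_df, "fits.csv")
  for (g in sexes) wcsv(res$boots[[g]]$draws, paste0("boot_draws_", g, ".csv"))
  ctr_df <- do.call(rbind, lapply(names(res$contrasts), function(nm) {
    ct <- res$contrasts[[nm]]
    data.frame(contrast = nm, estimate = ct$estimate, ci_low = ct$ci_low,
               ci_high = ct$ci_high, significant = ct$significant,
               n_used = ct$n_used)
  }))
  wcsv(ctr_df, "contrasts.csv")
  wcsv(coef_table(res$glm$fit), "glm_coefficients.csv")
  wcsv(res$sweep$curve, "sweep.csv")
  wcsv(res$sexratios$per_site, "sexratios.csv")

  rep_lines <- c(
    sprintf("seed: %d", res$config$seed),
    sprintf("n_trials: %d", nrow(res$trials)),
    unlist(lapply(sexes, function(g) c(
      sprintf("type_first_order_coef_%s: %.6f", g,
              res$type_tests[[g]]$first_order_coef),
      sprintf("attack_rate_%s: %.6f", g, res$fits[[g]]$a_hat),
      sprintf("handling_time_%s: %.6f", g, res$fits[[g]]$h_hat),
      sprintf("max_consumption_%s: %.6f", g,
              max_consumption(res$fits[[g]]$h_hat)),
      sprintf("frr_%s: %.6f", g,
              frr(res$fits[[g]]$a_hat, res$fits[[g]]$h_hat)),
      sprintf("boot_failed_%s: %d", g, res$boots[[g]]$n_failed)))),
    sprintf("frr_ratio: %.6f", res$contrasts$frr_ratio$estimate),
    sprintf("glm_boot_failed: %d", res$glm$n_failed),
    sprintf("threshold_q: %s",
            if (is.na(res$sweep$threshold_q)) "none" else
              sprintf("%.2f", res$sweep$threshold_q))
  )
  writeLines(rep_lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
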