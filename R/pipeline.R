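# End-to-end orchestration: simulate reference (and optional treatment)
# cohorts, extract the eleven parameters, build the solitariness model,
# score animals on the P-sol scale, and emit comparison + summary reports.
# Every numeric output is a pure function of the config (incl. its seed).

#' Serialize a solitariness model to JSON
#'
#' @param model A `"psol_logit"` model.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_psol_model <- function(model, path) {
  obj <- list(variables = model$variables,
              beta0 = unname(model$coefficients["(Intercept)"]),
              beta = as.list(model$coefficients[model$variables]),
              se = as.list(model$se),
              loglik = model$loglik, n = model$n,
              selection_path = model$path)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a solitariness model from JSON
#'
#' Reconstructs a scoring-capable `"psol_logit"` object (coefficients and
#' standard errors; no training data).
#'
#' @param path JSON path written by [write_psol_model()].
#' @return A `"psol_logit"` model.
#' @export
read_psol_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- c("(Intercept)", obj$variables)
  beta <- stats::setNames(c(obj$beta0, unlist(obj$beta)[obj$variables]), nm)
  se <- stats::setNames(unlist(obj$se)[nm], nm)
  wald <- (beta / se)^2
  structure(
    list(coefficients = beta, se = se, wald = wald,
         df = stats::setNames(rep(1L, length(nm)), nm),
         p.values = stats::setNames(stats::pchisq(wald, 1, lower.tail = FALSE), nm),
         exp_beta = exp(beta), vcov = NULL,
         loglik = if (is.null(obj$loglik)) NA_real_ else obj$loglik,
         n = obj$n, variables = obj$variables,
         fitted = NULL, y = NULL, converged = TRUE, iterations = 0L,
         path = obj$selection_path, call = quote(read_psol_model())),
    class = "psol_logit")
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults: arena
#' geometry, movement-bout detector, simulator phase parameters, model
#' building and output settings. Print the returned list to inspect every
#' default.
#'
#' @param show If `TRUE`, also print the configuration.
#' @return Nested configuration list.
#' @export
default_config <- function(show = FALSE) {
  cfg <- list(
    arena = list(test_length = 25, width = 30, stimulus_zone_fraction = 0.25,
                 wall_band = 2, stimulus_side = "low_x"),
    movement = list(start_speed = 1.0, stop_speed = 0.5, min_bout = 0.5,
                    min_step = 0),
    simulation = list(
      gregarious = list(p_start_move = 0.5, p_stop_move = 0.1,
                        speed_mean = 3, speed_sd = 1, turn_concentration = 4,
                        stimulus_bias = 0.6, wall_affinity = 0),
      solitary = list(p_start_move = 0.05, p_stop_move = 0.5,
                      speed_mean = 1.5, speed_sd = 0.5, turn_concentration = 4,
                      stimulus_bias = -0.4, wall_affinity = 0.5),
      duration = 360, dt = 0.08, seed = 1, n_per_group = 100),
    model = list(type = "stepwise", p_enter = 0.05),
    output = list(write_trajectories = FALSE))
  if (show) utils::str(cfg)
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML file with any subset of the sections of [default_config()]; missing
#' entries take their defaults.
#'
#' @param path YAML config path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge2(default_config(), user)
}

.cfg_arena <- function(cfg) do.call(arena_geometry, cfg$arena)
.cfg_movement <- function(cfg) do.call(movement_params, cfg$movement)
.cfg_sim <- function(cfg) {
  s <- cfg$simulation
  sim_config(gregarious = do.call(phase_params, s$gregarious),
             solitary = do.call(phase_params, s$solitary),
             duration = s$duration, dt = s$dt, seed = s$seed,
             n_per_group = s$n_per_group)
}

#' Run the full behavioral-phenotyping pipeline
#'
#' Simulates the reference gregarious and solitary cohorts, extracts the
#' eleven behavioral parameters, builds the solitariness model (forward
#' stepwise by default, or the fixed reference discriminant with
#' `model$type = "reference"`), scores every animal on the P-sol scale,
#' compares the two phases (Mann-Whitney U on P-sol) and writes the
#' reports.
#'
#' @param config A configuration list from [default_config()] /
#'   [read_config()], or a YAML path.
#' @param out_dir Output directory (created if needed). Files written:
#'   `features.csv`, `model.json`, `scores.csv`, `comparisons.csv`,
#'   `psol_summary.csv`, `manifest.json` (plus `trajectories.csv` if
#'   requested in the config).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the run manifest (config snapshot, seed, output paths,
#'   per-stage row counts, package version).
#' @export
run_all <- function(config = default_config(), out_dir = tempfile("lp_run_"),
                    quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- .cfg_arena(config)
  mp <- .cfg_movement(config)
  scfg <- .cfg_sim(config)

  say("[simulate] %d animals per phase, %g s at dt = %g s",
      scfg$n_per_group, scfg$duration, scfg$dt)
  cohort <- simulate_cohort(scfg, g)
  if (!length(cohort))
    .lp_stop("empty cohort: simulation.n_per_group is 0", "lp_contract_error")

  say("[extract] %d trajectories", length(cohort))
  feats <- extract_features_cohort(cohort, g, mp)

  say("[fit] %s model", config$model$type)
  model <- switch(config$model$type,
    stepwise = forward_stepwise(feats, outcome = "phase",
                                p_enter = config$model$p_enter),
    reference = psol_reference_model(),
    .lp_stop(sprintf("unknown model type '%s'", config$model$type),
             "lp_contract_error"))

  say("[score] %d animals", nrow(feats))
  scores <- score_psol(model, feats)
  scores$phase <- feats$phase
  sol <- scores$psol[scores$phase == "solitary"]
  greg <- scores$psol[scores$phase == "gregarious"]

  say("[compare] solitary vs gregarious P-sol")
  contrast <- mann_whitney_u(sol, greg)
  sum_sol <- summarize_psol(sol)
  sum_greg <- summarize_psol(greg)

  paths <- list(features = file.path(out_dir, "features.csv"),
                model = file.path(out_dir, "model.json"),
                scores = file.path(out_dir, "scores.csv"),
                comparisons = file.path(out_dir, "comparisons.csv"),
                psol_summary = file.path(out_dir, "psol_summary.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  if (isTRUE(config$output$write_trajectories)) {
    paths$trajectories <- file.path(out_dir, "trajectories.csv")
    write_trajectories(cohort, paths$trajectories)
  }
  write_features(feats, paths$features)
  write_psol_model(model, paths$model)
  utils::write.csv(scores, paths$scores, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(contrast = "psol_solitary_vs_gregarious",
               test = contrast$test, statistic = contrast$statistic,
               p = contrast$p, n1 = contrast$n_per_group[1],
               n2 = contrast$n_per_group[2]),
    paths$comparisons, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(phase = rep(c("solitary", "gregarious"), each = 6),
               quantity = rep(c("median", names(sum_sol$bins)), 2),
               value = c(sum_sol$median, unname(sum_sol$bins),
                         sum_greg$median, unname(sum_greg$bins))),
    paths$psol_summary, row.names = FALSE, quote = FALSE)

  manifest <- list(
    config = config, seed = scfg$seed,
    version = as.character(utils::packageVersion("locustphase")),
    outputs = lapply(paths, identity),
    rows = list(trajectories = length(cohort), features = nrow(feats),
                scores = nrow(scores)),
    results = list(median_psol_solitary = sum_sol$median,
                   median_psol_gregarious = sum_greg$median,
                   mann_whitney_u = contrast$statistic,
                   mann_whitney_p = contrast$p,
                   model_variables = model$variables))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("[done] %d outputs in %s", length(paths), out_dir)
  invisible(manifest)
}

#' Score a feature file with a serialized model
#'
#' @param features_path Feature CSV written by [write_features()].
#' @param model_path Model JSON written by [write_psol_model()], or a
#'   `"psol_logit"` object.
#' @return List with `scores` (per-subject data frame: subject_id, eta,
#'   psol) and `summary` (a `"psol_summary"`).
#' @export
score_cohort <- function(features_path, model_path) {
  feats <- read_features(features_path)
  if (!nrow(feats))
    .lp_stop("empty feature file", "lp_contract_error")
  model <- if (inherits(model_path, "psol_logit")) model_path
           else read_psol_model(model_path)
  scores <- score_psol(model, feats)
  list(scores = scores, summary = summarize_psol(scores))
}
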