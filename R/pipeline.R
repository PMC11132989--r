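#' Run the full diffusion-analysis pipeline
#'
#' One reproducible pass over an experiment: load (or simulate) the data,
#' validate, summarize individuals, fit the candidate model set over the
#' dynamic networks, compute profile CI and %ST for the best social model,
#' optionally fit the multistate extension and the observation-network
#' GLMM, and write the model table, a machine-readable summary and a
#' human-readable report. Every artifact is stamped with a hash of the
#' configuration and the seed.
#'
#' @param config a list (or path to a YAML file) with components:
#'   \describe{
#'     \item{`input`}{list with `events`, `ilv` and optional `kin` paths —
#'       or instead}
#'     \item{`simulation`}{arguments for [simulation_config()]; exactly one
#'       of `input`/`simulation` must be present.}
#'     \item{`model_set`}{configuration for [enumerate_model_set()].}
#'     \item{`inference`}{`level` (default 0.95) and `seed` (required for a
#'       simulation block; overrides the simulation seed).}
#'     \item{`multistate`}{fit the two-stage extension (default: only when
#'       first-manipulation events are present).}
#'     \item{`obsnet`}{fit the observation-network GLMM (default `FALSE`);
#'       `obsnet_iter` kept iterations (default 1000).}
#'     \item{`output_dir`}{optional directory for `model_table.csv`,
#'       `summary.json` and `report.txt`.}
#'   }
#' @return Object of class `pipeline_report` (the summary structure,
#'   invisibly written to `output_dir` when given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (sum(c("input", "simulation") %in% names(config)) != 1)
    stop("run_pipeline: exactly one of `input` or `simulation` must be given",
         call. = FALSE)
  level <- config$inference$level %||% 0.95
  seed <- config$inference$seed

  warnings_seen <- character(0)
  note <- function(w) { warnings_seen <<- c(warnings_seen, conditionMessage(w))
                        invokeRestart("muffleWarning") }

  if (!is.null(config$simulation)) {
    # YAML parses numeric vectors as lists; flatten atomic components
    sim_args <- lapply(config$simulation, function(x)
      if (is.list(x) && length(x) && all(vapply(x, is.atomic, TRUE))) unlist(x) else x)
    if (!is.null(seed)) sim_args$seed <- seed
    if (is.null(sim_args$seed)) stop("run_pipeline: simulation needs a seed",
                                     call. = FALSE)
    scfg <- do.call(simulation_config, sim_args)
    study <- simulate_diffusion(scfg)
    log <- study$log; ilv <- study$ilv
    truth <- study$truth
  } else {
    ilv <- load_ilv_table(config$input$ilv, config$input$kin)
    log <- load_event_log(config$input$events, ilv)
    truth <- NULL
  }
  validate_event_log(log, ilv)
  summaries <- summarize_individuals(log, ilv)

  specs <- enumerate_model_set(config$model_set %||% list())
  mset <- withCallingHandlers(fit_model_set(specs, log, ilv), warning = note)
  tab <- mset$table
  social <- which(tab$s_constraint != "asocial")
  best_i <- social[which.min(tab$aicc[social])]
  best <- mset$fits[[best_i]]
  ci <- profile_ci_s(best, level = level)
  pst <- percent_st_ci(best, ci = ci)

  support_net <- total_support(mset, by = "network")
  support_hyp <- total_support(mset, by = "hypothesis")

  ms_enabled <- config$multistate %||% (nrow(log$first_manipulations) > 0)
  ms <- NULL
  if (isTRUE(ms_enabled) && nrow(log$first_manipulations) > 0)
    ms <- withCallingHandlers(
      fit_multistate(multistate_data(log, ilv),
                     config$model_set %||% list(), level = level),
      warning = note)

  obs <- NULL
  if (isTRUE(config$obsnet)) {
    design <- build_obs_design(log, ilv)
    post <- mcmc_sample(design, n_iter = config$obsnet_iter %||% 1000,
                        seed = seed %||% 1)
    obs <- list(odds_ratios = odds_ratios_hpd(post, level = level, force = TRUE),
                rhat = rhat(post))
  }

  tied <- attr(acquisition_events(log, ilv), "tied_blocks")
  if (length(tied))
    warnings_seen <- c(warnings_seen, sprintf(
      "%d tied acquisition block(s) broken by event-log order", length(tied)))

  summary <- list(
    config_hash = config_hash(config), seed = seed,
    n_individuals = nrow(ilv), n_solve_events = nrow(log$solves),
    n_learners = count_learners(summaries),
    min_observations_among_learners =
      if (count_learners(summaries) > 0) min_observations_among_learners(summaries)
      else NA,
    best_model = tab[best_i, c("network", "s_constraint", "ilv_asocial",
                               "ilv_social", "aicc")],
    s_estimate = as.list(best$params$s_by_group),
    s_profile_ci = as.list(ci), percent_st = as.list(pst),
    percent_st_method = "event-wise attribution",
    support_by_network = as.list(support_net),
    support_by_hypothesis = as.list(support_hyp),
    truth = truth, warnings = warnings_seen)

  report <- structure(list(summary = summary, model_table = tab,
                           summaries = summaries, best_fit = best,
                           multistate = ms, obsnet = obs),
                      class = "pipeline_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$output_dir, "model_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(utils::capture.output(print(report)),
               file.path(config$output_dir, "report.txt"))
  }
  report
}

# Polynomial rolling hash of the JSON-serialized analytical configuration
# (stamping only; the output location is not part of the analysis).
config_hash <- function(config) {
  config$output_dir <- NULL
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                   force = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("== diffusion analysis report ==\n")
  cat(sprintf("config %s | seed %s | %d individuals | %d solve events\n",
              s$config_hash, s$seed %||% "-", s$n_individuals, s$n_solve_events))
  cat(sprintf("learners: %d | minimum observations among learners: %s\n",
              s$n_learners, s$min_observations_among_learners))
  cat(sprintf("best social model: %s / %s (AICc %.2f)\n",
              s$best_model$network, s$best_model$s_constraint, s$best_model$aicc))
  cat("  s estimates:", paste(sprintf("%s=%.4g", names(s$s_estimate),
                                      unlist(s$s_estimate)), collapse = ", "), "\n")
  cat(sprintf("  s profile CI: [%.4g, %.4g] | %%ST: [%.1f, %.1f] (%s)\n",
              s$s_profile_ci$lower, s$s_profile_ci$upper,
              s$percent_st$lower, s$percent_st$upper, s$percent_st_method))
  cat("support by network (%):",
      paste(sprintf("%s %.1f", names(s$support_by_network),
                    unlist(s$support_by_network)), collapse = ", "), "\n")
  cat("support by hypothesis (%):",
      paste(sprintf("%s %.1f", names(s$support_by_hypothesis),
                    unlist(s$support_by_hypothesis)), collapse = ", "), "\n")
  if (!is.null(x$multistate)) print(x$multistate)
  if (length(s$warnings)) {
    cat("warnings:\n"); for (w in unique(s$warnings)) cat("  -", w, "\n")
  }
  invisible(x)
}
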