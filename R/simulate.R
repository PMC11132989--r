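#' Configuration of a synthetic diffusion experiment
#'
#' Defaults emulate the study design the package analyses: two groups of 33
#' with one trained mid/high-ranking adult female demonstrator each, 39
#' two-hour sessions on a concatenated experimental-time axis,
#' observation propensities concentrated on a subset of individuals, and
#' acquisition hazards of the social/asocial rate form
#' `lambda0 * (s_g * exposure * exp(gamma' x) + exp(beta' x))`.
#'
#' @param n_groups number of groups.
#' @param n_per_group individuals per group (demonstrator included).
#' @param n_demonstrators trained demonstrators per group.
#' @param n_sessions,session_hours session structure; the experimental time
#'   axis is their concatenation (`n_sessions * session_hours` hours).
#' @param demo_solve_rate solves per hour of a trained demonstrator.
#' @param learner_solve_rate solves per hour of an individual after it
#'   acquires the skill.
#' @param attendance_beta shape parameters of the Beta distribution of
#'   per-individual attendance (probability of observing any given solve in
#'   the same group).
#' @param age_range uniform range of ages (years).
#' @param kin_density probability that a within-group dyad is maternal kin.
#' @param s_by_group true social-transmission parameter per group.
#' @param beta_asocial,gamma_social true ILV coefficients (named subsets of
#'   sex/age/rank) on the asocial and social rates.
#' @param baseline_rate asocial baseline hazard `lambda0` (per hour); the
#'   order likelihood cancels it, so it only sets the pace of the
#'   simulation.
#' @param two_stage simulate the naive -> interacting -> informed process.
#' @param s_stage2,baseline_rate_stage2 stage-2 (interacting -> informed)
#'   truth when `two_stage = TRUE`; stage 1 then uses `s_by_group` and
#'   `baseline_rate`.
#' @param max_acquisitions stop once this many untrained individuals have
#'   acquired (`NULL`: run to the end of the sessions).
#' @param seed integer seed (mandatory).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_groups = 2, n_per_group = 33,
                              n_demonstrators = 1, n_sessions = 39,
                              session_hours = 2, demo_solve_rate = 25,
                              learner_solve_rate = 5,
                              attendance_beta = c(0.5, 5),
                              age_range = c(8, 40), kin_density = 0.03,
                              s_by_group = rep(1, n_groups),
                              beta_asocial = c(sex = 0, age = 0, rank = 0),
                              gamma_social = c(sex = 0, age = 0, rank = 0),
                              baseline_rate = 0.001, two_stage = FALSE,
                              s_stage2 = rep(1, n_groups),
                              baseline_rate_stage2 = 0.01,
                              max_acquisitions = NULL, seed) {
  if (missing(seed)) stop("simulation_config: seed is mandatory", call. = FALSE)
  stopifnot(demo_solve_rate > 0, learner_solve_rate > 0, baseline_rate > 0,
            n_sessions > 0, session_hours > 0)
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a study population
#'
#' Sexes Bernoulli(0.5), ages uniform on the configured range, ranks a
#' within-group permutation score, kin dyads sampled at the configured
#' density, attendance propensities Beta-distributed, and one mid/high-rank
#' female per group flagged as the trained demonstrator.
#'
#' @param config a [simulation_config()].
#' @return List with `ilv` (an [ilv_table()]) and `attendance` (named
#'   propensity vector).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rows <- list(); kin <- list(); attendance <- c()
  for (g in seq_len(config$n_groups)) {
    n <- config$n_per_group
    ids <- sprintf("g%d_i%02d", g, seq_len(n))
    sex <- stats::rbinom(n, 1, 0.5)
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    rank <- sample(seq_len(n))
    trained <- rep(FALSE, n)
    if (config$n_demonstrators > 0 && n > 1) {
      # mid/high-ranking adult females; fall back to the top-ranked female,
      # then to the top-ranked individual
      cand <- which(sex == 0 & rank >= stats::median(rank))
      if (!length(cand)) cand <- which(sex == 0)
      if (!length(cand)) cand <- seq_len(n)
      cand <- cand[order(-rank[cand])]
      trained[cand[seq_len(min(config$n_demonstrators, length(cand)))]] <- TRUE
    }
    rows[[g]] <- data.frame(id = ids, group = g, sex = sex, age = age,
                            rank = rank, trained = trained,
                            stringsAsFactors = FALSE)
    if (config$kin_density > 0 && n > 1) {
      pairs <- utils::combn(ids, 2)
      pick <- stats::runif(ncol(pairs)) < config$kin_density
      if (any(pick)) kin[[length(kin) + 1]] <- t(pairs[, pick, drop = FALSE])
    }
    attendance <- c(attendance, stats::setNames(
      stats::rbeta(n, config$attendance_beta[1], config$attendance_beta[2]), ids))
  }
  ilv <- ilv_table(do.call(rbind, rows),
                   kin = if (length(kin)) do.call(rbind, kin) else NULL)
  list(ilv = ilv, attendance = attendance)
}

#' Simulate an open-diffusion experiment with known ground truth
#'
#' Continuous-time discrete-event simulation via competing exponentials:
#' informed individuals solve as Poisson processes; each solve is observed
#' by each other same-group individual independently with its attendance
#' propensity; naive untrained individuals acquire with hazard
#' `lambda0 * (s_g * exposure + exp(beta' x))` (exposure: number of solves
#' observed, updated at observation events), the social term multiplied by
#' `exp(gamma' x)`. An acquirer's first solve is appended as a solve event
#' (and can itself be observed). In two-stage mode a first-manipulation
#' event stream with stage-specific hazards is inserted before solving.
#' Hazards are constant between events, so the generated acquisition order
#' follows exactly the order likelihood the package fits.
#'
#' @param config a [simulation_config()].
#' @param population result of [simulate_population()] (regenerated from
#'   `config` when missing; note both draw from the seeded stream).
#' @return Object of class `simulated_study`: list with `log`
#'   (an [event_log()]), `ilv`, `attendance` and `truth`.
#' @export
simulate_diffusion <- function(config, population = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(population)) population <- simulate_population(config)
  ilv <- population$ilv
  attendance <- population$attendance
  N <- nrow(ilv)
  ids <- ilv$id
  T_total <- config$n_sessions * config$session_hours
  untrained <- !ilv$trained

  ilv_centred <- cbind(sex = as.numeric(ilv$sex),
                       age = ilv$age - mean(ilv$age[untrained]),
                       rank = ilv$rank - stats::median(ilv$rank[untrained]))
  lincomb <- function(coefs) {
    if (!length(coefs)) return(rep(0, N))
    drop(ilv_centred[, names(coefs), drop = FALSE] %*% coefs)
  }
  asoc1 <- exp(lincomb(config$beta_asocial))
  soc1 <- exp(lincomb(config$gamma_social))
  s1 <- config$s_by_group[ilv$group]
  s2 <- config$s_stage2[ilv$group]

  # states: 0 naive, 1 interacting (two-stage only), 2 informed
  state <- ifelse(ilv$trained, 2L, 0L)
  solve_rate <- ifelse(ilv$trained, config$demo_solve_rate, 0)
  exposure_n <- rep(0, N)
  n_acquired <- 0L

  solves <- list(); observations <- list(); manips <- list()
  t <- 0
  repeat {
    if (config$two_stage) {
      h1 <- ifelse(untrained & state == 0L,
                   config$baseline_rate * (s1 * exposure_n * soc1 + asoc1), 0)
      h2 <- ifelse(untrained & state == 1L,
                   config$baseline_rate_stage2 * (s2 * exposure_n * soc1 + asoc1), 0)
      hazards <- h1 + h2
    } else {
      hazards <- ifelse(untrained & state == 0L,
                        config$baseline_rate * (s1 * exposure_n * soc1 + asoc1), 0)
    }
    total_rate <- sum(solve_rate) + sum(hazards)
    if (total_rate <= 0) break
    t <- t + stats::rexp(1, total_rate)
    if (t > T_total) break
    # which event?
    pick <- sample.int(2 * N, 1, prob = c(solve_rate, hazards))
    if (pick <= N) { # a solve by an informed individual
      i <- pick
      record_solve <- TRUE
    } else { # a state transition of a naive/interacting individual
      i <- pick - N
      if (config$two_stage && state[i] == 0L) {
        state[i] <- 1L
        manips[[length(manips) + 1]] <- c(t, i)
        next
      }
      # acquisition: first solve
      state[i] <- 2L
      solve_rate[i] <- config$learner_solve_rate
      n_acquired <- n_acquired + 1L
      record_solve <- TRUE
    }
    if (record_solve) {
      solves[[length(solves) + 1]] <- c(t, i)
      same <- which(ilv$group == ilv$group[i] & seq_len(N) != i)
      seen <- same[stats::runif(length(same)) < attendance[same]]
      if (length(seen)) {
        for (o in seen)
          observations[[length(observations) + 1]] <- c(t, o, i)
        exposure_n[seen] <- exposure_n[seen] + 1
      }
    }
    if (!is.null(config$max_acquisitions) && n_acquired >= config$max_acquisitions)
      break
  }

  to_df <- function(lst, cols) {
    if (!length(lst)) return(NULL)
    m <- do.call(rbind, lst)
    df <- data.frame(time = m[, 1], stringsAsFactors = FALSE)
    for (j in seq_along(cols)) df[[cols[j]]] <- ids[m[, j + 1]]
    df
  }
  log <- event_log(
    solves = to_df(solves, "id") %||% empty_events("solve"),
    observations = to_df(observations, c("observer", "solver")) %||%
      empty_events("observe"),
    first_manipulations = to_df(manips, "id") %||% empty_events("first_manipulation"))
  truth <- config[c("s_by_group", "beta_asocial", "gamma_social", "baseline_rate",
                    "two_stage", "s_stage2", "baseline_rate_stage2", "seed")]
  structure(list(log = log, ilv = ilv, attendance = attendance,
                 truth = truth, config = config), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> truth s =", paste(x$truth$s_by_group, collapse = ", "), "\n")
  print(x$log)
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Replicates a simulation design, refits the generating model
#' (shared-`s`, no ILVs, matching network) to each replicate, and reports
#' bias, RMSE, the median estimate, profile-CI coverage of the true `s`,
#' and the rate at which the CI excludes 0 (the empirical type-I error when
#' the truth is `s = 0`). Replicate fit failures are recorded, not fatal.
#'
#' @param config a [simulation_config()]; its seed is replaced per
#'   replicate by `seed + replicate`.
#' @param n_replicates number of replicates.
#' @param seed base seed.
#' @param level profile-CI level.
#' @param min_events replicates with fewer acquisition events are recorded
#'   as failures (the AICc sample size must exceed `k + 1`).
#' @return Object of class `recovery_report`: list with `replicates` (data
#'   frame) and `summary`.
#' @export
recovery_experiment <- function(config, n_replicates = 100, seed = 1,
                                level = 0.95, min_events = 3) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- config$s_by_group[1]
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seed + r
    row <- data.frame(replicate = r, K = NA_integer_, s_hat = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      covered = NA, excludes_zero = NA, ok = FALSE,
                      error = "", stringsAsFactors = FALSE)
    res <- try({
      study <- simulate_diffusion(cfg)
      data <- oada_data(study$log, study$ilv, "absolute_observation")
      row$K <- data$K
      if (data$K < min_events) stop("too few acquisition events (", data$K, ")")
      spec <- oada_model_spec("absolute_observation", "s1_eq_s2")
      fit <- fit_oada(spec, data)
      ci <- profile_ci_s(fit, level = level)
      row$s_hat <- unname(fit$params$s_by_group[1])
      row$ci_lower <- ci[["lower"]]; row$ci_upper <- ci[["upper"]]
      row$covered <- ci[["lower"]] <= truth && truth <= ci[["upper"]]
      row$excludes_zero <- ci[["lower"]] > 0
      row$ok <- TRUE
    }, silent = TRUE)
    if (inherits(res, "try-error")) row$error <- conditionMessage(attr(res, "condition"))
    rows[[r]] <- row
  }
  reps <- do.call(rbind, rows)
  ok <- reps$ok
  summary <- list(
    truth_s = truth, n_replicates = n_replicates, n_ok = sum(ok),
    median_s_hat = stats::median(reps$s_hat[ok]),
    bias = mean(reps$s_hat[ok]) - truth,
    rmse = sqrt(mean((reps$s_hat[ok] - truth)^2)),
    ci_coverage = mean(reps$covered[ok]),
    excludes_zero_rate = mean(reps$excludes_zero[ok]),
    mean_events = mean(reps$K[ok]))
  structure(list(replicates = reps, summary = summary, level = level,
                 seed = seed), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<recovery_report> truth s = %g | %d/%d fits ok\n",
                     "  median s_hat %.3f | bias %.3f | rmse %.3f\n",
                     "  CI coverage %.3f | CI excludes 0 in %.3f of runs\n"),
              s$truth_s, s$n_ok, s$n_replicates, s$median_s_hat, s$bias,
              s$rmse, s$ci_coverage, s$excludes_zero_rate))
  invisible(x)
}

#' Write a simulated study to the package's CSV formats
#'
#' Emits `events.csv`, `ilv.csv`, `kin.csv` and `truth.json` into a
#' directory.
#'
#' @param study a [simulate_diffusion()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_event_log(study$log, file.path(dir, "events.csv"))
  ilv <- study$ilv
  utils::write.csv(data.frame(id = ilv$id, group = ilv$group, sex = ilv$sex,
                              age_years = ilv$age, rank = ilv$rank,
                              trained = ilv$trained),
                   file.path(dir, "ilv.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(attr(ilv, "kin")), file.path(dir, "kin.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
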