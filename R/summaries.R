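#' Per-individual observation and acquisition summaries
#'
#' Reproduces the per-individual summary used to describe an open diffusion:
#' the number of observations made before the individual's own first solve
#' (for learners) or before the final solve in its group (for non-learners),
#' whether the skill was acquired, the time available to observe, the rate of
#' observation, and the total number of solves. Trained demonstrators are
#' summarized with `NA` observation fields and are never counted as learners.
#'
#' The observation window closes strictly before a learner's first solve and
#' inclusively at the group's final solve for non-learners. Rates are computed
#' unrounded; rounding to 2 decimals (half-even) happens only at report time.
#'
#' @param log an [event_log()].
#' @param ilv an [ilv_table()].
#' @return A data frame of class `individual_summary` with columns `id`,
#'   `group`, `trained`, `n_observations_pre`, `acquired`,
#'   `observation_time`, `rate_of_observation`, `n_solves`.
#' @export
summarize_individuals <- function(log, ilv) {
  stopifnot(inherits(log, "event_log"), inherits(ilv, "ilv_table"))
  validate_event_log(log, ilv)
  solver_group <- ilv$group[match(log$solves$id, ilv$id)]
  group_end <- vapply(sort(unique(ilv$group)), function(g) {
    tg <- log$solves$time[solver_group == g]
    if (length(tg)) max(tg) else 0
  }, numeric(1))
  names(group_end) <- as.character(sort(unique(ilv$group)))

  first_solve <- tapply(log$solves$time, log$solves$id, min)
  n_solves_all <- table(log$solves$id)

  out <- lapply(seq_len(nrow(ilv)), function(i) {
    id <- ilv$id[i]
    ns <- if (id %in% names(n_solves_all)) as.integer(n_solves_all[[id]]) else 0L
    if (ilv$trained[i]) {
      return(data.frame(id = id, group = ilv$group[i], trained = TRUE,
                        n_observations_pre = NA_integer_, acquired = NA_integer_,
                        observation_time = NA_real_, rate_of_observation = NA_real_,
                        n_solves = ns, stringsAsFactors = FALSE))
    }
    acquired <- as.integer(ns >= 1)
    obs_t <- log$observations$time[log$observations$observer == id]
    if (acquired == 1) {
      window <- unname(first_solve[[id]])
      n_pre <- sum(obs_t < window)           # strictly before own first solve
    } else {
      window <- unname(group_end[[as.character(ilv$group[i])]])
      n_pre <- sum(obs_t <= window)          # inclusive at the closing instant
    }
    rate <- if (window > 0) n_pre / window else 0
    data.frame(id = id, group = ilv$group[i], trained = FALSE,
               n_observations_pre = as.integer(n_pre), acquired = acquired,
               observation_time = window, rate_of_observation = rate,
               n_solves = ns, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("individual_summary", "data.frame")
  out
}

#' @export
print.individual_summary <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$rate_of_observation <- round(y$rate_of_observation, digits)
  print(y, ...)
  invisible(x)
}

#' Number of untrained individuals that acquired the skill
#'
#' @param summaries an `individual_summary` data frame.
#' @return Integer count of learners; trained demonstrators never count.
#' @export
count_learners <- function(summaries) {
  sum(!summaries$trained & !is.na(summaries$acquired) & summaries$acquired == 1)
}

#' Minimum number of pre-acquisition observations among learners
#'
#' @param summaries an `individual_summary` data frame.
#' @return The smallest `n_observations_pre` over untrained learners.
#' @export
min_observations_among_learners <- function(summaries) {
  keep <- !summaries$trained & !is.na(summaries$acquired) & summaries$acquired == 1
  if (!any(keep))
    stop("min_observations_among_learners: no learners in summaries", call. = FALSE)
  min(summaries$n_observations_pre[keep])
}

#' Total baseline exposure hours
#'
#' Exposure-time arithmetic for a baseline phase run in parallel across
#' groups: `months * days_per_month * hours_per_day * n_groups`.
#'
#' @param months,days_per_month,hours_per_day,n_groups positive scalars.
#' @return Total hours of baseline testing.
#' @export
baseline_exposure_hours <- function(months, days_per_month, hours_per_day, n_groups) {
  args <- c(months, days_per_month, hours_per_day, n_groups)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("baseline_exposure_hours: all arguments must be positive", call. = FALSE)
  months * days_per_month * hours_per_day * n_groups
}

#' Load the packaged observation-record table
#'
#' A transcription of the published per-individual observation-record table
#' of the chimpanzee open-diffusion study (62 individuals in two groups; the
#' two trained demonstrators carry `NA` observation fields). The printed
#' rate-of-observation column is kept verbatim as `printed_rate`;
#' `rate_of_observation` is recomputed unrounded from the printed counts and
#' hours.
#'
#' @return An `individual_summary` data frame with an extra `printed_rate`
#'   column.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "socdiff", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(
    id = raw$chimpanzee, group = as.integer(raw$group),
    trained = as.logical(raw$trained),
    n_observations_pre = as.integer(raw$n_observations),
    acquired = as.integer(raw$acquired),
    observation_time = as.numeric(raw$observation_time_h),
    rate_of_observation = ifelse(is.na(raw$observation_time_h) |
                                   raw$observation_time_h == 0, 0,
                                 raw$n_observations / raw$observation_time_h),
    n_solves = as.integer(raw$n_solves),
    printed_rate = as.numeric(raw$rate_of_observation),
    stringsAsFactors = FALSE)
  out$rate_of_observation[is.na(raw$n_observations)] <- NA_real_
  class(out) <- c("individual_summary", "data.frame")
  out
}
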