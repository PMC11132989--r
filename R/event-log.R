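#' Event log of an open-diffusion experiment
#'
#' An `event_log` holds the three time-ordered event streams of a diffusion
#' experiment on a cumulative experimental-time axis (hours from the start of
#' the social-learning phase): successful solves, observations of solves, and
#' first manipulations of the apparatus.
#'
#' @param solves data frame with columns `time`, `id`.
#' @param observations data frame with columns `time`, `observer`, `solver`.
#' @param first_manipulations data frame with columns `time`, `id`.
#' @param phase optional phase label attached to the log.
#'
#' @return An object of class `event_log`: a list with components `solves`,
#'   `observations` and `first_manipulations`, each sorted by time with a
#'   stable sort (input order preserved among tied times).
#' @export
event_log <- function(solves = empty_events("solve"),
                      observations = empty_events("observe"),
                      first_manipulations = empty_events("first_manipulation"),
                      phase = "social") {
  solves <- as.data.frame(solves, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  first_manipulations <- as.data.frame(first_manipulations, stringsAsFactors = FALSE)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("event_log: %s stream is missing column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
    df[, cols, drop = FALSE]
  }
  solves <- need(solves, c("time", "id"), "solve")
  observations <- need(observations, c("time", "observer", "solver"), "observation")
  first_manipulations <- need(first_manipulations, c("time", "id"), "first-manipulation")

  for (df in list(solves, observations, first_manipulations))
    if (nrow(df) && any(!is.finite(df$time) | df$time < 0))
      stop("event_log: event times must be finite and non-negative", call. = FALSE)
  if (nrow(observations) && any(observations$observer == observations$solver))
    stop("event_log: observer-id equal to solver-id (self-observation) in observation stream",
         call. = FALSE)

  stable_sort <- function(df) df[order(df$time), , drop = FALSE]
  out <- structure(
    list(solves = reset_rows(stable_sort(solves)),
         observations = reset_rows(stable_sort(observations)),
         first_manipulations = reset_rows(stable_sort(first_manipulations)),
         phase = phase),
    class = "event_log")
  out
}

empty_events <- function(type) {
  if (type == "observe")
    data.frame(time = numeric(0), observer = character(0), solver = character(0),
               stringsAsFactors = FALSE)
  else
    data.frame(time = numeric(0), id = character(0), stringsAsFactors = FALSE)
}

reset_rows <- function(df) { rownames(df) <- NULL; df }

#' Read an event log from a delimited file
#'
#' The file format is long: one row per event with columns
#' `phase`, `time_h`, `event_type` (one of `solve`, `observe`,
#' `first_manipulation`), `actor_id` and `target_id` (the solver being
#' observed; empty unless `event_type == "observe"`).
#'
#' @param path path to a CSV file.
#' @param ilv optional [ilv_table()]; when supplied every id in the log must
#'   occur in the table, otherwise a reference error is raised.
#' @return A validated [event_log()].
#' @export
load_event_log <- function(path, ilv = NULL) {
  if (!file.exists(path)) stop("load_event_log: file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("phase", "time_h", "event_type", "actor_id", "target_id")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("load_event_log: missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0) return(event_log())
  time <- as.numeric(raw$time_h)
  if (any(is.na(time))) stop("load_event_log: non-numeric time_h", call. = FALSE)
  bad <- setdiff(unique(raw$event_type), c("solve", "observe", "first_manipulation"))
  if (length(bad))
    stop("load_event_log: unknown event_type: ", paste(bad, collapse = ", "), call. = FALSE)

  is_s <- raw$event_type == "solve"
  is_o <- raw$event_type == "observe"
  is_m <- raw$event_type == "first_manipulation"
  log <- event_log(
    solves = data.frame(time = time[is_s], id = raw$actor_id[is_s],
                        stringsAsFactors = FALSE),
    observations = data.frame(time = time[is_o], observer = raw$actor_id[is_o],
                              solver = raw$target_id[is_o], stringsAsFactors = FALSE),
    first_manipulations = data.frame(time = time[is_m], id = raw$actor_id[is_m],
                                     stringsAsFactors = FALSE),
    phase = if (length(unique(raw$phase)) == 1) raw$phase[1] else "mixed")
  if (!is.null(ilv)) validate_event_log(log, ilv)
  log
}

#' Write an event log to the long CSV format read by [load_event_log()]
#'
#' @param log an [event_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  stream <- function(df, type, actor, target = NULL) {
    n <- nrow(df)
    data.frame(time_h = df$time, event_type = rep(type, n),
               actor_id = df[[actor]],
               target_id = if (is.null(target)) rep("", n) else df[[target]],
               stringsAsFactors = FALSE)
  }
  rows <- rbind(stream(log$solves, "solve", "id"),
                stream(log$observations, "observe", "observer", "solver"),
                stream(log$first_manipulations, "first_manipulation", "id"))
  rows <- rows[order(rows$time_h), , drop = FALSE]
  rows <- cbind(phase = rep(log$phase %||% "social", nrow(rows)), rows)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an event log against an individual table
#'
#' Checks the `event_log` invariants that require the individual table:
#' every id mentioned in any stream exists, and every observation's solver
#' has a solve event at the same time.
#'
#' @param log an [event_log()].
#' @param ilv an [ilv_table()].
#' @return `log`, invisibly; errors describe the first violated invariant.
#' @export
validate_event_log <- function(log, ilv) {
  stopifnot(inherits(log, "event_log"))
  ids <- c(log$solves$id, log$observations$observer, log$observations$solver,
           log$first_manipulations$id)
  unknown <- setdiff(unique(ids), ilv$id)
  if (length(unknown))
    stop("event log refers to unknown id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (nrow(log$observations)) {
    key_obs <- paste(log$observations$time, log$observations$solver)
    key_sol <- paste(log$solves$time, log$solves$id)
    orphan <- !(key_obs %in% key_sol)
    if (any(orphan))
      stop("observation(s) of a solve with no matching solve event: observer ",
           paste(unique(log$observations$observer[orphan]), collapse = ", "),
           call. = FALSE)
  }
  invisible(log)
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> phase:", x$phase %||% "?", "\n",
      " solves:", nrow(x$solves),
      " observations:", nrow(x$observations),
      " first manipulations:", nrow(x$first_manipulations), "\n")
  invisible(x)
}
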