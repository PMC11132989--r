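#' Dynamic observation networks for diffusion analysis
#'
#' Builds one of the four connection structures a diffusion model can
#' condition on:
#' \describe{
#'   \item{`absolute_observation`}{connection(i, j, t) = number of times `i`
#'     observed `j` successfully solve before `t`; exposure is the total
#'     number of solves observed.}
#'   \item{`individuals_observed`}{connection is the 0/1 indicator that `i`
#'     has observed `j` solve; exposure counts distinct solvers observed.}
#'   \item{`single_observation`}{exposure is the 0/1 indicator that `i` has
#'     observed at least one solve.}
#'   \item{`group`}{static same-group network; exposure counts informed
#'     same-group individuals at `t`.}
#' }
#' All dynamic edges use the strictly-before-`t` convention: an observation
#' at exactly `t` does not contribute at `t`. Trained demonstrators are
#' informed from `t = 0`.
#'
#' @param log an [event_log()].
#' @param ilv an [ilv_table()].
#' @param variant one of `"absolute_observation"`, `"individuals_observed"`,
#'   `"single_observation"`, `"group"`.
#' @return An object of class `diffusion_network`.
#' @export
build_network <- function(log, ilv,
                          variant = c("absolute_observation", "individuals_observed",
                                      "single_observation", "group")) {
  variant <- match.arg(variant)
  stopifnot(inherits(log, "event_log"), inherits(ilv, "ilv_table"))
  validate_event_log(log, ilv)
  structure(list(variant = variant, log = log, ilv = ilv), class = "diffusion_network")
}

#' Pairwise connection strength at a time point
#'
#' @param net a [build_network()] object.
#' @param i,j individual ids.
#' @param t time (hours).
#' @return Non-negative connection weight; always 0 for `i == j`.
#' @export
connection <- function(net, i, j, t) {
  stopifnot(inherits(net, "diffusion_network"))
  if (i == j) return(0)
  obs <- net$log$observations
  n_ij <- sum(obs$observer == i & obs$solver == j & obs$time < t)
  switch(net$variant,
         absolute_observation = n_ij,
         individuals_observed = as.numeric(n_ij > 0),
         single_observation = as.numeric(n_ij > 0),
         group = {
           gi <- net$ilv$group[match(i, net$ilv$id)]
           gj <- net$ilv$group[match(j, net$ilv$id)]
           as.numeric(gi == gj)
         })
}

#' Total exposure of an individual to informed individuals at a time point
#'
#' For the observation variants this is the row sum of connections (the 0/1
#' any-observation indicator for `single_observation`); for the group
#' variant it is the number of informed same-group individuals (trained
#' demonstrators plus individuals whose first solve occurred strictly before
#' `t`).
#'
#' @param net a [build_network()] object.
#' @param i individual id.
#' @param t time (hours).
#' @return Non-negative exposure value.
#' @export
exposure <- function(net, i, t) {
  stopifnot(inherits(net, "diffusion_network"))
  obs <- net$log$observations
  mine <- obs$observer == i & obs$time < t
  switch(net$variant,
         absolute_observation = sum(mine),
         individuals_observed = length(unique(obs$solver[mine])),
         single_observation = as.numeric(any(mine)),
         group = {
           ilv <- net$ilv
           s <- net$log$solves
           first_solve <- tapply(s$time, s$id, min)
           informed <- union(ilv$id[ilv$trained],
                             names(first_solve)[first_solve < t])
           informed <- setdiff(informed, i)
           gi <- ilv$group[match(i, ilv$id)]
           sum(ilv$group[match(informed, ilv$id)] == gi)
         })
}

#' Acquisition events of a diffusion
#'
#' First solves of untrained individuals, in acquisition order (time order;
#' ties broken by event-log order, with the tied blocks reported).
#'
#' @param log an [event_log()].
#' @param ilv an [ilv_table()].
#' @return Data frame with columns `time`, `id` and attribute `tied_blocks`
#'   (list of id vectors sharing an acquisition time).
#' @export
acquisition_events <- function(log, ilv) {
  s <- log$solves
  trained_ids <- ilv$id[ilv$trained]
  s <- s[!(s$id %in% trained_ids), , drop = FALSE]
  ev <- s[!duplicated(s$id), , drop = FALSE]
  ev <- reset_rows(ev)
  tied <- split(ev$id, ev$time)
  tied <- unname(tied[vapply(tied, length, 1L) > 1])
  attr(ev, "tied_blocks") <- tied
  ev
}

#' Exposure of every individual immediately before every acquisition event
#'
#' Pre-computes the matrix the order-of-acquisition likelihood consumes:
#' entry `(k, i)` is the exposure of individual `i` immediately before the
#' `k`-th acquisition event. The informed-status vector used by the group
#' variant is updated after each event, so ties are resolved in acquisition
#' order. Trained demonstrators never appear as events (they are informed at
#' `t = 0`).
#'
#' @param net a [build_network()] object.
#' @param log an [event_log()]; defaults to the log the network was built
#'   from.
#' @param events optional data frame (`time`, `id`) of transition events to
#'   evaluate instead of the solve-acquisition events; risk sets then track
#'   which untrained individuals have not yet had one of these events.
#' @return A `K x N` matrix (events by individuals, columns named by id)
#'   with attributes `events` (the [acquisition_events()] frame), `risk`
#'   (logical `K x N` naive-at-risk indicator) and `acquirer_col` (column
#'   index of each event's acquirer).
#' @export
exposure_at_events <- function(net, log = net$log, events = NULL) {
  stopifnot(inherits(net, "diffusion_network"))
  ilv <- net$ilv
  ev <- if (is.null(events)) acquisition_events(log, ilv) else events
  K <- nrow(ev)
  ids <- ilv$id
  N <- length(ids)
  obs <- log$observations
  E <- matrix(0, K, N, dimnames = list(NULL, ids))
  risk <- matrix(FALSE, K, N, dimnames = list(NULL, ids))

  if (K > 0) {
    if (net$variant %in% c("absolute_observation", "individuals_observed",
                           "single_observation")) {
      for (i in seq_len(N)) {
        mine <- obs[obs$observer == ids[i], , drop = FALSE]
        E[, i] <- switch(net$variant,
          absolute_observation = vapply(ev$time, function(t) sum(mine$time < t), 0),
          individuals_observed = vapply(ev$time, function(t)
            length(unique(mine$solver[mine$time < t])), 0),
          single_observation = vapply(ev$time, function(t)
            as.numeric(any(mine$time < t)), 0))
      }
    } else { # group: informed same-group count, event-order informed status
      informed <- ilv$trained
      for (k in seq_len(K)) {
        same_group <- outer(ilv$group, ilv$group, "==")
        E[k, ] <- vapply(seq_len(N), function(i)
          sum(informed & same_group[i, ] & seq_len(N) != i), 0)
        informed[match(ev$id[k], ids)] <- TRUE
      }
    }
    acquired_before <- rep(FALSE, N)
    for (k in seq_len(K)) {
      risk[k, ] <- !ilv$trained & !acquired_before
      acquired_before[match(ev$id[k], ids)] <- TRUE
    }
  }
  attr(E, "events") <- ev
  attr(E, "risk") <- risk
  attr(E, "acquirer_col") <- match(ev$id, ids)
  E
}

#' Dump a dynamic network as a long-format table
#'
#' Connection weights of every ordered dyad evaluated immediately before
#' each acquisition event, for inspection.
#'
#' @param net a [build_network()] object.
#' @return Data frame with columns `t`, `i`, `j`, `weight`.
#' @export
network_as_table <- function(net) {
  ev <- acquisition_events(net$log, net$ilv)
  ids <- net$ilv$id
  rows <- expand.grid(t = ev$time, i = ids, j = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[rows$i != rows$j, , drop = FALSE]
  rows$weight <- mapply(function(i, j, t) connection(net, i, j, t),
                        rows$i, rows$j, rows$t)
  reset_rows(rows)
}
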