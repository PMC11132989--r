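#' State histories for the multistate diffusion extension
#'
#' Each untrained individual moves naive -> interacting (first manipulation)
#' -> informed (first solve), never backwards. Trained demonstrators are
#' informed from `t = 0`. An individual with a recorded solve but no prior
#' recorded manipulation is coerced: both transitions are set at the solve
#' time (manipulation ordered immediately before the solve) and the case is
#' listed in the `coerced` attribute.
#'
#' @param log an [event_log()].
#' @param ilv an [ilv_table()].
#' @return Data frame with columns `id`, `t_interact` (first manipulation
#'   time or `NA`), `t_informed` (first solve time or `NA`), `trained`,
#'   `coerced`; attribute `coerced` holds the coerced ids.
#' @export
build_state_histories <- function(log, ilv) {
  stopifnot(inherits(log, "event_log"), inherits(ilv, "ilv_table"))
  validate_event_log(log, ilv)
  first_of <- function(df) {
    df <- df[!duplicated(df$id), , drop = FALSE]
    stats::setNames(df$time, df$id)
  }
  tm <- first_of(log$first_manipulations)
  ts <- first_of(log$solves)
  out <- data.frame(id = ilv$id, trained = ilv$trained, stringsAsFactors = FALSE)
  out$t_interact <- unname(tm[out$id])
  out$t_informed <- unname(ts[out$id])
  bad <- !is.na(out$t_interact) & !is.na(out$t_informed) &
    out$t_interact > out$t_informed
  coerce <- (is.na(out$t_interact) & !is.na(out$t_informed)) | bad
  coerce <- coerce & !out$trained
  if (any(coerce)) {
    out$t_interact[coerce] <- out$t_informed[coerce]
    warning("solve without prior recorded manipulation for: ",
            paste(out$id[coerce], collapse = ", "),
            "; both transitions coerced to the solve time", call. = FALSE)
  }
  out$coerced <- coerce
  attr(out, "coerced") <- out$id[coerce]
  out
}

#' State of an individual at a time point
#'
#' @param histories a [build_state_histories()] frame.
#' @param id individual id.
#' @param t time (hours); states are right-continuous in `t`.
#' @return `"naive"`, `"interacting"` or `"informed"`.
#' @export
state_at <- function(histories, id, t) {
  row <- histories[histories$id == id, ]
  if (nrow(row) != 1) stop("unknown id: ", id, call. = FALSE)
  if (row$trained) return("informed")
  if (!is.na(row$t_informed) && t >= row$t_informed) return("informed")
  if (!is.na(row$t_interact) && t >= row$t_interact) return("interacting")
  "naive"
}

#' Assemble the two-stage multistate diffusion data
#'
#' Builds the globally time-ordered interleaved sequence of naive ->
#' interacting and interacting -> informed transitions and packages each
#' stage as an [oada_data()]-compatible block: stage-1 events are first
#' manipulations conditioned on the naive risk set; stage-2 events are first
#' solves conditioned on the interacting risk set. Exposures for both
#' stages come from the absolute observation network (observations of
#' successful solves, strictly before each event).
#'
#' @param log an [event_log()].
#' @param ilv an [ilv_table()].
#' @param network_variant exposure network for both stages (default
#'   `"absolute_observation"`).
#' @return An object of class `multistate_data`: list with `stage1`,
#'   `stage2` (each an `oada_data`), `histories` and `transitions`.
#' @export
multistate_data <- function(log, ilv, network_variant = "absolute_observation") {
  histories <- withCallingHandlers(build_state_histories(log, ilv),
                                   warning = function(w) invokeRestart("muffleWarning"))
  h <- histories[!histories$trained, , drop = FALSE]
  stage_rows <- function(times, stage) {
    keep <- !is.na(times)
    data.frame(time = times[keep], id = h$id[keep],
               stage = rep(stage, sum(keep)), stringsAsFactors = FALSE)
  }
  trans <- rbind(stage_rows(h$t_interact, 1L), stage_rows(h$t_informed, 2L))
  trans <- trans[order(trans$time, trans$stage), , drop = FALSE]
  trans <- reset_rows(trans)

  net <- build_network(log, ilv, network_variant)
  ids <- ilv$id
  N <- length(ids)
  K <- nrow(trans)
  E_all <- exposure_at_events(net, log,
                              events = trans[, c("time", "id"), drop = FALSE])
  # state bookkeeping over the interleaved order: 0 naive, 1 interacting, 2 informed
  state <- ifelse(ilv$trained, 2L, 0L)
  risk_all <- matrix(FALSE, K, N, dimnames = list(NULL, ids))
  for (k in seq_len(K)) {
    target_state <- if (trans$stage[k] == 1L) 0L else 1L
    risk_all[k, ] <- !ilv$trained & state == target_state
    state[match(trans$id[k], ids)] <- trans$stage[k]
  }

  stage_block <- function(stage) {
    keep <- trans$stage == stage
    ev <- reset_rows(trans[keep, c("time", "id"), drop = FALSE])
    attr(ev, "tied_blocks") <- list()
    untrained <- !ilv$trained
    X <- cbind(sex = as.numeric(ilv$sex),
               age = ilv$age - mean(ilv$age[untrained]),
               rank = ilv$rank - stats::median(ilv$rank[untrained]))
    rownames(X) <- ids
    structure(list(
      E = E_all[keep, , drop = FALSE], risk = risk_all[keep, , drop = FALSE],
      acq_col = match(ev$id, ids), events = ev, X = X,
      group = ilv$group, groups = sort(unique(ilv$group)),
      ids = ids, trained = ilv$trained, K = nrow(ev), N = N,
      network_variant = network_variant), class = "oada_data")
  }
  structure(list(stage1 = stage_block(1L), stage2 = stage_block(2L),
                 histories = histories, transitions = trans),
            class = "multistate_data")
}

#' Two-stage multistate diffusion log likelihood
#'
#' Sum of two order-of-acquisition likelihood terms with disjoint parameter
#' blocks: stage-1 (naive -> interacting) events conditioned on the naive
#' risk set, stage-2 (interacting -> informed) events on the interacting
#' risk set. A stage with no events contributes 0 and is flagged with a
#' warning.
#'
#' @param params_stage1,params_stage2 parameter lists as in [oada_loglik()].
#' @param spec_stage1,spec_stage2 [oada_model_spec()] objects for each
#'   stage.
#' @param data a [multistate_data()].
#' @return Log likelihood, with attributes `stage1` and `stage2` holding
#'   the per-stage terms.
#' @export
multistate_loglik <- function(params_stage1, params_stage2,
                              spec_stage1, spec_stage2, data) {
  stopifnot(inherits(data, "multistate_data"))
  term <- function(params, spec, block, label) {
    if (block$K == 0) {
      warning("multistate_loglik: no ", label, " events; stage contributes 0",
              call. = FALSE)
      return(0)
    }
    oada_loglik(params, spec, block)
  }
  l1 <- term(params_stage1, spec_stage1, data$stage1, "stage-1")
  l2 <- term(params_stage2, spec_stage2, data$stage2, "stage-2")
  structure(l1 + l2, stage1 = l1, stage2 = l2)
}

# Profile deviance CI for the group ratio s2/s1 within an s1_ne_s2 model:
# rho fixed, s1 >= 0 and coefficients re-optimized.
profile_ci_ratio <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "oada_fit"))
  if (fit$spec$s_constraint != "s1_ne_s2")
    stop("ratio profiling requires the s1_ne_s2 constraint", call. = FALSE)
  data <- fit$data; spec <- fit$spec; lay <- fit$layout
  ncoef <- lay$n_free - 2
  ll_at_rho <- function(rho) {
    nll <- function(th) { # th = (s1, coefs)
      s1 <- th[1]
      full <- c(s1, rho * s1, th[-1])
      -oada_loglik(lay$unpack(full), spec, data)
    }
    starts <- lapply(c(0.01, 0.1, 1, 10), function(s0) c(s0, rep(0, ncoef)))
    vals <- vapply(starts, function(th0) {
      o <- try(stats::optim(th0, nll, method = "L-BFGS-B",
                            lower = c(0, rep(-Inf, ncoef)),
                            control = list(factr = 1e7, maxit = 500)),
               silent = TRUE)
      if (inherits(o, "try-error")) Inf else o$value
    }, 0)
    -min(vals)
  }
  s_hat <- fit$params$s_by_group
  est <- if (s_hat[1] > 0) unname(s_hat[2] / s_hat[1]) else NA_real_
  q <- stats::qchisq(level, df = 1)
  llmax <- fit$loglik
  dev <- function(log_rho) 2 * (llmax - ll_at_rho(exp(log_rho)))
  centre <- log(if (is.finite(est) && est > 0) est else 1)
  lo_end <- centre - log(1e6); hi_end <- centre + log(1e6)
  lower <- if (dev(lo_end) <= q + 1e-9) 0 else
    exp(stats::uniroot(function(lr) dev(lr) - q, lower = lo_end, upper = centre,
                       tol = 1e-7)$root)
  upper <- if (dev(hi_end) <= q + 1e-9) Inf else
    exp(stats::uniroot(function(lr) dev(lr) - q, lower = centre, upper = hi_end,
                       tol = 1e-7)$root)
  c(estimate = est, lower = lower, upper = upper)
}

#' Fit the two-stage multistate diffusion model
#'
#' Fits each stage separately (the stages share no parameters, so the joint
#' maximum factorizes): enumerates the candidate set over s-constraints and
#' ILV patterns with the exposure network fixed, fits all models, and
#' reports per stage the model table, the model-averaged `s` per group, and
#' profile CI plus %ST conditional on the best model. For the stage-1 group
#' contrast it also profiles the ratio `s2/s1` within the stage-1
#' `s1_ne_s2` model.
#'
#' @param data a [multistate_data()].
#' @param config model-set configuration as in [enumerate_model_set()]
#'   (the network list is forced to the data's exposure network).
#' @param level confidence level for profile intervals.
#' @return An object of class `multistate_fit` with `stage1` and `stage2`
#'   result blocks and `ratio` (stage-1 group contrast).
#' @export
fit_multistate <- function(data, config = list(), level = 0.95) {
  stopifnot(inherits(data, "multistate_data"))
  config$networks <- data$stage1$network_variant
  specs <- enumerate_model_set(config)
  stage_fit <- function(block) {
    if (block$K == 0) return(NULL)
    fits <- lapply(specs, function(sp) fit_oada(sp, block))
    tab <- data.frame(
      s_constraint = vapply(specs, `[[`, "", "s_constraint"),
      ilv_asocial = vapply(specs, function(s) paste(s$ilv_asocial, collapse = "+"), ""),
      ilv_social = vapply(specs, function(s) paste(s$ilv_social, collapse = "+"), ""),
      loglik = vapply(fits, `[[`, 0, "loglik"),
      n_params = vapply(fits, `[[`, 0, "n_params"),
      aicc = vapply(fits, `[[`, 0, "aicc"), stringsAsFactors = FALSE)
    tab$delta_aicc <- tab$aicc - min(tab$aicc)
    tab$akaike_weight <- akaike_weights(tab$aicc)
    mset <- structure(list(fits = fits, table = tab), class = "model_set")
    best <- fits[[which.min(tab$aicc)]]
    s_avg <- vapply(as.character(block$groups), function(g)
      model_average(mset, "s", group = g), 0)
    ci <- pst <- NULL
    if (best$layout$n_s > 0) {
      ci <- profile_ci_s(best, level = level)
      pst <- percent_st_ci(best, ci = ci)
    }
    list(model_set = mset, best = best, s_model_averaged = s_avg,
         s_profile_ci = ci, percent_st_ci = pst)
  }
  st1 <- stage_fit(data$stage1)
  st2 <- stage_fit(data$stage2)
  ratio <- NULL
  if (!is.null(st1) && length(data$stage1$groups) >= 2) {
    contrast_specs <- specs[vapply(specs, function(s)
      s$s_constraint == "s1_ne_s2", TRUE)]
    if (length(contrast_specs)) {
      cf <- lapply(contrast_specs, function(sp) fit_oada(sp, data$stage1))
      best_c <- cf[[which.min(vapply(cf, `[[`, 0, "aicc"))]]
      ratio <- profile_ci_ratio(best_c, level = level)
    }
  }
  structure(list(stage1 = st1, stage2 = st2, ratio = ratio, level = level),
            class = "multistate_fit")
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat("<multistate_fit>\n")
  for (nm in c("stage1", "stage2")) {
    b <- x[[nm]]
    if (is.null(b)) { cat(" ", nm, ": no events\n"); next }
    cat(sprintf("  %s: model-averaged s = %s", nm,
                paste(sprintf("%s: %.3f", names(b$s_model_averaged),
                              b$s_model_averaged), collapse = ", ")))
    if (!is.null(b$s_profile_ci))
      cat(sprintf(" | best-model s CI (%.0f%%) = [%.3g, %.3g] | %%ST = [%.1f, %.1f]",
                  100 * x$level, b$s_profile_ci[1], b$s_profile_ci[2],
                  b$percent_st_ci[1], b$percent_st_ci[2]))
    cat("\n")
  }
  if (!is.null(x$ratio))
    cat(sprintf("  stage-1 group ratio s2/s1 = %.3g, CI [%.3g, %.3g]\n",
                x$ratio[1], x$ratio[2], x$ratio[3]))
  invisible(x)
}
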