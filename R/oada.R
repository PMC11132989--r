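#' Specify one candidate order-of-acquisition diffusion model
#'
#' A candidate model is a network variant crossed with a constraint on the
#' per-group social-transmission parameters and a pattern of individual-level
#' variables (ILVs) entering the asocial and/or social rates.
#'
#' Constraints: `s1_ne_s2` (a free `s` per group), `s1_eq_s2` (one shared
#' `s`), `s2_zero` (social transmission only in group 1), `s1_zero` (only in
#' group 2), `asocial` (all `s = 0`; social coefficients are dropped because
#' they would have no effect). The static group network is only meaningful
#' under `s1_eq_s2` and is rejected otherwise.
#'
#' @param network_variant network variant name, see [build_network()].
#' @param s_constraint one of `"s1_ne_s2"`, `"s1_eq_s2"`, `"s1_zero"`,
#'   `"s2_zero"`, `"asocial"`.
#' @param ilv_asocial,ilv_social character vectors naming ILVs (subsets of
#'   `c("sex", "age", "rank")`) with coefficients on the asocial and social
#'   rates respectively.
#' @return An object of class `oada_model_spec`.
#' @export
oada_model_spec <- function(network_variant = "absolute_observation",
                            s_constraint = c("s1_eq_s2", "s1_ne_s2", "s1_zero",
                                             "s2_zero", "asocial"),
                            ilv_asocial = character(),
                            ilv_social = character()) {
  s_constraint <- match.arg(s_constraint)
  network_variant <- match.arg(network_variant,
    c("absolute_observation", "individuals_observed", "single_observation", "group"))
  known <- c("sex", "age", "rank")
  if (length(setdiff(ilv_asocial, known)) || length(setdiff(ilv_social, known)))
    stop("unknown ILV name; known ILVs: ", paste(known, collapse = ", "), call. = FALSE)
  if (network_variant == "group" && s_constraint != "s1_eq_s2")
    stop("the group network is only fitted under the s1_eq_s2 constraint", call. = FALSE)
  if (s_constraint == "asocial" && length(ilv_social))
    stop("social coefficients have no effect in an asocial model and must be empty",
         call. = FALSE)
  structure(list(network_variant = network_variant, s_constraint = s_constraint,
                 ilv_asocial = sort(ilv_asocial), ilv_social = sort(ilv_social)),
            class = "oada_model_spec")
}

#' @export
print.oada_model_spec <- function(x, ...) {
  cat(sprintf("<oada_model_spec> %s | %s | asocial ILVs: {%s} | social ILVs: {%s}\n",
              x$network_variant, x$s_constraint,
              paste(x$ilv_asocial, collapse = ","),
              paste(x$ilv_social, collapse = ",")))
  invisible(x)
}

#' Assemble the data an order-of-acquisition likelihood consumes
#'
#' Pre-computes the exposure matrix for a network variant, the naive risk
#' sets, and centred ILV columns. ILVs are coded so that the asocial baseline
#' individual is a female of middle rank and average age: sex is 0/1 as
#' recorded, age is centred at the untrained individuals' mean, rank at
#' their median, making `exp(beta' x) = 1` for that reference individual.
#'
#' @param log an [event_log()].
#' @param ilv an [ilv_table()].
#' @param network_variant network variant name, see [build_network()].
#' @param acquisition which transition defines the acquisition events:
#'   first solves (default) or first manipulations (the naive -> interacting
#'   transition of the multistate extension). Exposures always come from
#'   observations of solves.
#' @return An object of class `oada_data`.
#' @export
oada_data <- function(log, ilv, network_variant = "absolute_observation",
                      acquisition = c("solve", "first_manipulation")) {
  acquisition <- match.arg(acquisition)
  net <- build_network(log, ilv, network_variant)
  events <- NULL
  if (acquisition == "first_manipulation") {
    m <- log$first_manipulations
    m <- m[!(m$id %in% ilv$id[ilv$trained]), , drop = FALSE]
    events <- reset_rows(m[!duplicated(m$id), , drop = FALSE])
  }
  E <- exposure_at_events(net, log, events = events)
  untrained <- !ilv$trained
  X <- cbind(sex = as.numeric(ilv$sex),
             age = ilv$age - mean(ilv$age[untrained]),
             rank = ilv$rank - stats::median(ilv$rank[untrained]))
  rownames(X) <- ilv$id
  structure(list(
    E = E, risk = attr(E, "risk"), acq_col = attr(E, "acquirer_col"),
    events = attr(E, "events"), X = X,
    group = ilv$group, groups = sort(unique(ilv$group)),
    ids = ilv$id, trained = ilv$trained,
    K = nrow(attr(E, "events")), N = length(ilv$id),
    network_variant = network_variant),
    class = "oada_data")
}

# Shared order-likelihood core. E, risk: K x N; acq_col: event acquirer
# column; s_ind, social_mult, asocial_mult: per-individual vectors.
order_loglik_core <- function(E, risk, acq_col, s_ind, social_mult, asocial_mult) {
  K <- nrow(E)
  if (K == 0) return(0)
  if (any(rowSums(risk) == 0))
    stop("empty risk set at an acquisition event", call. = FALSE)
  r <- sweep(E, 2, s_ind * social_mult, "*")
  r <- sweep(r, 2, asocial_mult, "+")
  num <- r[cbind(seq_len(K), acq_col)]
  den <- rowSums(r * risk)
  sum(log(num)) - sum(log(den))
}

# Expand constrained parameters into per-individual vectors.
expand_params <- function(params, spec, data) {
  s_by_group <- params$s_by_group
  if (is.null(names(s_by_group))) names(s_by_group) <- as.character(data$groups)
  if (any(s_by_group < 0)) stop("s must be non-negative", call. = FALSE)
  s_ind <- unname(s_by_group[as.character(data$group)])
  bmul <- exp(drop(data$X[, spec$ilv_asocial, drop = FALSE] %*%
                     (params$beta %||% numeric(length(spec$ilv_asocial)))))
  gmul <- exp(drop(data$X[, spec$ilv_social, drop = FALSE] %*%
                     (params$gamma %||% numeric(length(spec$ilv_social)))))
  list(s_ind = s_ind, social_mult = as.numeric(gmul), asocial_mult = as.numeric(bmul))
}

#' Order-of-acquisition diffusion log likelihood
#'
#' The probability of the observed acquisition order: at each acquisition
#' event the probability that the observed acquirer is the one to learn,
#' among the naive untrained risk set, with per-individual rate
#' `r(i) = s_g(i) * exposure(i, t_k) * exp(gamma' x_i) + exp(beta' x_i)`.
#' The common baseline time-hazard cancels, so only the order (not the
#' times) of acquisition informs the likelihood.
#'
#' @param params list with `s_by_group` (non-negative, named by group or in
#'   group order), `beta` (asocial ILV coefficients, in `spec$ilv_asocial`
#'   order) and `gamma` (social ILV coefficients).
#' @param spec an [oada_model_spec()].
#' @param data an [oada_data()] built with the matching network variant.
#' @return The log likelihood (non-positive).
#' @export
oada_loglik <- function(params, spec, data) {
  stopifnot(inherits(spec, "oada_model_spec"), inherits(data, "oada_data"))
  p <- expand_params(params, spec, data)
  order_loglik_core(data$E, data$risk, data$acq_col,
                    p$s_ind, p$social_mult, p$asocial_mult)
}

# Free-parameter layout for a spec on given data; returns packing helpers.
param_layout <- function(spec, data) {
  G <- data$groups
  s_template <- stats::setNames(rep(0, length(G)), as.character(G))
  free_s <- switch(spec$s_constraint,
    s1_ne_s2 = as.character(G),
    s1_eq_s2 = "shared",
    s2_zero  = as.character(G[1]),
    s1_zero  = as.character(G[length(G)]),
    asocial  = character(0))
  nb <- length(spec$ilv_asocial); ng <- length(spec$ilv_social)
  list(
    n_free = length(free_s) + nb + ng,
    n_s = length(free_s),
    free_s = free_s,
    lower = c(rep(0, length(free_s)), rep(-Inf, nb + ng)),
    unpack = function(theta) {
      s <- s_template
      if (length(free_s)) {
        sv <- theta[seq_along(free_s)]
        if (identical(free_s, "shared")) s[] <- sv else s[free_s] <- sv
      }
      list(s_by_group = s,
           beta = if (nb) theta[length(free_s) + seq_len(nb)] else numeric(0),
           gamma = if (ng) theta[length(free_s) + nb + seq_len(ng)] else numeric(0))
    })
}

#' Fit an order-of-acquisition diffusion model
#'
#' Maximizes [oada_loglik()] over the free parameters with bounded
#' quasi-Newton (`L-BFGS-B`), `s` bounded below at 0, using a 5-point
#' multi-start over `s` in `{0.01, 0.1, 1, 10, 100}` with ILV coefficients
#' started at 0. Deterministic given the fixed start schedule.
#'
#' @param spec an [oada_model_spec()].
#' @param data an [oada_data()].
#' @return An object of class `oada_fit`: parameter estimates, log
#'   likelihood, parameter count, AICc (sample size = number of acquisition
#'   events) and convergence flag.
#' @export
fit_oada <- function(spec, data) {
  stopifnot(inherits(spec, "oada_model_spec"), inherits(data, "oada_data"))
  if (!identical(spec$network_variant, data$network_variant))
    stop("spec and data disagree on the network variant", call. = FALSE)
  lay <- param_layout(spec, data)
  nll <- function(theta) -oada_loglik(lay$unpack(theta), spec, data)

  if (lay$n_free == 0) {
    ll <- -nll(numeric(0))
    est <- lay$unpack(numeric(0))
    fit <- list(par = est, theta = numeric(0), loglik = ll, converged = TRUE)
  } else {
    starts <- lapply(c(0.01, 0.1, 1, 10, 100), function(s0)
      c(rep(s0, lay$n_s), rep(0, lay$n_free - lay$n_s)))
    if (lay$n_s == 0) starts <- starts[1]
    best <- NULL
    for (th0 in starts) {
      o <- try(stats::optim(th0, nll, method = "L-BFGS-B", lower = lay$lower,
                            control = list(factr = 1e7, maxit = 500)), silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best))
      stop("fit_oada: optimizer failed from every start", call. = FALSE)
    fit <- list(par = lay$unpack(best$par), theta = best$par,
                loglik = -best$value, converged = best$convergence == 0)
  }
  k <- lay$n_free
  out <- structure(list(
    spec = spec, data = data, params = fit$par, theta = fit$theta,
    loglik = fit$loglik, n_params = k,
    aicc = aicc(fit$loglik, k, data$K),
    converged = fit$converged, layout = lay), class = "oada_fit")
  out
}

#' @export
print.oada_fit <- function(x, ...) {
  cat("<oada_fit>\n"); print(x$spec)
  s <- x$params$s_by_group
  cat("  s:", paste(sprintf("%s=%.4g", names(s), s), collapse = ", "), "\n")
  if (length(x$params$beta))
    cat("  beta:", paste(sprintf("%s=%.3g", x$spec$ilv_asocial, x$params$beta),
                         collapse = ", "), "\n")
  if (length(x$params$gamma))
    cat("  gamma:", paste(sprintf("%s=%.3g", x$spec$ilv_social, x$params$gamma),
                          collapse = ", "), "\n")
  cat(sprintf("  logLik %.4f | k %d | AICc %.3f | converged %s\n",
              x$loglik, x$n_params, x$aicc, x$converged))
  invisible(x)
}

# Profile log likelihood at a fixed value of one free s, nuisance
# parameters re-optimized.
profile_loglik_at_s <- function(fit, s_index, s_value) {
  lay <- fit$layout
  spec <- fit$spec; data <- fit$data
  fix <- function(theta_red) {
    th <- numeric(lay$n_free)
    th[-s_index] <- theta_red
    th[s_index] <- s_value
    th
  }
  nll <- function(theta_red) -oada_loglik(lay$unpack(fix(theta_red)), spec, data)
  if (lay$n_free == 1) return(-nll(numeric(0)))
  th0 <- fit$theta[-s_index]
  o <- stats::optim(th0, nll, method = "L-BFGS-B", lower = lay$lower[-s_index],
                    control = list(factr = 1e7, maxit = 500))
  -o$value
}

#' Profile-likelihood confidence interval for a social-transmission parameter
#'
#' Bounds where the profile deviance `2 * (l_max - l_profile(s))` reaches
#' the chi-square(1) quantile, with all other parameters re-optimized at
#' each fixed `s`. The upper bound is reported as `Inf` when the profile
#' deviance never reaches the threshold below a search ceiling of
#' `1e6 * s_hat` (or `1e6` when `s_hat = 0`).
#'
#' @param fit an [fit_oada()] result with at least one free `s`.
#' @param level confidence level (default 0.95).
#' @param which index among the free `s` parameters to profile (default 1).
#' @return Named vector `c(lower, upper)`; `upper` may be `Inf`.
#' @export
profile_ci_s <- function(fit, level = 0.95, which = 1) {
  stopifnot(inherits(fit, "oada_fit"))
  lay <- fit$layout
  if (lay$n_s == 0) stop("profile_ci_s: model has no free s parameter", call. = FALSE)
  s_index <- which
  q <- stats::qchisq(level, df = 1)
  llmax <- fit$loglik
  s_hat <- fit$theta[s_index]
  dev <- function(s) 2 * (llmax - profile_loglik_at_s(fit, s_index, s))

  lower <- if (dev(0) <= q + 1e-9) 0 else
    stats::uniroot(function(s) dev(s) - q, lower = 0, upper = max(s_hat, 1e-12),
                   tol = 1e-8)$root
  ceiling_s <- if (s_hat > 0) 1e6 * s_hat else 1e6
  upper <- if (dev(ceiling_s) <= q + 1e-9) Inf else
    stats::uniroot(function(s) dev(s) - q, lower = max(s_hat, 1e-12),
                   upper = ceiling_s, tol = 1e-8)$root
  c(lower = lower, upper = upper)
}

#' Percentage of acquisition events attributed to social transmission
#'
#' Event-wise attribution: for each acquisition event the fitted fraction of
#' the acquirer's rate that is social,
#' `s * exposure * exp(gamma' x) / r(acquirer)`, averaged over events and
#' expressed as a percentage.
#'
#' @param params parameter list as in [oada_loglik()].
#' @param spec an [oada_model_spec()].
#' @param data an [oada_data()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_st <- function(params, spec, data) {
  stopifnot(inherits(data, "oada_data"))
  if (data$K == 0)
    stop("percent_st: no acquisition events", call. = FALSE)
  p <- expand_params(params, spec, data)
  k <- seq_len(data$K)
  soc <- (p$s_ind * p$social_mult)[data$acq_col] * data$E[cbind(k, data$acq_col)]
  aso <- p$asocial_mult[data$acq_col]
  100 * mean(soc / (soc + aso))
}

#' %ST interval induced by the profile CI for s
#'
#' Evaluates [percent_st()] at the profile bounds for `s`, re-optimizing the
#' nuisance parameters at each bound. An infinite upper bound maps to the
#' limiting attribution (social fraction 1 for every event with positive
#' exposure).
#'
#' @param fit an [fit_oada()] result.
#' @param ci interval from [profile_ci_s()] (computed if missing).
#' @param level confidence level used when `ci` is missing.
#' @param which index among the free `s` parameters.
#' @return Named vector `c(lower, upper)` in percent.
#' @export
percent_st_ci <- function(fit, ci = NULL, level = 0.95, which = 1) {
  stopifnot(inherits(fit, "oada_fit"))
  if (is.null(ci)) ci <- profile_ci_s(fit, level = level, which = which)
  lay <- fit$layout; data <- fit$data
  at_s <- function(s) {
    if (!is.finite(s)) {
      k <- seq_len(data$K)
      return(100 * mean(data$E[cbind(k, data$acq_col)] > 0))
    }
    th <- fit$theta
    if (lay$n_free > 1) {
      nll <- function(theta_red) {
        full <- numeric(lay$n_free); full[-which] <- theta_red; full[which] <- s
        -oada_loglik(lay$unpack(full), fit$spec, data)
      }
      o <- stats::optim(fit$theta[-which], nll, method = "L-BFGS-B",
                        lower = lay$lower[-which],
                        control = list(factr = 1e7, maxit = 500))
      th <- numeric(lay$n_free); th[-which] <- o$par; th[which] <- s
    } else th[which] <- s
    percent_st(lay$unpack(th), fit$spec, data)
  }
  c(lower = at_s(ci[["lower"]]), upper = at_s(ci[["upper"]]))
}

#' Relative solving-rate multiplier implied by s
#'
#' For the baseline individual on an absolute observation network, the
#' expected rate after `n` observed solves relative to no observations:
#' `1 + n * s`.
#'
#' @param s social-transmission parameter (non-negative).
#' @param n_observations number of solves observed (non-negative).
#' @return The multiplier `1 + n_observations * s`.
#' @export
relative_rate <- function(s, n_observations) {
  stopifnot(s >= 0, n_observations >= 0)
  1 + n_observations * s
}
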