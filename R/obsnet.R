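#' Expand solve events into a binary observation-opportunity design
#'
#' Every successful manipulation (solve) is crossed with every same-group
#' potential observer (everyone but the manipulator): one row per
#' (event, candidate) pair with outcome `y = 1` if the candidate observed
#' that solve. Covariates: maternal kinship with the manipulator, the
#' manipulator-minus-observer age and rank differences, and a carryover
#' indicator `prev` (the candidate observed the immediately preceding
#' manipulation in its group; 0 at each group's first event).
#'
#' @param log an [event_log()].
#' @param ilv an [ilv_table()] (kin pairs attached).
#' @return Data frame of class `obs_design` with columns `event`,
#'   `observer`, `manipulator`, `group`, `y`, `kin`, `age_diff`,
#'   `rank_diff`, `prev`.
#' @export
build_obs_design <- function(log, ilv) {
  stopifnot(inherits(log, "event_log"), inherits(ilv, "ilv_table"))
  validate_event_log(log, ilv)
  s <- log$solves
  if (nrow(s) == 0) {
    out <- data.frame(event = integer(0), observer = character(0),
                      manipulator = character(0), group = integer(0),
                      y = integer(0), kin = integer(0), age_diff = numeric(0),
                      rank_diff = numeric(0), prev = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("obs_design", "data.frame")
    return(out)
  }
  obs_key <- paste(log$observations$time, log$observations$solver,
                   log$observations$observer)
  idx <- match(s$id, ilv$id)
  rows <- vector("list", nrow(s))
  prev_observers <- list()  # per group: observers of the previous event
  for (k in seq_len(nrow(s))) {
    man <- s$id[k]; g <- ilv$group[idx[k]]
    cand <- ilv$id[ilv$group == g & ilv$id != man]
    ci <- match(cand, ilv$id)
    gkey <- as.character(g)
    prev_set <- prev_observers[[gkey]] %||% character(0)
    y <- as.integer(paste(s$time[k], man, cand) %in% obs_key)
    rows[[k]] <- data.frame(
      event = k, observer = cand, manipulator = man, group = g, y = y,
      kin = as.integer(is_kin(ilv, man, cand)),
      age_diff = ilv$age[idx[k]] - ilv$age[ci],
      rank_diff = ilv$rank[idx[k]] - ilv$rank[ci],
      prev = as.integer(cand %in% prev_set), stringsAsFactors = FALSE)
    prev_observers[[gkey]] <- cand[y == 1]
  }
  out <- do.call(rbind, rows)
  out <- reset_rows(out)
  class(out) <- c("obs_design", "data.frame")
  out
}

#' Default priors of the observation-network GLMM
#'
#' Fixed effects Normal(0, 2.5^2); random-effect standard deviations
#' half-Normal(0, 1). Override by passing a modified copy to
#' [glmm_log_posterior()] or [mcmc_sample()].
#'
#' @return List with `fixed_sd` and `re_sd_scale`.
#' @export
obsnet_priors <- function() list(fixed_sd = 2.5, re_sd_scale = 1)

glmm_effect_names <- c("intercept", "kin", "age_diff", "rank_diff", "prev")

# log(1 + exp(x)) without overflow
log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

glmm_linpred <- function(params, design) {
  if (nrow(design) == 0) return(numeric(0))
  g <- as.character(design$group)
  Xf <- cbind(1, design$kin, design$age_diff, design$rank_diff, design$prev)
  eta <- rowSums(Xf * params$fixed[g, , drop = FALSE])
  if (length(params$u)) eta <- eta + unname(params$u[design$observer])
  if (length(params$v)) eta <- eta + unname(params$v[design$manipulator])
  eta
}

#' Log posterior of the observation-network logistic mixed model
#'
#' Bernoulli-logit likelihood with group-specific fixed effects
#' (intercept, kin, age difference, rank difference, previous-observation
#' carryover) plus crossed observer and manipulator random intercepts,
#' and the priors of [obsnet_priors()].
#'
#' @param params list with `fixed` (matrix, one row per group, columns
#'   `intercept`, `kin`, `age_diff`, `rank_diff`, `prev`), `u` (named
#'   observer effects), `v` (named manipulator effects), `sd_u`, `sd_v`.
#' @param design a [build_obs_design()] frame.
#' @param priors prior settings, see [obsnet_priors()].
#' @param include_prior set `FALSE` to return the likelihood term alone.
#' @return Log posterior (finite for finite parameters).
#' @export
glmm_log_posterior <- function(params, design, priors = obsnet_priors(),
                               include_prior = TRUE) {
  if (any(!is.finite(unlist(params[c("fixed", "u", "v", "sd_u", "sd_v")]))))
    stop("glmm_log_posterior: non-finite parameter", call. = FALSE)
  eta <- glmm_linpred(params, design)
  ll <- if (length(eta)) sum(design$y * eta - log1pexp(eta)) else 0
  if (!include_prior) return(ll)
  if (params$sd_u <= 0 || params$sd_v <= 0) return(-Inf)
  lp <- sum(stats::dnorm(params$fixed, 0, priors$fixed_sd, log = TRUE)) +
    stats::dnorm(params$sd_u, 0, priors$re_sd_scale, log = TRUE) + log(2) +
    stats::dnorm(params$sd_v, 0, priors$re_sd_scale, log = TRUE) + log(2)
  if (length(params$u)) lp <- lp + sum(stats::dnorm(params$u, 0, params$sd_u, log = TRUE))
  if (length(params$v)) lp <- lp + sum(stats::dnorm(params$v, 0, params$sd_v, log = TRUE))
  ll + lp
}

#' Posterior sampling for the observation-network GLMM
#'
#' Self-contained adaptive Metropolis-within-Gibbs sampler: scalar
#' random-walk updates for the fixed effects and (log-scale) random-effect
#' SDs, and vectorized one-at-a-time updates for the observer and
#' manipulator effects (their rows are disjoint, so the block accepts each
#' component independently). Proposal scales adapt during burn-in towards a
#' 0.44 acceptance rate. Chain `c` is seeded with `seed + c - 1`, making
#' draws reproducible per chain seed.
#'
#' @param design a [build_obs_design()] frame (may have zero rows, in which
#'   case the posterior is the prior).
#' @param priors prior settings, see [obsnet_priors()].
#' @param n_chains number of chains (at least 2).
#' @param n_iter kept iterations per chain after burn-in (at least 1000).
#' @param seed integer seed.
#' @param burn_in burn-in iterations per chain.
#' @param groups group labels to model (defaults to those in `design`;
#'   required when `design` is empty).
#' @return Object of class `posterior_sample`: list with `draws` (per-chain
#'   matrices of fixed effects and SDs), `accept` (mean acceptance rates)
#'   and `priors`.
#' @export
mcmc_sample <- function(design, priors = obsnet_priors(), n_chains = 2,
                        n_iter = 1000, seed = 1, burn_in = 500,
                        groups = NULL) {
  if (n_chains < 2) stop("mcmc_sample: at least 2 chains required", call. = FALSE)
  if (n_iter < 1000) stop("mcmc_sample: at least 1000 kept iterations required",
                          call. = FALSE)
  groups <- groups %||% sort(unique(design$group))
  if (!length(groups)) stop("mcmc_sample: no groups (empty design needs `groups`)",
                            call. = FALSE)
  observers <- sort(unique(design$observer))
  manipulators <- sort(unique(design$manipulator))
  G <- length(groups)
  par_names <- c(as.vector(outer(glmm_effect_names, groups,
                                 function(e, g) paste0(e, ".g", g))),
                 "sd_observer", "sd_manipulator")

  Xf <- if (nrow(design)) cbind(1, design$kin, design$age_diff,
                                design$rank_diff, design$prev) else NULL
  grp_rows <- lapply(groups, function(g) which(design$group == g))
  obs_rows <- lapply(observers, function(o) which(design$observer == o))
  man_rows <- lapply(manipulators, function(m) which(design$manipulator == m))
  y <- design$y

  run_chain <- function(chain) {
    set.seed(seed + chain - 1)
    fixed <- matrix(0, G, 5, dimnames = list(as.character(groups), glmm_effect_names))
    u <- stats::setNames(rep(0, length(observers)), observers)
    v <- stats::setNames(rep(0, length(manipulators)), manipulators)
    sd_u <- 0.5; sd_v <- 0.5
    eta <- if (nrow(design)) glmm_linpred(list(fixed = fixed, u = u, v = v), design)
           else numeric(0)
    llrow <- if (length(eta)) y * eta - log1pexp(eta) else numeric(0)

    sc_fixed <- matrix(0.3, G, 5)
    sc_u <- rep(0.3, length(u)); sc_v <- rep(0.3, length(v))
    sc_sd <- c(0.4, 0.4)
    acc <- num <- list(fixed = matrix(0, G, 5), u = numeric(length(u)),
                       v = numeric(length(v)), sd = c(0, 0))
    total <- burn_in + n_iter
    keep <- matrix(NA_real_, n_iter, length(par_names),
                   dimnames = list(NULL, par_names))

    for (it in seq_len(total)) {
      # fixed effects, scalar RW
      for (gi in seq_len(G)) for (j in seq_len(5)) {
        step <- stats::rnorm(1, 0, sc_fixed[gi, j])
        rows <- grp_rows[[gi]]
        d_lp <- stats::dnorm(fixed[gi, j] + step, 0, priors$fixed_sd, log = TRUE) -
                stats::dnorm(fixed[gi, j], 0, priors$fixed_sd, log = TRUE)
        if (length(rows)) {
          eta_new <- eta[rows] + step * Xf[rows, j]
          ll_new <- y[rows] * eta_new - log1pexp(eta_new)
          d_lp <- d_lp + sum(ll_new) - sum(llrow[rows])
        }
        num$fixed[gi, j] <- num$fixed[gi, j] + 1
        if (log(stats::runif(1)) < d_lp) {
          fixed[gi, j] <- fixed[gi, j] + step
          if (length(rows)) { eta[rows] <- eta_new; llrow[rows] <- ll_new }
          acc$fixed[gi, j] <- acc$fixed[gi, j] + 1
        }
      }
      # observer effects: disjoint rows, vector of independent accepts
      if (length(u)) {
        steps <- stats::rnorm(length(u), 0, sc_u)
        for (i in seq_along(u)) {
          rows <- obs_rows[[i]]
          eta_new <- eta[rows] + steps[i]
          ll_new <- y[rows] * eta_new - log1pexp(eta_new)
          d_lp <- sum(ll_new) - sum(llrow[rows]) +
            stats::dnorm(u[i] + steps[i], 0, sd_u, log = TRUE) -
            stats::dnorm(u[i], 0, sd_u, log = TRUE)
          num$u[i] <- num$u[i] + 1
          if (log(stats::runif(1)) < d_lp) {
            u[i] <- u[i] + steps[i]; eta[rows] <- eta_new; llrow[rows] <- ll_new
            acc$u[i] <- acc$u[i] + 1
          }
        }
      }
      if (length(v)) {
        steps <- stats::rnorm(length(v), 0, sc_v)
        for (i in seq_along(v)) {
          rows <- man_rows[[i]]
          eta_new <- eta[rows] + steps[i]
          ll_new <- y[rows] * eta_new - log1pexp(eta_new)
          d_lp <- sum(ll_new) - sum(llrow[rows]) +
            stats::dnorm(v[i] + steps[i], 0, sd_v, log = TRUE) -
            stats::dnorm(v[i], 0, sd_v, log = TRUE)
          num$v[i] <- num$v[i] + 1
          if (log(stats::runif(1)) < d_lp) {
            v[i] <- v[i] + steps[i]; eta[rows] <- eta_new; llrow[rows] <- ll_new
            acc$v[i] <- acc$v[i] + 1
          }
        }
      }
      # random-effect SDs, RW on log scale (half-normal prior + Jacobian)
      sd_target <- function(s, re) sum(stats::dnorm(re, 0, s, log = TRUE)) +
        stats::dnorm(s, 0, priors$re_sd_scale, log = TRUE) + log(s)
      for (b in 1:2) {
        cur <- if (b == 1) sd_u else sd_v
        re <- if (b == 1) u else v
        prop <- cur * exp(stats::rnorm(1, 0, sc_sd[b]))
        num$sd[b] <- num$sd[b] + 1
        if (log(stats::runif(1)) < sd_target(prop, re) - sd_target(cur, re)) {
          if (b == 1) sd_u <- prop else sd_v <- prop
          acc$sd[b] <- acc$sd[b] + 1
        }
      }
      # scale adaptation during burn-in
      if (it <= burn_in && it %% 50 == 0) {
        adapt <- function(sc, a, n) sc * exp(pmin(pmax(a / pmax(n, 1) - 0.44, -0.5), 0.5))
        sc_fixed <- adapt(sc_fixed, acc$fixed, num$fixed)
        if (length(u)) sc_u <- adapt(sc_u, acc$u, num$u)
        if (length(v)) sc_v <- adapt(sc_v, acc$v, num$v)
        sc_sd <- adapt(sc_sd, acc$sd, num$sd)
        acc <- list(fixed = matrix(0, G, 5), u = numeric(length(u)),
                    v = numeric(length(v)), sd = c(0, 0))
        num <- acc
      }
      if (it > burn_in)
        keep[it - burn_in, ] <- c(as.vector(t(fixed)), sd_u, sd_v)
    }
    list(draws = keep,
         accept = c(fixed = sum(acc$fixed) / max(sum(num$fixed), 1),
                    sd = sum(acc$sd) / max(sum(num$sd), 1)))
  }

  chains <- lapply(seq_len(n_chains), run_chain)
  structure(list(draws = lapply(chains, `[[`, "draws"),
                 accept = lapply(chains, `[[`, "accept"),
                 priors = priors, groups = groups, seed = seed),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("<posterior_sample>", length(x$draws), "chains x", nrow(x$draws[[1]]),
      "iterations,", ncol(x$draws[[1]]), "parameters\n")
  invisible(x)
}

#' Highest posterior density interval
#'
#' Narrowest interval containing the requested posterior mass, found by
#' scanning all windows of the sorted draws.
#'
#' @param x numeric draws.
#' @param level posterior mass (default 0.95).
#' @return `c(lower, upper)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1, ceiling(level * n))   # points the interval must contain
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Rank-normalized split R-hat
#'
#' Each chain is split in half, all draws are rank-normalized jointly
#' (normal scores of average ranks), and the classic potential scale
#' reduction factor is computed on the normalized split chains.
#'
#' @param sample a [mcmc_sample()] result, or a list of draw matrices with
#'   identical columns.
#' @return Named vector of R-hat values, one per parameter.
#' @export
rhat <- function(sample) {
  draws <- if (inherits(sample, "posterior_sample")) sample$draws else sample
  if (length(draws) < 2) stop("rhat: at least 2 chains required", call. = FALSE)
  one <- function(mat_list) {
    split_half <- function(m) {
      n <- floor(nrow(m) / 2) * 2
      list(m[seq_len(n / 2), , drop = FALSE], m[(n / 2 + 1):n, , drop = FALSE])
    }
    mats <- unlist(lapply(mat_list, split_half), recursive = FALSE)
    vapply(seq_len(ncol(mats[[1]])), function(j) {
      xs <- lapply(mats, function(m) m[, j])
      all_x <- unlist(xs)
      z <- stats::qnorm((rank(all_x, ties.method = "average") - 3 / 8) /
                          (length(all_x) + 1 / 4))
      zc <- split(z, rep(seq_along(xs), lengths(xs)))
      n <- length(zc[[1]]); m <- length(zc)
      means <- vapply(zc, mean, 0)
      W <- mean(vapply(zc, stats::var, 0))
      B <- n * stats::var(means)
      sqrt(((n - 1) / n * W + B / n) / W)
    }, 0)
  }
  out <- one(draws)
  names(out) <- colnames(draws[[1]])
  out
}

#' Posterior odds ratios with HPD intervals
#'
#' For each effect in each group: the odds ratio as the back-transformed
#' posterior mean of the coefficient, with the HPD interval of the
#' back-transformed draws; plus, when two groups are present, the
#' between-group ratio of each effect from the per-draw coefficient
#' difference. Refuses to summarize an unconverged sample
#' (any R-hat above 1.05) unless `force = TRUE`.
#'
#' @param sample a [mcmc_sample()] result.
#' @param level HPD mass (default 0.95).
#' @param force bypass the convergence gate.
#' @return Data frame with columns `effect`, `group`, `or`, `hpd_lower`,
#'   `hpd_upper`, `rhat`.
#' @export
odds_ratios_hpd <- function(sample, level = 0.95, force = FALSE) {
  stopifnot(inherits(sample, "posterior_sample"))
  rh <- rhat(sample)
  if (!force && any(rh > 1.05, na.rm = TRUE))
    stop("odds_ratios_hpd: unconverged sample (max R-hat = ",
         round(max(rh, na.rm = TRUE), 3), "); rerun longer or use force = TRUE",
         call. = FALSE)
  all_draws <- do.call(rbind, sample$draws)
  effects <- setdiff(glmm_effect_names, "intercept")
  rows <- list()
  for (e in effects) for (g in sample$groups) {
    col <- paste0(e, ".g", g)
    d <- all_draws[, col]
    h <- hpd_interval(exp(d), level)
    rows[[length(rows) + 1]] <- data.frame(
      effect = e, group = as.character(g), or = exp(mean(d)),
      hpd_lower = h[1], hpd_upper = h[2], rhat = unname(rh[col]),
      stringsAsFactors = FALSE)
  }
  if (length(sample$groups) == 2) {
    g1 <- sample$groups[1]; g2 <- sample$groups[2]
    for (e in effects) {
      d <- all_draws[, paste0(e, ".g", g1)] - all_draws[, paste0(e, ".g", g2)]
      h <- hpd_interval(exp(d), level)
      rows[[length(rows) + 1]] <- data.frame(
        effect = e, group = sprintf("ratio %s/%s", g1, g2), or = exp(mean(d)),
        hpd_lower = h[1], hpd_upper = h[2], rhat = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  reset_rows(do.call(rbind, rows))
}
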