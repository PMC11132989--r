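#' Akaike's information criterion corrected for small samples
#'
#' `AICc = -2 l + 2 k + 2 k (k + 1) / (n - k - 1)`, with the sample size `n`
#' taken as the number of acquisition events (the likelihood's independent
#' contributions).
#'
#' @param loglik maximized log likelihood.
#' @param k number of free parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1)
    stop("aicc: sample size n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights of a compared model set
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with `Delta` relative
#' to the smallest AICc (subtracting the minimum keeps the exponentials
#' stable).
#'
#' @param aiccs vector of finite AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) == 0) stop("akaike_weights: empty model set", call. = FALSE)
  if (any(!is.finite(aiccs))) stop("akaike_weights: non-finite AICc", call. = FALSE)
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Enumerate a candidate model set
#'
#' Builds the full duplicate-free list of [oada_model_spec()] candidates for
#' a set of networks, s-constraints (hypotheses) and an ILV enumeration
#' scheme. The group network is only combined with `s1_eq_s2`. The asocial
#' set (all `s = 0`) carries asocial ILV coefficients only and is enumerated
#' once (its likelihood does not depend on any network).
#'
#' Schemes: `"joint_in_out"` toggles each ILV in or out of the model as a
#' whole (in = coefficients on both the asocial and social rates; `2^3 = 8`
#' patterns); `"independent"` toggles each ILV independently on each rate
#' (`4^3 = 64` patterns).
#'
#' @param config list with elements `networks` (character), `hypotheses`
#'   (subset of `c("s1_ne_s2","s1_eq_s2","s2_zero","s1_zero")`), `ilvs`
#'   (default `c("sex","age","rank")`), `scheme` (default
#'   `"joint_in_out"`) and `include_asocial` (default `TRUE`).
#' @return List of [oada_model_spec()] objects.
#' @export
enumerate_model_set <- function(config = list()) {
  networks <- config$networks %||% c("absolute_observation", "individuals_observed",
                                     "single_observation", "group")
  hypotheses <- config$hypotheses %||% c("s1_ne_s2", "s1_eq_s2", "s2_zero", "s1_zero")
  ilvs <- config$ilvs %||% c("sex", "age", "rank")
  scheme <- config$scheme %||% "joint_in_out"
  include_asocial <- config$include_asocial %||% TRUE

  subsets <- function(x) {
    out <- list(character(0))
    for (v in x) out <- c(out, lapply(out, function(s) c(s, v)))
    out
  }
  patterns <- switch(scheme,
    joint_in_out = lapply(subsets(ilvs), function(s) list(asocial = s, social = s)),
    independent = {
      pats <- list()
      for (a in subsets(ilvs)) for (g in subsets(ilvs))
        pats[[length(pats) + 1]] <- list(asocial = a, social = g)
      pats
    },
    stop("enumerate_model_set: unknown ILV scheme: ", scheme, call. = FALSE))

  specs <- list()
  for (net in networks) {
    hyps <- if (net == "group") intersect(hypotheses, "s1_eq_s2") else hypotheses
    for (h in hyps) for (p in patterns)
      specs[[length(specs) + 1]] <- oada_model_spec(net, h, p$asocial, p$social)
  }
  if (include_asocial) {
    aso_pats <- unique(lapply(patterns, `[[`, "asocial"))
    for (p in aso_pats)
      specs[[length(specs) + 1]] <- oada_model_spec(networks[1], "asocial", p)
  }
  keys <- vapply(specs, function(s) paste(
    if (s$s_constraint == "asocial") "asocial" else s$network_variant,
    s$s_constraint, paste(s$ilv_asocial, collapse = "+"),
    paste(s$ilv_social, collapse = "+"), sep = "|"), "")
  specs[!duplicated(keys)]
}

#' Fit a full candidate model set
#'
#' Fits every spec in the set to one event log, assembling the model table
#' (log likelihood, AICc, delta-AICc and Akaike weights over all fitted
#' models).
#'
#' @param specs list of [oada_model_spec()] (e.g. from
#'   [enumerate_model_set()]).
#' @param log an [event_log()].
#' @param ilv an [ilv_table()].
#' @return An object of class `model_set`: list with `fits` and `table`
#'   (one row per model: `network`, `s_constraint`, `ilv_asocial`,
#'   `ilv_social`, `loglik`, `n_params`, `aicc`, `delta_aicc`,
#'   `akaike_weight`).
#' @export
fit_model_set <- function(specs, log, ilv) {
  variants <- unique(vapply(specs, `[[`, "", "network_variant"))
  data_cache <- lapply(variants, function(v) oada_data(log, ilv, v))
  names(data_cache) <- variants
  fits <- lapply(specs, function(sp) fit_oada(sp, data_cache[[sp$network_variant]]))
  tab <- data.frame(
    network = vapply(specs, `[[`, "", "network_variant"),
    s_constraint = vapply(specs, `[[`, "", "s_constraint"),
    ilv_asocial = vapply(specs, function(s) paste(s$ilv_asocial, collapse = "+"), ""),
    ilv_social = vapply(specs, function(s) paste(s$ilv_social, collapse = "+"), ""),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_params = vapply(fits, `[[`, 0, "n_params"),
    aicc = vapply(fits, `[[`, 0, "aicc"),
    stringsAsFactors = FALSE)
  tab$network[tab$s_constraint == "asocial"] <- "none"
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$akaike_weight <- akaike_weights(tab$aicc)
  structure(list(fits = fits, table = tab), class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("<model_set>", nrow(x$table), "fitted models\n")
  tab <- x$table[order(x$table$delta_aicc), ]
  print(utils::head(tab, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Total Akaike-weight support by hypothesis or network
#'
#' Sums Akaike weights within each category and reports shares as
#' percentages over the named comparison set. Asocial models (which are
#' assessed via profile confidence intervals, not total weight) are excluded
#' by default; weights are renormalized over the compared subset so shares
#' sum to 100.
#'
#' @param mset a [fit_model_set()] result (or its `table`).
#' @param by `"hypothesis"` (the s-constraint) or `"network"`.
#' @param include_asocial include the asocial rows in the comparison.
#' @return Named vector of percentage shares summing to 100; the comparison
#'   set is recorded in attribute `comparison`.
#' @export
total_support <- function(mset, by = c("hypothesis", "network"),
                          include_asocial = FALSE) {
  by <- match.arg(by)
  tab <- if (inherits(mset, "model_set")) mset$table else mset
  if (!include_asocial) tab <- tab[tab$s_constraint != "asocial", , drop = FALSE]
  w <- akaike_weights(tab$aicc)
  cat_var <- if (by == "hypothesis") tab$s_constraint else tab$network
  shares <- 100 * vapply(split(w, cat_var), sum, 0) / sum(w)
  structure(shares[order(-shares)],
            comparison = sprintf("%s models, %s categories%s", nrow(tab), by,
                                 if (include_asocial) " (asocial included)" else ""))
}

#' Support ratio between two subsets of a model table
#'
#' Ratio of summed Akaike weights of two subsets (e.g. one network/
#' constraint combination against another).
#'
#' @param mset a [fit_model_set()] result (or its `table`).
#' @param a,b logical vectors selecting the rows of the two compared
#'   subsets.
#' @return `sum(w[a]) / sum(w[b])`; `Inf` with a warning when the
#'   denominator subset has zero weight.
#' @export
support_ratio <- function(mset, a, b) {
  tab <- if (inherits(mset, "model_set")) mset$table else mset
  wa <- sum(tab$akaike_weight[a]); wb <- sum(tab$akaike_weight[b])
  if (wb == 0) {
    warning("support_ratio: denominator subset has zero weight")
    return(Inf)
  }
  wa / wb
}

#' Model-averaged parameter estimate
#'
#' Akaike-weight average of a parameter over every model in the set; models
#' where the parameter is fixed to 0 by constraint contribute 0.
#'
#' @param mset a [fit_model_set()] result.
#' @param quantity `"s"` (default) or the name of an ILV coefficient on the
#'   asocial (`"beta:<ilv>"`) or social (`"gamma:<ilv>"`) rate.
#' @param group group label whose `s` is averaged (default: first group).
#' @return The weighted estimate.
#' @export
model_average <- function(mset, quantity = "s", group = NULL) {
  stopifnot(inherits(mset, "model_set"))
  w <- mset$table$akaike_weight
  vals <- vapply(mset$fits, function(f) {
    if (quantity == "s") {
      s <- f$params$s_by_group
      g <- if (is.null(group)) names(s)[1] else as.character(group)
      unname(s[g])
    } else {
      parts <- strsplit(quantity, ":", fixed = TRUE)[[1]]
      block <- if (parts[1] == "beta") f$params$beta else f$params$gamma
      nm <- if (parts[1] == "beta") f$spec$ilv_asocial else f$spec$ilv_social
      i <- match(parts[2], nm)
      if (is.na(i)) 0 else block[i]
    }
  }, 0)
  sum(w * vals)
}
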