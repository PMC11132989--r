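# Hand-rolled brute-force oracles, written independently of the package
# internals: plain loops over events and explicit recounts of observations.

# Exposure of observer `i` at strictly-before time `t` under a variant,
# recounted directly from the observation rows.
brute_exposure <- function(observations, ilv_df, i, t, variant,
                           informed_ids = NULL) {
  mine <- observations[observations$observer == i & observations$time < t, ,
                       drop = FALSE]
  if (variant == "absolute_observation") return(nrow(mine))
  if (variant == "individuals_observed") return(length(unique(mine$solver)))
  if (variant == "single_observation") return(as.numeric(nrow(mine) > 0))
  if (variant == "group") {
    g <- ilv_df$group[ilv_df$id == i]
    others <- setdiff(informed_ids, i)
    return(sum(ilv_df$group[match(others, ilv_df$id)] == g))
  }
  stop("unknown variant")
}

# Order-of-acquisition log likelihood by explicit enumeration of the event
# sums. `ilv_df` must carry id, group, sex, age, rank, trained columns;
# covariates are centred here the same way the model defines its baseline.
brute_oada_loglik <- function(solves, observations, ilv_df, s_by_group,
                              beta = c(), gamma = c(),
                              variant = "absolute_observation") {
  untr <- !ilv_df$trained
  x <- cbind(sex = as.numeric(ilv_df$sex),
             age = ilv_df$age - mean(ilv_df$age[untr]),
             rank = ilv_df$rank - median(ilv_df$rank[untr]))
  rownames(x) <- ilv_df$id
  lc <- function(i, coefs) {
    if (!length(coefs)) return(0)
    sum(coefs * x[i, names(coefs)])
  }
  solves <- solves[order(solves$time), , drop = FALSE]
  first <- solves[!duplicated(solves$id), , drop = FALSE]
  events <- first[!ilv_df$trained[match(first$id, ilv_df$id)], , drop = FALSE]
  acquired <- character(0)
  informed <- ilv_df$id[ilv_df$trained]
  ll <- 0
  for (k in seq_len(nrow(events))) {
    a <- events$id[k]; t <- events$time[k]
    risk <- setdiff(ilv_df$id[!ilv_df$trained], acquired)
    r <- sapply(risk, function(i) {
      g <- as.character(ilv_df$group[ilv_df$id == i])
      e <- brute_exposure(observations, ilv_df, i, t, variant, informed)
      s_by_group[[g]] * e * exp(lc(i, gamma)) + exp(lc(i, beta))
    })
    ll <- ll + log(r[[a]]) - log(sum(r))
    acquired <- c(acquired, a)
    informed <- c(informed, a)
  }
  ll
}

# Two-stage log likelihood by explicit interleaved state tracking.
brute_multistate_loglik <- function(log, ilv_df, s1_by_group, s2_by_group,
                                    beta1 = c(), beta2 = c(),
                                    gamma1 = c(), gamma2 = c()) {
  untr_ids <- ilv_df$id[!ilv_df$trained]
  untr <- !ilv_df$trained
  x <- cbind(sex = as.numeric(ilv_df$sex),
             age = ilv_df$age - mean(ilv_df$age[untr]),
             rank = ilv_df$rank - median(ilv_df$rank[untr]))
  rownames(x) <- ilv_df$id
  lc <- function(i, coefs) if (!length(coefs)) 0 else sum(coefs * x[i, names(coefs)])
  first_time <- function(df, id) {
    tt <- df$time[df$id == id]
    if (length(tt)) min(tt) else NA_real_
  }
  tm <- sapply(untr_ids, function(i) first_time(log$first_manipulations, i))
  ts <- sapply(untr_ids, function(i) first_time(log$solves, i))
  coerced <- is.na(tm) & !is.na(ts)
  tm[coerced] <- ts[coerced]
  trans <- rbind(
    data.frame(time = tm[!is.na(tm)], id = untr_ids[!is.na(tm)], stage = 1),
    data.frame(time = ts[!is.na(ts)], id = untr_ids[!is.na(ts)], stage = 2))
  trans <- trans[order(trans$time, trans$stage), ]
  state <- setNames(rep(0, length(untr_ids)), untr_ids)
  ll <- 0
  for (k in seq_len(nrow(trans))) {
    a <- trans$id[k]; t <- trans$time[k]; stg <- trans$stage[k]
    risk <- untr_ids[state[untr_ids] == stg - 1]
    s_by_group <- if (stg == 1) s1_by_group else s2_by_group
    beta <- if (stg == 1) beta1 else beta2
    gamma <- if (stg == 1) gamma1 else gamma2
    r <- sapply(risk, function(i) {
      g <- as.character(ilv_df$group[ilv_df$id == i])
      e <- nrow(log$observations[log$observations$observer == i &
                                   log$observations$time < t, , drop = FALSE])
      s_by_group[[g]] * e * exp(lc(i, gamma)) + exp(lc(i, beta))
    })
    ll <- ll + log(r[[a]]) - log(sum(r))
    state[a] <- stg
  }
  ll
}

# Narrowest interval holding at least `level` mass: exhaustive pair search.
brute_hpd <- function(x, level = 0.95) {
  x <- sort(x); n <- length(x); m <- ceiling(level * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    j <- i + m - 1
    if (x[j] - x[i] < best[2] - best[1]) best <- c(x[i], x[j])
  }
  best
}
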