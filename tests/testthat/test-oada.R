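test_that("uniform-order null and symmetry cases are exact", {
  toy <- random_toy(11, n = 6)
  data <- oada_data(toy$log, toy$ilv, "absolute_observation")
  spec <- oada_model_spec("absolute_observation", "asocial")

  # s = 0, no ILVs: sum of log(1/n_k) over shrinking risk sets
  n_k <- rowSums(data$risk)
  expect_equal(oada_loglik(list(s_by_group = c(`1` = 0)), spec, data),
               sum(log(1 / n_k)))

  # two naive individuals with equal exposures and covariates: first event
  # contributes log(1/2) whatever the parameters
  ilv2 <- ilv_table(data.frame(id = c("A", "B", "C"), group = 1,
                               sex = c(0, 1, 1), age = c(20, 15, 15),
                               rank = c(3, 1, 1),
                               trained = c(TRUE, FALSE, FALSE)))
  log2 <- event_log(
    solves = data.frame(time = c(1, 2, 3), id = c("A", "B", "C")),
    observations = data.frame(time = c(1, 1), observer = c("B", "C"),
                              solver = c("A", "A")))
  d2 <- oada_data(log2, ilv2, "absolute_observation")
  for (s in c(0, 1, 7)) {
    ll <- oada_loglik(list(s_by_group = c(`1` = s), beta = 0.3, gamma = -0.2),
                      oada_model_spec("absolute_observation", "s1_eq_s2",
                                      "age", "age"), d2)
    first_term <- log(1 / 2)
    # second event is a singleton risk set: contributes 0
    expect_equal(ll, first_term)
  }
})

test_that("likelihood matches brute-force enumeration on small diffusions", {
  # includes a 4-individual toy with exposures {0,1,2,3} before the event
  ilv <- ilv_table(data.frame(id = c("Z", "P", "Q", "R", "S"), group = 1,
                              sex = c(0, 0, 1, 0, 1), age = c(25, 10, 14, 18, 22),
                              rank = c(5, 1, 2, 3, 4),
                              trained = c(TRUE, rep(FALSE, 4))))
  obs <- data.frame(
    time = c(1, 2, 2, 3, 3, 3),
    observer = c("Q", "Q", "R", "Q", "R", "S"),
    solver = "Z")
  log <- event_log(solves = data.frame(time = c(1, 2, 3, 4, 5),
                                       id = c("Z", "Z", "Z", "S", "Q")),
                   observations = obs)
  data <- oada_data(log, ilv, "absolute_observation")
  # P, Q, R, S exposures before t = 4: 0, 3, 2, 1
  expect_equal(unname(data$E[1, c("P", "Q", "R", "S")]), c(0, 3, 2, 1))

  cases <- list(
    list(s = 1, beta = c(), gamma = c()),
    list(s = 0.37, beta = c(), gamma = c()),
    list(s = 2, beta = c(age = 0.1, sex = -0.4), gamma = c(rank = 0.2)))
  for (cs in cases) {
    spec <- oada_model_spec("absolute_observation", "s1_eq_s2",
                            ilv_asocial = names(cs$beta),
                            ilv_social = names(cs$gamma))
    got <- oada_loglik(list(s_by_group = c(`1` = cs$s), beta = unname(cs$beta),
                            gamma = unname(cs$gamma)), spec, data)
    want <- brute_oada_loglik(log$solves, log$observations, ilv_as_df(ilv),
                              s_by_group = list(`1` = cs$s),
                              beta = cs$beta, gamma = cs$gamma)
    expect_equal(got, want, tolerance = 1e-12)
  }

  # random two-group toys across all variants
  for (seed in 21:24) {
    toy <- random_toy(seed, n = 6, two_groups = TRUE)
    for (v in c("absolute_observation", "individuals_observed",
                "single_observation", "group")) {
      data <- oada_data(toy$log, toy$ilv, v)
      spec <- oada_model_spec(v, "s1_eq_s2")
      got <- oada_loglik(list(s_by_group = c(`1` = 0.8, `2` = 0.8)), spec, data)
      want <- brute_oada_loglik(toy$log$solves, toy$log$observations,
                                ilv_as_df(toy$ilv),
                                s_by_group = list(`1` = 0.8, `2` = 0.8),
                                variant = v)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("event probabilities sum to one over each risk set", {
  for (seed in 31:34) {
    toy <- random_toy(seed, n = 6, two_groups = seed %% 2 == 0)
    data <- oada_data(toy$log, toy$ilv, "absolute_observation")
    for (s in c(0, 0.5, 3)) {
      p <- list(s_by_group = stats::setNames(rep(s, length(data$groups)),
                                             data$groups),
                beta = 0.2, gamma = -0.1)
      spec <- oada_model_spec("absolute_observation", "s1_eq_s2", "rank", "age")
      ex <- socdiff:::expand_params(p, spec, data)
      r <- sweep(data$E, 2, ex$s_ind * ex$social_mult, "*")
      r <- sweep(r, 2, ex$asocial_mult, "+")
      probs <- (r / rowSums(r * data$risk)) * data$risk
      expect_equal(unname(rowSums(probs)), rep(1, data$K))
    }
  }
})

test_that("only the order of acquisition matters, not the clock", {
  toy <- random_toy(41, n = 6)
  spec <- oada_model_spec("absolute_observation", "s1_eq_s2")
  d1 <- oada_data(toy$log, toy$ilv, "absolute_observation")
  # strictly monotone rescalings of the time axis
  for (f in list(function(t) 2 * t + 1, function(t) t^1.5, function(t) log1p(t) * 10)) {
    log2 <- event_log(
      solves = transform(toy$log$solves, time = f(time)),
      observations = transform(toy$log$observations, time = f(time)))
    d2 <- oada_data(log2, toy$ilv, "absolute_observation")
    p <- list(s_by_group = c(`1` = 1.3))
    expect_equal(oada_loglik(p, spec, d1), oada_loglik(p, spec, d2))
  }
})

test_that("optimizer attains the grid-search maximum", {
  toy <- random_toy(51, n = 6)
  data <- oada_data(toy$log, toy$ilv, "absolute_observation")
  spec <- oada_model_spec("absolute_observation", "s1_eq_s2")
  fit <- fit_oada(spec, data)
  grid <- c(0, 10^seq(-3, 3, length.out = 801))
  ll_grid <- vapply(grid, function(s)
    oada_loglik(list(s_by_group = c(`1` = s)), spec, data), 0)
  expect_gte(fit$loglik, max(ll_grid) - 1e-6)
  # nesting: free s never fits worse than s = 0
  ll0 <- oada_loglik(list(s_by_group = c(`1` = 0)), spec, data)
  expect_gte(fit$loglik, ll0)
})

test_that("asocial fits with no ILVs reproduce the uniform-order null exactly", {
  toy <- random_toy(61, n = 6)
  data <- oada_data(toy$log, toy$ilv, "absolute_observation")
  fit <- fit_oada(oada_model_spec("absolute_observation", "asocial"), data)
  expect_equal(fit$n_params, 0)
  expect_equal(fit$loglik, sum(log(1 / rowSums(data$risk))))
  expect_equal(fit$aicc, -2 * fit$loglik)
})

test_that("profile CI is (0, Inf) when exposures carry no information", {
  ilv <- toy_ilv_one_group()
  log <- event_log(solves = data.frame(time = 1:3 + 3, id = c("B", "C", "D")))
  data <- oada_data(log, ilv, "absolute_observation")
  expect_true(all(data$E == 0))
  fit <- fit_oada(oada_model_spec("absolute_observation", "s1_eq_s2"), data)
  ci <- profile_ci_s(fit)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], Inf)
})

test_that("simulated social data are separable from asocial data", {
  fits <- function(s_true, seeds) {
    vapply(seeds, function(sd) {
      cfg <- simulation_config(n_groups = 1, n_per_group = 15, n_sessions = 39,
                               session_hours = 2, demo_solve_rate = 1,
                               learner_solve_rate = 1, attendance_beta = c(1, 3),
                               s_by_group = s_true, baseline_rate = 0.05,
                               max_acquisitions = 10, seed = sd)
      st <- simulate_diffusion(cfg)
      d <- oada_data(st$log, st$ilv, "absolute_observation")
      f <- fit_oada(oada_model_spec("absolute_observation", "s1_eq_s2"), d)
      unname(f$params$s_by_group[1])
    }, 0)
  }
  s0 <- fits(0, 1:25)
  s2 <- fits(2, 101:125)
  expect_lt(median(s0), median(s2))
  expect_lt(median(s0), 1)

  # strong social signal: positive s and likelihood above the asocial null
  cfg <- simulation_config(n_groups = 1, n_per_group = 15, n_sessions = 39,
                           session_hours = 2, demo_solve_rate = 1,
                           learner_solve_rate = 1, attendance_beta = c(2, 2),
                           s_by_group = 20, baseline_rate = 0.01,
                           max_acquisitions = 10, seed = 77)
  st <- simulate_diffusion(cfg)
  d <- oada_data(st$log, st$ilv, "absolute_observation")
  f <- fit_oada(oada_model_spec("absolute_observation", "s1_eq_s2"), d)
  expect_gt(unname(f$params$s_by_group[1]), 0)
  expect_gt(f$loglik, sum(log(1 / rowSums(d$risk))))
})

test_that("percent ST attributes event-wise social fractions", {
  # two events engineered to fractions 1/2 and 2/3: s*E = 1 then 2, asocial 1
  ilv <- toy_ilv_one_group()
  log <- event_log(
    solves = data.frame(time = c(1, 2, 3, 4), id = c("A", "A", "B", "C")),
    observations = data.frame(time = c(1, 2, 2), observer = c("B", "C", "C"),
                              solver = "A"))
  data <- oada_data(log, ilv, "absolute_observation")
  spec <- oada_model_spec("absolute_observation", "s1_eq_s2")
  expect_equal(unname(data$E[cbind(1:2, data$acq_col)]), c(1, 2))
  expect_equal(percent_st(list(s_by_group = c(`1` = 1)), spec, data),
               100 * mean(c(1 / 2, 2 / 3)))
  expect_equal(round(percent_st(list(s_by_group = c(`1` = 1)), spec, data), 2),
               58.33)
  # s = 0: no social attribution; s huge: all of it
  expect_equal(percent_st(list(s_by_group = c(`1` = 0)), spec, data), 0)
  expect_equal(percent_st(list(s_by_group = c(`1` = 1e12)), spec, data),
               100, tolerance = 1e-9)
})

test_that("relative rate is the social multiplier at the baseline", {
  expect_equal(relative_rate(0.461, 10), 5.61)
  expect_equal(relative_rate(123.4, 0), 1)
  expect_equal(relative_rate(2, 3), 7)
})
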