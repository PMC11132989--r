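# Small in-code fixtures shared across test files.

toy_ilv <- function(n = 6, groups = c(1, 1, 1, 2, 2, 2),
                    trained = c(TRUE, rep(FALSE, n - 1)), kin = NULL) {
  ids <- LETTERS[seq_len(n)]
  ilv_table(data.frame(
    id = ids, group = groups[seq_len(n)],
    sex = rep_len(c(0, 1), n), age = seq(10, by = 4, length.out = n),
    rank = seq_len(n), trained = trained[seq_len(n)],
    stringsAsFactors = FALSE), kin = kin)
}

# One-group diffusion: trained demonstrator A; B, C, D naive. A solves at
# t = 1, 2, 3, 4; B watches all of them it can, C watches one, D none.
# B first-solves at t = 5, C at t = 7.
toy_log <- function() {
  event_log(
    solves = data.frame(
      time = c(1, 2, 3, 4, 5, 7),
      id = c("A", "A", "A", "A", "B", "C"), stringsAsFactors = FALSE),
    observations = data.frame(
      time = c(1, 2, 3, 2, 5),
      observer = c("B", "B", "B", "C", "D"),
      solver = c("A", "A", "A", "A", "B"), stringsAsFactors = FALSE),
    first_manipulations = data.frame(
      time = c(0.5, 2.5, 6), id = c("B", "C", "D"), stringsAsFactors = FALSE))
}

toy_ilv_one_group <- function() {
  ilv_table(data.frame(
    id = c("A", "B", "C", "D"), group = 1,
    sex = c(0, 1, 0, 1), age = c(20, 12, 16, 24), rank = c(4, 2, 3, 1),
    trained = c(TRUE, FALSE, FALSE, FALSE), stringsAsFactors = FALSE))
}

ilv_as_df <- function(ilv) as.data.frame(ilv)

# Random toy diffusion for property-style loops: n individuals in one or
# two groups, a trained demonstrator per group, random solves/observations.
random_toy <- function(seed, n = 6, two_groups = FALSE) {
  set.seed(seed)
  groups <- if (two_groups) rep(1:2, length.out = n) else rep(1, n)
  trained <- !duplicated(groups)
  ilv <- ilv_table(data.frame(
    id = LETTERS[seq_len(n)], group = groups,
    sex = rbinom(n, 1, 0.5), age = runif(n, 8, 40),
    rank = sample(n), trained = trained, stringsAsFactors = FALSE))
  demo <- ilv$id[trained]
  t_demo <- sort(runif(8, 0, 10))
  solves <- data.frame(time = t_demo,
                       id = sample(demo, 8, replace = TRUE),
                       stringsAsFactors = FALSE)
  # naive individuals acquire in random order at later times
  naive <- sample(ilv$id[!trained])
  n_acq <- sample(3:min(4, length(naive)), 1)
  acq_t <- sort(runif(n_acq, 10, 20))
  solves <- rbind(solves, data.frame(time = acq_t, id = naive[seq_len(n_acq)],
                                     stringsAsFactors = FALSE))
  obs <- list()
  for (k in seq_len(nrow(solves))) {
    cand <- setdiff(ilv$id[ilv$group == ilv$group[match(solves$id[k], ilv$id)]],
                    solves$id[k])
    seen <- cand[runif(length(cand)) < 0.5]
    if (length(seen))
      obs[[length(obs) + 1]] <- data.frame(time = solves$time[k], observer = seen,
                                           solver = solves$id[k],
                                           stringsAsFactors = FALSE)
  }
  log <- event_log(solves = solves,
                   observations = if (length(obs)) do.call(rbind, obs)
                                  else data.frame(time = numeric(0),
                                                  observer = character(0),
                                                  solver = character(0)))
  list(log = log, ilv = ilv)
}
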