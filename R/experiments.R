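#' Strategy profile
#'
#' A fixed (U, T) pair used to initialize individuals in competition
#' experiments.
#'
#' @param label character label (e.g. `"turn_taking"`).
#' @param U update factor in \[-1, 1\].
#' @param T_ giving-up threshold in \[0, 5\].
#' @return list of class `strategy_profile`.
#' @export
strategy_profile <- function(label, U, T_) {
  stopifnot(U >= -1, U <= 1, T_ >= 0, T_ <= 5)
  structure(list(label = label, U = U, T = T_), class = "strategy_profile")
}

# Derive a bounded per-run seed from a base seed and a run index.
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx * 16807) %% 2147483647)
}

#' Main benefit-by-initial-U sweep
#'
#' The central experiment design: one simulation per (benefit, initial U,
#' replicate) combination, with per-run seeds derived from `seed`. At full
#' scale this is benefits 1..10, initial U in \{-1, 1\}, ten replicates
#' (200 runs). Each run records the final-generation population means of U
#' and T, group-averaged DCI and linearity, fight-length statistics and the
#' strategy classification.
#'
#' @param config_template a [sim_config()] or [sim_preset()] supplying all
#'   non-swept parameters.
#' @param benefits numeric vector of benefit values.
#' @param U_inits numeric vector of initial update factors.
#' @param n_replicates replicates per combination.
#' @param seed base seed for per-run seed derivation.
#' @param n_randomizations randomizations for [linearity()].
#' @param keep_individuals if TRUE, attach each run's final-generation
#'   individual table (needed by [derive_strategy_profiles()]).
#' @return data.frame of class `sweep_result`, one row per run: `benefit`,
#'   `U_init`, `replicate`, `seed`, `mean_U`, `mean_T`, `dci`, `linearity`,
#'   `n_fights`, `mean_fight_length`, `strategy`. When `keep_individuals`,
#'   the individual tables are in `attr(, "individuals")`, keyed by row.
#' @export
main_sweep <- function(config_template, benefits = 1:10,
                       U_inits = c(-1, 1), n_replicates = 10L, seed = 1L,
                       n_randomizations = 1000L, keep_individuals = TRUE) {
  grid <- expand.grid(replicate = seq_len(n_replicates), U_init = U_inits,
                      benefit = benefits)
  rows <- vector("list", nrow(grid))
  indiv <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg <- validate_config(utils::modifyList(
      unclass(config_template),
      list(benefit = grid$benefit[k], U_init = grid$U_init[k],
           seed = derive_seed(seed, k))
    ))
    res <- run_simulation(cfg)
    gm <- group_metrics(res, n_randomizations)
    fls <- fight_length_stats(res$fight_lengths)
    rows[[k]] <- data.frame(
      benefit = grid$benefit[k], U_init = grid$U_init[k],
      replicate = grid$replicate[k], seed = cfg$seed,
      mean_U = mean(res$individuals$U), mean_T = mean(res$individuals$T),
      dci = mean(gm$dci, na.rm = TRUE),
      linearity = mean(gm$linearity, na.rm = TRUE),
      n_fights = fls$n,
      mean_fight_length = fls$mean,
      strategy = classify_strategy(res$individuals$U)
    )
    if (keep_individuals) indiv[[k]] <- res$individuals[, c("U", "T")]
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  if (keep_individuals) attr(out, "individuals") <- indiv
  out
}

#' Mean evolved (U, T) per strategy from a sweep
#'
#' Pools the final-generation individuals of all runs at the given benefit
#' that were classified as each strategy, and returns the mean (U, T) per
#' strategy as a pair of [strategy_profile()]s. These evolved means are the
#' initialization for [competition_experiment()].
#'
#' @param sweep_results a `sweep_result` from [main_sweep()] built with
#'   `keep_individuals = TRUE`.
#' @param benefit benefit value at which to derive the profiles.
#' @return list with `turn_taking` and `contest` profiles.
#' @export
derive_strategy_profiles <- function(sweep_results, benefit) {
  indiv <- attr(sweep_results, "individuals")
  if (is.null(indiv)) {
    stop("sweep_results must be built with keep_individuals = TRUE")
  }
  sel <- which(sweep_results$benefit == benefit)
  if (length(sel) == 0L) stop("no runs at benefit ", benefit)
  profiles <- lapply(c(turn_taking = "turn_taking", contest = "contest"),
                     function(lab) {
    runs <- sel[sweep_results$strategy[sel] == lab]
    if (length(runs) == 0L) {
      stop(sprintf("no runs classified '%s' at benefit %s", lab, benefit))
    }
    tab <- do.call(rbind, indiv[runs])
    strategy_profile(lab, U = mean(tab$U), T_ = mean(tab$T))
  })
  profiles
}

#' Two-strategy competition experiment
#'
#' Every group is initialized with `k_a_per_group` individuals carrying
#' strategy A's fixed (U, T) and the rest carrying strategy B's. One
#' generation of conflict rounds is run with no mutation and no
#' reproduction, and the mean final fitness per strategy is recorded. At
#' the published scale these experiments use groups of two (100,000
#' groups; direct dyadic competition) and ten (20,000 groups; indirect
#' competition among dyads).
#'
#' @param strategy_a,strategy_b [strategy_profile()]s.
#' @param group_size,n_groups group structure.
#' @param k_a_per_group number of strategy-A individuals in every group.
#' @param benefit,sigma_eps,n_conflict_rounds conflict-phase parameters.
#' @param initial_fitness starting fitness.
#' @param seed run seed.
#' @return list of class `competition_result`: the arguments plus
#'   `mean_fitness_a`, `mean_fitness_b` (NA when a strategy has no
#'   individuals) and `n_a`, `n_b`.
#' @export
competition_experiment <- function(strategy_a, strategy_b, group_size = 10L,
                                   n_groups = 1000L, k_a_per_group,
                                   benefit = 1, sigma_eps = 1,
                                   n_conflict_rounds = 10L,
                                   initial_fitness = 100, seed = 1L) {
  stopifnot(k_a_per_group >= 0, k_a_per_group <= group_size)
  is_a <- rep(c(rep(TRUE, k_a_per_group),
                rep(FALSE, group_size - k_a_per_group)), n_groups)
  U0 <- ifelse(is_a, strategy_a$U, strategy_b$U)
  T0 <- ifelse(is_a, strategy_a$T, strategy_b$T)
  set.seed(seed)
  raw <- sim_engine_cpp(
    n_groups = n_groups, group_size = group_size,
    n_rounds = n_conflict_rounds, benefit = benefit,
    F0 = initial_fitness, sigma_eps = sigma_eps,
    mutation_prob = 0, U0 = U0, T0 = T0,
    n_generations = 1L, max_fight_rounds = 10000L,
    U_lo = -1, U_hi = 1, T_lo = 0, T_hi = 5,
    evolve = FALSE, record_final = FALSE
  )
  fit <- raw$individuals$fitness
  structure(list(
    strategy_a = strategy_a, strategy_b = strategy_b,
    group_size = group_size, n_groups = n_groups,
    k_a_per_group = k_a_per_group, benefit = benefit,
    n_a = sum(is_a), n_b = sum(!is_a),
    mean_fitness_a = if (any(is_a)) mean(fit[is_a]) else NA_real_,
    mean_fitness_b = if (any(!is_a)) mean(fit[!is_a]) else NA_real_
  ), class = "competition_result")
}

#' Competition experiments across all strategy frequencies
#'
#' Runs [competition_experiment()] for every within-group count of
#' strategy-A individuals from 0 to `group_size`.
#'
#' @inheritParams competition_experiment
#' @param seed base seed; each frequency gets a derived seed.
#' @return data.frame: `k_a`, `mean_fitness_a`, `mean_fitness_b`.
#' @export
competition_curve <- function(strategy_a, strategy_b, group_size = 10L,
                              n_groups = 1000L, benefit = 1, sigma_eps = 1,
                              n_conflict_rounds = 10L,
                              initial_fitness = 100, seed = 1L) {
  rows <- lapply(0:group_size, function(k_a) {
    r <- competition_experiment(strategy_a, strategy_b, group_size,
                                n_groups, k_a, benefit, sigma_eps,
                                n_conflict_rounds, initial_fitness,
                                seed = derive_seed(seed, k_a + 1L))
    data.frame(k_a = k_a, mean_fitness_a = r$mean_fitness_a,
               mean_fitness_b = r$mean_fitness_b)
  })
  do.call(rbind, rows)
}

#' Sensitivity sweep along one model axis
#'
#' Repeats [main_sweep()] for each value of one varied parameter
#' (perception-noise SD, conflict rounds per generation, or group size),
#' holding everything else at the template. The published sensitivity
#' conditions are `sigma_eps` in \{0.5, 2\}, `n_conflict_rounds` in
#' \{4, 40\} and `group_size` in \{5, 20\}. The output supports the
#' comparison of interest: the largest benefit at which any run still
#' evolves turn-taking, per condition.
#'
#' @param axis `"sigma_eps"`, `"n_conflict_rounds"` or `"group_size"`.
#' @param values values of the varied parameter.
#' @param config_template base [sim_config()].
#' @param benefits,U_inits,n_replicates,seed,n_randomizations as in
#'   [main_sweep()].
#' @return data.frame: the sweep table with an extra column named after
#'   `axis`; attribute `"ceilings"` holds, per axis value, the largest
#'   benefit with at least one turn-taking run (NA if none).
#' @export
sensitivity_sweep <- function(axis = c("sigma_eps", "n_conflict_rounds",
                                       "group_size"),
                              values, config_template, benefits = 1:10,
                              U_inits = c(-1, 1), n_replicates = 2L,
                              seed = 1L, n_randomizations = 200L) {
  axis <- match.arg(axis)
  tabs <- lapply(seq_along(values), function(v) {
    tpl <- validate_config(utils::modifyList(
      unclass(config_template), stats::setNames(list(values[v]), axis)))
    tab <- main_sweep(tpl, benefits, U_inits, n_replicates,
                      seed = derive_seed(seed, v),
                      n_randomizations = n_randomizations,
                      keep_individuals = FALSE)
    tab[[axis]] <- values[v]
    tab
  })
  out <- do.call(rbind, tabs)
  ceil <- vapply(values, function(v) {
    tt <- out$benefit[out[[axis]] == v & out$strategy == "turn_taking"]
    if (length(tt) == 0L) NA_real_ else max(tt)
  }, numeric(1))
  attr(out, "ceilings") <- stats::setNames(ceil, values)
  out
}

#' Largest benefit with a turn-taking outcome
#'
#' @param sweep_results a `sweep_result`.
#' @return the maximum benefit at which any run was classified
#'   turn-taking, or NA if none was.
#' @export
turn_taking_ceiling <- function(sweep_results) {
  tt <- sweep_results$benefit[sweep_results$strategy == "turn_taking"]
  if (length(tt) == 0L) NA_real_ else max(tt)
}
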