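#' Run one conflict round within a group
#'
#' Every unordered dyad in the group enters exactly one conflict; the order
#' in which dyads are processed is randomized each round (order can matter
#' only through the fitness floor, and randomization removes systematic
#' bias).
#'
#' @param group list of `individual`s.
#' @param benefit,sigma_eps,max_fight_rounds see [run_conflict()].
#' @return list with the updated `group` and `outcomes`, a data.frame with
#'   one row per conflict (i, j, escalated_i, escalated_j, fought, winner,
#'   fight_length).
#' @export
run_conflict_round <- function(group, benefit, sigma_eps,
                               max_fight_rounds = 10000L) {
  n <- length(group)
  stopifnot(n >= 2)
  dyads <- utils::combn(n, 2L)
  ord <- sample.int(ncol(dyads))
  rows <- vector("list", ncol(dyads))
  for (k in seq_along(ord)) {
    ij <- dyads[, ord[k]]
    i <- ij[1]; j <- ij[2]
    res <- run_conflict(group[[i]], group[[j]], benefit, sigma_eps,
                        max_fight_rounds)
    group[[i]] <- res$ind_i
    group[[j]] <- res$ind_j
    out <- res$outcome
    rows[[k]] <- data.frame(
      i = group[[i]]$id, j = group[[j]]$id,
      escalated_i = out$escalated_i, escalated_j = out$escalated_j,
      fought = out$fought, winner = out$winner,
      fight_length = if (out$fought) out$fight_result$length else NA_integer_
    )
  }
  list(group = group, outcomes = do.call(rbind, rows))
}

#' Fitness-proportional parent selection
#'
#' Samples one parent with probability proportional to fitness clamped at
#' zero (negative fitness never reproduces). If every clamped fitness is
#' zero the choice is uniform.
#'
#' @param group list of `individual`s.
#' @return index of the selected parent within the group.
#' @export
select_parent <- function(group) {
  f <- pmax(vapply(group, function(x) x$fitness, numeric(1)), 0)
  if (sum(f) == 0) {
    sample.int(length(group), 1L)
  } else {
    sample.int(length(group), 1L, prob = f)
  }
}

#' Create an offspring from a parent
#'
#' The offspring inherits the parent's heritable pair (U, T); with
#' probability `mutation_prob` both are redrawn jointly from uniform
#' distributions over the mutation ranges. Strength is drawn fresh from
#' Uniform(0, 1), fitness reset to `initial_fitness`, every willingness
#' value set to one, and escalation enabled.
#'
#' @param parent an `individual`.
#' @param config a [sim_config()].
#' @param id id for the offspring within its (eventual) group.
#' @return a new `individual`.
#' @export
make_offspring <- function(parent, config, id = parent$id) {
  U <- parent$U; T_ <- parent$T
  if (stats::runif(1) < config$mutation_prob) {
    U <- stats::runif(1, config$U_mut_range[1], config$U_mut_range[2])
    T_ <- stats::runif(1, config$T_mut_range[1], config$T_mut_range[2])
  }
  gs <- config$group_size
  w <- rep(1, gs - 1L)
  names(w) <- setdiff(seq_len(gs), id)
  new_individual(id, s = stats::runif(1), fitness = config$initial_fitness,
                 U = U, T_ = T_, w = w)
}

#' Reproduction, death of parents, and migration of offspring
#'
#' Per group, `group_size` offspring are produced by repeated
#' fitness-proportional selection (with replacement) within the natal
#' group. All parents then die, and the pooled offspring are redistributed
#' by a global uniform permutation into groups of the fixed size, so group
#' count and group sizes are conserved exactly.
#'
#' @param pop a `population` at the end of its conflict phase.
#' @param config a [sim_config()].
#' @return the offspring `population`, generation index incremented.
#' @export
reproduce_and_migrate <- function(pop, config) {
  gs <- config$group_size
  offspring <- list()
  for (grp in pop$groups) {
    for (k in seq_len(gs)) {
      offspring[[length(offspring) + 1L]] <-
        make_offspring(grp[[select_parent(grp)]], config, id = 1L)
    }
  }
  perm <- sample.int(length(offspring))
  groups <- lapply(seq_along(pop$groups), function(g) {
    idx <- perm[((g - 1L) * gs + 1L):(g * gs)]
    grp <- offspring[idx]
    for (i in seq_len(gs)) {
      grp[[i]]$id <- i
      names(grp[[i]]$w) <- setdiff(seq_len(gs), i)
    }
    grp
  })
  structure(list(groups = groups, generation = pop$generation + 1L),
            class = "population")
}

#' Run a full evolutionary simulation
#'
#' Three nested time scales: within each generation, `n_conflict_rounds`
#' rounds in which every dyad of every group enters a conflict (escalated
#' conflicts run the within-fight assessment dynamics); then
#' fitness-proportional reproduction with mutation; then death of parents
#' and migration of offspring. The default `engine = "cpp"` runs the
#' compiled core and is the one to use at sweep scale; `engine = "r"`
#' drives the exported R-level operations directly and is intended for
#' small-scale validation (the two engines implement the identical model
#' but do not share a random-number stream).
#'
#' @param config a [sim_config()]; `config$seed` seeds the run.
#' @param engine `"cpp"` (compiled core) or `"r"` (reference R loop).
#' @param record `"final"` records dominance tallies, fight lengths and the
#'   conflict log for the final generation only (the measurement layer);
#'   `"none"` skips them.
#' @return list of class `sim_result`:
#'   \describe{
#'     \item{summary}{data.frame, one row per generation: `generation`,
#'       `mean_U`, `mean_T`, `mean_fitness` (end of conflict phase),
#'       `n_fights`, `mean_fight_length`, `n_forced_giveups`.}
#'     \item{individuals}{data.frame of the final generation (group, id, s,
#'       fitness, U, T).}
#'     \item{tallies}{list (one per group) of directed win-count matrices
#'       over final-generation conflicts with at least one escalator.}
#'     \item{fight_lengths}{integer vector of final-generation fight lengths.}
#'     \item{conflict_log}{data.frame of final-generation conflicts (round,
#'       group, i, j, escalated_i, escalated_j, fought, winner,
#'       fight_length).}
#'     \item{cap_breaches}{count of fights resolved by the length cap.}
#'     \item{config}{the config used.}
#'   }
#' @export
#' @examples
#' res <- run_simulation(sim_config(n_groups = 4, n_generations = 3,
#'                                  n_conflict_rounds = 2, seed = 1))
#' res$summary$mean_U
run_simulation <- function(config, engine = c("cpp", "r"),
                           record = c("final", "none")) {
  config <- validate_config(config)
  engine <- match.arg(engine)
  record <- match.arg(record)
  set.seed(config$seed)
  if (engine == "cpp") {
    n <- config$n_groups * config$group_size
    raw <- sim_engine_cpp(
      n_groups = config$n_groups, group_size = config$group_size,
      n_rounds = config$n_conflict_rounds, benefit = config$benefit,
      F0 = config$initial_fitness, sigma_eps = config$sigma_eps,
      mutation_prob = config$mutation_prob,
      U0 = rep(config$U_init, n), T0 = rep(config$T_init, n),
      n_generations = config$n_generations,
      max_fight_rounds = config$max_fight_rounds,
      U_lo = config$U_mut_range[1], U_hi = config$U_mut_range[2],
      T_lo = config$T_mut_range[1], T_hi = config$T_mut_range[2],
      evolve = TRUE, record_final = (record == "final")
    )
    res <- finalize_engine_result(raw, config)
  } else {
    res <- run_simulation_r(config, record)
  }
  class(res) <- "sim_result"
  res
}

# Shape the compiled engine's raw output into the sim_result contract.
finalize_engine_result <- function(raw, config) {
  summary <- as.data.frame(raw$summary)
  individuals <- as.data.frame(raw$individuals)
  tallies <- NULL
  log <- NULL
  if (!is.null(raw$tallies)) {
    gs <- config$group_size
    tallies <- lapply(seq_len(config$n_groups), function(g) {
      m <- matrix(raw$tallies[, , g], gs, gs)
      dimnames(m) <- list(winner = seq_len(gs), loser = seq_len(gs))
      m
    })
    log <- as.data.frame(raw$conflict_log)
  }
  list(summary = summary, individuals = individuals, tallies = tallies,
       fight_lengths = raw$fight_lengths, conflict_log = log,
       cap_breaches = raw$cap_breaches, config = config)
}

# Reference implementation of the generational loop in plain R, driving the
# exported per-operation functions. Small scale only.
run_simulation_r <- function(config, record = "final") {
  pop <- init_population(config)
  gens <- config$n_generations
  gs <- config$group_size
  sum_rows <- vector("list", gens)
  tallies <- NULL; flens <- integer(0); log <- NULL
  individuals <- population_df(pop)

  for (gen in seq_len(gens)) {
    final <- gen == gens && record == "final"
    logs <- vector("list", config$n_conflict_rounds)
    for (r in seq_len(config$n_conflict_rounds)) {
      per_group <- vector("list", length(pop$groups))
      for (g in seq_along(pop$groups)) {
        rr <- run_conflict_round(pop$groups[[g]], config$benefit,
                                 config$sigma_eps, config$max_fight_rounds)
        pop$groups[[g]] <- rr$group
        out <- rr$outcomes
        out$group <- g
        out$round <- r
        per_group[[g]] <- out
      }
      logs[[r]] <- do.call(rbind, per_group)
    }
    glog <- do.call(rbind, logs)
    df <- population_df(pop)
    fl <- glog$fight_length[glog$fought]
    sum_rows[[gen]] <- data.frame(
      generation = gen, mean_U = mean(df$U), mean_T = mean(df$T),
      mean_fitness = mean(df$fitness), n_fights = sum(glog$fought),
      mean_fight_length = if (length(fl)) mean(fl) else NA_real_,
      n_forced_giveups = sum(df$escalation_disabled)
    )
    if (final) {
      tallies <- lapply(seq_along(pop$groups), function(g) {
        tally_from_log(glog[glog$group == g, , drop = FALSE], gs)
      })
      flens <- as.integer(fl)
      log <- glog[, c("round", "group", "i", "j", "escalated_i",
                      "escalated_j", "fought", "winner", "fight_length")]
    }
    if (gen == gens) {
      individuals <- df  # final-generation table, recorded before death
    } else {
      pop <- reproduce_and_migrate(pop, config)
    }
  }
  list(summary = do.call(rbind, sum_rows),
       individuals = individuals[, c("group", "id", "s", "fitness", "U", "T")],
       tallies = tallies, fight_lengths = flens, conflict_log = log,
       cap_breaches = 0L, config = config)
}
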