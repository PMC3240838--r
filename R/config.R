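#' Simulation configuration
#'
#' Builds and validates the single source of truth for a simulation run.
#' Defaults reproduce the main full-scale analysis: 1000 groups of 10
#' individuals, 10 conflict rounds per generation, initial fitness 100,
#' perception-noise SD 1, mutation probability 0.001, initial giving-up
#' threshold 0 and 5000 generations.
#'
#' @param n_groups number of groups (positive integer).
#' @param group_size individuals per group (integer >= 2; dyads must exist).
#' @param n_conflict_rounds conflict rounds per generation; in each round
#'   every dyad in a group enters one conflict.
#' @param benefit fitness benefit `b` obtained by the winner of a conflict.
#' @param initial_fitness fitness `F0` assigned to every newborn individual.
#' @param sigma_eps standard deviation of the per-round, per-individual
#'   perception noise in the estimate of relative strength (>= 0).
#' @param mutation_prob probability that an offspring's heritable pair
#'   (U, T) is redrawn from the mutation ranges.
#' @param U_init initial update factor for all founders, in `[-1, 1]`.
#' @param T_init initial giving-up threshold for all founders, in `[0, 5]`.
#' @param U_mut_range,T_mut_range length-2 numeric ranges from which mutated
#'   values are drawn uniformly.
#' @param n_generations number of generations to simulate (>= 0).
#' @param seed integer seed; mandatory for archival runs, defaults to 1.
#' @param max_fight_rounds safety cap on fight length. Unreachable under the
#'   default noise level; breaches are counted and resolved by a fair coin.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [sim_preset()] for the "paper" and "desk" scale presets,
#'   [run_simulation()].
#' @export
#' @examples
#' cfg <- sim_config(n_groups = 2, n_generations = 5, seed = 42)
#' cfg$benefit
sim_config <- function(n_groups = 1000L,
                       group_size = 10L,
                       n_conflict_rounds = 10L,
                       benefit = 1,
                       initial_fitness = 100,
                       sigma_eps = 1,
                       mutation_prob = 0.001,
                       U_init = -1,
                       T_init = 0,
                       U_mut_range = c(-1, 1),
                       T_mut_range = c(0, 5),
                       n_generations = 5000L,
                       seed = 1L,
                       max_fight_rounds = 10000L) {
  cfg <- list(
    n_groups = n_groups, group_size = group_size,
    n_conflict_rounds = n_conflict_rounds, benefit = benefit,
    initial_fitness = initial_fitness, sigma_eps = sigma_eps,
    mutation_prob = mutation_prob, U_init = U_init, T_init = T_init,
    U_mut_range = U_mut_range, T_mut_range = T_mut_range,
    n_generations = n_generations, seed = seed,
    max_fight_rounds = max_fight_rounds
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every field of a [sim_config()] against its admissible range and
#' returns the config (with integer-like fields coerced) or stops with a
#' message naming the offending field and bound.
#'
#' @param config a `sim_config` or plain named list with the same fields.
#' @return the validated `sim_config`.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(
    n_groups = 1000L, group_size = 10L, n_conflict_rounds = 10L,
    benefit = 1, initial_fitness = 100, sigma_eps = 1,
    mutation_prob = 0.001, U_init = -1, T_init = 0,
    U_mut_range = c(-1, 1), T_mut_range = c(0, 5),
    n_generations = 5000L, seed = 1L, max_fight_rounds = 10000L
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])

  chk_scalar <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("config field '%s' must be a finite numeric scalar", field))
    }
  }
  chk_int <- function(x, field, min) {
    chk_scalar(x, field)
    if (x != round(x)) stop(sprintf("config field '%s' must be an integer", field))
    if (x < min) stop(sprintf("config field '%s' must be >= %s (got %s)", field, min, x))
    as.integer(x)
  }
  chk_range <- function(x, field, lo, hi) {
    chk_scalar(x, field)
    if (x < lo || x > hi) {
      stop(sprintf("config field '%s' must lie in [%s, %s] (got %s)", field, lo, hi, x))
    }
    x
  }
  chk_interval <- function(x, field, lo, hi) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x))) {
      stop(sprintf("config field '%s' must be a length-2 numeric interval", field))
    }
    if (x[1] > x[2]) stop(sprintf("config field '%s' has low > high", field))
    if (x[1] < lo || x[2] > hi) {
      stop(sprintf("config field '%s' must be contained in [%s, %s]", field, lo, hi))
    }
    as.numeric(x)
  }

  cfg$n_groups <- chk_int(cfg$n_groups, "n_groups", 1L)
  cfg$group_size <- chk_int(cfg$group_size, "group_size", 2L)
  cfg$n_conflict_rounds <- chk_int(cfg$n_conflict_rounds, "n_conflict_rounds", 1L)
  chk_scalar(cfg$benefit, "benefit")
  if (cfg$benefit <= 0) stop("config field 'benefit' must be > 0")
  chk_scalar(cfg$initial_fitness, "initial_fitness")
  if (cfg$initial_fitness <= 0) stop("config field 'initial_fitness' must be > 0")
  chk_scalar(cfg$sigma_eps, "sigma_eps")
  if (cfg$sigma_eps < 0) stop("config field 'sigma_eps' must be >= 0 (it is an SD)")
  cfg$mutation_prob <- chk_range(cfg$mutation_prob, "mutation_prob", 0, 1)
  cfg$U_init <- chk_range(cfg$U_init, "U_init", -1, 1)
  cfg$T_init <- chk_range(cfg$T_init, "T_init", 0, 5)
  cfg$U_mut_range <- chk_interval(cfg$U_mut_range, "U_mut_range", -1, 1)
  cfg$T_mut_range <- chk_interval(cfg$T_mut_range, "T_mut_range", 0, 5)
  cfg$n_generations <- chk_int(cfg$n_generations, "n_generations", 0L)
  cfg$seed <- chk_int(cfg$seed, "seed", -.Machine$integer.max)
  cfg$max_fight_rounds <- chk_int(cfg$max_fight_rounds, "max_fight_rounds", 1L)

  class(cfg) <- "sim_config"
  cfg
}

#' Scale presets
#'
#' `"paper"` is the full published scale (1000 groups, 5000 generations);
#' `"desk"` is a reduced preset (200 groups, 1000 generations) that preserves
#' the qualitative evolutionary outcomes at workstation runtimes.
#'
#' @param preset `"paper"` or `"desk"`.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
#' @examples
#' sim_preset("desk", benefit = 4, seed = 7)$n_groups
sim_preset <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    paper = list(n_groups = 1000L, n_generations = 5000L),
    desk  = list(n_groups = 200L, n_generations = 1000L)
  )
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Read a simulation configuration from a JSON file
#'
#' All fields are optional and fall back to the full-scale defaults; field
#' names mirror [sim_config()] arguments.
#'
#' @param path path to a JSON file.
#' @return a validated `sim_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config file must contain a JSON object")
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " .. ")))
  }
  invisible(x)
}
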