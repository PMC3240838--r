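#' Create an individual
#'
#' An individual carries a fixed strength `s` in \[0, 1\], a fitness account
#' `F`, the two heritable strategy parameters (update factor `U` in
#' \[-1, 1\] and giving-up threshold `T` in \[0, 5\]), a dyad-specific map
#' `w` of willingness-to-escalate values in \[0, 1\] (named by opponent id),
#' and an `escalation_disabled` flag that is set once fitness drops below
#' zero. A disabled individual keeps all `w` values at zero.
#'
#' @param id integer identity within the group.
#' @param s strength in \[0, 1\].
#' @param fitness current fitness.
#' @param U update factor in \[-1, 1\].
#' @param T_ giving-up threshold in \[0, 5\].
#' @param w named numeric vector of willingness values (names = opponent ids).
#' @return a list of class `individual`.
#' @export
new_individual <- function(id, s, fitness, U, T_, w) {
  stopifnot(s >= 0, s <= 1, U >= -1, U <= 1, T_ >= 0, T_ <= 5,
            all(w >= 0), all(w <= 1))
  structure(
    list(id = as.integer(id), s = s, fitness = fitness, U = U, T = T_,
         w = w, escalation_disabled = FALSE),
    class = "individual"
  )
}

#' Initialize a population
#'
#' Founders follow the same initialization rule as offspring: strength drawn
#' from Uniform(0, 1), fitness set to `initial_fitness`, every willingness
#' value set to one, and the heritable pair set to (`U_init`, `T_init`) for
#' all individuals (mutation later supplies variation).
#'
#' Uses R's global random number generator; call `set.seed()` (or go through
#' [run_simulation()], which seeds from the config) for reproducibility.
#'
#' @param config a validated [sim_config()].
#' @return a list of class `population` with elements `groups` (a list of
#'   groups, each a list of `individual`s) and `generation` (0 for founders).
#' @export
#' @examples
#' set.seed(1)
#' pop <- init_population(sim_config(n_groups = 2, group_size = 3))
#' length(pop$groups)
init_population <- function(config) {
  config <- validate_config(config)
  gs <- config$group_size
  groups <- lapply(seq_len(config$n_groups), function(g) {
    lapply(seq_len(gs), function(i) {
      w <- rep(1, gs - 1L)
      names(w) <- setdiff(seq_len(gs), i)
      new_individual(i, s = stats::runif(1), fitness = config$initial_fitness,
                     U = config$U_init, T_ = config$T_init, w = w)
    })
  })
  structure(list(groups = groups, generation = 0L), class = "population")
}

#' Flatten a population to a data frame
#'
#' One row per individual: group, id, strength, fitness, U, T and the
#' escalation-disabled flag.
#'
#' @param pop a `population`.
#' @return a data.frame.
#' @export
population_df <- function(pop) {
  rows <- lapply(seq_along(pop$groups), function(g) {
    grp <- pop$groups[[g]]
    data.frame(
      group = g,
      id = vapply(grp, function(x) x$id, integer(1)),
      s = vapply(grp, function(x) x$s, numeric(1)),
      fitness = vapply(grp, function(x) x$fitness, numeric(1)),
      U = vapply(grp, function(x) x$U, numeric(1)),
      T = vapply(grp, function(x) x$T, numeric(1)),
      escalation_disabled = vapply(grp, function(x) x$escalation_disabled,
                                   logical(1))
    )
  })
  do.call(rbind, rows)
}

# Zero the willingness map and mark the individual as unable to escalate.
# Applied when fitness drops below zero; permanent for the rest of the
# individual's life (offspring start fresh).
disable_escalation <- function(ind) {
  ind$w[] <- 0
  ind$escalation_disabled <- TRUE
  ind
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d groups x %d individuals, generation %d\n",
              length(x$groups), length(x$groups[[1]]), x$generation))
  invisible(x)
}
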