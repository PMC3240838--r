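#' Per-round fighting cost
#'
#' Each fighting round, individual i pays `exp(s_j - s_i)`: the weaker
#' opponent pays more than one fitness unit per round, the stronger less
#' than one, and equally matched opponents both pay exactly one. The two
#' opponents' per-round costs always multiply to one.
#'
#' @param s_i,s_j strengths of the focal individual and its opponent, in
#'   \[0, 1\].
#' @return per-round cost for the focal individual (strictly positive).
#' @export
#' @examples
#' round_cost(0.5, 0.5)  # 1
#' round_cost(1, 0)      # exp(-1), the stronger pays less
round_cost <- function(s_i, s_j) {
  stopifnot(all(s_i >= 0 & s_i <= 1), all(s_j >= 0 & s_j <= 1))
  exp(s_j - s_i)
}

#' Noisy perception of relative strength
#'
#' One per-round estimate `s_i - s_j + eps`, with `eps` drawn from a normal
#' distribution with mean zero and SD `sigma_eps`, independently for each
#' individual and round.
#'
#' @param s_i,s_j strengths.
#' @param sigma_eps noise SD (>= 0; 0 gives the exact difference).
#' @param n number of independent draws (default 1).
#' @return numeric vector of `n` estimates.
#' @export
perceive_relative_strength <- function(s_i, s_j, sigma_eps, n = 1L) {
  stopifnot(sigma_eps >= 0)
  (s_i - s_j) + stats::rnorm(n, mean = 0, sd = sigma_eps)
}

#' Simulate one escalated fight
#'
#' Sequential-assessment dynamics: both opponents start a decision variable
#' `d` at zero. Each round, both pay their per-round cost ([round_cost()]),
#' then each subtracts its own noisy estimate of relative strength from its
#' `d`, so positive `d` accumulates evidence of being the weaker one. Both
#' then decide simultaneously: an individual gives up when `d` exceeds its
#' giving-up threshold `T`, or is forced to give up when its fitness has
#' dropped below zero. If both give up in the same round the winner is a
#' fair coin flip. Costs are charged every round, including the final one.
#'
#' A forced give-up marks that individual for escalation disabling (the
#' caller zeroes its willingness map; see [run_conflict()]).
#'
#' @param ind_i,ind_j `individual`s (only `s`, `fitness`, `T`, `id` used).
#' @param sigma_eps perception-noise SD.
#' @param max_fight_rounds safety cap; a breach is resolved by a fair coin
#'   and flagged. Unreachable for `sigma_eps >= 0.5` at sane thresholds.
#' @param trace if TRUE, attach a per-round data.frame (round, d_i, d_j,
#'   cumulative costs) for diagnostics.
#' @return list of class `fight_result`: `winner`, `loser` (ids), `length`
#'   (rounds), `cost_i`, `cost_j` (total fitness deducted),
#'   `forced_giveup_i`, `forced_giveup_j`, `double_giveup`, `cap_breached`,
#'   and the two post-fight fitness values `fitness_i`, `fitness_j`.
#' @export
run_fight <- function(ind_i, ind_j, sigma_eps, max_fight_rounds = 10000L,
                      trace = FALSE) {
  s_i <- ind_i$s; s_j <- ind_j$s
  c_i <- round_cost(s_i, s_j); c_j <- round_cost(s_j, s_i)
  F_i <- ind_i$fitness; F_j <- ind_j$fitness
  d_i <- 0; d_j <- 0
  r <- 0L
  cap <- FALSE
  tr <- if (trace) vector("list", 16L) else NULL
  repeat {
    r <- r + 1L
    F_i <- F_i - c_i
    F_j <- F_j - c_j
    # each fighter perceives with its own independent error draw
    d_i <- d_i - perceive_relative_strength(s_i, s_j, sigma_eps)
    d_j <- d_j - perceive_relative_strength(s_j, s_i, sigma_eps)
    forced_i <- F_i < 0
    forced_j <- F_j < 0
    give_i <- d_i > ind_i$T || forced_i
    give_j <- d_j > ind_j$T || forced_j
    if (trace) tr[[r]] <- c(round = r, d_i = d_i, d_j = d_j,
                            cost_i = r * c_i, cost_j = r * c_j)
    if (give_i || give_j) break
    if (r >= max_fight_rounds) {
      cap <- TRUE
      warning("fight reached max_fight_rounds cap; winner drawn at random")
      break
    }
  }
  double <- give_i && give_j
  i_wins <- if (cap || double) stats::runif(1) < 0.5 else !give_i
  res <- list(
    winner = if (i_wins) ind_i$id else ind_j$id,
    loser = if (i_wins) ind_j$id else ind_i$id,
    length = r,
    cost_i = r * c_i, cost_j = r * c_j,
    forced_giveup_i = forced_i, forced_giveup_j = forced_j,
    double_giveup = double, cap_breached = cap,
    fitness_i = F_i, fitness_j = F_j
  )
  if (trace) res$trace <- as.data.frame(do.call(rbind, tr[seq_len(r)]))
  class(res) <- "fight_result"
  res
}
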