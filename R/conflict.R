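#' Decide whether to escalate a conflict
#'
#' A Bernoulli draw with success probability equal to the dyad-specific
#' willingness to escalate; an escalation-disabled individual (fitness
#' dropped below zero earlier) never escalates.
#'
#' @param w_value willingness in \[0, 1\].
#' @param escalation_disabled logical flag.
#' @return TRUE if the individual is willing to escalate.
#' @export
decide_escalation <- function(w_value, escalation_disabled = FALSE) {
  stopifnot(w_value >= 0, w_value <= 1)
  if (escalation_disabled) return(FALSE)
  stats::runif(1) < w_value
}

#' Update the willingness to escalate after a decided conflict
#'
#' The experience-update rule, applied by each individual with its own
#' heritable update factor `U` after any conflict in which at least one
#' member of the dyad was willing to escalate:
#'
#' * winner, `U > 0`: `w + U * (1 - w)` (winning emboldens),
#' * winner, `U < 0`: `w + U * w` (winning pacifies -- the turn-taking arm),
#' * loser,  `U > 0`: `w - U * w` (losing pacifies),
#' * loser,  `U < 0`: `w - U * (1 - w)` (losing emboldens),
#' * `U = 0`: no change.
#'
#' The map sends \[0, 1\] into \[0, 1\] for every admissible `U`. At
#' `U = 1` one win/loss saturates w at 1/0 (instant stable dominance); at
#' `U = -1` the roles flip completely each conflict (strict alternation).
#'
#' @param w_cur current willingness in \[0, 1\].
#' @param U update factor in \[-1, 1\].
#' @param role `"winner"` or `"loser"` (winning = obtaining the resource).
#' @return updated willingness. Vectorized over `w_cur` and `U`.
#' @export
#' @examples
#' update_willingness(0.5, 0.5, "winner")  # 0.75
#' update_willingness(0.5, 0.5, "loser")   # 0.25
update_willingness <- function(w_cur, U, role = c("winner", "loser")) {
  role <- match.arg(role)
  stopifnot(all(w_cur >= 0 & w_cur <= 1), all(U >= -1 & U <= 1))
  n <- max(length(w_cur), length(U))
  w <- rep_len(w_cur, n)
  u <- rep_len(U, n)
  pos <- u > 0  # the U = 0 identity falls out of the U < 0 formulas
  out <- numeric(n)
  if (role == "winner") {
    out[pos] <- w[pos] + u[pos] * (1 - w[pos])
    out[!pos] <- w[!pos] + u[!pos] * w[!pos]
  } else {
    out[pos] <- w[pos] - u[pos] * w[pos]
    out[!pos] <- w[!pos] - u[!pos] * (1 - w[!pos])
  }
  pmin(1, pmax(0, out))
}

#' Run one dyadic conflict
#'
#' Both individuals decide simultaneously (each a Bernoulli draw on its
#' willingness for this opponent) whether to escalate:
#'
#' * neither willing: a randomly chosen individual obtains the resource;
#'   no costs, and no willingness update (updates require at least one
#'   escalator);
#' * exactly one willing: that individual obtains the benefit; no costs;
#'   both update;
#' * both willing: a fight ([run_fight()]) decides the winner, who obtains
#'   the benefit; both pay fight costs and both update.
#'
#' Both updates are computed from the pre-conflict willingness values.
#' After the conflict, any individual whose fitness is negative (or who was
#' forced to give up by the fitness floor) has its whole willingness map
#' zeroed and is permanently barred from escalating.
#'
#' @param ind_i,ind_j `individual`s with willingness entries for each other.
#' @param benefit fitness benefit for the resource holder.
#' @param sigma_eps perception-noise SD inside fights.
#' @param max_fight_rounds fight-length safety cap.
#' @return list with `outcome` (class `conflict_outcome`: `escalated_i`,
#'   `escalated_j`, `fought`, `winner`, `fight_result`, `update_applied`)
#'   and the updated individuals `ind_i`, `ind_j`.
#' @export
run_conflict <- function(ind_i, ind_j, benefit, sigma_eps,
                         max_fight_rounds = 10000L) {
  key_j <- as.character(ind_j$id)
  key_i <- as.character(ind_i$id)
  esc_i <- decide_escalation(ind_i$w[[key_j]], ind_i$escalation_disabled)
  esc_j <- decide_escalation(ind_j$w[[key_i]], ind_j$escalation_disabled)
  fought <- esc_i && esc_j
  fres <- NULL

  if (!esc_i && !esc_j) {
    winner <- if (stats::runif(1) < 0.5) ind_i$id else ind_j$id
  } else if (!fought) {
    winner <- if (esc_i) ind_i$id else ind_j$id
  } else {
    fres <- run_fight(ind_i, ind_j, sigma_eps, max_fight_rounds)
    ind_i$fitness <- fres$fitness_i
    ind_j$fitness <- fres$fitness_j
    winner <- fres$winner
  }

  if (winner == ind_i$id) ind_i$fitness <- ind_i$fitness + benefit
  else ind_j$fitness <- ind_j$fitness + benefit

  update_applied <- esc_i || esc_j
  if (update_applied) {
    role_i <- if (winner == ind_i$id) "winner" else "loser"
    role_j <- if (winner == ind_j$id) "winner" else "loser"
    ind_i$w[[key_j]] <- update_willingness(ind_i$w[[key_j]], ind_i$U, role_i)
    ind_j$w[[key_i]] <- update_willingness(ind_j$w[[key_i]], ind_j$U, role_j)
  }

  # fitness floor: negative fitness bars all future escalation
  forced_i <- !is.null(fres) && fres$forced_giveup_i
  forced_j <- !is.null(fres) && fres$forced_giveup_j
  if (ind_i$escalation_disabled || forced_i || ind_i$fitness < 0) {
    ind_i <- disable_escalation(ind_i)
  }
  if (ind_j$escalation_disabled || forced_j || ind_j$fitness < 0) {
    ind_j <- disable_escalation(ind_j)
  }

  outcome <- structure(
    list(escalated_i = esc_i, escalated_j = esc_j, fought = fought,
         winner = winner, fight_result = fres,
         update_applied = update_applied),
    class = "conflict_outcome"
  )
  list(outcome = outcome, ind_i = ind_i, ind_j = ind_j)
}
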