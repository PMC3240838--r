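#' Directed win tally from a conflict log
#'
#' Builds the dyadic interaction tally that feeds the dominance metrics:
#' entry `[i, j]` counts conflicts in which `i` obtained the resource
#' against `j`. Only conflicts in which at least one individual was ready
#' to escalate qualify; undecided coin-flip conflicts (neither willing) are
#' excluded by construction.
#'
#' @param log data.frame with columns `i`, `j`, `escalated_i`,
#'   `escalated_j`, `winner` (one group's conflicts).
#' @param n group size.
#' @return an `n` x `n` integer matrix of directed win counts.
#' @export
tally_from_log <- function(log, n) {
  m <- matrix(0L, n, n, dimnames = list(winner = seq_len(n),
                                        loser = seq_len(n)))
  keep <- log$escalated_i | log$escalated_j
  log <- log[keep, , drop = FALSE]
  for (k in seq_len(nrow(log))) {
    w <- log$winner[k]
    l <- if (w == log$i[k]) log$j[k] else log$i[k]
    m[w, l] <- m[w, l] + 1L
  }
  m
}

#' Directional consistency index
#'
#' For each dyad with at least one qualifying interaction, let `H` be the
#' number of wins in the more frequent direction and `L` in the other. The
#' group DCI pools across dyads: `sum(H - L) / sum(H + L)`. 1 means every
#' dyad is fully unidirectional (stable dominance); 0 means perfectly
#' balanced interactions (e.g. strict alternation over an even number of
#' conflicts). An unweighted per-dyad mean is returned alongside.
#'
#' @param tally directed win-count matrix (see [tally_from_log()]).
#' @return list with `dci` (pooled), `dci_dyad_mean`, and `n_dyads` used.
#'   Both indices are `NA` when no dyad has qualifying interactions.
#' @export
#' @examples
#' m <- matrix(0, 2, 2); m[1, 2] <- 9; m[2, 1] <- 1
#' directional_consistency(m)$dci  # (9-1)/(9+1)
directional_consistency <- function(tally) {
  n <- nrow(tally)
  stopifnot(ncol(tally) == n)
  hs <- c(); ls <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- tally[i, j]; b <- tally[j, i]
      if (a + b > 0) {
        hs <- c(hs, max(a, b))
        ls <- c(ls, min(a, b))
      }
    }
  }
  if (length(hs) == 0L) {
    return(list(dci = NA_real_, dci_dyad_mean = NA_real_, n_dyads = 0L))
  }
  list(dci = sum(hs - ls) / sum(hs + ls),
       dci_dyad_mean = mean((hs - ls) / (hs + ls)),
       n_dyads = length(hs))
}

# Landau's h for a 0/1 dominance matrix (1 = row dominates column).
# h = 12 / (N^3 - N) * sum_i (V_i - (N-1)/2)^2, V_i = row sums.
landau_h <- function(dom) {
  n <- nrow(dom)
  v <- rowSums(dom)
  12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
}

#' Hierarchy linearity (Landau's h with randomization)
#'
#' The dominance matrix is built from the majority win direction per dyad;
#' dyads with equal win counts in both directions (including unobserved
#' dyads) are undecided. Following the randomization treatment of
#' undecided relationships, each of `n_randomizations` repeats assigns
#' every undecided dyad a uniformly random direction, computes Landau's
#' `h`, and the mean over repeats is returned. A fully transitive order
#' gives 1; a rock-paper-scissors cycle among three gives 0.
#'
#' @param tally directed win-count matrix.
#' @param n_randomizations number of random resolutions of undecided dyads
#'   (ignored when every dyad is decided).
#' @return linearity in \[0, 1\]; `NA` for groups of fewer than 3.
#' @export
linearity <- function(tally, n_randomizations = 2000L) {
  n <- nrow(tally)
  stopifnot(ncol(tally) == n)
  if (n < 3L) return(NA_real_)
  dom <- matrix(0, n, n)
  und_i <- integer(0); und_j <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (tally[i, j] > tally[j, i]) dom[i, j] <- 1
      else if (tally[j, i] > tally[i, j]) dom[j, i] <- 1
      else { und_i <- c(und_i, i); und_j <- c(und_j, j) }
    }
  }
  k <- length(und_i)
  if (k == 0L) return(landau_h(dom))
  # vectorized over randomizations: V = fixed row sums + incidence of the
  # randomly oriented undecided dyads
  v_fixed <- rowSums(dom)
  x <- matrix(stats::runif(k * n_randomizations) < 0.5, k, n_randomizations)
  inc_i <- matrix(0, n, k); inc_j <- matrix(0, n, k)
  inc_i[cbind(und_i, seq_len(k))] <- 1
  inc_j[cbind(und_j, seq_len(k))] <- 1
  v <- v_fixed + inc_i %*% x + inc_j %*% (1 - x)
  h <- 12 / (n^3 - n) * colSums((v - (n - 1) / 2)^2)
  mean(h)
}

#' Fight-length summary
#'
#' Statistics over escalated (fought) conflicts only.
#'
#' @param conflict_log data.frame with `fought` and `fight_length` columns,
#'   or a bare numeric vector of fight lengths.
#' @return list with `n`, `mean`, `median`, `max`; all `NA` (and `n = 0`)
#'   when no fights occurred.
#' @export
fight_length_stats <- function(conflict_log) {
  lens <- if (is.data.frame(conflict_log)) {
    conflict_log$fight_length[conflict_log$fought]
  } else {
    conflict_log
  }
  lens <- lens[!is.na(lens)]
  if (length(lens) == 0L) {
    return(list(n = 0L, mean = NA_real_, median = NA_real_, max = NA_real_))
  }
  list(n = length(lens), mean = mean(lens), median = stats::median(lens),
       max = max(lens))
}

#' Classify the evolved strategy of a population
#'
#' Turn-taking populations evolve strongly negative update factors; contest
#' populations evolve positive ones. Classification is by the mean final-
#' generation update factor against two configurable thresholds.
#'
#' @param U numeric vector of final-generation update factors.
#' @param turn_taking_max mean U at or below this is `"turn_taking"`.
#' @param contest_min mean U at or above this is `"contest"`.
#' @return `"turn_taking"`, `"contest"` or `"ambiguous"`.
#' @export
classify_strategy <- function(U, turn_taking_max = -0.5, contest_min = 0.1) {
  if (length(U) == 0L) stop("no update-factor values supplied")
  m <- mean(U)
  if (m <= turn_taking_max) "turn_taking"
  else if (m >= contest_min) "contest"
  else "ambiguous"
}

#' Synthetic dyadic interaction sequences
#'
#' Generates an idealized one-group conflict log for exercising the
#' dominance metrics: `"alternating"` emulates the turn-taking pattern
#' (within each dyad the winner alternates every round; exactly one
#' individual escalates), `"despotic"` a perfectly transitive hierarchy in
#' which the lower-indexed individual always escalates and wins, and
#' `"random"` an unstructured society (coin-flip winner each round, both
#' willing). Uses R's global RNG for `"random"` only.
#'
#' @param pattern `"alternating"`, `"despotic"` or `"random"`.
#' @param n_individuals group size (>= 2).
#' @param n_rounds conflict rounds; every dyad interacts once per round.
#' @return a conflict-log data.frame (`round`, `group`, `i`, `j`,
#'   `escalated_i`, `escalated_j`, `fought`, `winner`, `fight_length`)
#'   compatible with [tally_from_log()].
#' @export
#' @examples
#' log <- synthetic_interactions("despotic", 4, 6)
#' directional_consistency(tally_from_log(log, 4))$dci  # 1
synthetic_interactions <- function(pattern = c("alternating", "despotic",
                                               "random"),
                                   n_individuals = 10L, n_rounds = 10L) {
  pattern <- match.arg(pattern)
  stopifnot(n_individuals >= 2L, n_rounds >= 1L)
  dyads <- utils::combn(n_individuals, 2L)
  rows <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    winner <- switch(pattern,
      alternating = if (r %% 2L == 1L) dyads[1, ] else dyads[2, ],
      despotic = dyads[1, ],
      random = ifelse(stats::runif(ncol(dyads)) < 0.5, dyads[1, ], dyads[2, ])
    )
    esc_i <- switch(pattern,
      alternating = winner == dyads[1, ],
      despotic = TRUE,
      random = TRUE
    )
    esc_j <- switch(pattern,
      alternating = winner == dyads[2, ],
      despotic = FALSE,
      random = TRUE
    )
    rows[[r]] <- data.frame(
      round = r, group = 1L, i = dyads[1, ], j = dyads[2, ],
      escalated_i = esc_i, escalated_j = esc_j,
      fought = esc_i & esc_j, winner = winner,
      fight_length = ifelse(esc_i & esc_j, 1L, NA_integer_)
    )
  }
  do.call(rbind, rows)
}

#' Per-group metrics for a simulation result
#'
#' Convenience wrapper computing DCI and linearity for every group tally of
#' a [run_simulation()] result.
#'
#' @param result a `sim_result` with recorded tallies.
#' @param n_randomizations passed to [linearity()].
#' @return data.frame with one row per group: `group`, `dci`, `linearity`.
#' @export
group_metrics <- function(result, n_randomizations = 2000L) {
  stopifnot(!is.null(result$tallies))
  rows <- lapply(seq_along(result$tallies), function(g) {
    tl <- result$tallies[[g]]
    data.frame(group = g,
               dci = directional_consistency(tl)$dci,
               linearity = linearity(tl, n_randomizations))
  })
  do.call(rbind, rows)
}
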