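# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations of the stated rules, kept separate from
# the package implementation.

# Step-by-step trace of a zero-noise fight: both decision variables change
# by the exact strength difference each round, costs accrue every round,
# the fitness floor forces a give-up, decisions are simultaneous.
oracle_fight_zero_noise <- function(s_i, s_j, T_i, T_j,
                                    F_i = 1e9, F_j = 1e9,
                                    max_rounds = 10000L) {
  c_i <- exp(s_j - s_i); c_j <- exp(s_i - s_j)
  d_i <- 0; d_j <- 0; r <- 0L
  g_i <- FALSE; g_j <- FALSE
  repeat {
    r <- r + 1L
    F_i <- F_i - c_i; F_j <- F_j - c_j
    d_i <- d_i - (s_i - s_j)
    d_j <- d_j - (s_j - s_i)
    g_i <- d_i > T_i || F_i < 0
    g_j <- d_j > T_j || F_j < 0
    if (g_i || g_j || r >= max_rounds) break
  }
  list(
    winner = if (g_i && g_j) NA_character_ else if (g_i) "j" else "i",
    length = r
  )
}

# Pooled directional consistency computed by a different route: for each
# unordered dyad |a - b| summed over dyads, divided by total interactions.
oracle_dci <- function(tally) {
  n <- nrow(tally)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + abs(tally[i, j] - tally[j, i])
      den <- den + tally[i, j] + tally[j, i]
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Landau linearity via Kendall's circular-triad count: h = 1 - 24 d / (n^3 - n)
# with d the number of cyclic triads of the (complete) dominance relation.
oracle_landau_triads <- function(dom) {
  n <- nrow(dom)
  d <- 0L
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        cyc1 <- dom[i, j] == 1 && dom[j, k] == 1 && dom[k, i] == 1
        cyc2 <- dom[j, i] == 1 && dom[k, j] == 1 && dom[i, k] == 1
        if (cyc1 || cyc2) d <- d + 1L
      }
    }
  }
  1 - 24 * d / (n^3 - n)
}

# All complete tournaments on n nodes as 0/1 dominance matrices.
all_tournaments <- function(n) {
  pairs <- utils::combn(n, 2)
  k <- ncol(pairs)
  lapply(seq_len(2^k) - 1L, function(code) {
    bits <- bitwAnd(bitwShiftR(code, seq_len(k) - 1L), 1L)
    dom <- matrix(0L, n, n)
    for (p in seq_len(k)) {
      i <- pairs[1, p]; j <- pairs[2, p]
      if (bits[p] == 1L) dom[i, j] <- 1L else dom[j, i] <- 1L
    }
    dom
  })
}

# One fight length via the compiled fight path (ample fitness).
run_fight_stats_once <- function(s_i, s_j, T_, sigma = 1) {
  turntaking:::run_fight_cpp(s_i, s_j, 1e6, 1e6, T_, T_, sigma, 10000L)$length
}

# Closed-dyad repeated-conflict driver built on the exported operations;
# returns the per-conflict log for fixed-point checks.
run_closed_dyad <- function(U, T_, n_conflicts, benefit = 1, sigma_eps = 1,
                            F0 = 100) {
  a <- new_individual(1L, s = 0.6, fitness = F0, U = U, T_ = T_,
                      w = c("2" = 1))
  b <- new_individual(2L, s = 0.4, fitness = F0, U = U, T_ = T_,
                      w = c("1" = 1))
  rows <- vector("list", n_conflicts)
  for (k in seq_len(n_conflicts)) {
    res <- run_conflict(a, b, benefit, sigma_eps)
    a <- res$ind_i; b <- res$ind_j
    o <- res$outcome
    rows[[k]] <- data.frame(
      round = k, group = 1L, i = 1L, j = 2L,
      escalated_i = o$escalated_i, escalated_j = o$escalated_j,
      fought = o$fought, winner = o$winner,
      fight_length = if (o$fought) o$fight_result$length else NA_integer_
    )
  }
  do.call(rbind, rows)
}
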