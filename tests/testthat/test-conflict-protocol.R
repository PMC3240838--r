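make_dyad <- function(U_a = -1, U_b = -1, T_ = 0, w_a = 1, w_b = 1,
                      F0 = 100, s_a = 0.6, s_b = 0.4) {
  list(
    a = new_individual(1L, s = s_a, fitness = F0, U = U_a, T_ = T_,
                       w = c("2" = w_a)),
    b = new_individual(2L, s = s_b, fitness = F0, U = U_b, T_ = T_,
                       w = c("1" = w_b))
  )
}

test_that("decide_escalation is Bernoulli in the willingness", {
  expect_true(decide_escalation(1))
  expect_false(decide_escalation(0))
  expect_false(decide_escalation(1, escalation_disabled = TRUE))
  set.seed(31)
  hits <- mean(vapply(1:20000, function(k) decide_escalation(0.3),
                      logical(1)))
  expect_lt(abs(hits - 0.3), 3 * sqrt(0.3 * 0.7 / 20000))
  expect_error(decide_escalation(1.2))
})

test_that("update_willingness reproduces the four-branch update rule", {
  cases <- rbind(
    # w,    U,    role,     expected
    c(0.8,  1.0,  "winner", 1.0),
    c(0.8,  1.0,  "loser",  0.0),
    c(0.8, -1.0,  "winner", 0.0),
    c(0.2, -1.0,  "loser",  1.0),
    c(0.5,  0.5,  "winner", 0.75),
    c(0.5,  0.5,  "loser",  0.25),
    c(0.5, -0.5,  "winner", 0.25),
    c(0.5, -0.5,  "loser",  0.75),
    c(0.3,  0.0,  "winner", 0.3),
    c(0.3,  0.0,  "loser",  0.3)
  )
  for (k in seq_len(nrow(cases))) {
    expect_equal(
      update_willingness(as.numeric(cases[k, 1]), as.numeric(cases[k, 2]),
                         cases[k, 3]),
      as.numeric(cases[k, 4]),
      info = paste(cases[k, ], collapse = " / ")
    )
  }
})

test_that("update_willingness maps [0,1] x [-1,1] into [0,1]", {
  set.seed(32)
  w <- runif(1e5); U <- runif(1e5, -1, 1)
  for (role in c("winner", "loser")) {
    out <- update_willingness(w, U, role)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("no-escalation conflicts are fair coin flips without updates", {
  set.seed(33)
  n <- 10000L
  d0 <- make_dyad(w_a = 0, w_b = 0)
  outs <- lapply(seq_len(n), function(k) {
    run_conflict(d0$a, d0$b, benefit = 1, sigma_eps = 1)$outcome
  })
  # gating: no escalator, no update, ever
  expect_false(any(vapply(outs, `[[`, logical(1), "update_applied")))
  wins_a <- sum(vapply(outs, `[[`, integer(1), "winner") == 1L)
  expect_lt(abs(wins_a / n - 0.5), 3 * sqrt(0.25 / n))
  # spot-check state: no costs, willingness untouched
  d <- make_dyad(w_a = 0, w_b = 0)
  res <- run_conflict(d$a, d$b, benefit = 1, sigma_eps = 1)
  expect_identical(unname(res$ind_i$w[["2"]]), 0)
  expect_identical(unname(res$ind_j$w[["1"]]), 0)
  expect_equal(res$ind_i$fitness + res$ind_j$fitness, 201) # only the benefit
})

test_that("a lone escalator takes the resource and both dyad members update", {
  d <- make_dyad(U_a = 0.5, U_b = 0.5, w_a = 1, w_b = 0)
  set.seed(34)
  res <- run_conflict(d$a, d$b, benefit = 2, sigma_eps = 1)
  o <- res$outcome
  expect_true(o$escalated_i); expect_false(o$escalated_j)
  expect_false(o$fought)
  expect_identical(o$winner, 1L)
  expect_true(o$update_applied)
  expect_equal(res$ind_i$fitness, 102)  # benefit, no costs
  expect_equal(res$ind_j$fitness, 100)
  # winner, U = 0.5: w stays 1; loser, U = 0.5: 0 stays 0
  expect_equal(unname(res$ind_i$w[["2"]]), 1)
  expect_equal(unname(res$ind_j$w[["1"]]), 0)
})

test_that("escalated conflicts update both members from pre-conflict w", {
  set.seed(35)
  d <- make_dyad(U_a = 0.5, U_b = -0.5, T_ = 1, w_a = 0.9, w_b = 1)
  # force a fight by redrawing until both escalate (w_a = 0.9)
  repeat {
    res <- run_conflict(d$a, d$b, benefit = 1, sigma_eps = 1)
    if (res$outcome$fought) break
  }
  o <- res$outcome
  win_a <- o$winner == 1L
  expect_equal(unname(res$ind_i$w[["2"]]),
               update_willingness(0.9, 0.5, if (win_a) "winner" else "loser"))
  expect_equal(unname(res$ind_j$w[["1"]]),
               update_willingness(1, -0.5, if (win_a) "loser" else "winner"))
  # benefit conservation: winner gained b, both paid fight costs
  fr <- o$fight_result
  expect_equal(res$ind_i$fitness, 100 - fr$cost_i + if (win_a) 1 else 0)
  expect_equal(res$ind_j$fitness, 100 - fr$cost_j + if (win_a) 0 else 1)
})

test_that("turn-taking fixed point: U = -1 gives strict alternation", {
  set.seed(36)
  log <- run_closed_dyad(U = -1, T_ = 0.5, n_conflicts = 21)
  # the opening conflict is a fight (both willingness values start at 1)
  expect_true(log$fought[1])
  # afterwards the willingness pair sits on the {0,1} fixed point:
  # no further fights, and the winner alternates deterministically
  expect_false(any(log$fought[-1]))
  expect_true(all(log$escalated_i[-1] | log$escalated_j[-1]))
  expect_true(all(abs(diff(log$winner)) == 1))
  # each individual obtains the resource exactly k times in 2k conflicts
  post <- log$winner[-1]
  expect_identical(sum(post == 1L), 10L)
  expect_identical(sum(post == 2L), 10L)
})

test_that("contest fixed point: U = +1 gives fixed dominance", {
  set.seed(37)
  log <- run_closed_dyad(U = 1, T_ = 2, n_conflicts = 21)
  expect_true(log$fought[1])
  expect_false(any(log$fought[-1]))
  first_winner <- log$winner[1]
  expect_true(all(log$winner == first_winner))
})

test_that("an individual driven below zero fitness is disabled and stays so", {
  # tiny fitness guarantees the floor during the first fight
  a <- new_individual(1L, s = 0.5, fitness = 2, U = -1, T_ = 5,
                      w = c("2" = 1))
  b <- new_individual(2L, s = 0.5, fitness = 100, U = -1, T_ = 5,
                      w = c("1" = 1))
  set.seed(38)
  res <- run_conflict(a, b, benefit = 1, sigma_eps = 0.5)
  expect_true(res$ind_i$escalation_disabled)
  expect_identical(unname(res$ind_i$w[["2"]]), 0)
  # later conflicts: the disabled side never escalates again
  res2 <- run_conflict(res$ind_i, res$ind_j, benefit = 1, sigma_eps = 0.5)
  expect_false(res2$outcome$escalated_i)
  expect_true(res2$ind_i$escalation_disabled)
  expect_identical(unname(res2$ind_i$w[["2"]]), 0)
})
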