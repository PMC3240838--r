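tiny_cfg <- function(...) {
  base <- list(n_groups = 4L, group_size = 4L, n_conflict_rounds = 3L,
               n_generations = 3L, benefit = 2, seed = 5L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

test_that("run_conflict_round runs every dyad exactly once", {
  set.seed(41)
  cfg <- sim_config(n_groups = 1L, group_size = 10L)
  grp <- init_population(cfg)$groups[[1]]
  rr <- run_conflict_round(grp, benefit = 1, sigma_eps = 1)
  expect_identical(nrow(rr$outcomes), 45L)  # C(10, 2)
  key <- paste(pmin(rr$outcomes$i, rr$outcomes$j),
               pmax(rr$outcomes$i, rr$outcomes$j))
  expect_identical(length(unique(key)), 45L)
  # exactly one resource holder per conflict: benefit added = 45 b
  grp2 <- init_population(sim_config(n_groups = 1L, group_size = 2L))$groups[[1]]
  expect_identical(nrow(run_conflict_round(grp2, 1, 1)$outcomes), 1L)
})

test_that("benefit conservation holds over a no-fight round", {
  set.seed(42)
  cfg <- sim_config(n_groups = 1L, group_size = 6L)
  grp <- init_population(cfg)$groups[[1]]
  grp <- lapply(grp, function(ind) { ind$w[] <- 0; ind })  # nobody escalates
  rr <- run_conflict_round(grp, benefit = 3, sigma_eps = 1)
  tot_before <- 6 * 100
  tot_after <- sum(vapply(rr$group, function(x) x$fitness, numeric(1)))
  expect_equal(tot_after - tot_before, choose(6, 2) * 3)  # no costs, only b
})

test_that("select_parent is fitness-proportional with zero-clamping", {
  mk <- function(f) new_individual(1L, 0.5, f, 0, 0, c("2" = 1))
  set.seed(43)
  grp <- list(mk(300), mk(100))
  picks <- vapply(1:20000, function(k) select_parent(grp), integer(1))
  expect_lt(abs(mean(picks == 1L) - 0.75), 3 * sqrt(0.75 * 0.25 / 20000))
  # negative fitness never reproduces
  grp2 <- list(mk(-5), mk(10))
  expect_true(all(vapply(1:2000, function(k) select_parent(grp2),
                         integer(1)) == 2L))
  # all-zero clamped fitness: uniform fallback
  grp3 <- list(mk(-1), mk(-2), mk(0))
  picks3 <- vapply(1:6000, function(k) select_parent(grp3), integer(1))
  expect_true(all(1:3 %in% picks3))
})

test_that("make_offspring inherits, resets state, and mutates jointly", {
  parent <- new_individual(1L, 0.9, 17, U = 0.33, T_ = 1.21,
                           w = c("2" = 0.4, "3" = 0))
  cfg <- sim_config(group_size = 3L, mutation_prob = 0)
  set.seed(44)
  off <- make_offspring(parent, cfg)
  expect_equal(off$U, 0.33)
  expect_equal(off$T, 1.21)
  expect_equal(off$fitness, 100)
  expect_true(all(off$w == 1))
  expect_false(off$escalation_disabled)
  expect_false(off$s == parent$s)  # strength is redrawn, not inherited

  # mutated fraction matches the mutation probability
  cfg2 <- sim_config(group_size = 3L, mutation_prob = 0.001)
  set.seed(45)
  n <- 1e5L
  mut <- vapply(seq_len(n), function(k) {
    make_offspring(parent, cfg2)$U != 0.33
  }, logical(1))
  expect_lt(abs(mean(mut) - 0.001), 3 * sqrt(0.001 * 0.999 / n))

  # mutated values are uniform over the admissible ranges
  cfg3 <- sim_config(group_size = 3L, mutation_prob = 1)
  set.seed(46)
  kids <- lapply(1:20000, function(k) make_offspring(parent, cfg3))
  Us <- vapply(kids, `[[`, numeric(1), "U")
  Ts <- vapply(kids, `[[`, numeric(1), "T")
  expect_true(all(Us >= -1 & Us <= 1) && all(Ts >= 0 & Ts <= 5))
  expect_lt(abs(mean(Ts) - 2.5), 3 * sqrt(25 / 12 / 20000))
  expect_lt(abs(mean(Us) - 0), 3 * sqrt(4 / 12 / 20000))
})

test_that("reproduce_and_migrate conserves structure and lineages", {
  set.seed(47)
  cfg <- sim_config(n_groups = 5L, group_size = 4L, mutation_prob = 0)
  pop <- init_population(cfg)
  # give individuals distinguishable heritable values
  for (g in seq_along(pop$groups)) {
    for (i in seq_along(pop$groups[[g]])) {
      pop$groups[[g]][[i]]$U <- round(runif(1, -1, 1), 6)
    }
  }
  parents_U <- sort(unique(population_df(pop)$U))
  pop2 <- reproduce_and_migrate(pop, cfg)
  expect_identical(pop2$generation, 1L)
  expect_length(pop2$groups, 5L)
  expect_true(all(lengths(pop2$groups) == 4L))
  df2 <- population_df(pop2)
  # without mutation every offspring U is some parent's U
  expect_true(all(df2$U %in% parents_U))
  expect_true(all(df2$fitness == 100))
})

test_that("neutral drift matches Wright-Fisher sampling moments", {
  # one group, two lineages at equal fitness, no mutation: the offspring
  # count of lineage 1 is Binomial(group_size, 1/2)
  cfg <- sim_config(n_groups = 1L, group_size = 10L, mutation_prob = 0)
  pop <- init_population(cfg)
  for (i in 1:10) pop$groups[[1]][[i]]$U <- if (i <= 5) -1 else 1
  set.seed(48)
  reps <- 600L
  counts <- vapply(seq_len(reps), function(k) {
    sum(population_df(reproduce_and_migrate(pop, cfg))$U == -1)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(2.5 / reps))
  expect_lt(abs(var(counts) - 2.5) / 2.5, 0.25)  # binomial npq = 2.5
})

test_that("run_simulation honors the generation contract", {
  r0 <- run_simulation(tiny_cfg(n_generations = 0L))
  expect_identical(nrow(r0$summary), 0L)
  expect_identical(nrow(r0$individuals), 16L)
  r <- run_simulation(tiny_cfg())
  expect_identical(nrow(r$summary), 3L)
  expect_identical(r$summary$generation, 1:3)
  expect_identical(nrow(r$individuals), 16L)
  expect_true(all(r$individuals$U >= -1 & r$individuals$U <= 1))
  expect_true(all(r$individuals$T >= 0 & r$individuals$T <= 5))
  expect_length(r$tallies, 4L)
  # tallies are recomputable from the returned conflict log (cross-check)
  for (g in 1:4) {
    lg <- r$conflict_log[r$conflict_log$group == g, ]
    expect_identical(unname(tally_from_log(lg, 4L)),
                     unname(r$tallies[[g]]))
  }
  # fight lengths in the log match the recorded vector
  expect_identical(sort(r$conflict_log$fight_length[r$conflict_log$fought]),
                   sort(r$fight_lengths))
})

test_that("the R reference engine and compiled engine agree statistically", {
  # identical model, independent implementations: compare end-of-generation
  # mean fitness and fight counts over replicate seeds
  cfgs <- lapply(1:12, function(s) {
    sim_config(n_groups = 12L, group_size = 4L, n_conflict_rounds = 5L,
               n_generations = 1L, benefit = 2, U_init = 0.5,
               mutation_prob = 0, seed = 100L + s)
  })
  fit_c <- vapply(cfgs, function(cc) {
    run_simulation(cc, engine = "cpp")$summary$mean_fitness
  }, numeric(1))
  fit_r <- vapply(cfgs, function(cc) {
    run_simulation(cc, engine = "r")$summary$mean_fitness
  }, numeric(1))
  # same distribution: difference of means within 4 SE of the difference
  se <- sqrt(var(fit_c) / 12 + var(fit_r) / 12)
  expect_lt(abs(mean(fit_c) - mean(fit_r)), 4 * se)
})

test_that("turn-taking evolves in a scaled-down single run at benefit 1", {
  cfg <- sim_config(n_groups = 40L, group_size = 10L, n_generations = 150L,
                    benefit = 1, U_init = -1, seed = 7L)
  r <- run_simulation(cfg)
  expect_identical(classify_strategy(r$individuals$U), "turn_taking")
  expect_lt(mean(r$individuals$T), 1)
  # alternation shows up as low directional consistency
  gm <- group_metrics(r, n_randomizations = 100L)
  expect_lt(mean(gm$dci, na.rm = TRUE), 0.2)
})
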