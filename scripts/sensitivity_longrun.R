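#!/usr/bin/env Rscript
# Long-running sensitivity analysis (excluded from the default test suite;
# expect 30-45+ minutes). Checks that the largest benefit still producing a
# turn-taking outcome is
#   - non-decreasing in the perception-noise SD,
#   - non-increasing in the number of conflict rounds,
#   - non-decreasing in group size,
# at reduced (desk-preset) scale.
#
# Usage: Rscript scripts/sensitivity_longrun.R [--seed <int>] [--out <dir>]

library(turntaking)

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, out = "scratch/sensitivity")
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", args[i])
}
dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

tpl <- sim_preset("desk")
axes <- list(
  sigma_eps = c(0.5, 2),
  n_conflict_rounds = c(4, 40),
  group_size = c(5, 20)
)
expect_dir <- c(sigma_eps = 1, n_conflict_rounds = -1, group_size = 1)

ok <- TRUE
for (axis in names(axes)) {
  tab <- sensitivity_sweep(axis, axes[[axis]], tpl, benefits = 1:10,
                           n_replicates = 2L, seed = opt$seed,
                           n_randomizations = 200L)
  utils::write.csv(tab, file.path(opt$out, paste0(axis, ".csv")),
                   row.names = FALSE)
  ceil <- attr(tab, "ceilings")
  ceil[is.na(ceil)] <- 0
  mono <- if (expect_dir[[axis]] > 0) diff(ceil) >= 0 else diff(ceil) <= 0
  cat(sprintf("%-18s ceilings: %s  monotone as expected: %s\n",
              axis, paste(ceil, collapse = ", "), all(mono)))
  ok <- ok && all(mono)
}
cat(if (ok) "all monotonicity checks passed\n" else
  "monotonicity check FAILED\n")
quit(status = if (ok) 0L else 1L)
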