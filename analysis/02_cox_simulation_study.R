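#!/usr/bin/env Rscript
# Stage 2 -- Cox-regression replicate study.
#
# For the requested scenario sets, simulates `--replicates` datasets each
# and fits (i) Cox regression on the day-0 predictor value and group, and
# (ii) Cox regression with the full longitudinal record carried forward
# (LOCF counting-process layout). Summarizes 95% CI coverage and the
# percentage of estimates below the truth for the predictor and group
# coefficients.
#
#   Rscript analysis/02_cox_simulation_study.R [--sets 1,3,23,33]
#       [--replicates 100] [--seed 1] [--out results]

suppressPackageStartupMessages(library(jmbench))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
sets <- as.integer(strsplit(get_arg("--sets", "1,3,23,33"), ",")[[1]])
reps <- as.integer(get_arg("--replicates", "100"))
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "results")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

grid <- scenario_grid(seed = seed)
st <- run_study(grid[sets], methods = c("cox_baseline", "cox_locf"),
                replicates = reps)

write.csv(st$replicates, file.path(out, "cox_replicates.csv"),
          row.names = FALSE)
write.csv(st$summary, file.path(out, "cox_summary.csv"), row.names = FALSE)

cat("\nCoverage of 95% CIs and % estimates below truth",
    sprintf("(%d replicates):\n", reps))
print(st$summary[, c("set_id", "method", "coverage_lambda1",
                     "pct_below_lambda1", "coverage_tau",
                     "pct_below_tau", "flag_lambda1")],
      row.names = FALSE)
cat("\nCells with coverage < 90 or pct-below outside [40, 60] are the",
    "poorly performing ones;\nthe baseline-value fit shows the",
    "characteristic attenuation (pct-below well under 40).\n")
cat("written:", file.path(out, "cox_summary.csv"), "\n")
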