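#!/usr/bin/env Rscript
# Exhaustive best-ensemble selection on the simulated screen from
# analysis/02_simulate_screen.R: k = 5 ensembles selected for four
# objectives (antagonist/agonist enrichment vs decoys, and the two summed
# class-discrimination objectives), then cross-evaluated into a long-format
# AUC table.

suppressPackageStartupMessages(library(ensdock))
if (!file.exists("results/simulated/scores.csv"))
  stop("run analysis/02_simulate_screen.R first")

bundle <- run_full_benchmark(list(
  scores = "results/simulated/scores.csv",
  labels = "results/simulated/labels.csv",
  k = 5,
  out_dir = "results/ensemble_selection"))

truth <- jsonlite::read_json("results/simulated/truth.json",
                             simplifyVector = TRUE)
for (nm in names(bundle$selected)) {
  memb <- bundle$selected[[nm]]$members
  cat(sprintf("%-22s -> {%s} (%d antagonist-like)\n", nm,
              paste(memb, collapse = ", "),
              sum(truth$conformation_type[memb] == "antagonist_like")))
}

cat("\nCross-evaluation (ensemble x actives x inactives):\n")
print(bundle$auc_table, row.names = FALSE)

cat("\nNote the promiscuity pattern: the antagonist-selected ensemble also\n")
cat("enriches agonists, while the agonist-selected ensemble is the weaker\n")
cat("of the two for antagonist screening.\n")
if (length(bundle$decision_log))
  cat("Decisions:", paste(bundle$decision_log, collapse = "\n"), "\n")
cat("Wrote results/ensemble_selection/\n")
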