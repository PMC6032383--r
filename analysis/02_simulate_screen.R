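#!/usr/bin/env Rscript
# Simulate an ensemble-docking screen at the default study conditions:
# 118 agonists + 115 antagonists vs 3000 decoys over a pool of 12 receptor
# conformations (6 agonist-like, 6 antagonist-like), Gaussian scores with
# class-dependent docking failures. Writes the score matrix, labels and
# planted truth for the downstream selection step.

suppressPackageStartupMessages(library(ensdock))
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

cfg <- score_gen_config(seed = 20260922L)
g <- gen_score_matrix(cfg)
print(g$matrix)
print(g$labels)

write_score_matrix(g$matrix, "results/simulated/scores.csv")
write_labels(g$labels, "results/simulated/labels.csv")
jsonlite::write_json(
  list(conformation_type = as.list(g$truth$conformation_type),
       seed = cfg$seed),
  "results/simulated/truth.json", auto_unbox = TRUE, digits = NA)

d <- score_distribution(g$matrix, g$labels)
print(d)
cat("\nFraction of each class at or below the -10 score threshold and the\n")
cat("per-class failure fractions are shown above; antagonists fail on\n")
cat("agonist-like conformations by construction.\n")
cat("Wrote results/simulated/{scores,labels}.csv and truth.json\n")
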