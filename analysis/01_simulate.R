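#!/usr/bin/env Rscript
# Simulate the three panels the downstream analyses use:
#   - a training panel shaped like the reference study's training set
#     (44 genes, 56 cases / 75 controls, population AUCs spanning 0.67-0.94,
#     ~15% of cells missing at random),
#   - a same-population test panel (64 + 64): the transfer scenario where the
#     panel's per-gene effects carry over,
#   - an independent-population test panel (64 + 64) whose per-gene effects
#     are redrawn independently of training: the scenario a blinded
#     replication study probes.
# Writes the wide TSV tables + label files under results/data/.

suppressPackageStartupMessages(library(profscore))

seed <- 20110330L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

train_cfg <- paper_like_config(seed = seed)
training <- simulate_dataset(train_cfg)

same_cfg <- train_cfg
same_cfg$n_case <- 64L; same_cfg$n_control <- 64L
same_cfg$seed <- seed + 1L
same_pop <- simulate_dataset(same_cfg)

indep_cfg <- same_cfg
indep_cfg$seed <- seed + 2L
indep_cfg$gene_params$delta <- withr::with_seed(
  seed + 3L, sqrt(2) * qnorm(runif(nrow(indep_cfg$gene_params), 0.67, 0.94)))
indep_pop <- simulate_dataset(indep_cfg)

for (nm in c("training", "same_pop", "indep_pop")) {
  ds <- get(nm)
  write_expression_table(ds, sprintf("results/data/%s_rq.tsv", nm))
  write_labels(ds, sprintf("results/data/%s_labels.tsv", nm))
  message(sprintf("%s: %d genes x %d samples (%d case / %d control), %.1f%% missing",
                  nm, nrow(ds$values), ncol(ds$values),
                  sum(ds$labels == "case"), sum(ds$labels == "control"),
                  100 * mean(missing_mask(ds))))
}
message("population per-gene AUC range (training/same_pop): ",
        paste(round(range(expected_gene_auc(train_cfg$gene_params$delta, 1, 1)), 3),
              collapse = " - "))
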