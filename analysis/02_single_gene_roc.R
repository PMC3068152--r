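#!/usr/bin/env Rscript
# How well does each reporter gene classify on its own?  Per-gene empirical
# ROC/AUC on the training panel, plus Welch t-tests of case vs control RQ.
# Expects results/data/ from 01_simulate.R; writes results/tables/.

suppressPackageStartupMessages(library(profscore))

training <- read_expression_table("results/data/training_rq.tsv", "RQ",
                                  labels_path = "results/data/training_labels.tsv")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

aucs <- vapply(gene_ids(training), function(g)
  auc(roc_curve(training$values[g, ], training$labels)), numeric(1))
welch <- lapply(gene_ids(training), function(g) {
  v <- training$values[g, ]
  welch_t_test(v[training$labels == "case" & !is.na(v)],
               v[training$labels == "control" & !is.na(v)])
})
tab <- data.frame(gene = gene_ids(training), auc = unname(aucs),
                  welch_t = sapply(welch, `[[`, "t"),
                  welch_p = sapply(welch, `[[`, "p"))
write.table(tab[order(-tab$auc), ], "results/tables/single_gene_auc.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

best <- tab$gene[which.max(tab$auc)]
worst <- tab$gene[which.min(tab$auc)]
for (g in c(best, worst))
  write_roc_curve(roc_curve(training$values[g, ], training$labels),
                  sprintf("results/tables/roc_%s.tsv", g))

message(sprintf("per-gene AUC: %.3f (%s, best) down to %.3f (%s, worst)",
                max(tab$auc), best, min(tab$auc), worst))
message(sprintf("%d of %d genes have Welch p < 0.01 (case mean RQ above control)",
                sum(tab$welch_p < 0.01 & tab$welch_t > 0), nrow(tab)))
message("wrote results/tables/single_gene_auc.tsv and example ROC exports")
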