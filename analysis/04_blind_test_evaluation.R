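#!/usr/bin/env Rscript
# Apply the frozen training-calibrated classifier to the two test panels.
# The panels are scored blind (labels withheld until after prediction), then
# unblinded for evaluation: confusion matrices and percentage summaries at
# both FPR settings, per-gene accuracies, and the training-vs-test
# correlation of per-gene accuracy that measures whether the panel's gene
# ranking transfers to a new population.

suppressPackageStartupMessages(library(profscore))

training <- read_expression_table("results/data/training_rq.tsv", "RQ",
                                  labels_path = "results/data/training_labels.tsv")
dir.create("results/evaluation", recursive = TRUE, showWarnings = FALSE)

for (panel in c("same_pop", "indep_pop")) {
  blind <- read_expression_table(sprintf("results/data/%s_rq.tsv", panel), "RQ")
  truth <- read_labels(sprintf("results/data/%s_labels.tsv", panel))

  for (fpr in c(0.05, 0.10)) {
    tag <- sprintf("fpr%02d", round(100 * fpr))
    cutoffs <- read_gene_cutoffs(sprintf("results/classifier/gene_cutoffs_%s.json", tag))
    clf <- read_score_classifier(sprintf("results/classifier/score_classifier_%s.json", tag))

    profiles <- binarize(blind, cutoffs)                 # labels still unknown
    predictions <- classify(profile_score(profiles), clf)
    write_profiles(profiles,
                   sprintf("results/evaluation/%s_predictions_%s.tsv", panel, tag),
                   predictions = predictions)

    # unblind and evaluate
    unblinded <- blind; unblinded$labels <- truth[sample_ids(blind)]
    cm <- confusion(predictions, unblinded$labels)
    m <- summary_metrics(cm)
    jsonlite::write_json(list(confusion = unclass(cm), metrics = m),
                         sprintf("results/evaluation/%s_confusion_%s.json", panel, tag),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    message(sprintf(
      "%s [%s]: tp=%d fp=%d tn=%d fn=%d | sens %d%% spec %d%% ppv %s%% acc %d%%",
      panel, tag, cm$tp, cm$fp, cm$tn, cm$fn,
      m$sensitivity$pct_rounded, m$specificity$pct_rounded,
      format(m$ppv$pct_rounded), m$accuracy$pct_rounded))

    if (fpr == 0.05) {
      acc_train <- per_gene_accuracy(training, cutoffs)
      acc_test <- per_gene_accuracy(unblinded, cutoffs)
      r <- pearson_correlation(acc_train$pct_correct, acc_test$pct_correct)
      write.table(data.frame(gene = acc_train$gene,
                             pct_correct_training = acc_train$pct_correct,
                             pct_correct_test = acc_test$pct_correct),
                  sprintf("results/evaluation/%s_gene_accuracy_%s.tsv", panel, tag),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      message(sprintf(
        "%s [%s]: per-gene accuracy correlation training vs test r = %.3f",
        panel, tag, r))
    }
  }
}
message("wrote results/evaluation/: predictions, confusion matrices, per-gene accuracies")
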