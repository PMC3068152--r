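#' Configure an end-to-end panel classification run
#'
#' Bundles the inputs and settings of a full run: a labelled training panel,
#' an optional (possibly blinded) test panel, the value scale, the target
#' false-positive rates to calibrate at, and the optional minimum-measured
#' filter. Inputs come either from files (wide tables + label files, see
#' [read_expression_table()]) or from a synthetic specification -- exactly one
#' of the two.
#'
#' @param training_table,training_labels paths to the training expression
#'   table and its label file.
#' @param test_table path to the test expression table; `test_labels` may be
#'   omitted for a blinded set.
#' @param test_labels optional path to test labels.
#' @param synthetic alternatively, a list with element `training` (a
#'   [synthetic_config()]) and optional element `test` (another
#'   [synthetic_config()]).
#' @param scale `"RQ"` or `"DELTA_CT"`; applies to file inputs (synthetic
#'   configs carry their own `scale_out`).
#' @param target_fprs numeric vector of false-positive-rate settings in
#'   \[0, 1); the study used 0.05 and 0.10.
#' @param min_present optional minimum number of measured genes per sample
#'   ([filter_min_present()]); `NULL` disables the filter (the default -- the
#'   study applied it only in its clustering experiments, with value 22).
#' @param out_dir optional directory for serialized artifacts; created if
#'   needed. `NULL` keeps the run in memory.
#' @return A `run_config` list.
#' @export
run_config <- function(training_table = NULL, training_labels = NULL,
                       test_table = NULL, test_labels = NULL,
                       synthetic = NULL,
                       scale = c("RQ", "DELTA_CT"),
                       target_fprs = c(0.05, 0.10),
                       min_present = NULL, out_dir = NULL) {
  scale <- match.arg(scale)
  from_files <- !is.null(training_table)
  from_synth <- !is.null(synthetic)
  if (from_files == from_synth)
    stop("exactly one of file inputs (`training_table` + `training_labels`) ",
         "or `synthetic` must be given")
  if (from_files && is.null(training_labels))
    stop("`training_labels` is required with `training_table`")
  if (from_synth && !inherits(synthetic$training, "synthetic_config"))
    stop("`synthetic$training` must be a synthetic_config")
  if (any(target_fprs < 0) || any(target_fprs >= 1))
    stop("`target_fprs` must lie in [0, 1)")
  structure(list(training_table = training_table,
                 training_labels = training_labels,
                 test_table = test_table, test_labels = test_labels,
                 synthetic = synthetic, scale = scale,
                 target_fprs = target_fprs, min_present = min_present,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full calibrate-score-classify-evaluate workflow
#'
#' For every target FPR in the configuration: calibrates per-gene cut-offs on
#' the training set ([calibrate_gene_cutoffs()]), binarizes and scores the
#' training samples, calibrates the profile-score cut-off
#' ([calibrate_score_cutoff()]), scores and classifies the test set when one
#' is given, and -- when test labels are known -- evaluates with confusion
#' matrices, summary percentages and per-gene accuracy. When test labels are
#' absent (a blinded set), evaluation is skipped and predictions alone are
#' produced. A per-gene training summary (AUC, accuracy at the calibrated
#' cut-off, Welch t-test case vs control) is always computed.
#'
#' The run is deterministic given the configuration (synthetic inputs carry
#' their own seeds); with `out_dir` set, every intermediate artifact is
#' serialized (JSON for classifier artifacts, TSV for tables).
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return A `run_report`: list with `training`, `test` (datasets) and
#'   `per_fpr`, a named list keyed by FPR setting, each holding `cutoffs`,
#'   `classifier`, `training_scores`, `training_score_auc`, `gene_summary`,
#'   and -- with a test set -- `test_scores`, `test_predictions` plus
#'   `test_confusion`, `test_metrics`, `test_gene_accuracy` when labels are
#'   known.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(cfg$synthetic)) {
    training <- simulate_dataset(cfg$synthetic$training)
    test <- if (!is.null(cfg$synthetic$test)) simulate_dataset(cfg$synthetic$test)
  } else {
    training <- read_expression_table(cfg$training_table, scale = cfg$scale,
                                      labels_path = cfg$training_labels)
    test <- if (!is.null(cfg$test_table))
      read_expression_table(cfg$test_table, scale = cfg$scale,
                            labels_path = cfg$test_labels)
  }
  if (!is.null(cfg$min_present)) {
    n0 <- ncol(training$values)
    training <- filter_min_present(training, cfg$min_present)
    say("min-present filter (>= %d genes): kept %d of %d training samples",
        cfg$min_present, ncol(training$values), n0)
  }
  say("training: %d genes, %d samples (%d case / %d control)",
      nrow(training$values), ncol(training$values),
      sum(training$labels == "case"), sum(training$labels == "control"))

  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  art <- function(name) file.path(out_dir, name)

  per_fpr <- list()
  for (fpr in cfg$target_fprs) {
    tag <- sprintf("fpr%02d", as.integer(round(100 * fpr)))
    cutoffs <- calibrate_gene_cutoffs(training, target_fpr = fpr)
    say("[%s] calibrated %d genes; per-gene n_cases %d-%d, n_controls %d-%d",
        tag, nrow(cutoffs), min(cutoffs$n_cases_used), max(cutoffs$n_cases_used),
        min(cutoffs$n_controls_used), max(cutoffs$n_controls_used))
    train_profiles <- binarize(training, cutoffs)
    train_scores <- profile_score(train_profiles)
    zeroed <- sum(missing_mask(training))
    say("[%s] training profiles built (%d missing cells scored as 0)", tag, zeroed)
    clf <- calibrate_score_cutoff(train_scores, training$labels, target_fpr = fpr)
    score_roc <- roc_curve(train_scores, training$labels)
    res <- list(target_fpr = fpr, cutoffs = cutoffs, classifier = clf,
                training_scores = train_scores,
                training_score_auc = auc(score_roc),
                gene_summary = gene_summary(training, cutoffs))
    say("[%s] score cut-off %s: training FPR %.3f, TPR %.3f, score AUC %.3f",
        tag, format(clf$score_cutoff), clf$achieved_fpr, clf$achieved_tpr,
        res$training_score_auc)

    if (!is.null(test)) {
      test_profiles <- binarize(test, cutoffs)
      res$test_scores <- profile_score(test_profiles)
      res$test_predictions <- classify(res$test_scores, clf)
      if (all(test$labels %in% c("case", "control"))) {
        res$test_confusion <- confusion(res$test_predictions, test$labels)
        res$test_metrics <- summary_metrics(res$test_confusion)
        res$test_gene_accuracy <- per_gene_accuracy(test, cutoffs)
        say("[%s] test confusion: tp=%d fp=%d tn=%d fn=%d", tag,
            res$test_confusion$tp, res$test_confusion$fp,
            res$test_confusion$tn, res$test_confusion$fn)
      } else {
        say("[%s] test labels unknown: blinded mode, predictions only", tag)
      }
    }

    if (!is.null(out_dir)) {
      write_gene_cutoffs(cutoffs, art(paste0("gene_cutoffs_", tag, ".json")))
      write_score_classifier(clf, art(paste0("score_classifier_", tag, ".json")))
      write_profiles(train_profiles, art(paste0("training_profiles_", tag, ".tsv")),
                     predictions = classify(train_scores, clf))
      write_roc_curve(score_roc, art(paste0("training_score_roc_", tag, ".tsv")))
      utils::write.table(res$gene_summary, art(paste0("gene_summary_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(test)) {
        write_profiles(test_profiles, art(paste0("test_predictions_", tag, ".tsv")),
                       predictions = res$test_predictions)
        if (!is.null(res$test_confusion)) {
          jsonlite::write_json(
            list(confusion = unclass(res$test_confusion),
                 metrics = res$test_metrics),
            art(paste0("evaluation_", tag, ".json")),
            digits = NA, auto_unbox = TRUE, pretty = TRUE)
          utils::write.table(res$test_gene_accuracy,
                             art(paste0("test_gene_accuracy_", tag, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
    per_fpr[[sprintf("%g", fpr)]] <- res
  }
  structure(list(training = training, test = test, per_fpr = per_fpr),
            class = "run_report")
}

#' Per-gene training summary
#'
#' For each panel gene: empirical ROC AUC of the gene as a single predictor,
#' prediction accuracy at its calibrated cut-off, and a Welch two-sample
#' t-test comparing case and control values (on the dataset's scale, missing
#' values dropped).
#'
#' @param ds a labelled [expression_dataset()].
#' @param cutoffs a `gene_cutoff_table` for the panel.
#' @return Data frame with `gene`, `auc`, `n_correct`, `pct_correct`,
#'   `welch_t`, `welch_df`, `welch_p`.
#' @export
gene_summary <- function(ds, cutoffs) {
  stopifnot(inherits(ds, "expression_dataset"))
  direction <- scale_direction(ds$scale)
  acc <- per_gene_accuracy(ds, cutoffs)
  aucs <- vapply(cutoffs$gene, function(g)
    auc(roc_curve(ds$values[g, ], ds$labels, direction = direction)), numeric(1))
  welch <- lapply(cutoffs$gene, function(g) {
    v <- ds$values[g, ]
    welch_t_test(v[ds$labels == "case" & !is.na(v)],
                 v[ds$labels == "control" & !is.na(v)])
  })
  data.frame(gene = cutoffs$gene,
             auc = unname(aucs),
             n_correct = acc$n_correct,
             pct_correct = acc$pct_correct,
             welch_t = vapply(welch, `[[`, numeric(1), "t"),
             welch_df = vapply(welch, `[[`, numeric(1), "df"),
             welch_p = vapply(welch, `[[`, numeric(1), "p"),
             row.names = NULL)
}
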