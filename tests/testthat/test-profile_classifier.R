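sim_training <- function(seed = 3, n_genes = 8, missing_rate = 0.1) {
  simulate_dataset(synthetic_config(
    n_case = 30, n_control = 40,
    gene_params = data.frame(gene = sprintf("g%02d", seq_len(n_genes)),
                             mu = 0, delta = seq(0.5, 2, length.out = n_genes),
                             sd_case = 1, sd_control = 1),
    missing_rate = missing_rate, seed = seed))
}

test_that("per-gene calibration respects the FPR ceiling at both settings", {
  ds <- sim_training()
  for (target in c(0.05, 0.10)) {
    tab <- calibrate_gene_cutoffs(ds, target_fpr = target)
    expect_s3_class(tab, "gene_cutoff_table")
    expect_equal(tab$gene, gene_ids(ds))
    expect_true(all(tab$achieved_fpr <= target))
    expect_true(all(tab$direction == "greater_is_positive"))
    expect_true(all(tab$n_cases_used <= 30 & tab$n_controls_used <= 40))
    # achieved rates are reproducible from the data and the cut-off
    for (g in c("g01", "g08")) {
      v <- ds$values[g, ]
      ctrl <- v[ds$labels == "control" & !is.na(v)]
      expect_equal(mean(ctrl > tab$cutoff[tab$gene == g]),
                   tab$achieved_fpr[tab$gene == g])
    }
  }
})

test_that("a separable gene calibrates to a perfect operating point", {
  ds <- make_ds(matrix(c(5, 6, 7, 1, 2, 3), 1), labels = rep(c("case", "control"), each = 3))
  tab <- calibrate_gene_cutoffs(ds, 0.05)
  expect_equal(tab$achieved_fpr, 0)
  expect_equal(tab$achieved_tpr, 1)
})

test_that("calibration errors name a gene with no measured class", {
  v <- matrix(c(1, 2, NA, NA, 5, 6, 7, 8), 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), sprintf("s%d", 1:4)))
  ds <- expression_dataset(v, "RQ", rep(c("case", "control"), each = 2))
  expect_error(calibrate_gene_cutoffs(ds, 0.05), "gene 'gA'")
})

test_that("delta-Ct calibration flips direction and reproduces RQ profiles", {
  cfg_rq <- synthetic_config(20, 25, data.frame(
    gene = c("gA", "gB"), mu = 0, delta = c(1, 2), sd_case = 1, sd_control = 1),
    missing_rate = 0.1, seed = 13, scale_out = "RQ")
  cfg_dct <- cfg_rq; cfg_dct$scale_out <- "DELTA_CT"
  ds_rq <- simulate_dataset(cfg_rq)
  ds_dct <- simulate_dataset(cfg_dct)
  tab_rq <- calibrate_gene_cutoffs(ds_rq, 0.05)
  tab_dct <- calibrate_gene_cutoffs(ds_dct, 0.05)
  expect_true(all(tab_dct$direction == "less_is_positive"))
  expect_equal(tab_dct$achieved_fpr, tab_rq$achieved_fpr)
  expect_equal(tab_dct$achieved_tpr, tab_rq$achieved_tpr)
  # same samples fire on either scale: the profiles coincide digit for digit
  expect_equal(binarize(ds_dct, tab_dct), binarize(ds_rq, tab_rq))
})

test_that("binarization follows the strict greater-than and missing-to-0 rules", {
  v <- matrix(c(2.0, 1.5, NA, 0.4, 1.5, 9.9), 3, 2,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  ds <- expression_dataset(v, "RQ", c("control", "control"))
  tab <- structure(data.frame(gene = c("gA", "gB", "gC"),
                              cutoff = c(1.5, 1.5, 1.5),
                              direction = "greater_is_positive",
                              target_fpr = 0.05, achieved_fpr = 0,
                              achieved_tpr = 1, n_cases_used = 1L,
                              n_controls_used = 1L),
                   class = c("gene_cutoff_table", "data.frame"))
  prof <- binarize(ds, tab)
  expect_identical(prof["gA", ], c(s1 = 1L, s2 = 0L))  # 2.0 > 1.5; 0.4 below
  expect_identical(prof["gB", ], c(s1 = 0L, s2 = 0L))  # equal to cut-off is 0
  expect_identical(prof["gC", ], c(s1 = 0L, s2 = 1L))  # missing is 0
  expect_equal(unname(profile_score(prof)), c(1L, 1L))
})

test_that("gene-set mismatch is an error, not silent zeros", {
  ds <- sim_training(n_genes = 8)
  tab <- calibrate_gene_cutoffs(ds, 0.05)
  smaller <- expression_dataset(ds$values[1:7, ], "RQ", ds$labels)
  expect_error(binarize(smaller, tab), "configuration error.*g08")
})

test_that("profile scores count the fired digits and stay within [0, G]", {
  ds <- sim_training(seed = 5)
  tab <- calibrate_gene_cutoffs(ds, 0.05)
  prof <- binarize(ds, tab)
  sc <- profile_score(prof)
  expect_equal(unname(sc), unname(colSums(prof == 1L)))
  expect_true(all(sc >= 0 & sc <= nrow(prof)))
  expect_named(sc, sample_ids(ds))
  expect_error(profile_score(prof * 2L), "0/1 matrix")
})

test_that("score cut-off calibration mirrors the single-score ROC rules", {
  # separable scores: controls at <= 3, cases at >= 6
  scores <- c(rep(0:3, 10), rep(6:9, 4))
  labels <- rep(c("control", "case"), c(40, 16))
  clf <- calibrate_score_cutoff(scores, labels, 0.05)
  expect_true(clf$score_cutoff >= 3 && clf$score_cutoff < 6)
  expect_equal(clf$achieved_fpr, 0)
  expect_equal(clf$achieved_tpr, 1)

  # 20 controls at 5% leaves room for at most one false positive
  withr::local_seed(8)
  sc <- c(rpois(15, 8), rpois(20, 3))
  lab <- rep(c("case", "control"), c(15, 20))
  clf2 <- calibrate_score_cutoff(sc, lab, 0.05)
  expect_lte(sum(sc[lab == "control"] > clf2$score_cutoff), 1L)

  clf0 <- calibrate_score_cutoff(sc, lab, 0)
  expect_gte(clf0$score_cutoff, max(sc[lab == "control"]))
  expect_error(calibrate_score_cutoff(1:4, rep("case", 4), 0.05),
               "degenerate labels")
})

test_that("classification is strictly greater-than the score cut-off", {
  clf <- structure(list(score_cutoff = 5, target_fpr = 0.05,
                        achieved_fpr = 0.05, achieved_tpr = 0.8),
                   class = "score_classifier")
  expect_equal(classify(c(a = 6, b = 5, c = 0), clf),
               c(a = "case", b = "control", c = "control"))
  expect_length(classify(integer(0), clf), 0)
})

test_that("raising one measured value never lowers a sample's score or call", {
  ds <- sim_training(seed = 21)
  tab <- calibrate_gene_cutoffs(ds, 0.05)
  clf <- calibrate_score_cutoff(profile_score(binarize(ds, tab)),
                                ds$labels, 0.05)
  withr::local_seed(22)
  for (i in 1:25) {
    g <- sample(gene_ids(ds), 1); s <- sample(sample_ids(ds), 1)
    if (is.na(ds$values[g, s])) next
    before_score <- profile_score(binarize(ds, tab))[s]
    bumped <- ds
    bumped$values[g, s] <- bumped$values[g, s] * 2^runif(1, 0, 3)
    after_score <- profile_score(binarize(bumped, tab))[s]
    expect_gte(after_score, before_score)
    before_call <- classify(before_score, clf)
    after_call <- classify(after_score, clf)
    expect_false(before_call == "case" && after_call == "control")
  }
})

test_that("an all-missing sample scores 0 and is always called control", {
  ds <- sim_training(seed = 30, missing_rate = 0)
  ds$values[, "case_001"] <- NA
  tab <- calibrate_gene_cutoffs(ds, 0.05)
  sc <- profile_score(binarize(ds, tab))
  expect_equal(unname(sc["case_001"]), 0L)
  for (cut in c(0, 3, 8)) {
    clf <- structure(list(score_cutoff = cut, target_fpr = 0.05,
                          achieved_fpr = 0, achieved_tpr = 1),
                     class = "score_classifier")
    expect_equal(unname(classify(sc["case_001"], clf)), "control")
  }
})

test_that("classifier artifacts survive a JSON round trip", {
  ds <- sim_training(seed = 77)
  tab <- calibrate_gene_cutoffs(ds, 0.10)
  clf <- calibrate_score_cutoff(profile_score(binarize(ds, tab)),
                                ds$labels, 0.10)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_gene_cutoffs(tab, f1)
  write_score_classifier(clf, f2)
  tab2 <- read_gene_cutoffs(f1)
  clf2 <- read_score_classifier(f2)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  expect_equal(unclass(clf2), unclass(clf), ignore_attr = TRUE)
  # a frozen classifier reproduces the in-memory predictions
  sc <- profile_score(binarize(ds, tab2))
  expect_equal(classify(sc, clf2), classify(sc, clf))
})
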