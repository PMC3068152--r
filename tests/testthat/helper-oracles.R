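# Independent all-pairs Mann-Whitney AUC: P(case > control) + 0.5 P(equal),
# enumerated over every case-control pair. Direction greater_is_positive.
mw_auc <- function(scores, labels) {
  keep <- !is.na(scores)
  cs <- scores[keep & labels == "case"]
  ct <- scores[keep & labels == "control"]
  mean(outer(cs, ct, ">") + 0.5 * outer(cs, ct, "=="))
}

# Brute-force enumeration of every candidate operating point under the strict
# score > cutoff rule; independent of roc_curve()'s sweep.
enumerate_points <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  cuts <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  do.call(rbind, lapply(cuts, function(cut) {
    pos <- scores > cut
    data.frame(cutoff = cut,
               fpr = sum(pos & labels == "control") / sum(labels == "control"),
               tpr = sum(pos & labels == "case") / sum(labels == "case"))
  }))
}

# small labelled expression dataset builder
make_ds <- function(values, labels, scale = "RQ",
                    genes = sprintf("g%02d", seq_len(nrow(values))),
                    samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_dataset(values, scale = scale, labels = labels)
}

# random ROC instance with ties (integer-ish scores) and optional NAs
random_instance <- function(max_n = 30, p_na = 0) {
  n_case <- sample(1:(max_n / 2), 1)
  n_ctrl <- sample(1:(max_n / 2), 1)
  scores <- sample(1:8, n_case + n_ctrl, replace = TRUE) +
    sample(c(0, 0.5), n_case + n_ctrl, replace = TRUE)
  if (p_na > 0) scores[runif(length(scores)) < p_na] <- NA
  labels <- rep(c("case", "control"), c(n_case, n_ctrl))
  list(scores = scores, labels = labels)
}
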