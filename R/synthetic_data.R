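#' Configure a synthetic case/control qPCR panel
#'
#' Describes a case/control panel experiment under a log2-normal expression
#' model: for gene \eqn{g}, log2(RQ) of a control sample is
#' \eqn{N(\mu_g, \sigma_{0g}^2)} and of a case sample
#' \eqn{N(\mu_g + \delta_g, \sigma_{1g}^2)} -- an upward expression shift of
#' \eqn{\delta_g} log2 units in cases. Each cell is independently missing
#' (completely at random) with probability `missing_rate`. The log2-normal
#' form mirrors how RQ arises as \eqn{2^{-\Delta\Delta C_T}} of approximately
#' normal cycle-threshold differences, and makes the binormal AUC of every
#' gene available in closed form via [expected_gene_auc()].
#'
#' @param n_case,n_control sample counts (>= 1).
#' @param gene_params data frame with columns `gene`, `mu` (baseline log2-RQ
#'   mean), `delta` (case shift, log2-RQ units), `sd_case`, `sd_control`
#'   (log2-RQ standard deviations, > 0).
#' @param missing_rate per-cell missingness probability in \[0, 1).
#' @param seed integer seed; a single seed drives the whole dataset, with
#'   per-gene substreams derived from it so that appending genes to the panel
#'   never changes existing genes' draws.
#' @param scale_out `"RQ"` (values \eqn{2^{log2 value}}, strictly positive) or
#'   `"DELTA_CT"` (the negated log2 value: normalised cycle thresholds
#'   relative to a calibrator at 0, so higher expression means lower delta-Ct).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_case, n_control, gene_params,
                             missing_rate = 0, seed = 1L,
                             scale_out = c("RQ", "DELTA_CT")) {
  scale_out <- match.arg(scale_out)
  if (!is.numeric(n_case) || !is.numeric(n_control) ||
      n_case < 1 || n_control < 1)
    stop("validation error: sample counts must be >= 1")
  need <- c("gene", "mu", "delta", "sd_case", "sd_control")
  if (!is.data.frame(gene_params) || !all(need %in% names(gene_params)))
    stop("validation error: `gene_params` needs columns ",
         paste(need, collapse = ", "))
  if (any(gene_params$sd_case <= 0) || any(gene_params$sd_control <= 0))
    stop("validation error: all gene sds must be > 0")
  if (anyDuplicated(gene_params$gene))
    stop("validation error: duplicate gene id in `gene_params`")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("validation error: `missing_rate` must be in [0, 1)")
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 gene_params = gene_params,
                 missing_rate = missing_rate,
                 seed = as.integer(seed),
                 scale_out = scale_out),
            class = "synthetic_config")
}

#' A panel configuration shaped like the reference study
#'
#' 44 genes whose population (binormal) AUCs are evenly spaced over
#' 0.67-0.94 -- the span reported for the real reporter genes on the training
#' set -- with unit log2 sds in both classes, baseline means varying over the
#' panel, 56 cases and 75 controls, and 15% of cells missing at random.
#' The shifts are \eqn{\delta_g = \sqrt{2}\,\Phi^{-1}(AUC_g)}, inverting
#' [expected_gene_auc()].
#'
#' @param seed integer seed.
#' @param n_case,n_control sample counts; defaults are the study's training
#'   set sizes.
#' @param missing_rate per-cell missingness probability.
#' @return A [synthetic_config()].
#' @export
paper_like_config <- function(seed = 20110330L, n_case = 56L, n_control = 75L,
                              missing_rate = 0.15) {
  auc_targets <- seq(0.67, 0.94, length.out = 44)
  synthetic_config(
    n_case = n_case, n_control = n_control,
    gene_params = data.frame(
      gene = sprintf("g%02d", 1:44),
      mu = rep(seq(-2, 2, length.out = 11), each = 4),
      delta = sqrt(2) * stats::qnorm(auc_targets),
      sd_case = 1, sd_control = 1),
    missing_rate = missing_rate, seed = seed, scale_out = "RQ")
}

#' Simulate a panel dataset from a configuration
#'
#' Draws the log2-normal model of [synthetic_config()]: cases first
#' (`case_001`, ...), then controls (`ctrl_001`, ...). Fully reproducible
#' from the config's seed; gene \eqn{g}'s substream depends only on the seed
#' and the gene's position, never on how many genes follow it.
#'
#' @param cfg a [synthetic_config()].
#' @return An [expression_dataset()] on `cfg$scale_out` with case/control
#'   labels attached.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gp <- cfg$gene_params
  n <- cfg$n_case + cfg$n_control
  vals <- matrix(NA_real_, nrow = nrow(gp), ncol = n,
                 dimnames = list(gp$gene,
                                 c(sprintf("case_%03d", seq_len(cfg$n_case)),
                                   sprintf("ctrl_%03d", seq_len(cfg$n_control)))))
  for (g in seq_len(nrow(gp))) {
    set.seed(gene_substream_seed(cfg$seed, g))
    log2rq <- c(stats::rnorm(cfg$n_case, gp$mu[g] + gp$delta[g], gp$sd_case[g]),
                stats::rnorm(cfg$n_control, gp$mu[g], gp$sd_control[g]))
    if (cfg$missing_rate > 0)
      log2rq[stats::runif(n) < cfg$missing_rate] <- NA_real_
    vals[g, ] <- log2rq
  }
  if (cfg$scale_out == "RQ") vals <- 2^vals else vals <- -vals
  expression_dataset(vals, scale = cfg$scale_out,
                     labels = rep(c("case", "control"),
                                  c(cfg$n_case, cfg$n_control)))
}

# deterministic per-gene seed; independent of panel size so appending genes
# leaves earlier genes' draws untouched
gene_substream_seed <- function(seed, gene_index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(gene_index)) %% 2147483647)
}

#' Population AUC of a simulated gene (binormal closed form)
#'
#' Under the log2-normal model, a gene with case shift \eqn{\delta} and class
#' sds \eqn{\sigma_1, \sigma_0} has ROC AUC
#' \eqn{\Phi\!\left(\delta / \sqrt{\sigma_1^2 + \sigma_0^2}\right)}.
#' Because AUC is invariant under the monotone map to the RQ scale
#' (\eqn{2^x}), this is the population value that the empirical
#' [auc()] of a simulated gene estimates, on either scale.
#'
#' @param delta case shift in log2-RQ units.
#' @param sd_case,sd_control class standard deviations (> 0).
#' @return AUC in \[0, 1\].
#' @examples
#' expected_gene_auc(0, 1, 1)    # 0.5, uninformative
#' expected_gene_auc(2, 1, 1)    # pnorm(sqrt(2)) ~ 0.9214
#' @export
expected_gene_auc <- function(delta, sd_case, sd_control) {
  if (any(sd_case <= 0) || any(sd_control <= 0))
    stop("validation error: sds must be > 0")
  stats::pnorm(delta / sqrt(sd_case^2 + sd_control^2))
}
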