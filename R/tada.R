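#' Per-class de novo Bayes factor under a Gamma relative-risk prior
#'
#' Under the null the de novo count in a gene is Poisson(lambda0) with
#' lambda0 the expected count from the mutation model; under the alternative
#' the rate is lambda0 * gamma with gamma ~ Gamma(shape, rate). The marginal
#' alternative likelihood is negative binomial, giving the closed-form
#' Bayes factor
#' \deqn{BF = \frac{\Gamma(x+shape)}{\Gamma(shape)} rate^{shape}
#'   (rate+\lambda_0)^{-(shape+x)} e^{\lambda_0},}
#' computed in log space.
#'
#' @param x observed de novo count (vectorized).
#' @param lambda0 expected null count (positive).
#' @param shape,rate Gamma prior parameters of the relative risk (defaults:
#'   LGD prior Gamma(18, 1)).
#' @param log logical; return the log Bayes factor?
#' @return Bayes factor(s).
#' @export
bf_class <- function(x, lambda0, shape = 18, rate = 1, log = FALSE) {
  if (any(lambda0 <= 0)) stop("lambda0 must be > 0")
  stopifnot(shape > 0, rate > 0, all(x >= 0))
  lbf <- lgamma(x + shape) - lgamma(shape) + shape * log(rate) -
    (shape + x) * log(rate + lambda0) + lambda0
  if (log) lbf else exp(lbf)
}

#' Pool per-gene de novo counts and expectations across cohorts
#'
#' Counts sum across cohorts; null expectations sum after each cohort's
#' silent-variant scale factor is applied, absorbing platform differences.
#'
#' @param cohort_tables list of data.frames, each with columns \code{gene},
#'   \code{x_lgd}, \code{x_dmis}, \code{lambda0_lgd}, \code{lambda0_dmis}.
#' @param scales numeric vector of per-cohort silent calibration factors
#'   (see \code{\link{calibrate_to_silent}}); default all 1.
#' @return pooled data.frame over the union of genes.
#' @export
combine_counts <- function(cohort_tables, scales = rep(1, length(cohort_tables))) {
  stopifnot(length(cohort_tables) >= 1,
            length(scales) == length(cohort_tables))
  genes <- unique(unlist(lapply(cohort_tables, `[[`, "gene")))
  out <- data.frame(gene = genes, x_lgd = 0, x_dmis = 0,
                    lambda0_lgd = 0, lambda0_dmis = 0,
                    stringsAsFactors = FALSE)
  for (k in seq_along(cohort_tables)) {
    tab <- cohort_tables[[k]]
    i <- match(tab$gene, out$gene)
    out$x_lgd[i] <- out$x_lgd[i] + tab$x_lgd
    out$x_dmis[i] <- out$x_dmis[i] + tab$x_dmis
    out$lambda0_lgd[i] <- out$lambda0_lgd[i] + scales[k] * tab$lambda0_lgd
    out$lambda0_dmis[i] <- out$lambda0_dmis[i] + scales[k] * tab$lambda0_dmis
  }
  out
}

#' Bayesian FDR q-values from combined Bayes factors
#'
#' Converts each gene's total Bayes factor into the posterior probability of
#' the null, \code{(1-pi) / ((1-pi) + pi * BF)}, ranks genes by decreasing
#' BF and assigns the q-value at rank k as the mean posterior-null
#' probability of the top k genes; tied Bayes factors share the worst
#' q-value of their block.
#'
#' @param results data.frame with columns \code{gene} and \code{bf_total}.
#' @param pi prior fraction of risk genes (default 0.05).
#' @return \code{results} with \code{posterior_null} and \code{q_value}
#'   columns, sorted by decreasing \code{bf_total} (ties broken by gene id).
#' @export
tada_qvalues <- function(results, pi = 0.05) {
  stopifnot(pi > 0, pi < 1)
  results$posterior_null <- (1 - pi) / ((1 - pi) + pi * results$bf_total)
  o <- order(-results$bf_total, results$gene)
  results <- results[o, , drop = FALSE]
  q <- cumsum(results$posterior_null) / seq_len(nrow(results))
  results$q_value <- stats::ave(q, results$bf_total, FUN = max)
  rownames(results) <- NULL
  results
}

#' De novo TADA analysis over a per-gene count table
#'
#' Computes LGD and damaging-missense Bayes factors under Gamma relative-risk
#' priors, multiplies them into a total per-gene Bayes factor, and converts
#' to Bayesian FDR q-values. Genes with a zero null expectation in a class
#' contribute a class BF of 1 (no information) when their count is also
#' zero, and are excluded with a message otherwise.
#'
#' @param counts data.frame with columns \code{gene}, \code{x_lgd},
#'   \code{x_dmis}, \code{lambda0_lgd}, \code{lambda0_dmis}.
#' @param pi prior fraction of risk genes.
#' @param lgd_prior,dmis_prior length-2 numeric vectors (shape, rate) of the
#'   Gamma relative-risk priors.
#' @return ranked data.frame with per-class and total Bayes factors,
#'   posterior null probabilities and q-values.
#' @export
tada_test <- function(counts, pi = 0.05, lgd_prior = c(18, 1),
                      dmis_prior = c(6, 1)) {
  usable <- (counts$lambda0_lgd > 0 | counts$x_lgd == 0) &
    (counts$lambda0_dmis > 0 | counts$x_dmis == 0)
  if (any(!usable)) {
    message(sum(!usable),
            " gene(s) with observed counts but zero mutation rate excluded")
    counts <- counts[usable, , drop = FALSE]
  }
  bf_l <- ifelse(counts$lambda0_lgd > 0,
                 bf_class(counts$x_lgd, pmax(counts$lambda0_lgd, 1e-300),
                          lgd_prior[1], lgd_prior[2]), 1)
  bf_d <- ifelse(counts$lambda0_dmis > 0,
                 bf_class(counts$x_dmis, pmax(counts$lambda0_dmis, 1e-300),
                          dmis_prior[1], dmis_prior[2]), 1)
  res <- data.frame(gene = counts$gene,
                    x_lgd = counts$x_lgd, x_dmis = counts$x_dmis,
                    lambda0_lgd = counts$lambda0_lgd,
                    lambda0_dmis = counts$lambda0_dmis,
                    bf_lgd = bf_l, bf_dmis = bf_d,
                    bf_total = bf_l * bf_d, stringsAsFactors = FALSE)
  tada_qvalues(res, pi)
}

#' Simulation-based discovery power at FDR thresholds
#'
#' Simulates cohorts under the assumed genetic architecture (a fraction
#' \code{pi} of genes carry Gamma-distributed relative risks), runs the TADA
#' analysis on each replicate, and reports the mean and SD of the number of
#' genes passing each FDR threshold.
#'
#' @param rates mutation-rate table.
#' @param n_trios cohort size.
#' @param pi prior risk-gene fraction.
#' @param lgd_prior,dmis_prior Gamma priors (shape, rate).
#' @param dmis_fraction damaging fraction of the missense rate.
#' @param q_thresholds FDR thresholds to report.
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @return data.frame: threshold, mean_discoveries, sd_discoveries,
#'   mean_true_discoveries.
#' @export
discovery_power_sim <- function(rates, n_trios, pi = 0.05,
                                lgd_prior = c(18, 1), dmis_prior = c(6, 1),
                                dmis_fraction = 0.436,
                                q_thresholds = c(0.1, 0.2),
                                n_reps = 10L, seed = 1L) {
  set.seed(seed)
  n_g <- nrow(rates)
  lam_l <- 2 * n_trios * (rates$mu_non + rates$mu_splice + rates$mu_frameshift)
  lam_d <- 2 * n_trios * dmis_fraction * rates$mu_mis
  disc <- matrix(0, n_reps, length(q_thresholds))
  true_disc <- matrix(0, n_reps, length(q_thresholds))
  for (r in seq_len(n_reps)) {
    risk <- stats::runif(n_g) < pi
    g_l <- ifelse(risk, stats::rgamma(n_g, lgd_prior[1], lgd_prior[2]), 1)
    g_d <- ifelse(risk, stats::rgamma(n_g, dmis_prior[1], dmis_prior[2]), 1)
    counts <- data.frame(gene = rates$gene,
                         x_lgd = stats::rpois(n_g, lam_l * g_l),
                         x_dmis = stats::rpois(n_g, lam_d * g_d),
                         lambda0_lgd = lam_l, lambda0_dmis = lam_d)
    res <- tada_test(counts, pi, lgd_prior, dmis_prior)
    res$risk <- risk[match(res$gene, rates$gene)]
    for (j in seq_along(q_thresholds)) {
      hit <- res$q_value <= q_thresholds[j]
      disc[r, j] <- sum(hit)
      true_disc[r, j] <- sum(hit & res$risk)
    }
  }
  data.frame(threshold = q_thresholds,
             mean_discoveries = colMeans(disc),
             sd_discoveries = apply(disc, 2, stats::sd),
             mean_true_discoveries = colMeans(true_disc))
}
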