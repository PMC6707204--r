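#' Preprocessing filters for candidate mosaic sites
#'
#' Conservative filters applied before overdispersion estimation and mixture
#' modelling: population allele frequency at most 1e-4; no
#' mappability/segmental-duplication/low-complexity flags; not in MUC or HLA
#' genes; site depth at most 500; no strand bias (see
#' \code{\link{strand_bias_flag}}); cohort frequency at most 1\%; samples with
#' more than 7 de novo SNVs removed; clustered (complex) de novo SNVs within
#' 10 bp of each other in one sample removed.
#'
#' @param sites data.frame with columns \code{site_id}, \code{sample_id},
#'   \code{gene}, \code{chrom}, \code{pos}, \code{dp}, \code{pop_af},
#'   \code{cohort_ac}, \code{flags} (comma-separated region flags),
#'   \code{adf_ref}, \code{adr_ref}, \code{adf_alt}, \code{adr_alt}.
#' @param max_af population allele-frequency ceiling.
#' @param depth_cap maximum site depth.
#' @param max_cohort_freq cohort carrier-frequency ceiling.
#' @param n_cohort cohort size used for the frequency filter.
#' @param max_dn_per_sample outlier-sample de novo SNV cutoff.
#' @param cluster_bp window for the complex-variant (clustered SNV) filter.
#' @return list: \code{retained} (filtered data.frame) and \code{tally}
#'   (named integer vector of removals per filter).
#' @export
cumc_prefilter <- function(sites, max_af = 1e-4, depth_cap = 500L,
                           max_cohort_freq = 0.01, n_cohort = 465L,
                           max_dn_per_sample = 7L, cluster_bp = 10L) {
  tally <- c(pop_af = 0L, region = 0L, muc_hla = 0L, depth_cap = 0L,
             strand_bias = 0L, cohort_freq = 0L, outlier_sample = 0L,
             complex_cluster = 0L)
  drop <- rep(FALSE, nrow(sites))
  mark <- function(bad, reason) {
    bad <- bad & !drop
    tally[reason] <<- tally[reason] + sum(bad)
    drop <<- drop | bad
  }
  mark(sites$pop_af > max_af, "pop_af")
  region <- grepl("segdup|low_mappability|lcr", sites$flags)
  mark(region, "region")
  mark(grepl("^(MUC|HLA)", sites$gene) | grepl("muc_hla", sites$flags),
       "muc_hla")
  mark(sites$dp > depth_cap, "depth_cap")
  sb <- strand_bias_flag(sites$adf_ref, sites$adr_ref,
                         sites$adf_alt, sites$adr_alt)
  mark(sb, "strand_bias")
  mark(sites$cohort_ac / n_cohort > max_cohort_freq, "cohort_freq")
  dn_per_sample <- table(sites$sample_id)
  bad_samples <- names(dn_per_sample)[dn_per_sample > max_dn_per_sample]
  mark(sites$sample_id %in% bad_samples, "outlier_sample")
  # complex clusters: any two de novo SNVs within cluster_bp in one sample
  key <- paste(sites$sample_id, sites$chrom)
  cluster <- rep(FALSE, nrow(sites))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    pos <- sites$pos[idx]
    o <- order(pos)
    close_next <- c(diff(pos[o]) <= cluster_bp, FALSE)
    close_prev <- c(FALSE, diff(pos[o]) <= cluster_bp)
    cluster[idx[o]] <- close_next | close_prev
  }
  mark(cluster, "complex_cluster")
  list(retained = sites[!drop, , drop = FALSE], tally = tally)
}

#' Strand-bias flag
#'
#' A site is flagged if (a) it has zero alt reads on either strand, or
#' (b) Fisher's exact test on the 2x2 strand-by-allele table gives
#' p < 1e-3 with a cross-product odds ratio below 1/3 or above 3.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev per-strand reference and alternate
#'   read counts (vectorized).
#' @param p_cut Fisher p-value threshold.
#' @param or_low,or_high odds-ratio limits.
#' @return logical vector; TRUE = strand-biased.
#' @export
strand_bias_flag <- function(ref_fwd, ref_rev, alt_fwd, alt_rev,
                             p_cut = 1e-3, or_low = 1 / 3, or_high = 3) {
  n <- max(length(ref_fwd), length(ref_rev), length(alt_fwd), length(alt_rev))
  ref_fwd <- rep_len(ref_fwd, n); ref_rev <- rep_len(ref_rev, n)
  alt_fwd <- rep_len(alt_fwd, n); alt_rev <- rep_len(alt_rev, n)
  out <- alt_fwd == 0 | alt_rev == 0
  todo <- which(!out)
  for (i in todo) {
    tab <- matrix(c(ref_fwd[i], ref_rev[i], alt_fwd[i], alt_rev[i]), 2L, 2L)
    p <- stats::fisher.test(tab)$p.value
    or <- (ref_fwd[i] * alt_rev[i]) / (ref_rev[i] * alt_fwd[i])
    out[i] <- p < p_cut && (or < or_low || or > or_high)
  }
  out
}

#' Two-sided binomial deviation from heterozygosity (PHET)
#'
#' Exact two-sided binomial probability that the alt-read count is consistent
#' with a germline heterozygote (success probability 0.5). At p = 0.5 the
#' minimum-likelihood two-sided p equals twice the smaller tail.
#'
#' @param n_alt alt read counts (vectorized).
#' @param n site depths.
#' @return p-values in [0, 1].
#' @export
phet <- function(n_alt, n) {
  stopifnot(all(n_alt >= 0), all(n_alt <= n))
  m <- pmin(n_alt, n - n_alt)
  pmin(1, ifelse(2 * m == n, 1, 2 * stats::pbinom(m, n, 0.5)))
}

#' Upper bound of the Clopper-Pearson VAF confidence interval
#'
#' Upper limit of the two-sided exact (Clopper-Pearson) confidence interval
#' for the allele fraction at the given level; with \code{level = 0.90} this
#' places 0.05 in each tail, so the bound is \code{qbeta(0.95, k+1, N-k)}.
#'
#' @param n_alt alt read counts (vectorized).
#' @param n site depths.
#' @param level two-sided confidence level.
#' @return upper confidence bounds in [0, 1].
#' @export
vaf_ci_upper <- function(n_alt, n, level = 0.90) {
  stopifnot(all(n_alt >= 0), all(n_alt <= n))
  a <- (1 - level) / 2
  ifelse(n_alt == n, 1, stats::qbeta(1 - a, n_alt + 1, n - n_alt))
}

#' Filter/binomial-deviation mosaic classification
#'
#' The filter-based branch: a site is a usable de novo candidate only if the
#' parental alt-read count is at most 4, it has at least 5 alt reads,
#' population frequency at most 0.5\%, cohort allele count at most 1, read
#' mismatch support at most 3, and no segmental-duplication/repeat flag. A
#' candidate is labelled mosaic iff its two-sided deviation from
#' heterozygosity (\code{\link{phet}}) is at most 1e-3 AND the upper 90\%
#' Clopper-Pearson bound on the allele fraction is below 0.4. An externally
#' trained classifier score can optionally gate the call.
#'
#' @param sites data.frame with columns \code{site_id}, \code{dp},
#'   \code{ad_alt}, \code{parental_alt}, \code{pop_af}, \code{cohort_ac},
#'   \code{mismatch_support}, \code{flags}.
#' @param min_alt_reads,max_parental_alt,max_pop_af,max_cohort_ac,max_mismatch
#'   filter thresholds.
#' @param phet_max PHET mosaic threshold.
#' @param ci_max upper-CI mosaic threshold (strict).
#' @param ci_filter_max optional candidate-level ceiling on the upper CI
#'   bound (disabled by default; ambiguous in its source).
#' @param scores optional externally computed classifier scores per site.
#' @param score_min threshold applied to \code{scores} when supplied.
#' @return data.frame: \code{site_id}, \code{candidate}, \code{phet},
#'   \code{ci90_upper}, \code{label} (\code{"mosaic"}, \code{"germline"} or
#'   \code{"filtered"}).
#' @export
ohsu_classify <- function(sites, min_alt_reads = 5L, max_parental_alt = 4L,
                          max_pop_af = 0.005, max_cohort_ac = 1L,
                          max_mismatch = 3L, phet_max = 1e-3, ci_max = 0.4,
                          ci_filter_max = NULL,
                          scores = NULL, score_min = 0.518) {
  de_novo <- sites$parental_alt <= max_parental_alt
  candidate <- de_novo &
    sites$ad_alt >= min_alt_reads &
    sites$pop_af <= max_pop_af &
    sites$cohort_ac <= max_cohort_ac &
    sites$mismatch_support <= max_mismatch &
    !grepl("segdup|repeat", sites$flags)
  p <- phet(sites$ad_alt, sites$dp)
  ci <- vaf_ci_upper(sites$ad_alt, sites$dp, 0.90)
  if (!is.null(ci_filter_max)) candidate <- candidate & ci <= ci_filter_max
  mosaic <- candidate & p <= phet_max & ci < ci_max
  if (!is.null(scores)) mosaic <- mosaic & scores >= score_min
  data.frame(site_id = sites$site_id, candidate = candidate,
             phet = p, ci90_upper = ci,
             label = ifelse(!candidate, "filtered",
                            ifelse(mosaic, "mosaic", "germline")),
             stringsAsFactors = FALSE)
}

#' Estimate beta-binomial overdispersion from germline heterozygous sites
#'
#' Bins variants by site depth (N in 1-500), computes a maximum-likelihood
#' overdispersion estimate per bin by bounded one-dimensional optimization of
#' the beta-binomial likelihood with the mean fixed at \code{germline_mean},
#' and returns a global estimate as the variant-count-weighted mean over
#' bins. Bins with fewer than \code{min_bin_n} variants are merged into their
#' neighbours before estimation.
#'
#' @param dp site depths.
#' @param ad_alt alt read counts.
#' @param germline_mean fixed mean VAF of the germline component.
#' @param bin_width depth-bin width.
#' @param min_bin_n minimum variants per bin.
#' @param depth_cap maximum usable depth.
#' @return list: \code{theta_hat} (global overdispersion),
#'   \code{theta_per_bin} (data.frame: bin, theta, n), \code{germline_mean}.
#' @export
estimate_theta <- function(dp, ad_alt, germline_mean = 0.5, bin_width = 10L,
                           min_bin_n = 50L, depth_cap = 500L) {
  keep <- dp >= 1 & dp <= depth_cap
  dp <- dp[keep]; ad_alt <- ad_alt[keep]
  if (length(dp) < 2L) stop("no usable sites for overdispersion estimation")
  bin <- pmin((dp - 1L) %/% bin_width, (depth_cap - 1L) %/% bin_width)
  # merge sparse bins into their nearest nonsparse neighbour
  counts <- table(bin)
  labs <- as.integer(names(counts))
  big <- labs[counts >= min_bin_n]
  if (length(big) == 0L) big <- labs[which.max(counts)]
  remap <- big[pmax(1L, findInterval(labs, big))]
  # snap to the closer of the two flanking big bins
  for (j in seq_along(labs)) {
    k <- findInterval(labs[j], big)
    lo <- big[max(k, 1L)]; hi <- big[min(k + 1L, length(big))]
    remap[j] <- if (abs(labs[j] - lo) <= abs(hi - labs[j])) lo else hi
  }
  bin <- remap[match(bin, labs)]
  fit_one <- function(idx) {
    nll <- function(rho) -sum(dbetabinom(ad_alt[idx], dp[idx],
                                         germline_mean, rho, log = TRUE))
    stats::optimize(nll, c(0, 0.99))$minimum
  }
  bins <- sort(unique(bin))
  theta <- vapply(bins, function(b) fit_one(bin == b), numeric(1))
  nb <- vapply(bins, function(b) sum(bin == b), numeric(1))
  # optimize() cannot return exactly 0; collapse near-boundary estimates
  theta[theta < 1e-4] <- 0
  list(theta_hat = sum(theta * nb) / sum(nb),
       theta_per_bin = data.frame(bin = bins, theta = theta, n = nb),
       germline_mean = germline_mean)
}

#' Empirical-Bayes EM mixture for the mosaic fraction and per-site calls
#'
#' Models each apparent de novo site's alt-read count as a two-component
#' beta-binomial mixture: a germline component centred at
#' \code{germline_mean} and a mosaic component whose marginal likelihood
#' averages the beta-binomial over a uniform grid of candidate mosaic allele
#' fractions. EM jointly estimates the mosaic fraction (the mixture weight)
#' and per-site responsibilities; posterior odds and cumulative Bayesian FDR
#' q-values follow.
#'
#' @param sites data.frame with columns \code{site_id}, \code{dp},
#'   \code{ad_alt}.
#' @param theta_hat beta-binomial overdispersion (from
#'   \code{\link{estimate_theta}}).
#' @param germline_mean germline component mean VAF.
#' @param vaf_grid grid of mosaic allele fractions; default 50 uniform points
#'   on (0.01, 0.50].
#' @param pi_init initial mosaic fraction.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with \code{converged = FALSE}.
#' @param fdr_max per-site q-value threshold for a high-confidence mosaic
#'   label; sites with posterior odds above 1 but q above this threshold are
#'   low-confidence and labelled germline (they can still be rescued by the
#'   other branch, see \code{\link{union_mosaic_callset}}).
#' @return list: \code{pi_m}, \code{calls} (data.frame with
#'   \code{responsibility}, \code{posterior_odds}, \code{q_value},
#'   \code{label}), \code{loglik} (trace), \code{converged}.
#' @export
em_mosaic <- function(sites, theta_hat, germline_mean = 0.5,
                      vaf_grid = seq(0.01, 0.50, length.out = 50),
                      pi_init = 0.05, tol = 1e-8, max_iter = 1000L,
                      fdr_max = 0.1) {
  stopifnot(nrow(sites) >= 1, theta_hat >= 0, theta_hat < 1)
  n <- nrow(sites)
  lg <- dbetabinom(sites$ad_alt, sites$dp, germline_mean, theta_hat,
                   log = TRUE)
  lm_mat <- vapply(vaf_grid,
                   function(f) dbetabinom(sites$ad_alt, sites$dp, f,
                                          theta_hat, log = TRUE),
                   numeric(n))
  if (n == 1L) lm_mat <- matrix(lm_mat, nrow = 1L)
  lmos <- .log_mean_exp_rows(lm_mat)
  pi_m <- pi_init
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a <- log(pi_m) + lmos
    b <- log1p(-pi_m) + lg
    mx <- pmax(a, b)
    ll_i <- mx + log(exp(a - mx) + exp(b - mx))
    r <- exp(a - ll_i)
    ll <- sum(ll_i)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi_m <- mean(r)
    pi_m <- min(max(pi_m, 1e-12), 1 - 1e-12)
  }
  odds <- exp(log(pi_m) + lmos - log1p(-pi_m) - lg)
  # Bayesian FDR: expected false-mosaic fraction among sites called at or
  # above each site's posterior odds
  o <- order(odds, decreasing = TRUE)
  q_sorted <- cumsum(1 - r[o]) / seq_len(n)
  # ties share the worst q of their block
  q <- numeric(n)
  q[o] <- q_sorted
  q <- stats::ave(q, odds, FUN = max)
  calls <- data.frame(site_id = sites$site_id,
                      responsibility = r,
                      posterior_odds = odds,
                      q_value = q,
                      label = ifelse(odds > 1 & q <= fdr_max,
                                     "mosaic", "germline"),
                      stringsAsFactors = FALSE)
  list(pi_m = pi_m, calls = calls, loglik = ll_trace, converged = converged)
}

#' Union of the two mosaic call branches
#'
#' Combines the filter/binomial-deviation branch and the EM branch: sites
#' called mosaic by both are retained; sites called mosaic only by the EM
#' branch are retained; sites called mosaic by the filter branch but germline
#' by the EM branch are retained only when their posterior odds exceed 1.
#' Branch provenance is recorded.
#'
#' @param ohsu_calls output of \code{\link{ohsu_classify}}.
#' @param cumc_calls \code{calls} element of \code{\link{em_mosaic}}.
#' @return data.frame of retained mosaic sites with \code{branch} flags
#'   (comma-separated subset of \code{"ohsu"}, \code{"cumc"}) and
#'   \code{posterior_odds}.
#' @export
union_mosaic_callset <- function(ohsu_calls, cumc_calls) {
  m <- merge(ohsu_calls[, c("site_id", "label")],
             cumc_calls[, c("site_id", "label", "posterior_odds")],
             by = "site_id", suffixes = c("_ohsu", "_cumc"), all = TRUE)
  m$label_ohsu[is.na(m$label_ohsu)] <- "filtered"
  m$label_cumc[is.na(m$label_cumc)] <- "germline"
  m$posterior_odds[is.na(m$posterior_odds)] <- 0
  ohsu_m <- m$label_ohsu == "mosaic"
  cumc_m <- m$label_cumc == "mosaic"
  keep <- cumc_m | (ohsu_m & m$posterior_odds > 1)
  out <- m[keep, , drop = FALSE]
  out$branch <- paste0(ifelse(ohsu_m[keep], "ohsu", ""),
                       ifelse(ohsu_m[keep] & cumc_m[keep], ",", ""),
                       ifelse(cumc_m[keep], "cumc", ""))
  out[, c("site_id", "branch", "posterior_odds")]
}
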