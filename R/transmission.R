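#' Genotype-level quality control
#'
#' Sets genotype calls to missing unless read depth >= 10, GQ >= 30, and the
#' allele balance lies in the class-appropriate window: < 0.1 for
#' homozygous-reference, > 0.9 for homozygous-alternate, [0.3, 0.7] for
#' heterozygous SNVs and [0.25, 0.75] for heterozygous indels (all windows
#' treated as closed at their stated endpoints).
#'
#' @param depth read depth (vectorized).
#' @param gq genotype quality.
#' @param ab allele balance (alt fraction).
#' @param call genotype call: \code{"hom-ref"}, \code{"het"},
#'   \code{"hom-alt"} or \code{"missing"}.
#' @param var_type \code{"SNV"} or \code{"indel"}.
#' @return character vector of calls with failures set to \code{"missing"}.
#' @export
genotype_qc <- function(depth, gq, ab, call, var_type) {
  n <- max(length(depth), length(gq), length(ab), length(call),
           length(var_type))
  depth <- rep_len(depth, n); gq <- rep_len(gq, n); ab <- rep_len(ab, n)
  call <- rep_len(call, n); var_type <- rep_len(var_type, n)
  lo <- ifelse(var_type == "indel", 0.25, 0.3)
  hi <- ifelse(var_type == "indel", 0.75, 0.7)
  ok <- depth >= 10 & gq >= 30 &
    ((call == "hom-ref" & ab < 0.1) |
       (call == "hom-alt" & ab > 0.9) |
       (call == "het" & ab >= lo & ab <= hi))
  ifelse(ok, call, "missing")
}

#' Site-level founder missingness filter
#'
#' Drops sites whose founder genotypes are missing in strictly more than 25\%
#' of founders.
#'
#' @param missing_fraction per-site fraction of founders with missing calls.
#' @param max_missing missingness ceiling (kept if fraction <= ceiling).
#' @return logical vector; TRUE = site retained.
#' @export
site_missingness_filter <- function(missing_fraction, max_missing = 0.25) {
  missing_fraction <= max_missing
}

#' Calibrate a VQSLOD threshold to 50\% transmission of neutral singletons
#'
#' Neutral founder singletons (synonymous SNVs, nonframeshift indels) should
#' be transmitted to offspring half the time; call artifacts depress the
#' apparent transmission rate. This scans thresholds over the observed VQSLOD
#' values (descending) and returns the smallest threshold t such that among
#' singletons with VQSLOD >= t the transmitted fraction is within one
#' binomial standard error of 0.5 — i.e. the calibrated cutoff retaining the
#' most variants. SNVs and indels should be calibrated separately.
#'
#' @param vqslod numeric scores of neutral singletons.
#' @param transmitted logical transmission status, same length.
#' @param band_se half-width of the acceptance band in binomial SE units.
#' @return list: \code{threshold}, \code{fraction} (achieved transmitted
#'   fraction), \code{n_retained}, \code{warning} (TRUE if no threshold
#'   reached the band and the closest-to-0.5 threshold was returned).
#' @export
calibrate_vqslod <- function(vqslod, transmitted, band_se = 1) {
  stopifnot(length(vqslod) == length(transmitted))
  if (!any(transmitted) || all(transmitted))
    stop("need at least one transmitted and one untransmitted singleton")
  o <- order(vqslod, decreasing = TRUE)
  tx <- cumsum(transmitted[o])
  n <- seq_along(o)
  frac <- tx / n
  se <- sqrt(0.25 / n)
  thr <- vqslod[o]
  # one candidate threshold per distinct score: the full set of sites >= t
  last_of_score <- !duplicated(thr, fromLast = TRUE)
  ok <- abs(frac - 0.5) <= band_se * se & last_of_score
  if (any(ok)) {
    i <- max(which(ok))  # lowest qualifying threshold = most retained
    list(threshold = thr[i], fraction = frac[i], n_retained = n[i],
         warning = FALSE)
  } else {
    cand <- which(last_of_score)
    i <- cand[which.min(abs(frac[cand] - 0.5))]
    warning("no VQSLOD threshold reaches the 50% transmission band; ",
            "returning closest")
    list(threshold = thr[i], fraction = frac[i], n_retained = n[i],
         warning = TRUE)
  }
}

#' Exact binomial transmission-disequilibrium test
#'
#' Rate ratio and two-sided exact binomial p-value for transmitted vs
#' untransmitted counts against the null transmission probability 0.5. The
#' two-sided p sums all outcomes with probability at most that of the
#' observed outcome (the minimum-likelihood convention of
#' \code{\link[stats]{binom.test}}).
#'
#' @param transmitted,untransmitted non-negative counts (at least one > 0).
#' @return list: \code{rate_ratio} (transmitted/untransmitted) and
#'   \code{p_value}.
#' @export
transmission_test <- function(transmitted, untransmitted) {
  if (transmitted + untransmitted < 1) stop("both counts are zero")
  list(rate_ratio = transmitted / untransmitted,
       p_value = stats::binom.test(transmitted,
                                   transmitted + untransmitted,
                                   p = 0.5)$p.value)
}

#' High-confidence loss-of-function transcript filter
#'
#' Retains LGD singletons only when the high-confidence LoF annotation covers
#' strictly more than 60\% of transcripts; non-LGD classes pass unchanged.
#'
#' @param singletons data.frame with columns \code{class} and
#'   \code{hc_transcript_fraction}.
#' @param min_fraction threshold (strict inequality).
#' @return filtered data.frame.
#' @export
hc_lof_filter <- function(singletons, min_fraction = 0.6) {
  is_lgd <- singletons$class %in% .lgd_classes
  keep <- !is_lgd |
    (!is.na(singletons$hc_transcript_fraction) &
       singletons$hc_transcript_fraction > min_fraction)
  singletons[keep, , drop = FALSE]
}
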