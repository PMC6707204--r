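#' Cohort specification for expected-count scaling
#'
#' @param n_female,n_male numbers of female and male probands.
#' @return list of class \code{"cohort_spec"} with \code{n_trios},
#'   \code{n_female}, \code{n_male}.
#' @export
cohort_spec <- function(n_female, n_male) {
  stopifnot(n_female >= 0, n_male >= 0)
  structure(list(n_trios = n_female + n_male,
                 n_female = n_female, n_male = n_male),
            class = "cohort_spec")
}

# allele multiplier per gene: 2 per trio on autosomes; on chrX each female
# proband carries two at-risk alleles and each male one
.allele_count <- function(chrom, cohort) {
  ifelse(chrom == "X", 2 * cohort$n_female + cohort$n_male,
         2 * cohort$n_trios)
}

.class_mu <- function(rates, class) {
  col <- switch(class,
                synonymous = "mu_syn", missense = "mu_mis",
                nonsense = "mu_non", splice = "mu_splice",
                frameshift = "mu_frameshift",
                lgd = NA_character_,
                stop("unknown variant class: ", class))
  if (class == "lgd") rates$mu_non + rates$mu_splice + rates$mu_frameshift
  else rates[[col]]
}

#' Expected de novo count for a gene set
#'
#' Sums per-gene class rates over a gene set, multiplied by twice the number
#' of probands; genes on chromosome X are scaled by the at-risk allele count
#' \code{2 * n_female + n_male} instead.
#'
#' @param rates mutation-rate table (see \code{\link{gen_gene_table}} or
#'   \code{\link{read_rate_table}}).
#' @param class one of \code{"synonymous"}, \code{"missense"},
#'   \code{"nonsense"}, \code{"splice"}, \code{"frameshift"}, or the
#'   aggregate \code{"lgd"}.
#' @param gene_set character vector of gene ids (must exist in \code{rates});
#'   \code{NULL} means all genes.
#' @param cohort a \code{\link{cohort_spec}}.
#' @return expected count (non-negative scalar).
#' @export
expected_count <- function(rates, class, gene_set = NULL, cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!is.null(gene_set)) {
    if (length(gene_set) == 0L) return(0)
    missing <- setdiff(gene_set, rates$gene)
    if (length(missing))
      stop("unknown gene id(s): ", paste(utils::head(missing, 5),
                                         collapse = ", "))
    rates <- rates[rates$gene %in% gene_set, , drop = FALSE]
  }
  mu <- .class_mu(rates, class)
  sum(.allele_count(rates$chrom, cohort) * mu)
}

#' Calibrate mutation rates to the observed silent count
#'
#' Rescales every per-gene, per-class rate by a single factor
#' \code{s = observed_silent / expected_silent} so that the exome-wide
#' expected number of synonymous de novo variants matches the observed count.
#' Used to absorb platform differences before burden testing or cross-cohort
#' meta-analysis.
#'
#' @param rates mutation-rate table.
#' @param observed_silent observed synonymous de novo count.
#' @param cohort a \code{\link{cohort_spec}}.
#' @return list: \code{scale} (the factor s) and \code{rates} (rescaled table).
#' @export
calibrate_to_silent <- function(rates, observed_silent, cohort) {
  exp_silent <- expected_count(rates, "synonymous", NULL, cohort)
  if (exp_silent <= 0) stop("expected silent count is zero; cannot calibrate")
  s <- observed_silent / exp_silent
  out <- rates
  for (col in c("mu_syn", "mu_mis", "mu_non", "mu_splice", "mu_frameshift"))
    out[[col]] <- out[[col]] * s
  list(scale = s, rates = out)
}

#' One-sided exact Poisson upper-tail test
#'
#' Returns \eqn{P(X \ge observed)} for \eqn{X \sim Poisson(expected)},
#' computed as an exact tail sum (via the regularized incomplete gamma
#' function underlying \code{ppois}). \code{observed = 0} returns exactly 1.
#'
#' @param observed observed count (non-negative integer, vectorized).
#' @param expected expected count under the null (positive, vectorized).
#' @return upper-tail probability in [0, 1].
#' @export
poisson_upper_test <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be > 0")
  if (any(observed < 0)) stop("observed must be >= 0")
  ifelse(observed == 0, 1,
         stats::ppois(observed - 1, expected, lower.tail = FALSE))
}

#' De novo burden table over classes, gene sets and sex strata
#'
#' For each variant class (de novo LGD, damaging missense by CADD or MPC,
#' synonymous) and each gene set (all genes, constrained pLI >= 0.5,
#' unconstrained), computes the observed count, the model-expected count,
#' the fold enrichment and the one-sided exact Poisson p-value; per-proband
#' rates are also reported for female and male probands separately.
#'
#' @param variants data.frame of de novo variants with columns \code{gene},
#'   \code{class}, \code{cadd}, \code{mpc}, \code{sex} (proband sex).
#' @param rates mutation-rate table with \code{pli} column.
#' @param cohort a \code{\link{cohort_spec}}.
#' @param cadd_dmis,mpc_dmis damaging-missense thresholds.
#' @param pli_constrained constrained-gene pLI threshold.
#' @return data.frame with one row per class x gene-set stratum: columns
#'   \code{class}, \code{gene_set}, \code{observed}, \code{expected},
#'   \code{fold}, \code{p_value}, \code{rate_female}, \code{rate_male}.
#' @export
burden_table <- function(variants, rates, cohort,
                         cadd_dmis = 25, mpc_dmis = 2,
                         pli_constrained = 0.5) {
  stopifnot(inherits(cohort, "cohort_spec"))
  sets <- list(all = rates$gene,
               constrained = rates$gene[rates$pli >= pli_constrained],
               unconstrained = rates$gene[rates$pli < pli_constrained])
  is_lgd <- variants$class %in% .lgd_classes
  is_dmis_cadd <- variants$class == "missense" & variants$cadd >= cadd_dmis
  is_dmis_mpc <- variants$class == "missense" & variants$mpc >= mpc_dmis
  picks <- list(dnLGD = is_lgd,
                `dmis_cadd` = is_dmis_cadd,
                `dmis_mpc` = is_dmis_mpc,
                synonymous = variants$class == "synonymous")
  # expected D-mis counts use the damaging fraction of the missense rate;
  # with rate tables carrying only class totals we scale the missense
  # expectation by the observed damaging fraction among missense variants
  n_mis <- sum(variants$class == "missense")
  frac_cadd <- if (n_mis > 0) sum(is_dmis_cadd) / n_mis else 0
  frac_mpc <- if (n_mis > 0) sum(is_dmis_mpc) / n_mis else 0
  out <- list()
  for (cl in names(picks)) {
    for (gs in names(sets)) {
      sel <- picks[[cl]] & variants$gene %in% sets[[gs]]
      obs <- sum(sel)
      exp_cl <- switch(cl,
                       dnLGD = expected_count(rates, "lgd", sets[[gs]], cohort),
                       dmis_cadd = frac_cadd *
                         expected_count(rates, "missense", sets[[gs]], cohort),
                       dmis_mpc = frac_mpc *
                         expected_count(rates, "missense", sets[[gs]], cohort),
                       synonymous = expected_count(rates, "synonymous",
                                                   sets[[gs]], cohort))
      nf <- max(cohort$n_female, 1L)
      nm <- max(cohort$n_male, 1L)
      out[[length(out) + 1L]] <- data.frame(
        class = cl, gene_set = gs, observed = obs, expected = exp_cl,
        fold = if (exp_cl > 0) obs / exp_cl else NA_real_,
        p_value = if (exp_cl > 0) poisson_upper_test(obs, exp_cl) else 1,
        rate_female = sum(sel & variants$sex == "F") / nf,
        rate_male = sum(sel & variants$sex == "M") / nm,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read a gene-level mutation-rate table from TSV
#'
#' Expects the header \code{gene chrom mu_syn mu_mis mu_non mu_splice
#' mu_frameshift cds_len gc pli}.
#'
#' @param path file path.
#' @return data.frame rate table.
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "mu_syn", "mu_mis", "mu_non", "mu_splice",
            "mu_frameshift", "cds_len", "gc", "pli")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("rate table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}
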