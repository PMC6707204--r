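#' Expression-level gene filter
#'
#' Drops genes whose RPKM falls below 1 in at least 20\% of samples (the
#' boundary is inclusive: exactly 20\% low samples drops the gene).
#'
#' @param rpkm genes x samples matrix of RPKM values.
#' @param min_rpkm expression floor.
#' @param max_low_fraction maximum tolerated fraction of low samples
#'   (strictly below this fraction is kept).
#' @return character vector of retained gene names.
#' @export
expression_filter <- function(rpkm, min_rpkm = 1, max_low_fraction = 0.2) {
  if (is.null(dim(rpkm)) || nrow(rpkm) == 0L || ncol(rpkm) == 0L)
    stop("empty expression matrix")
  low <- rowMeans(rpkm < min_rpkm)
  rownames(rpkm)[low < max_low_fraction]
}

#' Per-gene layer specificity t-statistics
#'
#' Welch (unequal-variance) two-sample t-statistic per gene comparing
#' log2(RPKM + 1) in the samples of one layer against all other samples.
#'
#' @param rpkm genes x samples matrix.
#' @param labels per-sample layer labels.
#' @param layer the layer tested against the rest.
#' @param log_transform apply log2(x + 1) first?
#' @return named numeric vector of t-statistics.
#' @export
layer_tstat <- function(rpkm, labels, layer, log_transform = TRUE) {
  stopifnot(ncol(rpkm) == length(labels))
  g1 <- labels == layer
  if (sum(g1) < 2 || sum(!g1) < 2)
    stop("need at least two samples per group")
  x <- if (log_transform) log2(rpkm + 1) else rpkm
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, !g1, drop = FALSE], 1, stats::var)
  (m1 - m2) / sqrt(v1 / sum(g1) + v2 / sum(!g1))
}

# joint decile bin of (length, GC) per gene, over the universe
.covariate_bins <- function(covariates) {
  qlen <- stats::quantile(covariates$length, probs = seq(0, 1, 0.1))
  qgc <- stats::quantile(covariates$gc, probs = seq(0, 1, 0.1))
  blen <- findInterval(covariates$length, unique(qlen),
                       rightmost.closed = TRUE, all.inside = TRUE)
  bgc <- findInterval(covariates$gc, unique(qgc),
                      rightmost.closed = TRUE, all.inside = TRUE)
  paste(blen, bgc, sep = ":")
}

#' Covariate-matched resampling enrichment test
#'
#' Compares the mean per-gene statistic of a gene set against a null built
#' from randomly drawn gene sets matched for transcript length and GC
#' content. Matching uses joint decile bins of the two covariates over the
#' universe; each null set draws, for every set gene, one gene without
#' replacement from the same bin (bins with too few genes are widened to
#' their neighbours with a warning). Enrichment is reported both in null-SD
#' units and as an empirical p-value
#' \code{(1 + \#\{null >= observed\}) / (n_iter + 1)}.
#'
#' @param stat named per-gene statistic over the universe (e.g. layer
#'   t-statistics or specificity indices).
#' @param gene_set character vector, a subset of \code{names(stat)}.
#' @param covariates data.frame with columns \code{length}, \code{gc} and
#'   rownames over the universe.
#' @param n_iter number of null sets (default 10000).
#' @param seed RNG seed.
#' @return list: \code{set_score}, \code{null_mean}, \code{null_sd},
#'   \code{z_sd_units}, \code{empirical_p}, \code{n_iter}, \code{seed}.
#' @export
matched_null_enrichment <- function(stat, gene_set, covariates,
                                    n_iter = 10000L, seed = 1L) {
  universe <- names(stat)
  stopifnot(!is.null(universe), all(gene_set %in% universe),
            all(universe %in% rownames(covariates)))
  covariates <- covariates[universe, , drop = FALSE]
  bins <- .covariate_bins(covariates)
  names(bins) <- universe
  set_bins <- bins[gene_set]
  need <- table(set_bins)
  pool <- split(universe, bins)
  # widen bins that cannot supply enough matched genes
  for (b in names(need)) {
    if (length(pool[[b]]) < 2 * need[[b]]) {
      parts <- as.integer(strsplit(b, ":")[[1]])
      neigh <- as.vector(outer(parts[1] + (-1:1), parts[2] + (-1:1),
                               paste, sep = ":"))
      wide <- unique(unlist(pool[intersect(neigh, names(pool))]))
      if (length(wide) > length(pool[[b]])) {
        warning("matching bin ", b, " widened to neighbouring deciles")
        pool[[b]] <- wide
      }
    }
  }
  set.seed(seed)
  observed <- mean(stat[gene_set])
  k <- length(gene_set)
  null_scores <- numeric(n_iter)
  bin_names <- names(need)
  bin_k <- as.integer(need)
  for (i in seq_len(n_iter)) {
    tot <- 0
    for (j in seq_along(bin_names)) {
      g <- pool[[bin_names[j]]]
      pick <- if (length(g) <= bin_k[j]) g else sample(g, bin_k[j])
      tot <- tot + sum(stat[pick])
    }
    null_scores[i] <- tot / k
  }
  nm <- mean(null_scores)
  ns <- stats::sd(null_scores)
  list(set_score = observed, null_mean = nm, null_sd = ns,
       z_sd_units = (observed - nm) / ns,
       empirical_p = (1 + sum(null_scores >= observed)) / (n_iter + 1),
       n_iter = n_iter, seed = seed)
}

#' Cell-type specificity index
#'
#' For each gene, the mean expression in one cell type divided by the sum of
#' its mean expressions across all cell types. Rows sum to one when the gene
#' is expressed anywhere; genes with zero total expression get NA rows and
#' are flagged.
#'
#' @param rpkm genes x samples matrix.
#' @param types per-sample cell-type labels.
#' @return matrix genes x cell types of specificity indices, with attribute
#'   \code{"undefined"} listing zero-expression genes.
#' @export
specificity_index <- function(rpkm, types) {
  stopifnot(ncol(rpkm) == length(types))
  tl <- unique(types)
  means <- vapply(tl, function(ct)
    rowMeans(rpkm[, types == ct, drop = FALSE]), numeric(nrow(rpkm)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(rpkm), tl))
  tot <- rowSums(means)
  idx <- means / tot
  idx[tot == 0, ] <- NA_real_
  attr(idx, "undefined") <- rownames(rpkm)[tot == 0]
  idx
}

#' Hypergeometric network over-connectivity test
#'
#' Tests whether the number of observed edges spanning two gene sets (or
#' within one set, for interconnectivity) exceeds chance, treating the
#' observed edges as a draw of size E from the population of all unordered
#' gene pairs over the universe and the spanning pairs as successes: an
#' upper-tail hypergeometric p-value on the observed spanning-edge count.
#'
#' @param edges two-column data.frame of undirected edges (gene names).
#' @param setA,setB character gene sets; pass the same set twice (or leave
#'   \code{setB = NULL}) for within-set interconnectivity.
#' @param universe character vector of all genes considered.
#' @return list: \code{p_value}, \code{observed} spanning edges,
#'   \code{expected} under the null, \code{n_possible_pairs},
#'   \code{n_spanning_pairs}, \code{n_edges}.
#' @export
overconnectivity_test <- function(edges, setA, setB = NULL, universe) {
  if (is.null(setB)) setB <- setA
  setA <- intersect(unique(setA), universe)
  setB <- intersect(unique(setB), universe)
  keep <- edges[[1]] %in% universe & edges[[2]] %in% universe &
    edges[[1]] != edges[[2]]
  e1 <- pmin(edges[[1]][keep], edges[[2]][keep])
  e2 <- pmax(edges[[1]][keep], edges[[2]][keep])
  ekey <- unique(paste(e1, e2))
  n_u <- length(universe)
  m_pairs <- choose(n_u, 2)
  same <- setequal(setA, setB)
  if (same) {
    k_pairs <- choose(length(setA), 2)
  } else {
    shared <- length(intersect(setA, setB))
    k_pairs <- length(setA) * length(setB) - shared * (shared + 1) / 2
  }
  if (k_pairs == 0) {
    return(list(p_value = 1, observed = 0L, expected = 0,
                n_possible_pairs = m_pairs, n_spanning_pairs = 0,
                n_edges = length(ekey)))
  }
  parts <- strsplit(ekey, " ")
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  spanning <- (a %in% setA & b %in% setB) | (a %in% setB & b %in% setA)
  x <- sum(spanning)
  n_e <- length(ekey)
  list(p_value = stats::phyper(x - 1, k_pairs, m_pairs - k_pairs, n_e,
                               lower.tail = FALSE),
       observed = x, expected = n_e * k_pairs / m_pairs,
       n_possible_pairs = m_pairs, n_spanning_pairs = k_pairs,
       n_edges = n_e)
}
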