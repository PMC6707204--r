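#' Configuration for the synthetic trio-cohort generator
#'
#' Builds the configuration object shared by all synthetic-data generators.
#' Defaults encode the study conditions the downstream statistics are designed
#' for: a 465-trio simplex cohort with a 4.2:1 male:female proband ratio, a
#' genetic architecture in which 5\% of genes carry risk with Gamma-distributed
#' relative risks of mean 18 (LGD) and 6 (damaging missense), an exome-wide
#' de novo LGD expectation of 48.3 variants per 465 trios, beta-binomial
#' allele-depth overdispersion, a 10\% postzygotic-mosaic fraction among
#' apparent de novo SNVs, and a modest transmission distortion of rare
#' loss-of-function singletons in constrained genes.
#'
#' @param n_genes number of genes in the synthetic exome.
#' @param n_trios number of proband-mother-father trios.
#' @param female_fraction proportion of probands that are female.
#' @param risk_gene_fraction proportion of genes carrying risk (pi).
#' @param relative_risk_lgd,relative_risk_dmis mean relative risks for LGD and
#'   damaging-missense variants in risk genes; per-gene relative risks are
#'   drawn from Gamma(shape = mean, rate = 1).
#' @param theta_true beta-binomial overdispersion of allele depths, in [0, 1).
#' @param mosaic_fraction_true fraction of apparent de novo SNVs that are
#'   postzygotic mosaics.
#' @param mosaic_vaf_range interval within (0, 0.5) from which true mosaic
#'   allele fractions are drawn uniformly.
#' @param transmission_distortion probability a constrained-gene LGD singleton
#'   is transmitted (0.5 = null).
#' @param depth_mean,depth_size negative-binomial site-depth model (mean and
#'   dispersion size); depths are capped at \code{depth_cap}.
#' @param depth_cap maximum site depth, matching the downstream 500 ceiling.
#' @param exome_lgd_rate summed haploid LGD mutation rate over the exome, so
#'   that 2 * n_trios * exome_lgd_rate is the expected de novo LGD count.
#' @param exome_syn_rate,exome_mis_rate summed haploid synonymous and missense
#'   rates.
#' @param chrx_fraction proportion of genes placed on chromosome X.
#' @param dmis_fraction fraction of the missense rate that is damaging
#'   (CADD >= 25) under the null.
#' @param n_singletons number of founder singletons to generate.
#' @param artifact_fraction proportion of singletons that are call artifacts.
#' @param artifact_transmission apparent transmission probability of artifact
#'   singletons (below 0.5, so quality-threshold calibration is learnable).
#' @param vqslod_true_mean,vqslod_artifact_mean,vqslod_sd normal VQSLOD score
#'   model for true and artifact singletons.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 18000L,
                       n_trios = 465L,
                       female_fraction = 89 / 465,
                       risk_gene_fraction = 0.05,
                       relative_risk_lgd = 18,
                       relative_risk_dmis = 6,
                       theta_true = 0.05,
                       mosaic_fraction_true = 0.10,
                       mosaic_vaf_range = c(0.03, 0.35),
                       transmission_distortion = 0.536,
                       depth_mean = 80,
                       depth_size = 10,
                       depth_cap = 500L,
                       exome_lgd_rate = 48.3 / (2 * 465),
                       exome_syn_rate = 0.15,
                       exome_mis_rate = 0.325,
                       chrx_fraction = 0.04,
                       dmis_fraction = 0.436,
                       n_singletons = 10000L,
                       artifact_fraction = 0.15,
                       artifact_transmission = 0.25,
                       vqslod_true_mean = 3,
                       vqslod_artifact_mean = -4,
                       vqslod_sd = 1.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_trios = as.integer(n_trios),
              female_fraction = female_fraction,
              risk_gene_fraction = risk_gene_fraction,
              relative_risk_lgd = relative_risk_lgd,
              relative_risk_dmis = relative_risk_dmis,
              theta_true = theta_true,
              mosaic_fraction_true = mosaic_fraction_true,
              mosaic_vaf_range = mosaic_vaf_range,
              transmission_distortion = transmission_distortion,
              depth_mean = depth_mean, depth_size = depth_size,
              depth_cap = as.integer(depth_cap),
              exome_lgd_rate = exome_lgd_rate,
              exome_syn_rate = exome_syn_rate,
              exome_mis_rate = exome_mis_rate,
              chrx_fraction = chrx_fraction,
              dmis_fraction = dmis_fraction,
              n_singletons = as.integer(n_singletons),
              artifact_fraction = artifact_fraction,
              artifact_transmission = artifact_transmission,
              vqslod_true_mean = vqslod_true_mean,
              vqslod_artifact_mean = vqslod_artifact_mean,
              vqslod_sd = vqslod_sd,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$n_trios < 0L) stop("n_trios must be >= 0")
  props <- c(cfg$female_fraction, cfg$risk_gene_fraction,
             cfg$mosaic_fraction_true, cfg$transmission_distortion,
             cfg$artifact_fraction, cfg$artifact_transmission,
             cfg$dmis_fraction)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  if (cfg$theta_true < 0 || cfg$theta_true >= 1)
    stop("theta_true must lie in [0, 1)")
  if (length(cfg$mosaic_vaf_range) != 2L ||
      cfg$mosaic_vaf_range[1] <= 0 || cfg$mosaic_vaf_range[2] >= 0.5 ||
      diff(cfg$mosaic_vaf_range) < 0)
    stop("mosaic_vaf_range must be an interval within (0, 0.5)")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic gene-level mutation-rate table
#'
#' Produces per-gene, per-class baseline de novo mutation probabilities (per
#' haploid genome per generation) for the classes synonymous, missense,
#' nonsense, splice and frameshift, together with gene covariates (CDS length,
#' GC fraction, pLI) and chromosome labels. Per-gene rates are proportional to
#' CDS length and scaled so that exome totals match the configured class
#' rates. The frameshift rate is exactly 1.1 times the nonsense rate, and
#' nonsense:splice rates are in a 3:1 ratio within the LGD total. The summed
#' haploid LGD rate is attached as attribute \code{"mu_lgd_total"}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame with columns \code{gene}, \code{chrom}, \code{mu_syn},
#'   \code{mu_mis}, \code{mu_non}, \code{mu_splice}, \code{mu_frameshift},
#'   \code{cds_len}, \code{gc}, \code{pli}.
#' @export
gen_gene_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene <- sprintf("G%05d", seq_len(n))
  chrom <- ifelse(stats::runif(n) < cfg$chrx_fraction, "X",
                  as.character(sample(1:22, n, replace = TRUE)))
  cds_len <- pmax(150L, as.integer(round(stats::rlnorm(n, log(1300), 0.55))))
  gc <- stats::rbeta(n, 20, 25)
  w <- cds_len / sum(cds_len)
  mu_syn <- w * cfg$exome_syn_rate
  mu_mis <- w * cfg$exome_mis_rate
  # LGD split: nonsense + splice (=non/3) + frameshift (=1.1*non)
  mu_non <- w * cfg$exome_lgd_rate / (1 + 1 / 3 + 1.1)
  mu_splice <- mu_non / 3
  mu_frameshift <- 1.1 * mu_non
  constrained <- stats::runif(n) < 0.22
  pli <- ifelse(constrained, stats::rbeta(n, 6, 1), stats::rbeta(n, 1, 12))
  tab <- data.frame(gene = gene, chrom = chrom, mu_syn = mu_syn,
                    mu_mis = mu_mis, mu_non = mu_non, mu_splice = mu_splice,
                    mu_frameshift = mu_frameshift, cds_len = cds_len,
                    gc = gc, pli = pli, stringsAsFactors = FALSE)
  attr(tab, "mu_lgd_total") <- sum(mu_non + mu_splice + mu_frameshift)
  tab
}

.lgd_classes <- c("nonsense", "splice", "frameshift")
.rate_col <- c(synonymous = "mu_syn", missense = "mu_mis",
               nonsense = "mu_non", splice = "mu_splice",
               frameshift = "mu_frameshift")

#' Generate a synthetic cohort of apparent de novo variants
#'
#' Simulates per-gene de novo counts as Poisson(2 N mu gamma) (with the
#' chromosome-X allele-count adjustment), where gamma > 1 only in risk genes,
#' then attaches read-level evidence to every site: negative-binomial site
#' depth capped at the configured ceiling, alt-read counts drawn
#' beta-binomially around 0.5 for germline sites and around a uniform
#' low-fraction VAF for the planted mosaic subset, binomial strand splits,
#' and zero parental alt reads. Ground truth (risk genes, per-gene relative
#' risks, mosaic site ids) is returned alongside.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param genes gene table from \code{\link{gen_gene_table}}.
#' @return list with elements \code{variants} (data.frame of candidate de novo
#'   sites) and \code{truth} (list: \code{risk_gene_ids},
#'   \code{per_gene_gamma_lgd}, \code{per_gene_gamma_dmis},
#'   \code{mosaic_site_ids}, \code{theta_true}).
#' @export
gen_trio_cohort <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(genes) == 0L) stop("gene table is empty")
  set.seed(cfg$seed + 1L)
  n_g <- nrow(genes)
  n_fem <- round(cfg$n_trios * cfg$female_fraction)
  sex <- rep("M", cfg$n_trios)
  if (n_fem > 0) sex[sample(cfg$n_trios, n_fem)] <- "F"
  sample_id <- sprintf("T%04d", seq_len(cfg$n_trios))

  n_risk <- round(cfg$risk_gene_fraction * n_g)
  risk_idx <- if (n_risk > 0) sample(n_g, n_risk) else integer(0)
  gamma_lgd <- rep(1, n_g)
  gamma_dmis <- rep(1, n_g)
  if (n_risk > 0) {
    gamma_lgd[risk_idx] <- stats::rgamma(n_risk, shape = cfg$relative_risk_lgd,
                                         rate = 1)
    gamma_dmis[risk_idx] <- stats::rgamma(n_risk,
                                          shape = cfg$relative_risk_dmis,
                                          rate = 1)
  }
  # diploid allele count per gene: autosomes 2 per trio, chrX 2F + 1M
  alleles <- ifelse(genes$chrom == "X",
                    2 * sum(sex == "F") + sum(sex == "M"), 2 * cfg$n_trios)

  rows <- list()
  for (cls in names(.rate_col)) {
    mu <- genes[[.rate_col[[cls]]]]
    gam <- if (cls %in% .lgd_classes) gamma_lgd else rep(1, n_g)
    if (cls == "missense") {
      # damaging fraction of the missense rate carries gamma_dmis in risk genes
      lam <- alleles * mu * ((1 - cfg$dmis_fraction) +
                               cfg$dmis_fraction * gamma_dmis)
    } else {
      lam <- alleles * mu * gam
    }
    cnt <- stats::rpois(n_g, lam)
    idx <- rep.int(seq_len(n_g), cnt)
    if (length(idx) == 0L) next
    df <- data.frame(gene = genes$gene[idx], chrom = genes$chrom[idx],
                     class = cls, pli = genes$pli[idx],
                     stringsAsFactors = FALSE)
    if (cls == "missense") {
      p_dmis <- cfg$dmis_fraction * gamma_dmis[idx] /
        ((1 - cfg$dmis_fraction) + cfg$dmis_fraction * gamma_dmis[idx])
      df$cadd <- ifelse(stats::runif(nrow(df)) < p_dmis,
                        stats::runif(nrow(df), 25, 45),
                        stats::runif(nrow(df), 0, 25))
    } else {
      df$cadd <- stats::runif(nrow(df), 0, 25)
    }
    rows[[cls]] <- df
  }
  v <- do.call(rbind, rows)
  if (is.null(v)) {
    v <- data.frame(gene = character(), chrom = character(),
                    class = character(), pli = numeric(), cadd = numeric())
  }
  n_v <- nrow(v)
  rownames(v) <- NULL
  v$mpc <- ifelse(v$class == "missense" & v$cadd >= 25 &
                    stats::runif(n_v) < 0.18,
                  stats::runif(n_v, 2, 4), stats::runif(n_v, 0, 2))
  v$site_id <- sprintf("S%06d", seq_len(n_v))
  tri <- sample.int(cfg$n_trios, n_v, replace = TRUE)
  v$sample_id <- sample_id[tri]
  v$sex <- sex[tri]
  v$pos <- sample.int(2e8L, n_v, replace = TRUE)
  v$dp <- pmin(stats::rnbinom(n_v, mu = cfg$depth_mean,
                              size = cfg$depth_size) + 1L, cfg$depth_cap)
  is_snv <- !(v$class %in% "frameshift")
  mosaic <- is_snv & stats::runif(n_v) < cfg$mosaic_fraction_true
  vaf_true <- ifelse(mosaic,
                     stats::runif(n_v, cfg$mosaic_vaf_range[1],
                                  cfg$mosaic_vaf_range[2]), 0.5)
  v$ad_alt <- rbetabinom(n_v, v$dp, vaf_true, cfg$theta_true)
  v$ad_ref <- v$dp - v$ad_alt
  v$adf_alt <- stats::rbinom(n_v, v$ad_alt, 0.5)
  v$adr_alt <- v$ad_alt - v$adf_alt
  v$adf_ref <- stats::rbinom(n_v, v$ad_ref, 0.5)
  v$adr_ref <- v$ad_ref - v$adf_ref
  v$parental_alt <- 0L
  v$parental_dp <- pmin(stats::rnbinom(n_v, mu = cfg$depth_mean,
                                       size = cfg$depth_size) + 1L,
                        cfg$depth_cap)
  v$pop_af <- 0
  v$cohort_ac <- 1L
  v$mismatch_support <- 0L
  v$flags <- ""
  truth <- list(risk_gene_ids = genes$gene[risk_idx],
                per_gene_gamma_lgd = stats::setNames(gamma_lgd, genes$gene),
                per_gene_gamma_dmis = stats::setNames(gamma_dmis, genes$gene),
                mosaic_site_ids = v$site_id[mosaic],
                theta_true = cfg$theta_true)
  list(variants = v, truth = truth)
}

#' Generate germline heterozygous allele-depth data
#'
#' Read-depth and alt-read counts for inherited heterozygous sites, used to
#' exercise overdispersion estimation: depth is negative-binomial (capped),
#' alt reads are beta-binomial around 0.5 with the configured theta.
#'
#' @param n number of sites.
#' @param cfg a \code{\link{sim_config}}.
#' @param seed_offset added to \code{cfg$seed} so different draws can be taken
#'   from one config.
#' @return data.frame with columns \code{dp}, \code{ad_alt}.
#' @export
gen_het_reads <- function(n, cfg, seed_offset = 10L) {
  stopifnot(inherits(cfg, "sim_config"), n >= 1)
  set.seed(cfg$seed + seed_offset)
  dp <- pmin(stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_size) + 1L,
             cfg$depth_cap)
  data.frame(dp = dp, ad_alt = rbetabinom(n, dp, 0.5, cfg$theta_true))
}

#' Generate founder singleton variants with transmission status
#'
#' Each singleton is transmitted with probability 0.5 (neutral classes),
#' with the configured distortion (constrained-gene LGD), or with the
#' artifact transmission rate for planted call artifacts. VQSLOD scores are
#' drawn from a two-component normal mixture (true vs artifact), so a
#' quality threshold that restores 50\% transmission of neutral singletons
#' is learnable from the table.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param genes gene table from \code{\link{gen_gene_table}}.
#' @return data.frame of singletons with columns \code{variant_id},
#'   \code{var_type}, \code{gene}, \code{class}, \code{carrier},
#'   \code{transmitted}, \code{vqslod}, \code{constrained}, \code{in_exac},
#'   \code{hc_transcript_fraction}, \code{artifact} (truth label).
#' @export
gen_singleton_transmissions <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(genes) == 0L) stop("gene table is empty")
  set.seed(cfg$seed + 2L)
  n <- cfg$n_singletons
  cls <- sample(c("synonymous", "nonframeshift_indel", "missense",
                  "nonsense", "frameshift", "splice"),
                n, replace = TRUE,
                prob = c(0.35, 0.10, 0.30, 0.10, 0.10, 0.05))
  gi <- sample.int(nrow(genes), n, replace = TRUE)
  var_type <- ifelse(cls %in% c("frameshift", "nonframeshift_indel"),
                     "indel", "SNV")
  constrained <- genes$pli[gi] >= 0.5
  artifact <- stats::runif(n) < cfg$artifact_fraction
  p_tx <- ifelse(artifact, cfg$artifact_transmission,
                 ifelse(cls %in% .lgd_classes & constrained,
                        cfg$transmission_distortion, 0.5))
  vqslod <- stats::rnorm(n,
                         ifelse(artifact, cfg$vqslod_artifact_mean,
                                cfg$vqslod_true_mean),
                         cfg$vqslod_sd)
  hc <- ifelse(cls %in% .lgd_classes, stats::rbeta(n, 4, 1.2), NA_real_)
  data.frame(variant_id = sprintf("V%06d", seq_len(n)),
             var_type = var_type, gene = genes$gene[gi], class = cls,
             carrier = sprintf("F%05d", sample.int(2L * cfg$n_trios, n,
                                                   replace = TRUE)),
             transmitted = stats::runif(n) < p_tx,
             vqslod = vqslod, constrained = constrained,
             in_exac = stats::runif(n) < 0.3,
             hc_transcript_fraction = hc,
             artifact = artifact, stringsAsFactors = FALSE)
}

#' Generate an expression panel with a planted layer effect
#'
#' Log-normal RPKM values for a panel of genes across labelled samples
#' (cortical laminae by default), with an optional mean shift planted for a
#' chosen gene set in one layer, expressed in units of the per-sample noise
#' SD. Gene covariates (transcript length, GC) are attached for
#' matched-resampling tests.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_genes number of panel genes.
#' @param layers character vector of layer labels.
#' @param n_per_layer samples per layer.
#' @param signal_genes indices (or names) of genes carrying the planted shift.
#' @param signal_layer layer receiving the shift.
#' @param effect size of the planted shift in noise-SD units.
#' @return list: \code{rpkm} (genes x samples matrix), \code{labels},
#'   \code{covariates} (data.frame: length, gc), \code{truth}.
#' @export
gen_expression_panel <- function(cfg, n_genes = 2000L,
                                 layers = c("MZ", "CP", "SP", "IZ", "SVZ", "VZ"),
                                 n_per_layer = 8L,
                                 signal_genes = NULL, signal_layer = NULL,
                                 effect = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  labels <- rep(layers, each = n_per_layer)
  n_s <- length(labels)
  base <- stats::rnorm(n_genes, 3, 1.5)
  noise_sd <- 1
  x <- matrix(stats::rnorm(n_genes * n_s, 0, noise_sd), n_genes, n_s) + base
  if (!is.null(signal_genes) && !is.null(signal_layer) && effect != 0) {
    x[signal_genes, labels == signal_layer] <-
      x[signal_genes, labels == signal_layer] + effect * noise_sd
  }
  rpkm <- 2^x
  rownames(rpkm) <- sprintf("G%05d", seq_len(n_genes))
  colnames(rpkm) <- sprintf("%s_%02d", labels, seq_along(labels))
  cov <- data.frame(length = pmax(200L,
                                  as.integer(round(stats::rlnorm(n_genes,
                                                                 log(2000),
                                                                 0.6)))),
                    gc = stats::rbeta(n_genes, 20, 25),
                    row.names = rownames(rpkm))
  list(rpkm = rpkm, labels = labels, covariates = cov,
       truth = list(signal_genes = signal_genes, signal_layer = signal_layer,
                    effect = effect))
}

#' Generate a random interaction graph with planted over-connectivity
#'
#' An Erdos-Renyi background over \code{n_nodes} genes, plus a planted excess
#' of edges between two gene sets, for exercising hypergeometric
#' connectivity tests.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_nodes number of genes (nodes).
#' @param density background edge probability.
#' @param setA,setB integer node index sets.
#' @param excess_edges number of extra A-B edges planted beyond background.
#' @return list: \code{edges} (two-column data.frame of node names),
#'   \code{nodes}, \code{truth}.
#' @export
gen_ppi_graph <- function(cfg, n_nodes = 400L, density = 0.02,
                          setA = NULL, setB = NULL, excess_edges = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2L)
  on <- stats::runif(ncol(pairs)) < density
  edge_idx <- which(on)
  if (excess_edges > 0L && !is.null(setA) && !is.null(setB)) {
    spanning <- (pairs[1, ] %in% setA & pairs[2, ] %in% setB) |
      (pairs[1, ] %in% setB & pairs[2, ] %in% setA)
    candidates <- which(spanning & !on)
    add <- candidates[seq_len(min(excess_edges, length(candidates)))]
    edge_idx <- sort(c(edge_idx, add))
  }
  edges <- data.frame(from = nodes[pairs[1, edge_idx]],
                      to = nodes[pairs[2, edge_idx]],
                      stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes,
       truth = list(setA = setA, setB = setB, excess_edges = excess_edges))
}

#' Generate paired synthetic CNV call sets with known truth
#'
#' Simulates true CNV events per sample and derives two caller outputs with
#' independently jittered breakpoints, plus caller-specific false positives,
#' so consensus merging and inheritance assignment can be tested against
#' ground truth. Coordinates are 0-based half-open.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_events number of true CNV events.
#' @param n_samples number of samples carrying them.
#' @param jitter_bp SD of breakpoint jitter per caller.
#' @param fp_per_caller false-positive calls added per caller.
#' @param inherited_fraction fraction of true events also present in a parent.
#' @return list: \code{caller_a}, \code{caller_b}, \code{parent_calls},
#'   \code{truth}.
#' @export
gen_cnv_callsets <- function(cfg, n_events = 40L, n_samples = 20L,
                             jitter_bp = 2000L, fp_per_caller = 10L,
                             inherited_fraction = 0.6) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 5L)
  samp <- sprintf("T%04d", sample.int(cfg$n_trios, n_samples))
  ev_chrom <- as.character(sample(1:22, n_events, replace = TRUE))
  ev_start <- sample.int(1e8L, n_events)
  ev_len <- pmax(20000L, as.integer(round(stats::rlnorm(n_events,
                                                        log(2e5), 1))))
  ev <- data.frame(event_id = sprintf("E%03d", seq_len(n_events)),
                   chrom = ev_chrom, start = ev_start,
                   end = ev_start + ev_len,
                   svtype = sample(c("DEL", "DUP"), n_events, replace = TRUE),
                   sample_id = sample(samp, n_events, replace = TRUE),
                   inherited = stats::runif(n_events) < inherited_fraction,
                   stringsAsFactors = FALSE)
  jitter_calls <- function(tag) {
    s <- pmax(0L, as.integer(round(ev$start +
                                     stats::rnorm(n_events, 0, jitter_bp))))
    e <- as.integer(round(ev$end + stats::rnorm(n_events, 0, jitter_bp)))
    e <- pmax(e, s + 1000L)
    fp_chrom <- as.character(sample(1:22, fp_per_caller, replace = TRUE))
    fp_start <- sample.int(1e8L, fp_per_caller)
    fp_len <- pmax(20000L, as.integer(round(stats::rlnorm(fp_per_caller,
                                                          log(1e5), 1))))
    rbind(data.frame(chrom = ev$chrom, start = s, end = e,
                     svtype = ev$svtype, sample_id = ev$sample_id,
                     tier = 2L, caller = tag, event_id = ev$event_id,
                     stringsAsFactors = FALSE),
          data.frame(chrom = fp_chrom, start = fp_start,
                     end = fp_start + fp_len,
                     svtype = sample(c("DEL", "DUP"), fp_per_caller,
                                     replace = TRUE),
                     sample_id = sample(samp, fp_per_caller, replace = TRUE),
                     tier = 2L, caller = tag,
                     event_id = NA_character_, stringsAsFactors = FALSE))
  }
  ca <- jitter_calls("A")
  cb <- jitter_calls("B")
  parent <- ev[ev$inherited, c("chrom", "start", "end", "svtype",
                               "sample_id", "event_id")]
  list(caller_a = ca, caller_b = cb, parent_calls = parent, truth = ev)
}
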