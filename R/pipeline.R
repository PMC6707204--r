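#' Variant-table dialect columns
#'
#' The flat TSV dialect shared by all stages. Header-required, one row per
#' candidate variant observation.
#' @format character vector of required column names.
#' @export
variant_table_columns <- c(
  "site_id", "sample_id", "chrom", "pos", "gene", "class",
  "dp", "ad_ref", "ad_alt", "adf_alt", "adr_alt",
  "vqslod", "cadd", "mpc", "pli", "pop_af", "cohort_ac", "flags")

.class_vocab <- c("synonymous", "missense", "nonsense", "splice",
                  "frameshift", "nonframeshift_indel")

#' Map annotation strings to the internal variant-class vocabulary
#'
#' Annotation labels from common annotators (e.g. "stopgain",
#' "frameshift_deletion", "splice_donor") are mapped onto
#' \{synonymous, missense, nonsense, splice, frameshift,
#' nonframeshift_indel\}. LGD (likely gene disrupting) comprises nonsense,
#' frameshift and essential splice-site variants.
#'
#' @param annotation character vector of annotation strings.
#' @return character vector of class labels; attribute \code{"lgd"} is a
#'   logical vector marking LGD classes.
#' @export
classify_variant_class <- function(annotation) {
  key <- tolower(gsub("[ -]", "_", annotation))
  map <- c(synonymous = "synonymous", synonymous_snv = "synonymous",
           silent = "synonymous",
           missense = "missense", missense_snv = "missense",
           nonsynonymous_snv = "missense",
           nonsense = "nonsense", stopgain = "nonsense",
           stop_gained = "nonsense",
           splice = "splice", splicing = "splice",
           splice_donor = "splice", splice_acceptor = "splice",
           essential_splice_site = "splice",
           frameshift = "frameshift", frameshift_insertion = "frameshift",
           frameshift_deletion = "frameshift",
           nonframeshift_indel = "nonframeshift_indel",
           nonframeshift_insertion = "nonframeshift_indel",
           nonframeshift_deletion = "nonframeshift_indel")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unknown annotation string(s): ",
         paste(unique(annotation[is.na(out)]), collapse = ", "),
         "; known: ", paste(sort(unique(names(map))), collapse = ", "))
  }
  attr(out, "lgd") <- out %in% .lgd_classes
  out
}

#' Read the variant-table TSV dialect
#'
#' Parses and validates a variant table: required columns present, alt reads
#' not exceeding depth, strand counts summing to the alt count, class labels
#' in vocabulary. Malformed rows raise an error naming the offending line
#' numbers. Per-column missingness is attached as attribute
#' \code{"missingness"}.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
load_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "."),
                           colClasses = c(chrom = "character",
                                          flags = "character"))
  if (!is.null(tab$flags)) tab$flags[is.na(tab$flags)] <- ""
  miss <- setdiff(variant_table_columns, names(tab))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(tab$ad_alt > tab$dp | tab$ad_alt < 0 | tab$dp < 0)
  if (length(bad))
    stop("alt reads exceed depth at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  bad <- which(tab$adf_alt + tab$adr_alt != tab$ad_alt)
  if (length(bad))
    stop("strand counts do not sum to alt count at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  bad <- which(!tab$class %in% .class_vocab)
  if (length(bad))
    stop("unknown variant class at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         "; known: ", paste(.class_vocab, collapse = ", "))
  attr(tab, "missingness") <- vapply(tab, function(x) mean(is.na(x)),
                                     numeric(1))
  tab
}

#' Write a variant table in the TSV dialect
#'
#' @param variants data.frame containing at least
#'   \code{variant_table_columns}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  miss <- setdiff(variant_table_columns, names(variants))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  utils::write.table(variants[, variant_table_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variants from a VCF encoding of the dialect
#'
#' Accepts a single-sample VCF whose INFO field carries
#' \code{GENE, CLASS, CADD, MPC, PLI, POP_AF, AC, FLAGS, VQSLOD} and whose
#' genotype FORMAT carries \code{DP:GQ:AD:ADF:ADR} (AD/ADF/ADR as
#' ref,alt pairs). Returns records in the same shape as
#' \code{\link{load_variant_table}}.
#'
#' @param path VCF file path (plain text).
#' @return data.frame with \code{variant_table_columns}.
#' @export
load_variant_vcf <- function(path) {
  lines <- readLines(path)
  header <- grep("^#CHROM", lines)
  if (!length(header)) stop("not a VCF: no #CHROM header line")
  body <- lines[-seq_len(header)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(variant_table_columns)),
      variant_table_columns))
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  sample_name <- strsplit(lines[header], "\t")[[1]][10]
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  info <- vapply(fields, `[`, "", 8L)
  fmt <- strsplit(vapply(fields, `[`, "", 10L), ":", fixed = TRUE)
  fkeys <- strsplit(vapply(fields, `[`, "", 9L), ":", fixed = TRUE)
  fget <- function(key) {
    mapply(function(k, v) {
      i <- match(key, k)
      if (is.na(i)) NA_character_ else v[i]
    }, fkeys, fmt)
  }
  ad <- strsplit(fget("AD"), ",", fixed = TRUE)
  adf <- strsplit(fget("ADF"), ",", fixed = TRUE)
  adr <- strsplit(fget("ADR"), ",", fixed = TRUE)
  second <- function(x) as.integer(vapply(x, `[`, "", 2L))
  first <- function(x) as.integer(vapply(x, `[`, "", 1L))
  data.frame(
    site_id = vapply(fields, `[`, "", 3L),
    sample_id = sample_name,
    chrom = vapply(fields, `[`, "", 1L),
    pos = as.integer(vapply(fields, `[`, "", 2L)),
    gene = info_get(info, "GENE"),
    class = info_get(info, "CLASS"),
    dp = as.integer(fget("DP")),
    ad_ref = first(ad), ad_alt = second(ad),
    adf_alt = second(adf), adr_alt = second(adr),
    vqslod = as.numeric(info_get(info, "VQSLOD")),
    cadd = as.numeric(info_get(info, "CADD")),
    mpc = as.numeric(info_get(info, "MPC")),
    pli = as.numeric(info_get(info, "PLI")),
    pop_af = as.numeric(info_get(info, "POP_AF")),
    cohort_ac = as.integer(info_get(info, "AC")),
    flags = ifelse(is.na(info_get(info, "FLAGS")), "",
                   info_get(info, "FLAGS")),
    stringsAsFactors = FALSE)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a synthetic trio cohort and drives every analysis stage over
#' it: de novo burden testing, singleton transmission disequilibrium with
#' VQSLOD calibration, two-branch mosaic detection, TADA gene discovery,
#' expression/network enrichment, and CNV consensus with an aneuploidy scan.
#' Per-stage TSV tables and a JSON summary are written to \code{out_dir};
#' re-running with the same seed reproduces the outputs exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving all randomness.
#' @param cfg optional \code{\link{sim_config}} (its seed is overridden by
#'   \code{seed}); the default uses scaled-down sizes for a fast demo.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("burden", "transmission", "mosaic", "tada", "enrichment",
#'   "cnv")}.
#' @param n_iter_enrichment null-set count for the enrichment stage.
#' @return list of per-stage results, invisibly; side effect: files in
#'   \code{out_dir}.
#' @export
run_pipeline <- function(out_dir, seed = 1L, cfg = NULL,
                         stages = c("burden", "transmission", "mosaic",
                                    "tada", "enrichment", "cnv"),
                         n_iter_enrichment = 1000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg)) {
    cfg <- sim_config(n_genes = 4000L, n_trios = 465L,
                      n_singletons = 4000L, seed = seed)
  } else {
    cfg$seed <- as.integer(seed)
  }
  genes <- gen_gene_table(cfg)
  cohort <- gen_trio_cohort(cfg, genes)
  variants <- cohort$variants
  cs <- cohort_spec(n_female = round(cfg$n_trios * cfg$female_fraction),
                    n_male = cfg$n_trios -
                      round(cfg$n_trios * cfg$female_fraction))
  out <- list(seed = seed, n_trios = cfg$n_trios, n_genes = cfg$n_genes)

  if ("burden" %in% stages) {
    cal <- calibrate_to_silent(genes,
                               sum(variants$class == "synonymous"), cs)
    bt <- burden_table(variants, cal$rates, cs)
    utils::write.table(bt, file.path(out_dir, "burden.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$burden <- bt
    out$silent_scale <- cal$scale
  }
  if ("transmission" %in% stages) {
    sg <- gen_singleton_transmissions(cfg, genes)
    neutral <- sg[sg$class %in% c("synonymous", "nonframeshift_indel"), ]
    thr <- list(
      SNV = calibrate_vqslod(neutral$vqslod[neutral$var_type == "SNV"],
                             neutral$transmitted[neutral$var_type == "SNV"]),
      indel = calibrate_vqslod(neutral$vqslod[neutral$var_type == "indel"],
                               neutral$transmitted[neutral$var_type ==
                                                     "indel"]))
    pass <- sg$vqslod >= ifelse(sg$var_type == "SNV",
                                thr$SNV$threshold, thr$indel$threshold)
    lgd <- hc_lof_filter(sg[pass & sg$class %in% .lgd_classes, ])
    tt_con <- transmission_test(sum(lgd$transmitted & lgd$constrained),
                                sum(!lgd$transmitted & lgd$constrained))
    tt_unc <- transmission_test(sum(lgd$transmitted & !lgd$constrained),
                                sum(!lgd$transmitted & !lgd$constrained))
    out$transmission <- list(vqslod_thresholds = thr,
                             constrained = tt_con, unconstrained = tt_unc)
  }
  if ("mosaic" %in% stages) {
    het <- gen_het_reads(10000L, cfg)
    th <- estimate_theta(het$dp, het$ad_alt)
    snvs <- variants[variants$class != "frameshift", ]
    pf <- cumc_prefilter(snvs, n_cohort = cfg$n_trios)
    em <- em_mosaic(pf$retained, th$theta_hat)
    oh <- ohsu_classify(snvs)
    un <- union_mosaic_callset(oh, em$calls)
    utils::write.table(em$calls, file.path(out_dir, "mosaic_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$mosaic <- list(theta_hat = th$theta_hat, pi_m = em$pi_m,
                       n_union = nrow(un), prefilter_tally = pf$tally,
                       union = un)
  }
  if ("tada" %in% stages) {
    lam_scale <- if (!is.null(out$silent_scale)) out$silent_scale else 1
    lam_l <- .allele_count(genes$chrom, cs) *
      (genes$mu_non + genes$mu_splice + genes$mu_frameshift) * lam_scale
    lam_d <- .allele_count(genes$chrom, cs) * genes$mu_mis *
      cfg$dmis_fraction * lam_scale
    is_lgd <- variants$class %in% .lgd_classes
    is_dmis <- variants$class == "missense" & variants$cadd >= 25
    counts <- data.frame(
      gene = genes$gene,
      x_lgd = as.integer(table(factor(variants$gene[is_lgd],
                                      levels = genes$gene))),
      x_dmis = as.integer(table(factor(variants$gene[is_dmis],
                                       levels = genes$gene))),
      lambda0_lgd = lam_l, lambda0_dmis = lam_d,
      stringsAsFactors = FALSE)
    res <- tada_test(counts)
    utils::write.table(utils::head(res, 200),
                       file.path(out_dir, "tada.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$tada <- list(n_q10 = sum(res$q_value <= 0.1),
                     n_q20 = sum(res$q_value <= 0.2),
                     top = utils::head(res, 20))
  }
  if ("enrichment" %in% stages) {
    sig <- seq_len(50)
    panel <- gen_expression_panel(cfg, n_genes = 1000L, signal_genes = sig,
                                  signal_layer = "CP", effect = 1)
    keep <- expression_filter(panel$rpkm)
    tt <- layer_tstat(panel$rpkm, panel$labels, "CP")
    enr <- matched_null_enrichment(tt[keep],
                                   intersect(rownames(panel$rpkm)[sig], keep),
                                   panel$covariates,
                                   n_iter = n_iter_enrichment, seed = seed)
    si <- specificity_index(panel$rpkm, panel$labels)
    g <- gen_ppi_graph(cfg, n_nodes = 200L, setA = 1:20, setB = 21:40,
                       excess_edges = 20L)
    oc <- overconnectivity_test(g$edges, g$nodes[1:20], g$nodes[21:40],
                                g$nodes)
    out$enrichment <- list(layer_z = enr$z_sd_units,
                           layer_p = enr$empirical_p,
                           overconnectivity_p = oc$p_value,
                           mean_specificity = mean(si, na.rm = TRUE))
  }
  if ("cnv" %in% stages) {
    cn <- gen_cnv_callsets(cfg)
    cons <- consensus_merge(cn$caller_a, cn$caller_b)
    inh <- assign_inheritance(cons, cn$parent_calls, NULL)
    utils::write.table(inh, file.path(out_dir, "cnv_consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    depth <- data.frame(chrom = as.character(c(1:22, "X")),
                        norm_depth = c(1, rep(1, 21), 0.5))
    hv <- data.frame(chrom = rep(as.character(c(1:22, "X")), each = 50),
                     vaf = stats::rbeta(23 * 50, 30, 30))
    out$cnv <- list(n_consensus = nrow(cons),
                    n_de_novo = sum(inh$inheritance == "de novo"),
                    aneuploidy = aneuploidy_scan(depth, hv))
  }
  summary <- out
  summary$burden <- NULL; summary$tada$top <- NULL
  summary$mosaic$union <- NULL; summary$cnv$aneuploidy <- NULL
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out)
}
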