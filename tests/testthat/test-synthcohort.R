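test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 11)
  g1 <- gen_gene_table(cfg)
  g2 <- gen_gene_table(cfg)
  expect_identical(g1, g2)
  expect_identical(gen_trio_cohort(cfg, g1), gen_trio_cohort(cfg, g2))
  expect_identical(gen_singleton_transmissions(cfg, g1),
                   gen_singleton_transmissions(cfg, g1))
})

test_that("gene table honors the frameshift construction rule and class totals", {
  cfg <- small_cfg(seed = 2)
  g <- gen_gene_table(cfg)
  expect_equal(g$mu_frameshift, 1.1 * g$mu_non)
  expect_equal(sum(g$mu_non + g$mu_splice + g$mu_frameshift),
               cfg$exome_lgd_rate)
  expect_equal(attr(g, "mu_lgd_total"), cfg$exome_lgd_rate)
  expect_equal(sum(g$mu_syn), cfg$exome_syn_rate)
  expect_true(all(g$pli >= 0 & g$pli <= 1))
  expect_error(gen_gene_table(sim_config(n_genes = 0)), "n_genes")
})

test_that("null cohorts reproduce the exome-wide de novo LGD expectation", {
  # gamma = 1 everywhere; expected dnLGD per trio is 2 * exome_lgd_rate
  # (autosomes) minus the chrX male deficit; compare the Monte-Carlo mean
  # of observed/expected against 1 with Poisson spread
  cfg <- sim_config(n_genes = 10000L, n_trios = 465L,
                    risk_gene_fraction = 0, chrx_fraction = 0, seed = 1)
  g <- gen_gene_table(cfg)
  cs <- cohort_spec(n_female = 89, n_male = 376)
  expected <- expected_count(g, "lgd", NULL, cs)
  expect_equal(expected, 48.3, tolerance = 1e-10)
  n_reps <- 30
  obs <- vapply(seq_len(n_reps), function(r) {
    cfg_r <- cfg; cfg_r$seed <- 1000L + r
    co <- gen_trio_cohort(cfg_r, g)
    sum(co$variants$class %in% c("nonsense", "splice", "frameshift"))
  }, numeric(1))
  # per-trio rate: 48.3 / 465 = 0.1039
  mc_se <- sqrt(48.3 / n_reps) / 465
  expect_lt(abs(mean(obs) / 465 - 0.1039), 3 * mc_se + 1e-4)
  ratio <- obs / expected
  expect_lt(abs(mean(ratio) - 1), 3 * sqrt(1 / 48.3 / n_reps))
})

test_that("germline allele fractions are binomial when theta is zero and truth labels are consistent", {
  cfg <- small_cfg(seed = 5, theta_true = 0)
  het <- gen_het_reads(10000, cfg)
  vaf <- het$ad_alt / het$dp
  v_pred <- mean(0.25 / het$dp)  # pure binomial VAF variance
  expect_lt(abs(var(vaf) - v_pred), 4 * v_pred / sqrt(nrow(het)) * 3)

  cfg0 <- small_cfg(seed = 5, mosaic_fraction_true = 0)
  co <- gen_trio_cohort(cfg0, gen_gene_table(cfg0))
  expect_length(co$truth$mosaic_site_ids, 0)

  co2 <- gen_trio_cohort(small_cfg(seed = 6), gen_gene_table(small_cfg(seed = 6)))
  expect_true(all(co2$truth$mosaic_site_ids %in% co2$variants$site_id))
  expect_true(all(co2$truth$risk_gene_ids %in%
                    gen_gene_table(small_cfg(seed = 6))$gene))
  expect_true(all(co2$variants$ad_alt <= co2$variants$dp))
  expect_true(all(co2$variants$adf_alt + co2$variants$adr_alt ==
                    co2$variants$ad_alt))
})

test_that("singleton transmission honors the null and the planted distortion", {
  cfg <- sim_config(n_genes = 2000L, n_singletons = 10000L,
                    transmission_distortion = 0.5, artifact_fraction = 0,
                    seed = 9)
  g <- gen_gene_table(cfg)
  sg <- gen_singleton_transmissions(cfg, g)
  expect_lt(abs(mean(sg$transmitted) - 0.5), 3 * sqrt(0.25 / nrow(sg)))

  cfg2 <- sim_config(n_genes = 2000L, n_singletons = 40000L,
                     transmission_distortion = 0.536, artifact_fraction = 0,
                     seed = 9)
  sg2 <- gen_singleton_transmissions(cfg2, g)
  con_lgd <- sg2$constrained &
    sg2$class %in% c("nonsense", "splice", "frameshift")
  n <- sum(con_lgd)
  expect_gt(n, 500)
  expect_lt(abs(mean(sg2$transmitted[con_lgd]) - 0.536),
            3 * sqrt(0.536 * 0.464 / n))
  # the reported 464/866 split corresponds to this distortion: n * p
  expect_equal(866 * 0.536, 464.2, tolerance = 1e-4)
})

test_that("expression and graph generators plant recoverable effects", {
  cfg <- small_cfg(seed = 3)
  # null panel: no planted effect => set-level z within +/- 3
  p0 <- gen_expression_panel(cfg, n_genes = 600)
  tt <- layer_tstat(p0$rpkm, p0$labels, "CP")
  e0 <- matched_null_enrichment(tt, sample(rownames(p0$rpkm), 30),
                                p0$covariates, n_iter = 300, seed = 4)
  expect_lt(abs(e0$z_sd_units), 3)

  # single-type expression => specificity index 1 for that type
  rpkm <- matrix(0, 2, 6,
                 dimnames = list(c("g1", "g2"),
                                 paste0("s", 1:6)))
  types <- rep(c("neuron", "glia", "micro"), each = 2)
  rpkm[1, types == "neuron"] <- 7
  rpkm[2, ] <- 5
  si <- specificity_index(rpkm, types)
  expect_equal(unname(si["g1", "neuron"]), 1)
  expect_equal(unname(si["g1", "glia"]), 0)
  expect_equal(unname(si["g2", ]), rep(1 / 3, 3), ignore_attr = TRUE)

  # over-connectivity p decreases monotonically in the planted edge excess
  pvals <- vapply(c(0, 5, 20), function(e) {
    gr <- gen_ppi_graph(cfg, n_nodes = 150, setA = 1:12, setB = 13:24,
                        excess_edges = e)
    overconnectivity_test(gr$edges, gr$nodes[1:12], gr$nodes[13:24],
                          gr$nodes)$p_value
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})
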