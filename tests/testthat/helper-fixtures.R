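# shared scaled-down configuration for fast module tests
small_cfg <- function(seed = 1L, ...) {
  args <- list(n_genes = 2000L, n_trios = 200L, n_singletons = 3000L,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# a tiny hand-buildable variant table in the TSV dialect
toy_variants <- function(n = 6L) {
  data.frame(site_id = sprintf("S%03d", seq_len(n)),
             sample_id = rep(c("T0001", "T0002"), length.out = n),
             chrom = "1", pos = seq(1000L, by = 5000L, length.out = n),
             gene = sprintf("G%05d", seq_len(n)),
             class = rep(c("synonymous", "missense", "nonsense"),
                         length.out = n),
             dp = 100L, ad_ref = 50L, ad_alt = 50L,
             adf_alt = 25L, adr_alt = 25L,
             vqslod = 2.5, cadd = 10, mpc = 0.5, pli = 0.1,
             pop_af = 0, cohort_ac = 1L, flags = "",
             stringsAsFactors = FALSE)
}
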