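test_that("reciprocal overlap follows interval arithmetic", {
  expect_equal(reciprocal_overlap("1", 0, 100, "1", 0, 100)[1, ],
               c(fraction_a = 1, fraction_b = 1))
  expect_equal(reciprocal_overlap("1", 0, 100, "1", 50, 150)[1, ],
               c(fraction_a = 0.5, fraction_b = 0.5))
  expect_equal(reciprocal_overlap("1", 0, 100, "2", 0, 100)[1, ],
               c(fraction_a = 0, fraction_b = 0))
  expect_equal(reciprocal_overlap("1", 0, 100, "1", 0, 100,
                                  "DEL", "DUP")[1, ],
               c(fraction_a = 0, fraction_b = 0))
})

mk_calls <- function(start, end, chrom = "1", svtype = "DEL",
                     sample_id = "T0001", tier = 2L) {
  data.frame(chrom = chrom, start = start, end = end, svtype = svtype,
             sample_id = sample_id, tier = tier, stringsAsFactors = FALSE)
}

test_that("consensus merge reports intersections for RO and containment matches", {
  out <- consensus_merge(mk_calls(0, 100), mk_calls(50, 150))
  expect_equal(out[, c("start", "end")],
               data.frame(start = 50, end = 100), ignore_attr = TRUE)
  out2 <- consensus_merge(mk_calls(0, 1000), mk_calls(200, 300))
  expect_equal(out2[, c("start", "end")],
               data.frame(start = 200, end = 300), ignore_attr = TRUE)
  # RO = 0.4 each way, no containment: no consensus
  out3 <- consensus_merge(mk_calls(0, 100), mk_calls(60, 160))
  expect_equal(nrow(out3), 0)
  # different svtype never matches
  out4 <- consensus_merge(mk_calls(0, 100), mk_calls(0, 100, svtype = "DUP"))
  expect_equal(nrow(out4), 0)
  # unmatched tier-1 calls survive only when requested
  out5 <- consensus_merge(mk_calls(0, 100, tier = 1L), mk_calls(5000, 6000),
                          keep_unmatched_tier1 = TRUE)
  expect_true(any(out5$supporting_callers == "A"))
})

test_that("consensus merge is symmetric, idempotent and matches a brute-force oracle", {
  set.seed(29)
  n <- 1000
  # n random interval pairs, one pair per sample so matches are pairwise
  a_start <- sample.int(1e6, n)
  a <- mk_calls(start = a_start, end = a_start + sample(1000:50000, n, TRUE),
                sample_id = sprintf("P%04d", seq_len(n)))
  b_start <- pmax(1L, a_start + sample(-40000:40000, n, TRUE))
  b <- mk_calls(start = b_start, end = b_start + sample(1000:50000, n, TRUE),
                sample_id = sprintf("P%04d", seq_len(n)))
  cons <- consensus_merge(a, b)
  # oracle: plain integer arithmetic per pair
  oracle <- list()
  for (i in seq_len(n)) {
    ov <- min(a$end[i], b$end[i]) - max(a$start[i], b$start[i])
    if (ov <= 0) next
    roa <- ov / (a$end[i] - a$start[i])
    rob <- ov / (b$end[i] - b$start[i])
    if ((roa >= 0.5 && rob >= 0.5) || roa == 1 || rob == 1) {
      oracle[[length(oracle) + 1]] <-
        data.frame(sample_id = a$sample_id[i],
                   start = max(a$start[i], b$start[i]),
                   end = min(a$end[i], b$end[i]))
    }
  }
  om <- do.call(rbind, oracle)
  expect_equal(nrow(cons), nrow(om))
  m <- match(om$sample_id, cons$sample_id)
  expect_false(anyNA(m))
  expect_equal(cons$start[m], om$start)
  expect_equal(cons$end[m], om$end)
  # consensus intervals are contained in both inputs by construction
  expect_true(all(cons$end - cons$start > 0))
  # symmetry up to labels
  cons_ba <- consensus_merge(b, a)
  expect_setequal(paste(cons$start, cons$end),
                  paste(cons_ba$start, cons_ba$end))
  # idempotence on an already-merged set
  again <- consensus_merge(cons, cons)
  expect_setequal(paste(again$start, again$end),
                  paste(cons$start, cons$end))
})

test_that("exclusion filters apply the segdup fraction and blocklist rules", {
  calls <- mk_calls(c(0, 0, 0), c(100, 100, 100))
  calls$inheritance <- "de novo"
  segd <- data.frame(chrom = "1", start = c(0, 0, 0), end = c(75, 74, 0))
  out75 <- exclusion_filters(calls[1, ], segdups = segd[1, ])
  expect_equal(nrow(out75$retained), 0)  # 75% exactly: dropped
  out74 <- exclusion_filters(calls[2, ], segdups = segd[2, ])
  expect_equal(nrow(out74$retained), 1)
  gt <- data.frame(gene = c("DUSP22", "OR2T1"), chrom = "1",
                   start = c(10, 5000), end = c(50, 6000))
  outbl <- exclusion_filters(calls[3, ], gene_track = gt,
                             blocklist = c("DUSP22", "OR2T1"))
  expect_equal(nrow(outbl$retained), 0)
  expect_equal(unname(outbl$tally["blocklist"]), 1L)
  # inherited calls are not blocklist-filtered
  inh <- calls[3, ]; inh$inheritance <- "inherited(mother)"
  expect_equal(nrow(exclusion_filters(inh, gene_track = gt,
                                      blocklist = "DUSP22")$retained), 1)
})

test_that("inheritance labels prefer parental matches over de novo", {
  child <- mk_calls(1000, 2000)
  expect_equal(assign_inheritance(child, mk_calls(1100, 2100),
                                  NULL)$inheritance, "inherited(mother)")
  expect_equal(assign_inheritance(child, NULL, NULL)$inheritance, "de novo")
  expect_equal(assign_inheritance(child, mk_calls(1000, 2000),
                                  mk_calls(900, 1900))$inheritance,
               "inherited(both)")
  # svtype must match
  expect_equal(assign_inheritance(child, mk_calls(1000, 2000,
                                                  svtype = "DUP"),
                                  NULL)$inheritance, "de novo")
})

test_that("aneuploidy scan requires concordant depth and heterozygosity evidence", {
  chroms <- as.character(c(1:22, "X"))
  depth <- data.frame(chrom = chroms, norm_depth = rep(1, 23))
  set.seed(37)
  het <- data.frame(chrom = rep(chroms, each = 100),
                    vaf = rbinom(2300, 80, 0.5) / 80)
  base <- aneuploidy_scan(depth, het)
  expect_true(all(abs(base$copy_estimate[base$chrom %in% as.character(1:22)]
                      - 2) < 1e-12))
  expect_false(any(base$flagged))

  # depth-only anomaly is reported but not flagged
  d21 <- depth; d21$norm_depth[d21$chrom == "21"] <- 1.5
  r1 <- aneuploidy_scan(d21, het)
  expect_true(r1$depth_outlier[r1$chrom == "21"])
  expect_false(r1$flagged[r1$chrom == "21"])

  # trisomy: depth 1.5x plus het VAFs at a 1:2 allelic mixture
  het2 <- het
  tri <- het2$chrom == "21"
  het2$vaf[tri] <- rbinom(sum(tri), 80, sample(c(1 / 3, 2 / 3), sum(tri),
                                               TRUE)) / 80
  r2 <- aneuploidy_scan(d21, het2)
  expect_true(r2$flagged[r2$chrom == "21"])
  expect_equal(r2$copy_estimate[r2$chrom == "21"], 3)
  expect_error(aneuploidy_scan(depth[-1, ], het), "chromosome 1")
})

test_that("consensus coordinates round-trip through BED text losslessly", {
  cfg <- small_cfg(seed = 8)
  cn <- gen_cnv_callsets(cfg)
  cons <- consensus_merge(cn$caller_a, cn$caller_b)
  bed <- tempfile(fileext = ".bed")
  write.table(cons[, c("chrom", "start", "end", "svtype", "sample_id")],
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- read.table(bed, sep = "\t",
                     col.names = c("chrom", "start", "end", "svtype",
                                   "sample_id"),
                     colClasses = c("character", "integer", "integer",
                                    "character", "character"))
  expect_equal(back$start, cons$start)
  expect_equal(back$end, cons$end)
  expect_equal(back$chrom, cons$chrom)
})
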