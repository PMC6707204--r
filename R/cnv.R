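#' Reciprocal overlap of two CNV calls
#'
#' Overlap length expressed as a fraction of each interval's own length.
#' Coordinates are 0-based half-open. Intervals on different chromosomes or
#' with different SV types overlap by 0.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b interval coordinates
#'   (vectorized over pairs).
#' @param svtype_a,svtype_b SV types (\code{"DEL"}/\code{"DUP"}); optional.
#' @return two-column matrix \code{fraction_a}, \code{fraction_b}.
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a,
                               chrom_b, start_b, end_b,
                               svtype_a = NULL, svtype_b = NULL) {
  stopifnot(all(start_a < end_a), all(start_b < end_b))
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  same <- chrom_a == chrom_b
  if (!is.null(svtype_a) && !is.null(svtype_b)) same <- same & svtype_a == svtype_b
  ov <- ov * same
  cbind(fraction_a = ov / (end_a - start_a),
        fraction_b = ov / (end_b - start_b))
}

# overlap pairs between two call tables restricted to same sample & svtype;
# returns indices and intersection widths
.cnv_pairs <- function(a, b) {
  lv <- unique(c(a$chrom, b$chrom))
  ga <- GenomicRanges::GRanges(factor(a$chrom, levels = lv),
                               IRanges::IRanges(a$start + 1L, a$end))
  gb <- GenomicRanges::GRanges(factor(b$chrom, levels = lv),
                               IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  keep <- a$sample_id[i] == b$sample_id[j] & a$svtype[i] == b$svtype[j]
  i <- i[keep]; j <- j[keep]
  w <- pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j])
  list(i = i, j = j,
       int_start = pmax(a$start[i], b$start[j]),
       int_end = pmin(a$end[i], b$end[j]),
       w = w,
       wa = a$end[i] - a$start[i],
       wb = b$end[j] - b$start[j])
}

#' Consensus merge of CNV calls from two pipelines
#'
#' Two calls (same sample, same SV type) match when their reciprocal overlap
#' is at least \code{min_ro} in both directions or when one call is fully
#' contained in the other; in both cases the overlapping region is reported
#' as the consensus interval. A call may also be matched cumulatively by the
#' union of several overlapping calls from the other pipeline when the
#' summed overlap reaches \code{min_ro} of both the call and its partners;
#' the per-pair intersections are then merged by union. Unmatched calls are
#' retained only when flagged high-confidence (tier 1) and
#' \code{keep_unmatched_tier1} is set.
#'
#' @param calls_a,calls_b data.frames with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{svtype},
#'   \code{sample_id}, and optionally \code{tier}.
#' @param min_ro reciprocal-overlap threshold (inclusive).
#' @param keep_unmatched_tier1 keep unmatched tier-1 calls?
#' @return data.frame of consensus calls: \code{chrom}, \code{start},
#'   \code{end}, \code{svtype}, \code{sample_id}, \code{supporting_callers}.
#' @export
consensus_merge <- function(calls_a, calls_b, min_ro = 0.5,
                            keep_unmatched_tier1 = FALSE) {
  if (is.null(calls_a$tier)) calls_a$tier <- 2L
  if (is.null(calls_b$tier)) calls_b$tier <- 2L
  pr <- .cnv_pairs(calls_a, calls_b)
  ro_a <- pr$w / pr$wa
  ro_b <- pr$w / pr$wb
  pairwise <- (ro_a >= min_ro & ro_b >= min_ro) |
    pr$w == pr$wa | pr$w == pr$wb
  # cumulative matching: per A call, the union of its B partners
  cum_ok <- rep(FALSE, length(pr$i))
  if (length(pr$i)) {
    for (ai in unique(pr$i[!pairwise])) {
      sel <- pr$i == ai
      tot <- sum(pr$w[sel])
      span_b <- sum(pr$wb[sel])  # partners assumed non-overlapping per caller
      if (tot / pr$wa[sel][1] >= min_ro && tot / span_b >= min_ro)
        cum_ok[sel] <- TRUE
    }
  }
  ok <- pairwise | cum_ok
  cons <- NULL
  if (any(ok)) {
    cons <- data.frame(chrom = calls_a$chrom[pr$i[ok]],
                       start = pr$int_start[ok], end = pr$int_end[ok],
                       svtype = calls_a$svtype[pr$i[ok]],
                       sample_id = calls_a$sample_id[pr$i[ok]],
                       supporting_callers = "A,B",
                       stringsAsFactors = FALSE)
    # merge per-pair intersections of one A call by union
    key <- paste(calls_a$sample_id[pr$i[ok]], calls_a$svtype[pr$i[ok]],
                 calls_a$chrom[pr$i[ok]], pr$i[ok])
    cons <- do.call(rbind, lapply(split(cons, key), function(d) {
      gr <- GenomicRanges::reduce(
        GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$start + 1L, d$end)))
      data.frame(chrom = d$chrom[1],
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 svtype = d$svtype[1], sample_id = d$sample_id[1],
                 supporting_callers = "A,B", stringsAsFactors = FALSE)
    }))
    rownames(cons) <- NULL
  }
  out <- cons
  if (keep_unmatched_tier1) {
    um_a <- setdiff(seq_len(nrow(calls_a)), pr$i[ok])
    um_a <- um_a[calls_a$tier[um_a] == 1L]
    um_b <- setdiff(seq_len(nrow(calls_b)), pr$j[ok])
    um_b <- um_b[calls_b$tier[um_b] == 1L]
    add <- rbind(
      if (length(um_a)) data.frame(calls_a[um_a, c("chrom", "start", "end",
                                                   "svtype", "sample_id")],
                                   supporting_callers = "A"),
      if (length(um_b)) data.frame(calls_b[um_b, c("chrom", "start", "end",
                                                   "svtype", "sample_id")],
                                   supporting_callers = "B"))
    out <- rbind(out, add)
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), svtype = character(),
                      sample_id = character(),
                      supporting_callers = character())
  rownames(out) <- NULL
  out
}

#' Exclusion filters for CNV calls
#'
#' Drops calls with at least \code{max_segdup_fraction} of their length
#' covered by segmental duplications, and de novo calls intersecting a
#' blocklisted gene (e.g. genes in copy-number-hypervariable regions).
#'
#' @param calls data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{inheritance}.
#' @param segdups data.frame of segmental-duplication intervals
#'   (\code{chrom}, \code{start}, \code{end}), 0-based half-open.
#' @param gene_track data.frame of gene intervals (\code{gene}, \code{chrom},
#'   \code{start}, \code{end}); required when \code{blocklist} is given.
#' @param blocklist character vector of blocklisted gene names.
#' @param max_segdup_fraction coverage threshold (inclusive).
#' @return list: \code{retained} calls and \code{tally} of removals.
#' @export
exclusion_filters <- function(calls, segdups = NULL, gene_track = NULL,
                              blocklist = NULL, max_segdup_fraction = 0.75) {
  tally <- c(segdup = 0L, blocklist = 0L)
  drop <- rep(FALSE, nrow(calls))
  lv <- unique(c(calls$chrom,
                 if (!is.null(segdups)) segdups$chrom,
                 if (!is.null(gene_track)) gene_track$chrom))
  gc_calls <- GenomicRanges::GRanges(factor(calls$chrom, levels = lv),
                                     IRanges::IRanges(calls$start + 1L,
                                                      calls$end))
  if (!is.null(segdups) && nrow(segdups)) {
    gs <- GenomicRanges::reduce(
      GenomicRanges::GRanges(factor(segdups$chrom, levels = lv),
                             IRanges::IRanges(segdups$start + 1L,
                                              segdups$end)))
    cov <- rep(0, nrow(calls))
    hits <- GenomicRanges::findOverlaps(gc_calls, gs)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      w <- pmin(calls$end[qi], GenomicRanges::end(gs)[si]) -
        pmax(calls$start[qi], GenomicRanges::start(gs)[si] - 1L)
      cov <- tapply(w, factor(qi, levels = seq_len(nrow(calls))),
                    sum, default = 0)
    }
    frac <- as.numeric(cov) / (calls$end - calls$start)
    bad <- frac >= max_segdup_fraction
    tally["segdup"] <- sum(bad)
    drop <- drop | bad
  }
  if (!is.null(blocklist) && length(blocklist)) {
    stopifnot(!is.null(gene_track))
    gt <- gene_track[gene_track$gene %in% blocklist, , drop = FALSE]
    if (nrow(gt)) {
      gg <- GenomicRanges::GRanges(factor(gt$chrom, levels = lv),
                                   IRanges::IRanges(gt$start + 1L, gt$end))
      hit <- GenomicRanges::countOverlaps(gc_calls, gg) > 0
      is_dn <- if (is.null(calls$inheritance)) rep(TRUE, nrow(calls))
               else calls$inheritance == "de novo"
      bad <- hit & is_dn & !drop
      tally["blocklist"] <- sum(bad)
      drop <- drop | bad
    }
  }
  list(retained = calls[!drop, , drop = FALSE], tally = tally)
}

#' Assign inheritance labels to child CNV calls
#'
#' A child call matching a parental call (same SV type, reciprocal overlap at
#' least \code{min_ro} both ways or containment) is labelled inherited from
#' that parent; matches in both parents are labelled
#' \code{"inherited(both)"} — inherited status is always preferred over
#' de novo. Calls with no parental match are de novo.
#'
#' @param child_calls,mother_calls,father_calls data.frames with
#'   \code{chrom}, \code{start}, \code{end}, \code{svtype}; sample ids are
#'   not compared (pass one family at a time) unless a \code{sample_id}
#'   column is present in all three.
#' @param min_ro reciprocal-overlap threshold.
#' @return \code{child_calls} with an \code{inheritance} column.
#' @export
assign_inheritance <- function(child_calls, mother_calls, father_calls,
                               min_ro = 0.5) {
  match_parent <- function(parent) {
    if (is.null(parent) || nrow(parent) == 0L)
      return(rep(FALSE, nrow(child_calls)))
    a <- child_calls; b <- parent
    if (is.null(a$sample_id) || is.null(b$sample_id)) {
      a$sample_id <- "fam"
      b$sample_id <- "fam"
    }
    pr <- .cnv_pairs(a, b)
    ok <- (pr$w / pr$wa >= min_ro & pr$w / pr$wb >= min_ro) |
      pr$w == pr$wa | pr$w == pr$wb
    seq_len(nrow(a)) %in% pr$i[ok]
  }
  mo <- match_parent(mother_calls)
  fa <- match_parent(father_calls)
  child_calls$inheritance <- ifelse(mo & fa, "inherited(both)",
                                    ifelse(mo, "inherited(mother)",
                                           ifelse(fa, "inherited(father)",
                                                  "de novo")))
  child_calls
}

#' Chromosome aneuploidy scan from depth and heterozygosity summaries
#'
#' Estimates per-chromosome copy number as twice the ratio of normalized
#' read depth to that of chromosome 1 (assumed diploid); the ratio is left
#' unmultiplied for X and Y. Per-chromosome heterozygous-site allele-balance
#' deviation (mean |VAF - 0.5|) is computed alongside, and an autosome is
#' flagged as a candidate aneuploidy only when both metrics are outliers —
#' depth-only or VAF-only anomalies are reported but not flagged.
#'
#' @param depth data.frame with columns \code{chrom} and \code{norm_depth}
#'   (probe-density-normalized mean depth); must include chromosome "1".
#' @param het_vafs data.frame with columns \code{chrom} and \code{vaf} of
#'   heterozygous sites.
#' @param copy_dev minimum |copy estimate - 2| for a depth outlier.
#' @param vaf_dev minimum mean |VAF - 0.5| for an allele-balance outlier.
#' @return data.frame per chromosome: \code{chrom}, \code{copy_estimate},
#'   \code{het_count}, \code{mean_vaf_dev}, \code{depth_outlier},
#'   \code{vaf_outlier}, \code{flagged}.
#' @export
aneuploidy_scan <- function(depth, het_vafs, copy_dev = 0.4, vaf_dev = 0.1) {
  ref <- depth$norm_depth[depth$chrom == "1"]
  if (length(ref) != 1L || ref <= 0)
    stop("depth table must contain a single positive entry for chromosome 1")
  ratio <- depth$norm_depth / ref
  sex <- depth$chrom %in% c("X", "Y")
  copy <- ifelse(sex, ratio, 2 * ratio)
  dev <- tapply(abs(het_vafs$vaf - 0.5), het_vafs$chrom, mean)
  cnt <- tapply(het_vafs$vaf, het_vafs$chrom, length)
  mean_dev <- as.numeric(dev[depth$chrom])
  het_count <- as.integer(cnt[depth$chrom])
  het_count[is.na(het_count)] <- 0L
  depth_out <- !sex & abs(copy - 2) >= copy_dev
  vaf_out <- !is.na(mean_dev) & mean_dev >= vaf_dev
  data.frame(chrom = depth$chrom, copy_estimate = copy,
             het_count = het_count, mean_vaf_dev = mean_dev,
             depth_outlier = depth_out, vaf_outlier = vaf_out,
             flagged = depth_out & vaf_out, stringsAsFactors = FALSE)
}
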