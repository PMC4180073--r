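# three-step coding-evidence filter and threshold calibration

gr2 <- function(chrom, start, end, strand = "*") {
  GRanges(chrom, IRanges(start, end), strand = strand)
}

mk_probes <- function(gr) {
  gr$probe_id <- sprintf("P%02d", seq_along(gr))
  gr$role <- "expression"
  gr$uniquely_mapped <- TRUE
  gr
}

# one gene on chr1 '+' with exons 1001-1200 and 2001-2200
toy_models <- function() {
  g <- GRanges("chr1", IRanges(1001, 2200), strand = "+",
               gene_id = "G1", name = "G1", biotype = "protein_coding")
  gene_models(g, GRangesList(G1 = gr2("chr1", c(1001, 2001),
                                      c(1200, 2200), "+")))
}

test_that("classify_probes traces the three filter rules case by case", {
  models <- toy_models()
  probes <- mk_probes(c(
    gr2("chr1", 1050, 1109, "+"),   # inside same-strand exon -> coding
    gr2("chr1", 1050, 1109, "-"),   # opposite-only, no same-strand segment
    gr2("chr1", 5001, 5060, "+"),   # intergenic, sig segment -> step 2
    gr2("chr1", 6001, 6060, "+"),   # intergenic, in mask, p=0.2 seg + hit
    gr2("chr1", 7001, 7060, "+"),   # intergenic, outside mask, hit -> step 3
    gr2("chr1", 1500, 1559, "-"),   # intron of G1, clean -> intronic
    gr2("chr1", 9001, 9060, "-")))  # clean intergenic
  segs <- c(gr2("chr1", 4990, 5070, "+"), gr2("chr1", 5990, 6070, "+"))
  segs$p <- c(0.01, 0.2)
  ev <- coding_evidence(
    coding_segments = segs,
    coverage_mask = c(gr2("chr1", 4900, 5100), gr2("chr1", 5900, 6100)),
    protein_hits = c(gr2("chr1", 6010, 6050), gr2("chr1", 7010, 7050)))
  cls <- classify_probes(probes, models, ev)
  expect_equal(cls$stratum,
               c("coding_exonic", "antisense_noncoding",
                 "excluded_coding_evidence", "bona_fide_intergenic",
                 "excluded_protein_similarity", "bona_fide_intronic",
                 "bona_fide_intergenic"))
  # a same-strand significant segment under the antisense probe kills it
  segs2 <- gr2("chr1", 1040, 1120, "-"); segs2$p <- 0.001
  ev2 <- coding_evidence(segs2, gr2("chr1", 1000, 1200), GRanges())
  cls2 <- classify_probes(probes[2], models, ev2)
  expect_equal(cls2$stratum, "coding_exonic")
  # unknown chromosome errors when a genome is supplied
  expect_error(classify_probes(mk_probes(gr2("chrZ", 1, 60)), models, ev,
                               genome = c(chr1 = 10000L)),
               "unknown chromosome")
})

test_that("strata are exclusive/exhaustive and bona fide never overlaps exons", {
  sim <- shared_sim()
  cls <- classify_probes(sim$probes, sim$models, sim$evidence,
                         genome = sim$genome)
  expect_equal(sort(cls$probe_id),
               sort(as.character(
                 sim$probes$probe_id[sim$probes$role == "expression"])))
  expect_false(any(duplicated(cls$probe_id)))
  # zero tolerance: same-strand exon overlap is never bona fide
  pc_ex <- exon_track(sim$models, "protein_coding")
  pid <- as.character(sim$probes$probe_id)
  bona <- cls$probe_id[grepl("^bona_fide", cls$stratum)]
  ov <- overlaps_any_nt(sim$probes[match(bona, pid)], pc_ex, "same")
  expect_equal(sum(ov), 0L)
  # classification equals the generator's planted truth
  m <- merge(cls, sim$truth, by = "probe_id")
  expect_equal(m$stratum.x, m$stratum.y)
})

test_that("removing all evidence empties excluded strata, only to bona fide", {
  sim <- shared_sim()
  cls <- classify_probes(sim$probes, sim$models, sim$evidence,
                         genome = sim$genome)
  empty_ev <- coding_evidence(
    {g <- GRanges(); g$p <- numeric(0); g}, GRanges(), GRanges())
  cls0 <- classify_probes(sim$probes, sim$models, empty_ev,
                          genome = sim$genome)
  expect_equal(sum(grepl("^excluded", cls0$stratum)), 0L)
  chg <- merge(cls, cls0, by = "probe_id")
  moved <- chg[chg$stratum.x != chg$stratum.y, ]
  expect_true(all(grepl("^excluded", moved$stratum.x)))
  expect_true(all(grepl("^bona_fide", moved$stratum.y)))
})

test_that("threshold calibration recovers planted sensitivity/specificity", {
  set.seed(21)
  pos <- GRanges("chr1", IRanges(seq(1, 20000, by = 1000)[1:20], width = 200))
  neg <- GRanges("chr2", IRanges(seq(1, 20000, by = 1000)[1:20], width = 200))
  # 18/20 positives significant at 0.05 (sens 0.9),
  # 1/20 negatives covered (spec 0.95)
  segs <- suppressWarnings(c(granges(pos)[1:18], granges(neg)[1]))
  segs$p <- c(runif(18, 1e-4, 0.04), 0.01)
  ev <- coding_evidence(segs,
                        suppressWarnings(c(granges(pos), granges(neg))),
                        GRanges())
  cal <- calibrate_coding_threshold(c(1e-6, 0.05, 1.0), pos, neg, ev)
  at05 <- cal[cal$cutoff == 0.05, ]
  expect_equal(at05$sensitivity, 0.9)
  expect_equal(at05$specificity, 0.95)
  # limiting cutoffs and monotonicity
  expect_equal(cal$sensitivity[cal$cutoff == 1e-6], 0)
  expect_equal(cal$specificity[cal$cutoff == 1e-6], 1)
  expect_true(all(diff(cal$sensitivity) >= 0))
  expect_true(all(diff(cal$specificity) <= 0))
  expect_error(calibrate_coding_threshold(0.05, pos, neg,
    coding_evidence({g <- GRanges(); g$p <- numeric(0); g},
                    GRanges(), GRanges())), "empty")
})
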