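# interval engine: overlap fractions, any-nt queries, nearest gene,
# matched interval sampling

gr <- function(chrom, start, end, strand = "*") {
  GRanges(chrom, IRanges(start, end), strand = strand)
}

test_that("overlap_fraction follows the single-interval 90% rule semantics", {
  probe <- gr("chr1", 1, 60)                       # [0,60) in 0-based terms
  expect_equal(overlap_fraction(probe, gr("chr1", 1, 60)), 1.0)
  # interval [6,80) covers 54 of 60 bases: exactly the 90% boundary
  expect_equal(overlap_fraction(probe, gr("chr1", 7, 80)), 0.9)
  # two abutting intervals each cover half; best single interval is 0.5
  two <- c(gr("chr1", 1, 30), gr("chr1", 31, 60))
  expect_equal(overlap_fraction(probe, two), 0.5)
  expect_equal(overlap_fraction(probe, two, union = TRUE), 1.0)
  # unknown chromosome is a zero, not an error
  expect_equal(overlap_fraction(probe, gr("chrX", 1, 60)), 0)
  # monotone as the track interval is extended over the probe
  fr <- vapply(seq(10, 60, by = 10), function(e)
    overlap_fraction(probe, gr("chr1", 1, e)), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("overlap_fraction and overlaps_any_nt strand modes respect '*'", {
  probe_p <- gr("chr1", 1, 60, "+")
  track_m <- gr("chr1", 1, 60, "-")
  track_u <- gr("chr1", 1, 60, "*")
  expect_equal(overlap_fraction(probe_p, track_m, "same"), 0)
  expect_equal(overlap_fraction(probe_p, track_m, "opposite"), 1)
  expect_equal(overlap_fraction(probe_p, track_u, "same"), 1)
  expect_true(overlaps_any_nt(gr("chr1", 1, 60, "*"), track_m, "same"))
  expect_false(overlaps_any_nt(probe_p, track_m, "same"))
})

test_that("overlaps_any_nt is exact at single-base and adjacency boundaries", {
  probe <- gr("chr1", 101, 160)                    # [100,160) 0-based
  expect_true(overlaps_any_nt(probe, gr("chr1", 160, 200)))   # shares base
  expect_false(overlaps_any_nt(probe, gr("chr1", 161, 200)))  # adjacent
})

test_that("overlap queries agree with the quadratic all-pairs oracle", {
  set.seed(101)
  for (rep in 1:20) {
    q <- gr(sample(c("chr1", "chr2"), 50, TRUE),
            s <- sample(1e4, 50), s + sample(20:200, 50, TRUE))
    t_s <- sample(1e4, 50)
    tr <- gr(sample(c("chr1", "chr2"), 50, TRUE), t_s,
             t_s + sample(20:200, 50, TRUE))
    expect_identical(overlaps_any_nt(q, tr), oracle_any_nt(q, tr))
    expect_equal(overlap_fraction(q, tr), oracle_max_fraction(q, tr))
  }
})

test_that("nearest_protein_coding_gene measures gaps and breaks ties", {
  mk_models <- function(starts, ends, ids, strands = "+", chrom = "chr1") {
    g <- GRanges(chrom, IRanges(starts, ends), strand = strands,
                 gene_id = ids, name = ids, biotype = "protein_coding")
    ex <- GRangesList(setNames(lapply(seq_along(g), function(i) granges(g)[i]),
                               ids))
    gene_models(g, ex)
  }
  # probe [1000,1060) 0-based; spans [0,500) and [2000,3000):
  # gaps are 500 and 940 -> the left gene wins at distance 500
  m <- mk_models(c(1, 2001), c(500, 3000), c("gA", "gB"))
  nn <- nearest_protein_coding_gene(gr("chr1", 1001, 1060), m)
  expect_equal(nn$gene_id, "gA")
  expect_equal(nn$distance, 500)
  # probe inside a span -> 0
  expect_equal(
    nearest_protein_coding_gene(gr("chr1", 2100, 2159), m)$distance, 0)
  # exact tie -> lexicographically smallest gene_id
  m2 <- mk_models(c(1, 1201), c(100, 1300), c("gB", "gA"))
  tie <- nearest_protein_coding_gene(gr("chr1", 601, 700), m2)
  expect_equal(tie$gene_id, "gA")
  # no gene on the chromosome -> Inf sentinel
  far <- nearest_protein_coding_gene(gr("chr2", 1, 60), m)
  expect_true(is.na(far$gene_id) && is.infinite(far$distance))
  # random instances vs brute force
  set.seed(7)
  st <- sort(sample(seq(1, 5e4, by = 500), 20))
  m3 <- mk_models(st, st + 200, sprintf("g%02d", 1:20))
  q <- gr("chr1", qs <- sample(5e4, 100), qs + 59)
  nn3 <- nearest_protein_coding_gene(q, m3)
  expect_equal(nn3$distance, oracle_nearest(q, m3$genes))
})

test_that("nearest distances are invariant under coordinate mirroring", {
  set.seed(11)
  L <- 1e5
  st <- sort(sample(seq(1, L - 300, by = 700), 15))
  g <- GRanges("chr1", IRanges(st, st + 250), strand = "+",
               gene_id = sprintf("g%02d", 1:15), name = sprintf("g%02d", 1:15),
               biotype = "protein_coding")
  ex <- GRangesList(setNames(lapply(seq_along(g),
                                    function(i) granges(g)[i]), g$gene_id))
  m <- gene_models(g, ex)
  q <- gr("chr1", qs <- sample(L - 60, 50), qs + 59)
  d1 <- nearest_protein_coding_gene(q, m)$distance
  mirror <- function(x) GRanges("chr1", IRanges(L - end(x) + 1,
                                                L - start(x) + 1),
                                strand = strand(x))
  gm <- mirror(g); mcols(gm) <- mcols(g)
  exm <- GRangesList(setNames(lapply(seq_along(gm),
                                     function(i) granges(gm)[i]), gm$gene_id))
  d2 <- nearest_protein_coding_gene(mirror(q), gene_models(gm, exm))$distance
  expect_equal(d1, d2)
})

test_that("sample_matched_intervals honours lengths, exclusions and seed", {
  genome <- c(chr1 = 10000L, chr2 = 8000L)
  templates <- gr("chr1", c(1, 101, 201), c(60, 160, 260))  # all length 60
  s1 <- sample_matched_intervals(50, templates, genome, seed = 5)
  expect_true(all(width(s1) == 60))
  expect_true(all(start(s1) >= 1))
  expect_true(all(end(s1) <= genome[as.character(seqnames(s1))]))
  s2 <- sample_matched_intervals(50, templates, genome, seed = 5)
  expect_identical(s1, s2)                      # determinism
  # forced placement: everything excluded except one 100-base window
  excl <- suppressWarnings(c(gr("chr1", 1, 9900), gr("chr2", 1, 8000)))
  s3 <- sample_matched_intervals(20, templates, genome, exclusion = excl,
                                 seed = 1)
  expect_true(all(start(s3) >= 9901 & end(s3) <= 10000))
  expect_true(all(as.character(seqnames(s3)) == "chr1"))
  # sampled intervals never intersect the exclusion track
  excl2 <- gr("chr1", seq(1, 9000, by = 1000), seq(1, 9000, by = 1000) + 400)
  s4 <- sample_matched_intervals(100, templates, genome, exclusion = excl2,
                                 seed = 2)
  expect_false(any(overlaps_any_nt(s4, excl2)))
  # impossible repeat matching fails with an informative error
  rep_track <- gr("chr1", 1, 5000)
  tmpl_in_rep <- gr("chr1", 100, 159)           # repeat fraction 1
  expect_error(
    sample_matched_intervals(5, tmpl_in_rep, genome,
                             exclusion = gr("chr1", 1, 6000),
                             matching = "length_and_repeat",
                             repeat_track = rep_track, repeat_tol = 0.05,
                             max_attempts = 50, seed = 3),
    "rejection sampling failed")
  # feasible repeat matching stays within tolerance
  s5 <- sample_matched_intervals(30, tmpl_in_rep, genome,
                                 matching = "length_and_repeat",
                                 repeat_track = rep_track, repeat_tol = 0.1,
                                 seed = 4)
  rf <- lncarray:::.covered_fraction(s5, rep_track)
  expect_true(all(abs(rf - 1) <= 0.1))
})
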