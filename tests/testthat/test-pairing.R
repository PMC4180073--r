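# lncRNA-mRNA pairing, quadrant classification, distance null test

test_that("gene-level fold change picks the max-|log2FC| significant probe", {
  de <- data.frame(probe_id = c("a", "b", "c", "d", "e"),
                   log2fc = c(1.2, -0.3, -2.0, 1.9, -0.7),
                   fdr = c(0.01, 0.01, 0.001, 0.001, 0.2))
  map <- data.frame(probe_id = c("a", "b", "c", "d", "e"),
                    gene_id = c("G1", "G1", "G2", "G2", "G3"))
  fc <- gene_level_fold_change(de, map, fdr_cut = 0.05)
  expect_equal(fc$gene_log2fc[fc$gene_id == "G1"], 1.2)
  expect_equal(fc$gene_log2fc[fc$gene_id == "G2"], -2.0)  # |-2| > |1.9|
  expect_false("G3" %in% fc$gene_id)                       # not significant
  one <- gene_level_fold_change(
    data.frame(probe_id = "z", log2fc = -0.7, fdr = 0.01),
    data.frame(probe_id = "z", gene_id = "G9"))
  expect_equal(one$gene_log2fc, -0.7)
})

# toy world: gene G1 '+' at 1001..2200 (one exon), probe near it
toy_pair_world <- function(probe_strand, probe_lfc, gene_lfc,
                           gene_strand = "+") {
  g <- GRanges("chr1", IRanges(1001, 2200), strand = gene_strand,
               gene_id = "G1", name = "G1", biotype = "protein_coding")
  models <- gene_models(g, GRangesList(
    G1 = GRanges("chr1", IRanges(1001, 2200), strand = gene_strand)))
  probes <- GRanges("chr1", IRanges(c(3001, 1101), width = 60),
                    strand = c(probe_strand, gene_strand))
  probes$probe_id <- c("nc1", "ex1")
  probes$role <- "expression"; probes$uniquely_mapped <- TRUE
  de <- data.frame(probe_id = c("nc1", "ex1"),
                   log2fc = c(probe_lfc, gene_lfc), fdr = c(0.01, 0.01))
  cls <- data.frame(probe_id = c("nc1", "ex1"),
                    stratum = c("bona_fide_intergenic", "coding_exonic"))
  emap <- data.frame(probe_id = "ex1", gene_id = "G1")
  build_lnc_mrna_pairs(probes, cls, de, models, emap)
}

test_that("strand exclusion rules accept/reject pairs as specified", {
  # same strand, synonymous -> rejected
  p1 <- toy_pair_world("+", +1, +2)
  expect_equal(nrow(p1), 1)
  expect_false(p1$accepted)
  expect_equal(p1$quadrant, "synonymous_both_up")
  # same strand, converse -> accepted
  p2 <- toy_pair_world("+", +1, -2)
  expect_true(p2$accepted)
  expect_equal(p2$quadrant, "converse_probe_up_gene_down")
  # opposite strand, synonymous -> accepted (rule 2)
  p3 <- toy_pair_world("-", +1, +2)
  expect_true(p3$accepted)
  expect_equal(p3$quadrant, "synonymous_both_up")
  # unknown strand treated as rule 2
  p4 <- toy_pair_world("*", -1, -2)
  expect_true(p4$accepted)
  expect_equal(p4$quadrant, "synonymous_both_down")
  expect_equal(p4$distance, 800)   # 3001 - 2200 - 1
})

test_that("planted converse pairs are recovered with correct quadrants", {
  sim <- shared_sim()
  grp <- factor(sim$samples$group, levels = c("normal", "tumor"))
  kept <- nonspecific_filter(sim$expr,
                             sim$probes$probe_id[sim$probes$role ==
                                                   "negative_control"],
                             iqr_min = 0)
  de <- fit_moderated_t(sim$expr[kept, ], grp, batch = sim$samples$batch)
  cls <- classify_probes(sim$probes, sim$models, sim$evidence,
                         genome = sim$genome)
  pid <- as.character(sim$probes$probe_id)
  ex_ids <- cls$probe_id[cls$stratum == "coding_exonic"]
  emap <- data.frame(
    probe_id = ex_ids,
    gene_id = nearest_protein_coding_gene(sim$probes[match(ex_ids, pid)],
                                          sim$models)$gene_id)
  pairs <- build_lnc_mrna_pairs(sim$probes, cls, de$table, sim$models, emap)
  tr <- sim$truth[!is.na(sim$truth$pair_gene_id), ]
  m <- merge(tr, pairs, by = "probe_id")
  expect_equal(nrow(m), nrow(tr))                  # all planted pairs found
  expect_equal(m$gene_id, m$pair_gene_id)          # paired to their anchor
  expect_true(all(m$accepted))
  expect_equal(m$quadrant,
               ifelse(m$de_sign == 1, "converse_probe_up_gene_down",
                      "converse_probe_down_gene_up"))
  # hard invariants over all pairs
  gstrand <- setNames(as.character(strand(sim$models$genes)),
                      as.character(sim$models$genes$gene_id))
  pstrand <- setNames(as.character(strand(sim$probes)), pid)
  acc <- pairs[pairs$accepted, ]
  same <- pstrand[acc$probe_id] == gstrand[acc$gene_id] &
    pstrand[acc$probe_id] != "*"
  expect_true(all(sign(acc$probe_log2fc[same]) !=
                    sign(acc$gene_log2fc[same])))
  expect_true(all(table(pairs$probe_id) == 1))
})

test_that("quadrant counts tally unique genes and probes", {
  expect_equal(sum(quadrant_counts(
    data.frame(probe_id = character(0), gene_id = character(0),
               relation = character(0), probe_log2fc = numeric(0),
               gene_log2fc = numeric(0), distance = numeric(0),
               quadrant = character(0), accepted = logical(0)))$n_genes), 0)
  pr <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_id = c("G1", "G1", "G2", "G2"),
    relation = "intergenic_proximal",
    probe_log2fc = c(1, 2, 1, 1), gene_log2fc = c(-1, -1, 1, 1),
    distance = 0,
    quadrant = c("converse_probe_up_gene_down", "converse_probe_up_gene_down",
                 "synonymous_both_up", "synonymous_both_up"),
    accepted = c(TRUE, TRUE, TRUE, FALSE))
  qc <- quadrant_counts(pr)
  conv <- qc[qc$relation == "intergenic_proximal" &
               qc$quadrant == "converse_probe_up_gene_down", ]
  expect_equal(conv$n_genes, 1)     # one gene, two probes
  expect_equal(conv$n_probes, 2)
  syn <- qc[qc$relation == "intergenic_proximal" &
              qc$quadrant == "synonymous_both_up", ]
  expect_equal(syn$n_probes, 1)     # the rejected pair does not count
  # totals equal accepted pairs (by probe)
  expect_equal(sum(qc$n_probes), sum(pr$accepted))
  # independent tally on a random pair table
  set.seed(41)
  quads <- c("converse_probe_up_gene_down", "converse_probe_down_gene_up",
             "synonymous_both_up", "synonymous_both_down")
  rnd <- data.frame(probe_id = sprintf("p%03d", 1:150),
                    gene_id = sprintf("G%02d", sample(20, 150, TRUE)),
                    relation = sample(c("intergenic_proximal", "intronic",
                                        "antisense_overlap"), 150, TRUE),
                    probe_log2fc = 1, gene_log2fc = 1, distance = 0,
                    quadrant = sample(quads, 150, TRUE),
                    accepted = sample(c(TRUE, FALSE), 150, TRUE, c(.8, .2)))
  qc2 <- quadrant_counts(rnd)
  acc <- rnd[rnd$accepted, ]
  for (i in seq_len(nrow(qc2))) {
    sel <- acc[acc$relation == qc2$relation[i] &
                 acc$quadrant == qc2$quadrant[i], ]
    expect_equal(qc2$n_genes[i], length(unique(sel$gene_id)))
    expect_equal(qc2$n_probes[i], length(unique(sel$probe_id)))
  }
})

test_that("distance-to-nearest KS test is sane and calibrated", {
  set.seed(42)
  x <- rexp(300, 1 / 2000)
  self <- distance_to_nearest_ks(x, x)
  expect_equal(self$p.value, 1)
  near <- rexp(300, 1 / 200)
  r <- distance_to_nearest_ks(near, x)
  expect_lt(r$p.value, 1e-6)
  expect_error(distance_to_nearest_ks(numeric(0), x), "empty")
  # type-I calibration: identical distributions -> uniform p over replicates
  set.seed(43)
  ps <- replicate(200, {
    distance_to_nearest_ks(runif(40, 0, 1e4), runif(60, 0, 1e4))$p.value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
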