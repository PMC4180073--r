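# synthetic study generator: determinism, planted structure, edge cases

test_that("the generator is a pure function of (config, seed)", {
  cfg <- small_config(seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$seg, s2$seg)
  expect_identical(as.data.frame(s1$probes), as.data.frame(s2$probes))
  # a different seed changes the study
  s3 <- simulate_study(small_config(seed = 8))
  expect_false(identical(s1$expr, s3$expr))
})

test_that("probe strata hold by construction", {
  sim <- shared_sim()
  pid <- as.character(sim$probes$probe_id)
  pc_ex <- exon_track(sim$models, "protein_coding")
  spans <- sim$models$genes
  g <- function(ids) sim$probes[match(ids, pid)]
  tr <- sim$truth
  # antisense probes overlap an exon on the opposite strand only
  anti <- g(tr$probe_id[tr$placement == "antisense"])
  expect_true(all(overlaps_any_nt(anti, pc_ex, "ignore")))
  expect_false(any(vapply(seq_along(anti), function(i) {
    ex <- pc_ex[oracle_any_nt(pc_ex, anti[i])]
    any(as.character(strand(ex)) == as.character(strand(anti[i])))
  }, logical(1))))
  # intergenic probes overlap no exon on either strand and no gene span
  ig <- g(tr$probe_id[tr$placement == "intergenic"])
  expect_false(any(overlaps_any_nt(ig, pc_ex, "ignore")))
  expect_false(any(overlaps_any_nt(ig, spans, "ignore")))
  # intronic probes are inside a span but clear of exons
  intr <- g(tr$probe_id[tr$placement == "intronic"])
  expect_true(all(overlaps_any_nt(intr, spans, "ignore")))
  expect_false(any(overlaps_any_nt(intr, pc_ex, "ignore")))
  # all expression probes are 60-mers with unique ids
  expect_true(all(width(sim$probes) == 60))
  expect_false(any(duplicated(pid)))
  # every expression probe appears exactly once in the truth table
  expect_setequal(tr$probe_id, pid[sim$probes$role == "expression"])
})

test_that("planted evidence exclusions equal the truth exactly", {
  sim <- shared_sim()
  cls <- classify_probes(sim$probes, sim$models, sim$evidence,
                         genome = sim$genome)
  m <- merge(cls, sim$truth, by = "probe_id")
  expect_equal(m$stratum.x[m$stratum.y == "excluded_coding_evidence"],
               rep("excluded_coding_evidence",
                   sum(m$stratum.y == "excluded_coding_evidence")))
  expect_equal(m$stratum.x[m$stratum.y == "excluded_protein_similarity"],
               rep("excluded_protein_similarity",
                   sum(m$stratum.y == "excluded_protein_similarity")))
})

test_that("the noiseless limit reproduces planted effects exactly", {
  cfg <- small_config(seed = 9, noise_sd = 0, batch_effect = 0,
                      cnv_slope = 0)
  sim <- simulate_study(cfg)
  grp <- sim$samples$group
  lfc <- rowMeans(sim$expr[, grp == "tumor"]) -
    rowMeans(sim$expr[, grp == "normal"])
  tr <- sim$truth
  de_ids <- tr$probe_id[tr$true_de & tr$expressed & !tr$subtype_de]
  expect_equal(unname(lfc[de_ids]),
               2 * tr$de_sign[match(de_ids, tr$probe_id)])
  null_ids <- tr$probe_id[!tr$true_de & tr$expressed & !tr$subtype_de]
  expect_equal(max(abs(lfc[null_ids])), 0)
})

test_that("degenerate configurations behave as specified", {
  # no genes: whole genome is intergenic space
  cfg0 <- small_config(n_protein_coding = 0,
                       n_probes = c(coding_exonic = 0, intronic = 0,
                                    intergenic = 50, antisense = 0),
                       car_pattern = c(consistent_down = 0,
                                       consistent_up = 0, inconsistent = 0,
                                       not_significant = 0),
                       n_converse_pairs = 0, n_lncRNA = 5)
  ga0 <- simulate_genome_annotation(cfg0)
  expect_equal(length(ga0$models$genes), 0)
  ps0 <- simulate_probe_set(cfg0, ga0)
  expect_equal(sum(ps0$truth$placement == "intergenic"), 50)
  # genes too large for the chromosome: placement error
  expect_error(simulate_genome_annotation(
    small_config(exon_meanlog = log(1e7))), "placement failure")
  # invalid config values are rejected up front
  expect_error(sim_config(n_tumor = -1), "counts")
  expect_error(sim_config(de_fraction = 1.5), "fractions")
})

test_that("negative controls sit at background and quiet CARs are dark", {
  sim <- shared_sim()
  cfg <- small_config()
  negs <- sim$probes$probe_id[sim$probes$role == "negative_control"]
  expect_equal(mean(sim$expr[negs, ]), cfg$background_mean, tolerance = 0.05)
  quiet_cars <- sim$car_truth$car_id[sim$car_truth$true_class ==
                                       "not_significant"]
  dark <- sim$truth$probe_id[sim$truth$car_id %in% quiet_cars]
  expect_true(all(!sim$truth$expressed[match(dark, sim$truth$probe_id)]))
  expect_equal(mean(sim$expr[dark, ]), cfg$background_mean, tolerance = 0.2)
})

test_that("a null study yields almost no FDR discoveries (calibration)", {
  cfg <- small_config(seed = 13, de_fraction = 0, subtype_de_fraction = 0,
                      cnv_driven_fraction = 0, n_converse_pairs = 0,
                      car_pattern = c(consistent_down = 0, consistent_up = 0,
                                      inconsistent = 0, not_significant = 0))
  sim <- simulate_study(cfg)
  grp <- factor(sim$samples$group, levels = c("normal", "tumor"))
  expr_ids <- as.character(sim$probes$probe_id[sim$probes$role ==
                                                 "expression"])
  de <- fit_moderated_t(sim$expr[expr_ids, ], grp, batch = sim$samples$batch)
  expect_lte(sum(de$table$significant), 2)
})

test_that("generated files round-trip bit-identically", {
  sim <- shared_sim()
  d1 <- file.path(tempdir(), "simrt1"); d2 <- file.path(tempdir(), "simrt2")
  write_simulation(sim, d1)
  # read every file back with the package readers and re-serialise
  dir.create(d2, showWarnings = FALSE)
  write_probe_bed(read_probe_bed(file.path(d1, "probes.bed")),
                  file.path(d2, "probes.bed"))
  write_gene_models_gff3(read_gene_models_gff3(file.path(d1, "genes.gff3")),
                         file.path(d2, "genes.gff3"))
  write_chrom_sizes(read_chrom_sizes(file.path(d1, "genome.chrom.sizes")),
                    file.path(d2, "genome.chrom.sizes"))
  write_expression_matrix(
    read_expression_matrix(file.path(d1, "expression.tsv")),
    file.path(d2, "expression.tsv"))
  write_sample_sheet(read_sample_sheet(file.path(d1, "samples.tsv")),
                     file.path(d2, "samples.tsv"))
  write_seg(read_seg(file.path(d1, "cnv.seg")), file.path(d2, "cnv.seg"))
  write_gmt(read_gmt(file.path(d1, "gene_sets.gmt")),
            file.path(d2, "gene_sets.gmt"))
  write_truth_table(read_truth_table(file.path(d1, "truth.tsv")),
                    file.path(d2, "truth.tsv"))
  write_conservation(read_conservation(file.path(d1, "conservation.tsv")),
                     file.path(d2, "conservation.tsv"))
  for (f in c("track_cars.bed", "track_lncRNA.bed", "track_regulatory.bed",
              "track_repeats.bed", "coverage_mask.bed")) {
    gr <- read_bed(file.path(d1, f))
    write_bed(gr, file.path(d2, f))
  }
  for (f in list.files(d2)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)),
                     label = paste("round trip of", f))
  }
})
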