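# Synthetic study generator.  Emits a miniature genome with
# protein-coding gene models, annotation tracks (known lncRNAs,
# regulatory sites, repeats, chromatin-associated lncRNA regions),
# a 60-mer probe set stratified by genomic context, coding-evidence
# tracks, a log2 expression matrix for a 5-normal / 26-tumor design with
# five tumor subtypes, and segmented copy-number profiles -- all with a
# planted truth table so every pipeline stage can be checked against
# known answers.  Everything is a deterministic function of
# (config, seed).

#' Simulation configuration
#'
#' Default scale mirrors the shape of a small clinical array study at toy
#' size: 2 chromosomes of 1 Mb, 100 protein-coding genes, 2,000
#' expression probes of 60 bp in four strata, 5 normal and 26 tumor
#' samples over five subtypes, a planted CAR consistency pattern of
#' 43 down / 17 up / 4 inconsistent (plus 24 quiet CARs), 20 planted
#' converse lncRNA-mRNA pairs, and a 6% copy-number-driven fraction with
#' unit slope and 0.3 log2 noise.
#'
#' @param seed integer seed; the whole study is a function of it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_protein_coding number of protein-coding genes.
#' @param n_lncRNA number of annotated lncRNA intervals.
#' @param exons_per_gene integer vector sampled from per gene.
#' @param exon_meanlog,exon_sdlog,intron_meanlog,intron_sdlog,gap_meanlog,gap_sdlog
#'   log-normal length parameters (bases).
#' @param n_probes named counts per stratum (`coding_exonic`,
#'   `intronic`, `intergenic`, `antisense`).
#' @param n_negative_controls negative-control spots.
#' @param n_normal,n_tumor sample sizes; `subtype_labels` are cycled over
#'   the tumors; `n_batches` additive batch groups.
#' @param de_effect planted two-group log2 effect size;
#'   `de_fraction` planted DE fraction per stratum (applied to probes not
#'   already committed to a CAR or pair).
#' @param subtype_effect,subtype_de_fraction planted Basal-specific shift.
#' @param n_converse_pairs planted converse intergenic lncRNA-mRNA
#'   pairs; `pair_distance` range of probe-to-gene gaps (bases).
#' @param car_pattern named counts of planted CAR classes
#'   (`consistent_down`, `consistent_up`, `inconsistent`,
#'   `not_significant`); `probes_per_car` sampled per CAR (inconsistent
#'   CARs always get >= 2).
#' @param exclude_coding_fraction,exclude_protein_fraction fractions of
#'   uncommitted intronic/intergenic probes planted to fail filter steps
#'   2 and 3.
#' @param rnacode_sensitivity fraction of protein-coding exons carrying
#'   a significant coding segment (calibration ground truth).
#' @param mask_fraction approximate fraction of the genome covered by
#'   the coding-scan coverage mask outside exons.
#' @param n_repeats,repeat_meanlog,repeat_sdlog repeat-track shape.
#' @param cnv_driven_fraction,cnv_slope,cnv_segments_per_chrom,cnv_segment_sd
#'   copy-number model: fraction of non-coding probes whose expression
#'   tracks the segment value with slope `cnv_slope`; per-sample
#'   profiles have `cnv_segments_per_chrom` segments with values
#'   N(0, `cnv_segment_sd`).
#' @param noise_sd residual log2 noise; `baseline_mean`, `baseline_sd`
#'   per-probe baselines; `batch_effect` additive batch offset;
#'   `background_mean`, `background_sd` negative-control level.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 1e6,
                       n_protein_coding = 100, n_lncRNA = 30,
                       exons_per_gene = 2:6,
                       exon_meanlog = log(150), exon_sdlog = 0.35,
                       intron_meanlog = log(700), intron_sdlog = 0.5,
                       gap_meanlog = log(2500), gap_sdlog = 0.6,
                       n_probes = c(coding_exonic = 600, intronic = 600,
                                    intergenic = 600, antisense = 200),
                       n_negative_controls = 100,
                       n_normal = 5, n_tumor = 26,
                       subtype_labels = c("LumA", "LumB", "ERBB2", "Basal",
                                          "NormalLike"),
                       n_batches = 2,
                       de_effect = 2, de_fraction = 0.25,
                       subtype_effect = 2, subtype_de_fraction = 0.05,
                       n_converse_pairs = 20, pair_distance = c(200, 1200),
                       car_pattern = c(consistent_down = 43,
                                       consistent_up = 17,
                                       inconsistent = 4,
                                       not_significant = 24),
                       probes_per_car = 1:3,
                       exclude_coding_fraction = 0.05,
                       exclude_protein_fraction = 0.03,
                       rnacode_sensitivity = 0.9,
                       mask_fraction = 0.5,
                       n_repeats = 300, repeat_meanlog = log(300),
                       repeat_sdlog = 0.4,
                       cnv_driven_fraction = 0.06, cnv_slope = 1,
                       cnv_segments_per_chrom = 6, cnv_segment_sd = 0.6,
                       noise_sd = 0.3, baseline_mean = 8, baseline_sd = 1,
                       batch_effect = 0.3,
                       background_mean = 5, background_sd = 0.5) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chroms, cfg$n_protein_coding, cfg$n_lncRNA,
              cfg$n_probes, cfg$n_negative_controls, cfg$n_normal,
              cfg$n_tumor, cfg$n_converse_pairs, cfg$car_pattern,
              cfg$n_repeats)
  if (any(counts < 0)) stop("all counts must be >= 0")
  fr <- c(cfg$de_fraction, cfg$subtype_de_fraction,
          cfg$exclude_coding_fraction, cfg$exclude_protein_fraction,
          cfg$rnacode_sensitivity, cfg$mask_fraction,
          cfg$cnv_driven_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  need <- c("coding_exonic", "intronic", "intergenic", "antisense")
  if (!all(need %in% names(cfg$n_probes))) {
    stop("n_probes needs counts for: ", paste(need, collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

.lnorm_len <- function(n, meanlog, sdlog, minimum) {
  pmax(minimum, round(stats::rlnorm(n, meanlog, sdlog)))
}

# uniform placement of n width-w intervals inside a pool of allowed
# segments, keeping at least `pad` bases from the 'avoid' set and from
# each other (stratum probes keep 80 bp apart so planted per-probe
# evidence segments, plus the coverage-mask padding around them, never
# reach a neighbouring probe).  Batched
# rejection sampling: draw all outstanding candidates at once, drop the
# ones clashing with 'avoid' or with an earlier-drawn candidate, redraw.
.place_in_pool <- function(n, w, pool, avoid = GRanges(), pad = 0L,
                           max_attempts = 500) {
  if (n == 0) return(GRanges())
  pool <- pool[width(pool) >= w]
  if (!length(pool)) stop("placement failure: no pool segment can host width ",
                          w)
  weights <- width(pool) - w + 1
  kept_chrom <- character(0); kept_start <- integer(0)
  pool_chrom <- as.character(seqnames(pool))
  for (round in seq_len(max_attempts)) {
    need <- n - length(kept_start)
    if (need == 0) break
    s <- sample.int(length(pool), need, replace = TRUE, prob = weights)
    off <- floor(runif(need) * (weights[s])) # 0 .. width-w
    cst <- start(pool)[s] + as.integer(off)
    cand <- GRanges(pool_chrom[s], IRanges(cst, width = w))
    all_prev <- .c_gr(list(GRanges(kept_chrom, IRanges(kept_start,
                                                       width = w)), avoid))
    bad <- overlaps_any_nt(cand + pad, all_prev, "ignore")
    # also drop candidates clashing with an earlier candidate this round
    hits <- suppressWarnings(findOverlaps(cand + pad, cand, ignore.strand = TRUE))
    dup <- queryHits(hits)[queryHits(hits) > subjectHits(hits)]
    bad[unique(dup)] <- TRUE
    kept_chrom <- c(kept_chrom, pool_chrom[s][!bad])
    kept_start <- c(kept_start, cst[!bad])
    if (length(kept_start) > n) {
      kept_chrom <- kept_chrom[seq_len(n)]
      kept_start <- kept_start[seq_len(n)]
    }
  }
  if (length(kept_start) < n) {
    stop("placement failure: could not place ", n, " intervals of width ",
         w, " after ", max_attempts, " rounds")
  }
  GRanges(kept_chrom, IRanges(kept_start, width = w))
}

# independent uniform placement (intervals may overlap each other);
# used for exonic/antisense probes, which tile densely on real arrays
.sample_in_pool <- function(n, w, pool) {
  if (n == 0) return(GRanges())
  pool <- pool[width(pool) >= w]
  if (!length(pool)) stop("placement failure: no pool segment can host width ",
                          w)
  weights <- width(pool) - w + 1
  s <- sample.int(length(pool), n, replace = TRUE, prob = weights)
  off <- as.integer(floor(runif(n) * weights[s]))
  GRanges(as.character(seqnames(pool))[s], IRanges(start(pool)[s] + off,
                                                   width = w))
}

.genome_granges <- function(genome) {
  GRanges(names(genome), IRanges(1L, as.integer(unname(genome))))
}

#' Simulate the genome, gene models and annotation tracks
#'
#' Places non-overlapping protein-coding genes with log-normal exon and
#' intron lengths along each chromosome, then CAR intervals (in introns,
#' spanning an exon, or intergenic), known-lncRNA windows, promoter-like
#' regulatory sites and a repeat track.
#'
#' @param config `sim_config`.
#' @return list with `genome` (named chrom lengths), `models`
#'   (`gene_models`), `tracks` (named list of `GRanges`: `cars` with
#'   `car_id` and planted `true_class`, `lncRNA`, `regulatory`,
#'   `repeats`) and `car_truth` (data.frame `car_id`, `location`,
#'   `true_class`).
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- setNames(rep(as.integer(config$chrom_length), config$n_chroms),
                     paste0("chr", seq_len(config$n_chroms)))
  # --- gene placement -------------------------------------------------
  rows <- list(); exlist <- list(); gid <- 0L
  for (chr in names(genome)) {
    cursor <- 1L + .lnorm_len(1, config$gap_meanlog, config$gap_sdlog, 200)
    while (gid < config$n_protein_coding) {
      k <- if (length(config$exons_per_gene) == 1) config$exons_per_gene else
        sample(config$exons_per_gene, 1)
      el <- .lnorm_len(k, config$exon_meanlog, config$exon_sdlog, 80)
      il <- if (k > 1) .lnorm_len(k - 1, config$intron_meanlog,
                                  config$intron_sdlog, 250) else integer(0)
      span <- sum(el) + sum(il)
      if (cursor + span > genome[[chr]] - 1000) break
      gid <- gid + 1L
      starts <- cursor + cumsum(c(0L, utils::head(el, -1) + il))
      ends <- starts + el - 1L
      strand <- sample(c("+", "-"), 1)
      id <- sprintf("PCG%04d", gid)
      rows[[gid]] <- data.frame(gene_id = id, chrom = chr, strand = strand,
                                start = cursor, end = cursor + span - 1L,
                                stringsAsFactors = FALSE)
      exlist[[id]] <- GRanges(chr, IRanges(starts, ends), strand = strand)
      cursor <- cursor + span +
        .lnorm_len(1, config$gap_meanlog, config$gap_sdlog, 400)
    }
  }
  if (gid < config$n_protein_coding) {
    stop("placement failure: only ", gid, " of ", config$n_protein_coding,
         " genes fit the genome (increase chrom_length or shrink genes)")
  }
  if (gid > 0) {
    gdf <- do.call(rbind, rows)
    genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                     strand = gdf$strand, gene_id = gdf$gene_id,
                     name = gdf$gene_id, biotype = "protein_coding")
  } else {
    genes <- GRanges(gene_id = character(0), name = character(0),
                     biotype = character(0))
  }
  models <- gene_models(genes, GenomicRanges::GRangesList(exlist))
  spans <- models$genes
  exons <- if (gid > 0) exon_track(models) else GRanges()
  introns <- if (gid > 0) intron_track(models) else GRanges()
  ggr <- .genome_granges(genome)
  gaps <- GenomicRanges::setdiff(
    ggr, if (length(spans)) spans + 50L else GRanges(), ignore.strand = TRUE)

  # --- CARs: intronic, exon-spanning, intergenic ----------------------
  n_cars <- sum(config$car_pattern)
  n_intron_car <- round(0.10 * n_cars)
  n_span_car <- round(0.45 * n_cars)
  n_ig_car <- n_cars - n_intron_car - n_span_car
  car_rows <- list()
  if (n_cars > 0) {
    big_introns <- introns[width(introns) >= 600]
    if (length(big_introns) < n_intron_car) {
      stop("placement failure: not enough large introns for intronic CARs")
    }
    intron_car_genes <- character(0)
    pick <- sample(seq_along(big_introns), n_intron_car)
    intron_car_genes <- unique(big_introns$gene_id[pick])
    for (i in seq_len(n_intron_car)) {
      intr <- big_introns[pick[i]]
      len <- min(width(intr) - 60L, sample(200:500, 1))
      st <- start(intr) + sample.int(width(intr) - len - 40L, 1) + 20L
      car_rows[[length(car_rows) + 1]] <- data.frame(
        chrom = as.character(seqnames(intr)), start = st, end = st + len - 1L,
        location = "intronic", stringsAsFactors = FALSE)
    }
    # spanning CARs: from late in an intron across the following exon
    elig <- which(vapply(models$exons, length, 1L) >= 2 &
                    !(as.character(models$genes$gene_id) %in%
                        intron_car_genes))
    if (length(elig) < n_span_car) {
      stop("placement failure: not enough multi-exon genes for spanning CARs")
    }
    for (g in sample(elig, n_span_car)) {
      ex <- GenomicRanges::sort(models$exons[[g]])
      j <- if (length(ex) == 2) 2L else sample(2:length(ex), 1)
      st <- start(ex)[j] - 150L
      en <- min(end(ex)[j] + 50L, end(models$genes)[g])
      car_rows[[length(car_rows) + 1]] <- data.frame(
        chrom = as.character(seqnames(ex))[1], start = st, end = en,
        location = "spanning", stringsAsFactors = FALSE)
    }
    ig_pool <- gaps[width(gaps) >= 1800]
    prev <- GRanges()
    for (i in seq_len(n_ig_car)) {
      len <- sample(500:1500, 1)
      cand <- .place_in_pool(1, len, ig_pool, avoid = prev)
      prev <- .c_gr(list(prev, cand))
      car_rows[[length(car_rows) + 1]] <- data.frame(
        chrom = as.character(seqnames(cand)), start = start(cand),
        end = end(cand), location = "intergenic", stringsAsFactors = FALSE)
    }
  }
  if (length(car_rows)) {
    cdf <- do.call(rbind, car_rows)
    cdf$car_id <- sprintf("CAR%03d", seq_len(nrow(cdf)))
    cls <- sample(rep(names(config$car_pattern), config$car_pattern))
    cdf$true_class <- cls
    cars <- GRanges(cdf$chrom, IRanges(cdf$start, cdf$end), strand = "*",
                    car_id = cdf$car_id, true_class = cdf$true_class)
    car_truth <- cdf[, c("car_id", "location", "true_class")]
  } else {
    cars <- GRanges(car_id = character(0), true_class = character(0))
    car_truth <- data.frame(car_id = character(0), location = character(0),
                            true_class = character(0))
  }

  # --- other annotation tracks ---------------------------------------
  lnc_pool <- gaps[width(gaps) >= 700]
  lncRNA <- if (config$n_lncRNA > 0 && length(lnc_pool))
    .place_in_pool(config$n_lncRNA, 500L, lnc_pool, avoid = cars) else
    GRanges()
  if (length(spans)) {
    tss <- ifelse(as.character(strand(spans)) == "-", end(spans),
                  start(spans))
    regulatory <- GRanges(seqnames(spans),
                          IRanges(pmax(1L, tss - 500L), tss + 500L))
    regulatory <- GenomicRanges::sort(regulatory)
  } else regulatory <- GRanges()
  repeats <- if (config$n_repeats > 0) {
    rl <- .lnorm_len(config$n_repeats, config$repeat_meanlog,
                     config$repeat_sdlog, 50)
    starts <- integer(config$n_repeats); chroms <- character(config$n_repeats)
    for (i in seq_len(config$n_repeats)) {
      chroms[i] <- sample(names(genome), 1)
      starts[i] <- sample.int(genome[[chroms[i]]] - rl[i], 1)
    }
    GenomicRanges::sort(GRanges(chroms, IRanges(starts, width = rl)))
  } else GRanges()

  list(genome = genome, models = models,
       tracks = list(cars = cars, lncRNA = lncRNA, regulatory = regulatory,
                     repeats = repeats),
       car_truth = car_truth)
}

#' Simulate the probe set, coding evidence and truth table
#'
#' Places 60-mer expression probes by stratum (coding exonic, intronic,
#' intergenic, antisense), commits probes to the planted CAR pattern and
#' converse pairs, plants coding-evidence tracks so that configured
#' subsets of intronic/intergenic probes fail filter steps 2 and 3, and
#' records the full truth table.
#'
#' @param config `sim_config`.
#' @param genome_ann result of [simulate_genome_annotation()].
#' @return list with `probes` (`GRanges` incl. negative controls),
#'   `evidence` (`coding_evidence`), `truth` (data.frame),
#'   `conservation` (data.frame `probe_id`, `score`).
#' @export
simulate_probe_set <- function(config, genome_ann) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genome <- genome_ann$genome
  models <- genome_ann$models
  cars <- genome_ann$tracks$cars
  spans <- models$genes
  has_genes <- length(spans) > 0
  exons <- if (has_genes) exon_track(models) else GRanges()
  introns <- if (has_genes) intron_track(models) else GRanges()
  ggr <- .genome_granges(genome)
  W <- 60L

  probe_list <- list()
  truth_list <- list()
  add_probe <- function(gr, stratum, placement, car_id = NA, pair_gene = NA,
                        strand_vec = NULL) {
    n0 <- length(gr)
    if (!n0) return(invisible())
    if (is.null(strand_vec)) strand_vec <- sample(c("+", "-"), n0,
                                                  replace = TRUE)
    strand(gr) <- strand_vec
    probe_list[[length(probe_list) + 1]] <<- gr
    truth_list[[length(truth_list) + 1]] <<- data.frame(
      stratum = stratum, placement = placement,
      car_id = rep(car_id, length.out = n0),
      pair_gene_id = rep(pair_gene, length.out = n0),
      stringsAsFactors = FALSE)
    invisible()
  }

  # --- CAR probes (committed first so the pattern is exact) ----------
  if (length(cars)) {
    safe_exons <- if (length(exons)) granges(exons) + 30L else GRanges()
    elig_all <- GenomicRanges::setdiff(granges(cars), safe_exons,
                                       ignore.strand = TRUE)
    hits <- suppressWarnings(findOverlaps(elig_all, cars,
                                          ignore.strand = TRUE))
    pieces <- pintersect(granges(elig_all)[queryHits(hits)],
                         granges(cars)[subjectHits(hits)],
                         ignore.strand = TRUE)
    owner <- subjectHits(hits)
    keep_p <- width(pieces) >= W
    pieces <- pieces[keep_p]; owner <- owner[keep_p]
    for (i in seq_along(cars)) {
      eligible <- pieces[owner == i]
      k <- sample(config$probes_per_car, 1)
      if (cars$true_class[i] == "inconsistent") k <- max(k, 2L)
      pr <- .sample_in_pool(k, W, eligible)
      placement <- ifelse(overlaps_any_nt(pr, spans, "ignore"),
                          "intronic", "intergenic")
      add_probe(pr, stratum = ifelse(placement == "intronic",
                                     "bona_fide_intronic",
                                     "bona_fide_intergenic"),
                placement = placement, car_id = cars$car_id[i])
    }
  }
  car_region <- if (length(cars)) cars + 60L else GRanges()

  # exons free of CAR overlap host exonic/antisense probes (probes in
  # CARs are planted separately so the consistency truth stays exact)
  free_ex <- if (length(exons)) {
    fe <- exons[width(exons) >= W]
    fe[!overlaps_any_nt(fe, car_region, "ignore")]
  } else GRanges()

  # --- converse-pair probes and their anchor genes -------------------
  pair_genes <- character(0)
  if (config$n_converse_pairs > 0) {
    if (!has_genes) stop("converse pairs need protein-coding genes")
    # per-gene flanking gaps from plain vectors, one candidate per gene;
    # the probe is placed closer to its anchor than to the neighbour so
    # the nearest protein-coding gene is the anchor by construction
    gd <- data.frame(gene_id = as.character(spans$gene_id),
                     chrom = as.character(seqnames(spans)),
                     start = start(spans), end = end(spans),
                     stringsAsFactors = FALSE)
    gd <- gd[order(gd$chrom, gd$start), ]
    n_g <- nrow(gd)
    same_prev <- c(FALSE, gd$chrom[-1] == gd$chrom[-n_g])
    gd$gap_left <- gd$start - ifelse(same_prev, c(0L, gd$end[-n_g]), 0L) - 1L
    nxt_start <- c(gd$start[-1], NA)
    same_next <- c(gd$chrom[-n_g] == gd$chrom[-1], FALSE)
    gd$gap_right <- ifelse(same_next, nxt_start - gd$end - 1L,
                           genome[gd$chrom] - gd$end)
    gd <- gd[gd$gene_id %in% free_ex$gene_id, ]
    gd <- gd[sample.int(nrow(gd)), ]
    dmin <- config$pair_distance[1]
    side_first <- sample(c("right", "left"), nrow(gd), replace = TRUE)
    cand_start <- integer(nrow(gd)); feasible <- logical(nrow(gd))
    for (i in seq_len(nrow(gd))) {
      for (side in unique(c(side_first[i], "right", "left"))) {
        gap <- if (side == "right") gd$gap_right[i] else gd$gap_left[i]
        dmax <- min(config$pair_distance[2], floor((gap - W) / 2) - 60L)
        if (dmax < dmin) next
        d <- dmin + sample.int(dmax - dmin + 1L, 1L) - 1L
        cand_start[i] <- if (side == "right") gd$end[i] + d + 1L else
          gd$start[i] - d - W
        feasible[i] <- TRUE
        break
      }
    }
    gd <- gd[feasible, ]; cand_start <- cand_start[feasible]
    cand <- GRanges(gd$chrom, IRanges(cand_start, width = W))
    occupied <- .c_gr(probe_list)
    bad <- overlaps_any_nt(cand, car_region, "ignore") |
      overlaps_any_nt(cand, occupied, "ignore")
    # drop candidates clashing with an earlier candidate
    hits <- suppressWarnings(findOverlaps(cand, cand, ignore.strand = TRUE))
    bad[unique(queryHits(hits)[queryHits(hits) > subjectHits(hits)])] <- TRUE
    keep <- which(!bad)
    if (length(keep) < config$n_converse_pairs) {
      stop("placement failure: could only anchor ", length(keep), " of ",
           config$n_converse_pairs, " converse pairs")
    }
    keep <- keep[seq_len(config$n_converse_pairs)]
    add_probe(cand[keep], stratum = "bona_fide_intergenic",
              placement = "intergenic", pair_gene = gd$gene_id[keep])
    pair_genes <- gd$gene_id[keep]
  }

  occupied <- .c_gr(lapply(probe_list, granges))

  # --- stratum probes -------------------------------------------------
  np <- config$n_probes
  # coding exonic: one probe per pair gene guaranteed, rest anywhere
  if (np[["coding_exonic"]] > 0 || length(pair_genes)) {
    big_ex <- free_ex
    if (!length(big_ex)) stop("placement failure: no exon can host a probe")
    gstrand <- setNames(as.character(strand(spans)),
                        as.character(spans$gene_id))
    n_left <- max(0L, np[["coding_exonic"]] - length(pair_genes))
    anchors <- GRanges()
    for (g in pair_genes) {
      ex <- big_ex[big_ex$gene_id == g]
      if (!length(ex)) stop("placement failure: pair gene ", g,
                            " has no exon hosting a probe")
      pr <- .sample_in_pool(1, W, ex)
      strand(pr) <- gstrand[[g]]
      anchors <- .c_gr(list(anchors, pr))
    }
    if (length(anchors)) {
      add_probe(anchors, "coding_exonic", "coding_exonic",
                strand_vec = as.character(strand(anchors)))
    }
    if (n_left > 0) {
      pr <- .sample_in_pool(n_left, W, big_ex)
      hostg <- nearest_protein_coding_gene(pr, models)$gene_id
      add_probe(pr, "coding_exonic", "coding_exonic",
                strand_vec = gstrand[hostg])
    }
  }
  # antisense: inside an exon, opposite strand
  if (np[["antisense"]] > 0) {
    big_ex <- free_ex
    pr <- .sample_in_pool(np[["antisense"]], W, big_ex)
    hostg <- nearest_protein_coding_gene(pr, models)$gene_id
    gstrand <- setNames(as.character(strand(spans)),
                        as.character(spans$gene_id))
    opp <- ifelse(gstrand[hostg] == "+", "-", "+")
    add_probe(pr, "antisense_noncoding", "antisense", strand_vec = opp)
    occupied <- c(occupied, granges(pr))
  }
  # intronic: inside introns, clear of exons and CARs
  if (np[["intronic"]] > 0) {
    pool <- GenomicRanges::setdiff(
    introns, .c_gr(list(granges(exons) + 60L, car_region)),
    ignore.strand = TRUE)
    pr <- .place_in_pool(np[["intronic"]], W, pool, avoid = occupied, pad = 80L)
    add_probe(pr, "bona_fide_intronic", "intronic")
    occupied <- .c_gr(list(occupied, granges(pr)))
  }
  # intergenic: clear of gene spans and CARs
  ig_pool <- GenomicRanges::setdiff(
    ggr, .c_gr(list(if (has_genes) granges(spans) + 60L else GRanges(),
                    car_region)),
    ignore.strand = TRUE)
  if (np[["intergenic"]] > 0) {
    pr <- .place_in_pool(np[["intergenic"]], W, ig_pool, avoid = occupied, pad = 80L)
    add_probe(pr, "bona_fide_intergenic", "intergenic")
    occupied <- .c_gr(list(occupied, granges(pr)))
  }

  probes <- .c_gr(probe_list)
  truth <- do.call(rbind, truth_list)
  truth$probe_id <- sprintf("P%05d", seq_len(nrow(truth)))
  probes$probe_id <- truth$probe_id
  probes$role <- "expression"
  probes$uniquely_mapped <- TRUE

  # --- planted filter exclusions -------------------------------------
  free <- which(truth$placement %in% c("intronic", "intergenic") &
                is.na(truth$car_id) & is.na(truth$pair_gene_id))
  n_ec <- round(config$exclude_coding_fraction * length(free))
  n_ep <- round(config$exclude_protein_fraction * length(free))
  pick <- sample(free, n_ec + n_ep)
  ec_idx <- utils::head(pick, n_ec)
  ep_idx <- utils::tail(pick, n_ep)
  truth$stratum[ec_idx] <- "excluded_coding_evidence"
  truth$stratum[ep_idx] <- "excluded_protein_similarity"

  # --- coding-evidence tracks ----------------------------------------
  seg_list <- list()
  if (length(exons)) {
    n_ex <- length(exons)
    sig_ex <- sample(n_ex, round(config$rnacode_sensitivity * n_ex))
    pex <- runif(n_ex, 0.055, 0.95)
    pex[sig_ex] <- runif(length(sig_ex), 1e-4, 0.045)
    seg_ex <- granges(exons)
    strand(seg_ex) <- strand(exons)
    seg_ex$p <- pex
    seg_list <- c(seg_list, list(seg_ex))
  }
  if (length(ec_idx)) {
    seg_pr <- granges(probes[ec_idx]) + 20L
    strand(seg_pr) <- strand(probes[ec_idx])
    seg_pr$p <- runif(length(ec_idx), 1e-4, 0.045)
    seg_list <- c(seg_list, list(seg_pr))
  }
  coding_segments <- if (length(seg_list)) .c_gr(seg_list) else {
    g <- GRanges(); g$p <- numeric(0); g
  }
  protein_hits <- if (length(ep_idx)) granges(probes[ep_idx]) + 20L else
    GRanges()
  # coverage mask: all segments (+pad) plus random chunks, minus the
  # protein-hit neighbourhoods (step 3 only applies outside the mask)
  chunk_list <- list()
  for (chr in names(genome)) {
    n_chunk <- max(1L, round(config$mask_fraction * genome[[chr]] / 5000))
    st <- sort(sample.int(genome[[chr]] - 5000L, n_chunk))
    chunk_list[[chr]] <- GRanges(chr, IRanges(st, width = 5000L))
  }
  chunks <- GenomicRanges::reduce(.c_gr(unname(chunk_list)))
  if (length(protein_hits)) {
    chunks <- GenomicRanges::setdiff(chunks, protein_hits + 40L,
                                     ignore.strand = TRUE)
  }
  mask <- GenomicRanges::reduce(.c_gr(list(
    chunks, if (length(coding_segments)) granges(coding_segments) + 50L
    else GRanges())), ignore.strand = TRUE)
  evidence <- coding_evidence(coding_segments, mask, protein_hits)

  # --- planted DE, subtype and CNV truth ------------------------------
  n <- nrow(truth)
  truth$true_de <- FALSE
  truth$de_sign <- 0L
  # CAR-committed probes
  if (length(cars)) {
    cls <- setNames(cars$true_class, cars$car_id)
    for (i in which(!is.na(truth$car_id))) {
      cl <- cls[[truth$car_id[i]]]
      if (cl == "consistent_down") {
        truth$true_de[i] <- TRUE; truth$de_sign[i] <- -1L
      } else if (cl == "consistent_up") {
        truth$true_de[i] <- TRUE; truth$de_sign[i] <- 1L
      }
    }
    for (cid in cars$car_id[cars$true_class == "inconsistent"]) {
      idx <- which(!is.na(truth$car_id) & truth$car_id == cid)
      sgn <- rep(c(-1L, 1L), length.out = length(idx))
      truth$true_de[idx] <- TRUE
      truth$de_sign[idx] <- sgn
    }
  }
  # converse pairs: probe one way, the gene's exonic probes the other
  pair_idx <- which(!is.na(truth$pair_gene_id))
  pair_sign <- sample(c(-1L, 1L), length(pair_idx), replace = TRUE)
  truth$true_de[pair_idx] <- TRUE
  truth$de_sign[pair_idx] <- pair_sign
  gene_sign <- setNames(-pair_sign, truth$pair_gene_id[pair_idx])
  if (length(pair_idx)) {
    ex_idx <- which(truth$placement == "coding_exonic")
    host <- nearest_protein_coding_gene(probes[ex_idx], models)$gene_id
    hit <- host %in% names(gene_sign)
    truth$true_de[ex_idx[hit]] <- TRUE
    truth$de_sign[ex_idx[hit]] <- gene_sign[host[hit]]
  }
  # free probes: stratum-wise planted DE
  committed <- !is.na(truth$car_id) | !is.na(truth$pair_gene_id) |
    (truth$placement == "coding_exonic" & truth$true_de)
  free2 <- which(!committed)
  de_pick <- free2[runif(length(free2)) < config$de_fraction]
  truth$true_de[de_pick] <- TRUE
  truth$de_sign[de_pick] <- sample(c(-1L, 1L), length(de_pick),
                                   replace = TRUE)
  # subtype (Basal) shift
  truth$subtype_de <- FALSE
  truth$subtype_sign <- 0L
  sub_pick <- which(runif(n) < config$subtype_de_fraction)
  truth$subtype_de[sub_pick] <- TRUE
  truth$subtype_sign[sub_pick] <- sample(c(-1L, 1L), length(sub_pick),
                                         replace = TRUE)
  # CNV-driven probes among uncommitted non-coding probes
  nc <- which(truth$placement %in% c("intronic", "intergenic", "antisense") &
              is.na(truth$car_id) & is.na(truth$pair_gene_id))
  n_noncoding <- sum(truth$placement %in%
                     c("intronic", "intergenic", "antisense"))
  n_cnv <- min(length(nc), round(config$cnv_driven_fraction * n_noncoding))
  truth$cnv_driven <- FALSE
  truth$cnv_driven[sample(nc, n_cnv)] <- TRUE

  # quiet CARs are planted as unexpressed: their probes sit at
  # negative-control background and fall to the nonspecific filter
  truth$expressed <- TRUE
  if (length(cars)) {
    quiet <- cars$car_id[cars$true_class == "not_significant"]
    truth$expressed[!is.na(truth$car_id) & truth$car_id %in% quiet] <- FALSE
  }

  # --- negative controls ---------------------------------------------
  if (config$n_negative_controls > 0) {
    ncp <- .place_in_pool(config$n_negative_controls, W, ig_pool,
                          avoid = occupied)
    strand(ncp) <- "*"
    ncp$probe_id <- sprintf("NEG%04d", seq_along(ncp))
    ncp$role <- "negative_control"
    ncp$uniquely_mapped <- TRUE
    probes <- .c_gr(list(probes, ncp))
  }

  # --- conservation summaries -----------------------------------------
  expr_idx <- which(probes$role == "expression")
  base <- ifelse(truth$placement == "coding_exonic", 0.7, 0.3)
  score <- pmin(1, pmax(0, base + rnorm(length(expr_idx), 0, 0.15)))
  conservation <- data.frame(probe_id = truth$probe_id, score = score,
                             stringsAsFactors = FALSE)

  truth <- truth[, c("probe_id", "stratum", "placement", "true_de",
                     "de_sign", "subtype_de", "subtype_sign", "cnv_driven",
                     "expressed", "car_id", "pair_gene_id")]
  list(probes = probes, evidence = evidence, truth = truth,
       conservation = conservation)
}

#' Simulate segmented copy-number profiles for tumor samples
#'
#' Per tumor sample and chromosome, a piecewise-constant log2-ratio
#' profile with `cnv_segments_per_chrom` segments and values
#' N(0, `cnv_segment_sd`); segments tile the chromosome without gaps.
#'
#' @param config `sim_config`.
#' @param genome named chromosome lengths.
#' @param tumor_ids character vector of tumor sample ids.
#' @return SEG-like data.frame (`sample_id`, `chrom`, `start`, `end`,
#'   `value`).
#' @export
simulate_cnv_profiles <- function(config, genome, tumor_ids) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  k <- config$cnv_segments_per_chrom
  rows <- list()
  for (s in tumor_ids) {
    for (chr in names(genome)) {
      L <- genome[[chr]]
      brk <- if (k > 1) sort(sample.int(L - 1L, k - 1L)) else integer(0)
      st <- c(1L, brk + 1L); en <- c(brk, L)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, chrom = chr, start = st, end = en,
        value = rnorm(k, 0, config$cnv_segment_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.sample_sheet <- function(config) {
  n_ids <- sprintf("N%02d", seq_len(config$n_normal))
  t_ids <- sprintf("T%02d", seq_len(config$n_tumor))
  subty <- rep(config$subtype_labels,
               length.out = config$n_tumor)
  ids <- c(n_ids, t_ids)
  data.frame(sample_id = ids,
             group = c(rep("normal", config$n_normal),
                       rep("tumor", config$n_tumor)),
             subtype = c(rep("none", config$n_normal), subty),
             batch = paste0("b", (seq_along(ids) - 1L) %% config$n_batches +
                              1L),
             stringsAsFactors = FALSE)
}

#' Simulate the log2 expression matrix
#'
#' Log2 intensity = per-probe baseline + planted tumor effect + planted
#' Basal subtype effect + batch offset + optional copy-number term
#' (`cnv_slope` x segment value, tumor samples of CNV-driven probes
#' only) + N(0, `noise_sd`).  Negative-control rows are pure background.
#' Probes committed to a CAR or a converse pair draw their baselines
#' from the upper half of the baseline distribution so the planted
#' pattern is expressed above background.
#'
#' @param config `sim_config`.
#' @param probes probe `GRanges` from [simulate_probe_set()].
#' @param truth truth table from [simulate_probe_set()].
#' @param seg optional SEG data.frame from [simulate_cnv_profiles()].
#' @return list with `expr` (matrix probes x samples) and `samples`
#'   (sample sheet).
#' @export
simulate_expression <- function(config, probes, truth, seg = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  sheet <- .sample_sheet(config)
  ids <- as.character(probes$probe_id)
  n <- length(ids); m <- nrow(sheet)
  ti <- match(truth$probe_id, ids)
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  committed <- ti[!is.na(truth$car_id) | !is.na(truth$pair_gene_id) |
                    (truth$true_de & truth$placement == "coding_exonic")]
  baseline[committed] <- config$baseline_mean +
    abs(rnorm(length(committed), 0, config$baseline_sd))
  eff <- numeric(n)
  eff[ti] <- truth$de_sign * truth$true_de * config$de_effect
  sub_eff <- numeric(n)
  sub_eff[ti] <- truth$subtype_sign * truth$subtype_de *
    config$subtype_effect
  is_tumor <- sheet$group == "tumor"
  is_basal <- sheet$subtype == "Basal"
  boff <- config$batch_effect *
    (as.integer(factor(sheet$batch)) - 1L)
  expr <- matrix(baseline, n, m) +
    outer(eff, as.numeric(is_tumor)) +
    outer(sub_eff, as.numeric(is_basal)) +
    matrix(boff, n, m, byrow = TRUE) +
    matrix(rnorm(n * m, 0, config$noise_sd), n, m)
  if (!is.null(seg) && config$cnv_slope != 0) {
    drv <- truth$probe_id[truth$cnv_driven]
    if (length(drv)) {
      di <- match(drv, ids)
      cn <- cnv_matrix(seg, probes[di],
                       samples = sheet$sample_id[is_tumor])
      expr[di, is_tumor] <- expr[di, is_tumor] + config$cnv_slope * cn
    }
  }
  if ("expressed" %in% names(truth)) {
    off <- ti[!truth$expressed]
    if (length(off)) {
      expr[off, ] <- rnorm(length(off) * m, config$background_mean,
                           config$background_sd)
    }
  }
  negs <- which(probes$role == "negative_control")
  if (length(negs)) {
    expr[negs, ] <- rnorm(length(negs) * m, config$background_mean,
                          config$background_sd)
  }
  dimnames(expr) <- list(ids, sheet$sample_id)
  list(expr = expr, samples = sheet)
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_genome_annotation()], [simulate_probe_set()],
#' [simulate_cnv_profiles()] and [simulate_expression()] under one seed
#' and assembles gene sets for over-representation testing.
#'
#' @param config `sim_config`.
#' @return list with `genome`, `models`, `tracks`, `probes`, `evidence`,
#'   `truth`, `car_truth`, `conservation`, `expr`, `samples`, `seg`,
#'   `gene_sets`.
#' @export
simulate_study <- function(config = sim_config()) {
  ga <- simulate_genome_annotation(config)
  ps <- simulate_probe_set(config, ga)
  sheet <- .sample_sheet(config)
  seg <- simulate_cnv_profiles(config, ga$genome,
                               sheet$sample_id[sheet$group == "tumor"])
  ex <- simulate_expression(config, ps$probes, ps$truth, seg)
  set.seed(config$seed + 4L)
  gids <- as.character(ga$models$genes$gene_id)
  gene_sets <- list()
  if (length(gids) >= 10) {
    grp <- split(sample(gids), ceiling(seq_along(gids) / 10))
    names(grp) <- sprintf("SET%02d", seq_along(grp))
    # one set deliberately enriched for genes anchoring converse pairs
    pg <- unique(ps$truth$pair_gene_id[!is.na(ps$truth$pair_gene_id)])
    if (length(pg)) {
      grp$SET_PAIR_ANCHORS <- unique(c(
        pg, sample(gids, min(5, length(gids)))))
    }
    gene_sets <- grp
  }
  list(genome = ga$genome, models = ga$models, tracks = ga$tracks,
       probes = ps$probes, evidence = ps$evidence, truth = ps$truth,
       car_truth = ga$car_truth, conservation = ps$conservation,
       expr = ex$expr, samples = ex$samples, seg = seg,
       gene_sets = gene_sets, config = config)
}

#' Write a simulated study to disk
#'
#' Writes every input the pipeline consumes as plain text: chromosome
#' sizes, gene models (GFF3), probe table (BED6+2), annotation and
#' coding-evidence tracks (BED6, with the segment p-value / hit e-value
#' in the score column), expression matrix, sample sheet, SEG profiles,
#' gene sets (GMT), conservation summaries and the truth table.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_chrom_sizes(sim$genome, fp("genome.chrom.sizes"))
  write_gene_models_gff3(sim$models, fp("genes.gff3"))
  write_probe_bed(sim$probes, fp("probes.bed"))
  for (nm in names(sim$tracks)) {
    tr <- sim$tracks[[nm]]
    if (nm == "cars") tr$name <- tr$car_id
    write_bed(tr, fp(paste0("track_", nm, ".bed")))
  }
  segs <- sim$evidence$coding_segments
  segs$name <- sprintf("seg%05d", seq_along(segs))
  segs$score <- segs$p
  write_bed(segs, fp("coding_segments.bed"))
  write_bed(sim$evidence$coverage_mask, fp("coverage_mask.bed"))
  ph <- sim$evidence$protein_hits
  if (length(ph)) ph$name <- sprintf("hit%05d", seq_along(ph))
  write_bed(ph, fp("protein_hits.bed"))
  write_expression_matrix(sim$expr, fp("expression.tsv"))
  write_sample_sheet(sim$samples, fp("samples.tsv"))
  write_seg(sim$seg, fp("cnv.seg"))
  write_gmt(sim$gene_sets, fp("gene_sets.gmt"))
  write_conservation(sim$conservation, fp("conservation.tsv"))
  write_truth_table(sim$truth, fp("truth.tsv"))
  invisible(dir)
}
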