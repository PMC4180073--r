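# shared fixtures and independent oracles

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# reduced study used by unit tests (fast; same structure as the default)
small_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed,
                   n_chroms = 2, chrom_length = 4e5,
                   n_protein_coding = 40, n_lncRNA = 10,
                   n_probes = c(coding_exonic = 150, intronic = 150,
                                intergenic = 150, antisense = 60),
                   n_negative_controls = 40,
                   car_pattern = c(consistent_down = 6, consistent_up = 4,
                                   inconsistent = 2, not_significant = 3),
                   n_converse_pairs = 5,
                   n_repeats = 80)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# one small simulated study per session, shared across tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(small_config())
    cache
  }
})

# quadratic all-pairs oracle for interval overlap queries (0 strand logic)
oracle_any_nt <- function(query, track) {
  qs <- start(query); qe <- end(query); qc <- as.character(seqnames(query))
  ts <- start(track); te <- end(track); tc <- as.character(seqnames(track))
  vapply(seq_along(query), function(i) {
    any(tc == qc[i] & ts <= qe[i] & te >= qs[i])
  }, logical(1))
}

oracle_max_fraction <- function(query, track) {
  qs <- start(query); qe <- end(query); qc <- as.character(seqnames(query))
  vapply(seq_along(query), function(i) {
    ov <- pmax(0, pmin(qe[i], end(track)) - pmax(qs[i], start(track)) + 1)
    ov[as.character(seqnames(track)) != qc[i]] <- 0
    if (!length(ov)) 0 else max(ov) / (qe[i] - qs[i] + 1)
  }, numeric(1))
}

# brute-force nearest protein-coding gene over gene spans
oracle_nearest <- function(query, spans) {
  ids <- as.character(spans$gene_id)
  vapply(seq_along(query), function(i) {
    same <- as.character(seqnames(spans)) == as.character(seqnames(query))[i]
    if (!any(same)) return(Inf)
    d <- pmax(0, pmax(start(spans) - end(query)[i],
                      start(query)[i] - end(spans)) - 1)
    min(d[same])
  }, numeric(1))
}

# exact two-sided Fisher p by full enumeration of the hypergeometric
# support, summing tables at most as probable as the observed one
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n, k)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# step-up FDR adjustment written independently of p.adjust
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
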