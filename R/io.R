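# File formats.  Parsing of BED and GFF3 is delegated to rtracklayer;
# writers are deliberately minimal fixed-format serialisers so that a
# write -> read -> write cycle is byte-identical (required for
# reproducible pipeline runs).  Coordinates are GRanges (1-based closed)
# in memory; BED files are 0-based half-open on disk as usual.

.fmt_num <- function(x) {
  # fixed 6-decimal format; survives read/write round trips bit-identically
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}

#' Read a BED track
#'
#' @param path BED file (3-6 columns, or more via `extra_cols`).
#' @param extra_cols named character vector passed to
#'   [rtracklayer::import()] `extraCols` for BED6+N files.
#' @return `GRanges`; BED strand `.` becomes `*` (unknown).
#' @export
read_bed <- function(path, extra_cols = NULL) {
  if (is.null(extra_cols)) {
    rtracklayer::import(path, format = "BED")
  } else {
    rtracklayer::import(path, format = "BED", extraCols = extra_cols)
  }
}

#' Write a BED6(+N) track
#'
#' @param gr `GRanges`; `name` metadata column becomes BED name (or the
#'   `name_col` column), `score` the score (0 when absent); strand `*`
#'   is written as `.`.
#' @param path output file.
#' @param name_col metadata column used for the BED name field.
#' @param extra_cols metadata columns appended after the strand field.
#' @export
write_bed <- function(gr, path, name_col = "name", extra_cols = character(0)) {
  nm <- if (name_col %in% names(mcols(gr))) as.character(mcols(gr)[[name_col]])
        else rep(".", length(gr))
  nm[is.na(nm)] <- "." 
  sc <- if ("score" %in% names(mcols(gr))) mcols(gr)$score else
        rep(0, length(gr))
  sc <- ifelse(is.na(sc), "0", ifelse(sc == round(sc) & abs(sc) < 1e9,
               sprintf("%d", as.integer(round(sc))), .fmt_num(sc)))
  st <- as.character(strand(gr)); st[st == "*"] <- "."
  fields <- list(as.character(seqnames(gr)), start(gr) - 1L, end(gr), nm, sc,
                 st)
  for (cc in extra_cols) {
    v <- mcols(gr)[[cc]]
    fields <- c(fields, list(if (is.numeric(v) && !is.integer(v))
      .fmt_num(v) else as.character(v)))
  }
  lines <- do.call(paste, c(fields, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression probe table (BED6 + role + mapping flag)
#'
#' @param path BED6+2 file with columns 7 (`role`) and 8
#'   (`uniquely_mapped`).
#' @return `GRanges` with `probe_id`, `role`, `uniquely_mapped`.
#' @export
read_probe_bed <- function(path) {
  gr <- read_bed(path, extra_cols = c(role = "character",
                                      uniquely_mapped = "logical"))
  gr$probe_id <- gr$name
  gr$name <- NULL
  gr$score <- NULL
  gr
}

#' Write an expression probe table
#'
#' @param probes `GRanges` with `probe_id`, `role`, `uniquely_mapped`.
#' @param path output BED6+2 file.
#' @export
write_probe_bed <- function(probes, path) {
  probes$name <- probes$probe_id
  write_bed(probes, path, extra_cols = c("role", "uniquely_mapped"))
}

#' Write gene models as GFF3
#'
#' One `gene` feature per gene (attributes `ID`, `Name`, `biotype`) and
#' one `exon` feature per exon (`Parent`).
#'
#' @param models `gene_models` object.
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(models, path) {
  g <- models$genes
  lines <- c("##gff-version 3")
  for (i in seq_along(g)) {
    gid <- as.character(g$gene_id[i])
    lines <- c(lines, paste(
      as.character(seqnames(g))[i], "lncarray", "gene", start(g)[i], end(g)[i],
      ".", as.character(strand(g))[i], ".",
      sprintf("ID=%s;Name=%s;biotype=%s", gid, g$name[i], g$biotype[i]),
      sep = "\t"))
    ex <- models$exons[[gid]]
    for (j in seq_along(ex)) {
      lines <- c(lines, paste(
        as.character(seqnames(ex))[j], "lncarray", "exon",
        start(ex)[j], end(ex)[j], ".", as.character(strand(ex))[j], ".",
        sprintf("ID=%s.exon%d;Parent=%s", gid, j, gid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features with `ID`/`Name`/`biotype` attributes and
#' `exon` features with `Parent`.
#'
#' @param path GFF3 file.
#' @return `gene_models` object.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  parent <- vapply(exons$Parent, function(p) as.character(p)[1], "")
  g <- granges(genes)
  mcols(g) <- DataFrame(gene_id = as.character(genes$ID),
                        name = as.character(genes$Name),
                        biotype = as.character(genes$biotype))
  ex_by <- split(granges(exons), factor(parent, levels = g$gene_id))
  gene_models(g, methods::as(ex_by, "GRangesList"))
}

#' Read/write two-column chromosome sizes
#' @param path TSV with columns chrom, length (no header).
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "length"),
                  colClasses = c("character", "integer"))
  setNames(d$length, d$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

#' Read/write a log2 expression matrix
#'
#' TSV with probes as rows; first column `probe_id`, remaining columns
#' one per sample.
#'
#' @param path TSV file.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param mat numeric matrix (probes x samples).
#' @export
write_expression_matrix <- function(mat, path) {
  header <- paste(c("probe_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], .fmt_num(mat[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write the sample sheet
#'
#' TSV with columns `sample_id`, `group` (normal/tumor), `subtype`
#' (PAM50 label or `none` for normals) and `batch`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character")
}

#' @rdname read_sample_sheet
#' @param sheet data.frame with the four columns above.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write segmented copy-number profiles (SEG-like TSV)
#'
#' Columns `sample_id`, `chrom`, `start`, `end` (1-based closed, matching
#' the in-memory convention) and `value` (mean log2 copy-number ratio of
#' the segment).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_seg <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "integer", "integer",
                            "numeric"))
}

#' @rdname read_seg
#' @param seg data.frame with the five columns above.
#' @export
write_seg <- function(seg, path) {
  lines <- c(paste(c("sample_id", "chrom", "start", "end", "value"),
                   collapse = "\t"),
             paste(seg$sample_id, seg$chrom, as.integer(seg$start),
                   as.integer(seg$end), .fmt_num(seg$value), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene ids.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the simulation truth table
#'
#' @param path TSV file.
#' @return data.frame (logical columns restored).
#' @export
read_truth_table <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  na.strings = "NA")
  for (cc in c("true_de", "cnv_driven", "subtype_de", "expressed")) {
    if (cc %in% names(d)) d[[cc]] <- as.logical(d[[cc]])
  }
  d
}

#' @rdname read_truth_table
#' @param truth data.frame as produced by [simulate_study()].
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read per-probe conservation summaries
#'
#' @param path TSV with columns `probe_id`, `score` (mean per-base
#'   conservation in \[0,1\]).
#' @return data.frame.
#' @export
read_conservation <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c("character", "numeric"))
}

#' @rdname read_conservation
#' @param cons data.frame with columns `probe_id`, `score`.
#' @export
write_conservation <- function(cons, path) {
  lines <- c("probe_id\tscore",
             paste(cons$probe_id, .fmt_num(cons$score), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
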