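## Transcript models and amplicon definitions (models_io).
##
## Internally every genomic coordinate is 0-based half-open (BED semantics);
## only user-facing reports convert to 1-based inclusive. Exons are stored
## sorted by genomic coordinate and numbered 1..n in transcript (biological)
## order, so for a minus-strand transcript exon 1 is the rightmost interval.

#' Construct a transcript model
#'
#' @param gene_symbol gene symbol (display only).
#' @param transcript_id transcript accession, e.g. with version.
#' @param chrom chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open
#'   genomic intervals) in any order; exon numbers are assigned in
#'   transcript orientation.
#' @param cds_start,cds_end optional genomic CDS bounds (0-based).
#' @return An object of class `transcript_model` whose `$exons` data.frame
#'   (columns `exon`, `start`, `end`) is sorted by genomic coordinate.
#' @examples
#' m <- transcript_model("GENE", "TX.1", "chr1", "+",
#'                       data.frame(start = c(0, 200), end = c(100, 300)))
#' m$exons
#' @export
transcript_model <- function(gene_symbol, transcript_id, chrom, strand,
                             exons, cds_start = NA, cds_end = NA) {
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  n <- nrow(exons)
  if (n < 2L) stopf("a transcript model needs at least 2 exons")
  if (any(exons$end <= exons$start)) stopf("empty exon interval")
  if (any(exons$start[-1] - exons$end[-n] < 1L))
    stopf("exons overlap or abut: introns must be at least 1 bp")
  exons$exon <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  m <- structure(list(gene_symbol = gene_symbol,
                      transcript_id = transcript_id,
                      chrom = chrom, strand = strand,
                      exons = exons[, c("exon", "start", "end")],
                      cds_start = cds_start, cds_end = cds_end),
                 class = "transcript_model")
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s], %d exons\n",
              x$transcript_id, x$gene_symbol %||% "?", x$chrom,
              to1(min(x$exons$start)), max(x$exons$end), x$strand,
              nrow(x$exons)))
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

## genomic interval of exon number k (transcript order)
exon_interval <- function(model, k) {
  row <- model$exons[model$exons$exon == k, ]
  if (nrow(row) != 1L) stopf("no exon %d in %s", k, model$transcript_id)
  c(start = row$start, end = row$end)
}

#' Canonical exon-exon junctions of a model (optionally within an amplicon)
#'
#' Junctions are `(donor_end, acceptor_start)` pairs in genomic coordinates:
#' `donor_end` is the half-open end of the upstream-in-genome exon (equal to
#' the 1-based position of its last base) and `acceptor_start` the 0-based
#' start of the next exon. Ordering is genomic.
#'
#' @param model a `transcript_model`.
#' @param amplicon optional `amplicon`; restricts to junctions between the
#'   amplicon's exons.
#' @return data.frame with columns `donor_end`, `acceptor_start`.
#' @export
canonical_junctions <- function(model, amplicon = NULL) {
  ex <- model$exons
  if (!is.null(amplicon)) {
    keep <- ex$exon >= amplicon$first_exon & ex$exon <= amplicon$last_exon
    ex <- ex[keep, , drop = FALSE]
  }
  n <- nrow(ex)
  data.frame(donor_end = ex$end[-n], acceptor_start = ex$start[-1])
}

#' Define an amplicon over a transcript model
#'
#' An amplicon spans a contiguous exon range (the exons the RT-PCR primers
#' enclose). Primer offsets within the first/last exon are deliberately not
#' modeled: reads are only required to begin and end within those exons, and
#' junction logic never depends on exact primer ends.
#'
#' @param model a `transcript_model`.
#' @param first_exon,last_exon exon numbers (transcript order) spanned by the
#'   primers, `1 <= first_exon < last_exon <= n`.
#' @param expected_wt_length optional expected wild-type fragment length; if
#'   given it must equal the summed lengths of the included exons.
#' @return An object of class `amplicon`.
#' @export
amplicon <- function(model, first_exon, last_exon, expected_wt_length = NULL) {
  n <- n_exons(model)
  if (!(first_exon >= 1L && first_exon < last_exon && last_exon <= n))
    stopf("need 1 <= first_exon < last_exon <= %d", n)
  keep <- model$exons$exon >= first_exon & model$exons$exon <= last_exon
  wt <- sum(model$exons$end[keep] - model$exons$start[keep])
  if (!is.null(expected_wt_length) && expected_wt_length != wt)
    stopf("expected_wt_length %d != summed exon lengths %d",
          expected_wt_length, wt)
  structure(list(model = model, first_exon = as.integer(first_exon),
                 last_exon = as.integer(last_exon),
                 expected_wt_length = expected_wt_length %||% wt),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s exons %d-%d (WT %d bp)\n",
              x$model$transcript_id, x$first_exon, x$last_exon,
              x$expected_wt_length))
  invisible(x)
}

## 0-based half-open genomic span covered by the amplicon's exon range
## (including the introns between them).
amplicon_span <- function(amp) {
  keep <- amp$model$exons$exon >= amp$first_exon &
    amp$model$exons$exon <= amp$last_exon
  c(start = min(amp$model$exons$start[keep]),
    end = max(amp$model$exons$end[keep]))
}

## exons (genomically sorted data.frame) included in the amplicon
amplicon_exons <- function(amp) {
  ex <- amp$model$exons
  ex[ex$exon >= amp$first_exon & ex$exon <= amp$last_exon, , drop = FALSE]
}

#' Load a transcript model from BED12 or GFF3
#'
#' BED12 blocks become exons directly (BED is already 0-based half-open).
#' The BED name field may be `gene:transcript_id` or a bare transcript id.
#' For GFF3, `exon` features are grouped by `Parent` and matched against
#' `transcript_id`. Exon numbering follows transcript orientation, so a
#' minus-strand model's exon 1 is the genomically rightmost exon.
#'
#' @param path file path.
#' @param format `"BED12"` or `"GFF3"`.
#' @param transcript_id transcript to select; may be `NULL` for a
#'   single-record BED12 file.
#' @return A `transcript_model`.
#' @export
load_transcript_model <- function(path, format = c("BED12", "GFF3"),
                                  transcript_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "BED12") load_model_bed12(path, transcript_id)
  else load_model_gff3(path, transcript_id)
}

load_model_bed12 <- function(path, transcript_id) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stopf("parse error in %s, line %d: expected 12 BED fields, got %d",
          path, which(nf < 12L)[1], nf[nf < 12L][1])
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stopf("parse error in %s: %s",
                                           path, conditionMessage(e)))
  nm <- as.character(gr$name)
  idx <- if (is.null(transcript_id)) {
    if (length(gr) != 1L)
      stopf("%d BED12 records; give transcript_id to select one", length(gr))
    1L
  } else {
    hit <- which(nm == transcript_id |
                   vapply(strsplit(nm, ":", fixed = TRUE),
                          function(p) p[length(p)] == transcript_id,
                          logical(1)))
    if (length(hit) != 1L) stopf("unknown transcript_id '%s'", transcript_id)
    hit
  }
  rec <- gr[idx]
  blocks <- gr$blocks[[idx]]  # IRanges, 1-based, relative to chromStart
  rel <- sort(BiocGenerics::start(blocks))
  if (is.unsorted(BiocGenerics::start(blocks)))
    stopf("parse error in %s, line %d: blockStarts unsorted", path, idx)
  abs_start <- BiocGenerics::start(rec) - 1L + BiocGenerics::start(blocks) - 1L
  abs_end <- abs_start + BiocGenerics::width(blocks)
  name <- nm[idx]
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  gene <- if (length(parts) == 2L) parts[1] else NA_character_
  txid <- if (length(parts) == 2L) parts[2] else name
  thick <- gr$thick[idx]
  cds_s <- BiocGenerics::start(thick) - 1L
  cds_e <- BiocGenerics::end(thick)
  has_cds <- !is.na(cds_s) && cds_e > cds_s
  transcript_model(gene, txid, as.character(GenomicRanges::seqnames(rec)),
                   as.character(BiocGenerics::strand(rec)),
                   data.frame(start = abs_start, end = abs_end),
                   cds_start = if (has_cds) cds_s else NA,
                   cds_end = if (has_cds) cds_e else NA)
}

load_model_gff3 <- function(path, transcript_id) {
  if (is.null(transcript_id))
    stopf("transcript_id is required for GFF3 input")
  gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                 error = function(e) stopf("parse error in %s: %s",
                                           path, conditionMessage(e)))
  ex <- gr[tolower(gr$type) == "exon"]
  parent <- vapply(as.list(ex$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  hit <- !is.na(parent) &
    (parent == transcript_id | sub("^transcript:", "", parent) == transcript_id)
  ex <- ex[hit]
  if (length(ex) == 0L) stopf("unknown transcript_id '%s'", transcript_id)
  gene <- NA_character_
  for (key in c("gene_name", "gene", "gene_id"))
    if (key %in% names(S4Vectors::mcols(ex))) {
      v <- S4Vectors::mcols(ex)[[key]]
      v <- unlist(v)
      if (length(v) && !is.na(v[1])) { gene <- as.character(v[1]); break }
    }
  transcript_model(gene, transcript_id,
                   as.character(GenomicRanges::seqnames(ex))[1],
                   as.character(BiocGenerics::strand(ex))[1],
                   data.frame(start = BiocGenerics::start(ex) - 1L,
                              end = BiocGenerics::end(ex)))
}

#' Write a transcript model as one BED12 record
#'
#' Round-trips with [load_transcript_model()]: the name field is written as
#' `gene:transcript_id` (or the bare id when no gene symbol is set).
#'
#' @param model a `transcript_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(model, path) {
  ex <- model$exons  # genomically sorted
  chrom_start <- min(ex$start)
  chrom_end <- max(ex$end)
  name <- if (is.na(model$gene_symbol) || is.null(model$gene_symbol))
    model$transcript_id else paste0(model$gene_symbol, ":", model$transcript_id)
  thick_s <- if (is.na(model$cds_start)) chrom_start else model$cds_start
  thick_e <- if (is.na(model$cds_end)) chrom_start else model$cds_end
  line <- paste(model$chrom, chrom_start, chrom_end, name, 0, model$strand,
                thick_s, thick_e, "0,0,0", nrow(ex),
                paste0(paste(ex$end - ex$start, collapse = ","), ","),
                paste0(paste(ex$start - chrom_start, collapse = ","), ","),
                sep = "\t")
  writeLines(line, path)
  invisible(path)
}
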