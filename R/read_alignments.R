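## In-memory form of spliced long-read alignments (splice_analysis).
##
## A `read_set` holds one BAM's reads column-wise (id, 0-based position,
## CIGAR, sequence, RQ). Alignment geometry (aligned blocks, skip junctions,
## insertion operations, query offsets) is derived once per unique
## (position, CIGAR) pair — reads sharing an alignment shape share their
## geometry, which keeps per-read work flat in deep amplicon data where a
## handful of isoform shapes dominate.

#' Load spliced read alignments from BAM
#'
#' @param bam path to a BAM file.
#' @param rq_tag name of the float tag carrying per-read quality (default
#'   `"rq"`); reads lacking the tag get `NA`.
#' @param region optional `GRanges`-style restriction (unused by default).
#' @return object of class `read_set` with fields `read_id`, `chrom`,
#'   `pos0`, `cigar`, `seq` ([Biostrings::DNAStringSet]), `rq`.
#' @export
read_alignments <- function(bam, rq_tag = "rq", region = NULL) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq"),
    tag = rq_tag,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  rq <- b$tag[[rq_tag]]
  if (is.null(rq)) rq <- rep(NA_real_, length(b$qname))
  new_read_set(read_id = b$qname, chrom = as.character(b$rname),
               pos0 = b$pos - 1L, cigar = b$cigar, seq = b$seq, rq = rq)
}

new_read_set <- function(read_id, chrom, pos0, cigar, seq, rq) {
  structure(list(read_id = read_id, chrom = chrom, pos0 = pos0,
                 cigar = cigar, seq = seq, rq = rq),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$read_id)

#' @export
`[.read_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$read_id)
  new_read_set(x$read_id[i], x$chrom[i], x$pos0[i], x$cigar[i],
               x$seq[i], x$rq[i])
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads on %s\n", length(x),
              paste(unique(x$chrom), collapse = ",")))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Geometry: one entry per unique (pos0, cigar).
##
## Returns list(key (per read), geoms (named list)); each geom has
##   blocks  : matrix [start, end) 0-based, genomically sorted
##   qstart  : 1-based query offset of each block's first base
##   skips   : matrix (donor_end, acceptor_start)
##   ins     : data.frame(boundary, qpos (1-based query start), len)
read_geometry <- function(reads) {
  key <- paste(reads$pos0, reads$cigar, sep = "@")
  ukey <- !duplicated(key)
  upos <- reads$pos0[ukey]; ucig <- reads$cigar[ukey]; uk <- key[ukey]
  ops <- GenomicAlignments::explodeCigarOps(ucig)
  lens <- GenomicAlignments::explodeCigarOpLengths(ucig)
  geoms <- vector("list", length(uk)); names(geoms) <- uk
  for (g in seq_along(uk)) {
    op <- ops[[g]]; ln <- lens[[g]]
    rpos <- upos[g]; qpos <- 0L
    bl_s <- integer(0); bl_e <- integer(0); bl_q <- integer(0)
    open <- FALSE
    ins_b <- integer(0); ins_q <- integer(0); ins_l <- integer(0)
    for (t in seq_along(op)) {
      o <- op[t]; l <- ln[t]
      if (o %in% c("M", "=", "X")) {
        if (!open) { bl_s <- c(bl_s, rpos); bl_q <- c(bl_q, qpos + 1L); open <- TRUE }
        rpos <- rpos + l; qpos <- qpos + l
      } else if (o == "D") {
        if (!open) { bl_s <- c(bl_s, rpos); bl_q <- c(bl_q, qpos + 1L); open <- TRUE }
        rpos <- rpos + l
      } else if (o == "N") {
        if (open) { bl_e <- c(bl_e, rpos); open <- FALSE }
        rpos <- rpos + l
      } else if (o == "I") {
        ins_b <- c(ins_b, rpos); ins_q <- c(ins_q, qpos + 1L)
        ins_l <- c(ins_l, l)
        qpos <- qpos + l
      } else if (o %in% c("S", "H", "P")) {
        if (o == "S") qpos <- qpos + l
      }
    }
    if (open) bl_e <- c(bl_e, rpos)
    blocks <- cbind(start = bl_s, end = bl_e)
    nb <- nrow(blocks)
    skips <- if (nb >= 2L)
      cbind(donor_end = bl_e[-nb], acceptor_start = bl_s[-1]) else
      cbind(donor_end = integer(0), acceptor_start = integer(0))
    geoms[[g]] <- list(blocks = blocks, qstart = bl_q, skips = skips,
                       ins = data.frame(boundary = ins_b, qpos = ins_q,
                                        len = ins_l))
  }
  list(key = key, geoms = geoms)
}

#' Extract a read's exon-junction chain
#'
#' Returns the read's skip (intron) operations as genomically sorted
#' `(donor_end, acceptor_start)` pairs — the read's splicing fingerprint.
#' A single-block (unspliced) read yields a 0-row result.
#'
#' @param read a `read_set` of length 1 (subset with `[`).
#' @return data.frame with columns `donor_end`, `acceptor_start` (0-based
#'   half-open convention: `donor_end` equals the 1-based position of the
#'   donor exon's last base).
#' @export
extract_junction_chain <- function(read) {
  stopifnot(inherits(read, "read_set"))
  if (length(read) != 1L) stopf("extract_junction_chain expects a single read")
  g <- read_geometry(read)$geoms[[1]]
  as.data.frame(g$skips)
}

## Per-read base at an arbitrary genomic position (NA when not covered by an
## aligned block). Vectorized over reads; `pos0` is a scalar.
base_at <- function(reads, pos0, geometry = NULL) {
  if (is.null(geometry)) geometry <- read_geometry(reads)
  out <- rep(NA_character_, length(reads))
  for (k in names(geometry$geoms)) {
    g <- geometry$geoms[[k]]
    hit <- which(g$blocks[, "start"] <= pos0 & pos0 < g$blocks[, "end"])
    if (!length(hit)) next
    qp <- g$qstart[hit[1]] + (pos0 - g$blocks[hit[1], "start"])
    idx <- which(geometry$key == k)
    out[idx] <- as.character(Biostrings::subseq(reads$seq[idx], qp, qp))
  }
  out
}

## Observed bases at each marker for each read: matrix reads x markers.
marker_bases <- function(reads, markers, geometry = NULL) {
  if (is.null(geometry)) geometry <- read_geometry(reads)
  m <- vapply(seq_len(nrow(markers)), function(t)
    base_at(reads, markers$pos[t], geometry), character(length(reads)))
  if (!is.matrix(m)) m <- matrix(m, nrow = length(reads))
  colnames(m) <- sprintf("%s:%d", markers$chrom, to1(markers$pos))
  m
}

#' Filter reads by per-read quality (RQ)
#'
#' Retains reads with `rq >= threshold` — the HiFi criterion at the default
#' threshold 0.99. Reads lacking an RQ tag are retained with a warning and
#' counted separately (attribute `rq_missing`); attribute `rq_dropped`
#' counts the discarded reads.
#'
#' @param reads a `read_set`.
#' @param threshold RQ threshold in `[0, 1]`, default 0.99.
#' @return the filtered `read_set`.
#' @export
filter_by_rq <- function(reads, threshold = 0.99) {
  if (threshold < 0 || threshold > 1) stopf("threshold must lie in [0, 1]")
  missing_rq <- is.na(reads$rq)
  if (any(missing_rq))
    warnf("%d read(s) lack an RQ tag; retained and counted separately",
          sum(missing_rq))
  keep <- missing_rq | reads$rq >= threshold
  out <- reads[which(keep)]
  attr(out, "rq_missing") <- sum(missing_rq)
  attr(out, "rq_dropped") <- sum(!keep)
  out
}
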