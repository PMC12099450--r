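## Novel-sequence (mobile-element) insertion analysis: event collection,
## consensus building, element identification by local alignment, genomic
## breakpoint decomposition, and donor-motif scanning.

## Fixed local-alignment scoring (configurable through sw_align): match +2,
## mismatch -3, affine gaps costing (5 + 2 * length). The scoring mirrors
## common nucleotide-BLAST-style parameters; exact published parameters for
## the original analysis are unavailable.
sw_align <- function(pattern, subject, match = 2, mismatch = -3,
                     gap_opening = 5, gap_extension = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(pattern, subject, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = gap_opening,
                                gapExtension = gap_extension)
}

aln_identity <- function(aln) {
  ins_w <- sum(Biostrings::width(Biostrings::insertion(aln)[[1]]))
  del_w <- sum(Biostrings::width(Biostrings::deletion(aln)[[1]]))
  cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) + ins_w + del_w
  100 * Biostrings::nmatch(aln) / cols
}

#' Identify the origin of an inserted sequence against an element library
#'
#' Smith-Waterman local alignment (match +2, mismatch -3, gap open -5, gap
#' extend -2) of the consensus against every library element in both
#' orientations; the best-scoring hit is returned with
#' `percent_identity = matches / alignment columns x 100`. Reverse hits are
#' found by aligning the reverse complement of the consensus; spans are
#' reported on both the element and the consensus (consensus-forward
#' coordinates).
#'
#' @param consensus inserted nucleotide string (non-empty).
#' @param library named [Biostrings::DNAStringSet] (see
#'   [load_element_library()]).
#' @param min_score score threshold below which an explicit no-hit result is
#'   returned (default 30).
#' @return list of class `element_hit`: `hit` (logical), and when `TRUE`:
#'   `element`, `percent_identity`, `element_span`, `consensus_span`
#'   (1-based inclusive), `orientation` (`"forward"`/`"reverse"`), `score`.
#' @export
identify_element <- function(consensus, library, min_score = 30) {
  if (!nzchar(consensus)) stopf("empty consensus sequence")
  if (length(library) == 0L) stopf("empty element library")
  L <- nchar(consensus)
  rc <- reverse_complement(consensus)
  best <- NULL
  for (e in seq_along(library)) {
    subject <- library[[e]]
    for (ori in c("forward", "reverse")) {
      pat <- if (ori == "forward") consensus else rc
      aln <- sw_align(pat, subject)
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$score) {
        ps <- c(Biostrings::start(Biostrings::pattern(aln)),
                Biostrings::end(Biostrings::pattern(aln)))
        cons_span <- if (ori == "forward") ps else c(L - ps[2] + 1L, L - ps[1] + 1L)
        best <- list(element = names(library)[e],
                     percent_identity = aln_identity(aln),
                     element_span = c(Biostrings::start(Biostrings::subject(aln)),
                                      Biostrings::end(Biostrings::subject(aln))),
                     consensus_span = cons_span,
                     orientation = ori, score = sc)
      }
    }
  }
  if (best$score < min_score)
    return(structure(list(hit = FALSE, score = best$score), class = "element_hit"))
  structure(c(list(hit = TRUE), best), class = "element_hit")
}

#' @export
print.element_hit <- function(x, ...) {
  if (!x$hit) cat("<element_hit> no hit\n")
  else cat(sprintf("<element_hit> %s %0.1f%% identity, %s, span %d-%d (score %g)\n",
                   x$element, x$percent_identity, x$orientation,
                   x$element_span[1], x$element_span[2], x$score))
  invisible(x)
}

#' Position-wise majority consensus of inserted sequences
#'
#' Sequences are anchored at the insertion start; the consensus length is
#' the median observed length (rounded down). Each position takes the
#' majority base among sequences long enough to cover it, ties broken to
#' the alphabetically first base; the number of ambiguous (tied) positions
#' is attached as attribute `n_ambiguous` and reported via a message.
#'
#' @param seqs character vector of inserted sequences (>= 1).
#' @return consensus string with attribute `n_ambiguous`.
#' @export
consensus_sequence <- function(seqs) {
  if (length(seqs) == 0L) stopf("no supporting sequences")
  L <- as.integer(stats::median(nchar(seqs)))
  padded <- paste0(substr(seqs, 1L, L),
                   strrep("N", pmax(0L, L - nchar(seqs))))
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(padded))
  acgt <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  top <- apply(acgt, 2, which.max)              # first index wins ties
  n_amb <- sum(apply(acgt, 2, function(v) sum(v == max(v)) > 1L))
  if (n_amb > 0L) message(sprintf("consensus: %d ambiguous position(s)", n_amb))
  structure(paste(c("A", "C", "G", "T")[top], collapse = ""),
            n_ambiguous = n_amb)
}

#' Collect and cluster insertion events from cDNA reads
#'
#' Gathers alignment insertion operations of at least `min_insertion_len`
#' bp, clusters them by genomic anchor (single linkage within
#' `cluster_window`), and emits, for clusters with at least `min_support`
#' reads, an event with length statistics and a majority consensus.
#' Insertions are read from insertion operations, not soft clips: amplicon
#' reads anchor on both sides of a novel internal segment, so spliced
#' aligners represent it as an I operation.
#'
#' @param reads a `read_set`.
#' @param min_insertion_len minimal insertion length (bp), default 50.
#' @param cluster_window anchor clustering window (bp), default 20.
#' @param min_support minimal supporting reads per event, default 10.
#' @return list of `insertion_event` objects (possibly empty); each has
#'   `anchor` (0-based boundary), `supporting_reads`, `length_stats`
#'   (n, median, mean, q1, q3, min, max), `consensus`, `sequences`,
#'   `mode = "cdna"`.
#' @export
collect_insertion_reads <- function(reads, min_insertion_len = 50,
                                    cluster_window = 20, min_support = 10) {
  geometry <- read_geometry(reads)
  recs <- list()
  for (k in names(geometry$geoms)) {
    g <- geometry$geoms[[k]]
    if (!nrow(g$ins)) next
    rows <- which(g$ins$len >= min_insertion_len)
    if (!length(rows)) next
    idx <- which(geometry$key == k)
    for (r in rows) {
      qp <- g$ins$qpos[r]; l <- g$ins$len[r]
      recs[[length(recs) + 1L]] <- data.frame(
        read = idx, boundary = g$ins$boundary[r], len = l,
        seq = as.character(Biostrings::subseq(reads$seq[idx], qp, qp + l - 1L)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(list())
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$boundary), , drop = FALSE]
  cluster <- cumsum(c(1L, diff(recs$boundary) > cluster_window))
  events <- list()
  for (cl in unique(cluster)) {
    sub <- recs[cluster == cl, , drop = FALSE]
    if (nrow(sub) < min_support) next
    q <- stats::quantile(sub$len, c(0.25, 0.5, 0.75), names = FALSE, type = 1)
    cons <- suppressMessages(consensus_sequence(sub$seq))
    events[[length(events) + 1L]] <- structure(
      list(anchor = as.integer(stats::median(sub$boundary)),
           supporting_reads = nrow(sub),
           length_stats = c(n = nrow(sub), median = q[2], mean = mean(sub$len),
                            q1 = q[1], q3 = q[3], min = min(sub$len),
                            max = max(sub$len)),
           consensus = as.character(cons),
           n_ambiguous = attr(cons, "n_ambiguous"),
           sequences = sub$seq, mode = "cdna"),
      class = "insertion_event")
  }
  events
}

#' @export
print.insertion_event <- function(x, ...) {
  cat(sprintf("<insertion_event> anchor %d, %d reads, median length %g nt\n",
              to1(x$anchor), x$supporting_reads, x$length_stats[["median"]]))
  invisible(x)
}

## Split a residual chunk into terminal homopolymer runs (>= hp_min) and
## literal remainder.
residual_segments <- function(s, hp_min) {
  empty <- data.frame(kind = character(0), seq = character(0),
                      length = integer(0), element = character(0),
                      elt_start = integer(0), elt_end = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  if (!nzchar(s)) return(empty)
  seg_row <- function(kind, seq) data.frame(
    kind = kind, seq = seq, length = nchar(seq), element = NA_character_,
    elt_start = NA_integer_, elt_end = NA_integer_,
    orientation = NA_character_, stringsAsFactors = FALSE)
  out <- empty
  lead <- regmatches(s, regexpr("^(.)\\1*", s))
  if (nchar(lead) >= hp_min) {
    out <- rbind(out, seg_row("homopolymer", lead))
    s <- substr(s, nchar(lead) + 1L, nchar(s))
  }
  trail <- ""
  if (nzchar(s)) {
    trail <- regmatches(s, regexpr("(.)\\1*$", s))
    if (nchar(trail) >= hp_min) s <- substr(s, 1L, nchar(s) - nchar(trail))
    else trail <- ""
  }
  if (nzchar(s)) out <- rbind(out, seg_row("literal", s))
  if (nzchar(trail)) out <- rbind(out, seg_row("homopolymer", trail))
  out
}

decompose_segments <- function(s, library, hp_min, min_score) {
  if (nchar(s) < 20L) return(residual_segments(s, hp_min))
  hit <- identify_element(s, library, min_score)
  if (!hit$hit) return(residual_segments(s, hp_min))
  cs <- hit$consensus_span
  mid <- data.frame(kind = "element_fragment",
                    seq = substr(s, cs[1], cs[2]),
                    length = cs[2] - cs[1] + 1L, element = hit$element,
                    elt_start = hit$element_span[1],
                    elt_end = hit$element_span[2],
                    orientation = hit$orientation, stringsAsFactors = FALSE)
  rbind(decompose_segments(substr(s, 1L, cs[1] - 1L), library, hp_min, min_score),
        mid,
        decompose_segments(substr(s, cs[2] + 1L, nchar(s)), library, hp_min,
                           min_score))
}

#' Resolve a genomic insertion allele from spanning reads
#'
#' Selects reads whose alignment carries an insertion operation of at least
#' `min_insertion_len` bp anchored inside `locus` with flanking aligned
#' sequence on both sides, builds a majority consensus of the inserted
#' segment, and decomposes it into ordered segments by greedy local
#' alignment against the element library: element fragments (orientation
#' detected), terminal homopolymer runs of at least `homopolymer_min`
#' bases, and residual literals. The insertion site is reported as the pair
#' of flanking reference positions (1-based).
#'
#' @param reads a `read_set` (genomic alignments).
#' @param locus 0-based half-open interval the insertion boundary must fall
#'   in.
#' @param library element library ([Biostrings::DNAStringSet]).
#' @param min_insertion_len,min_support,homopolymer_min,min_score,flank
#'   tuning parameters; `flank` is the minimal anchored bases required on
#'   each side of the insertion site.
#' @return list of class `genomic_insertion_allele`: `insertion_site`
#'   (1-based flanking pair), `segments` (ordered data.frame, one row per
#'   segment), `total_length`, `consensus`, `supporting_reads`,
#'   `mode = "genomic"`. The segment sequences concatenate to the
#'   consensus.
#' @export
resolve_genomic_insertion <- function(reads, locus, library,
                                      min_insertion_len = 50,
                                      min_support = 10, homopolymer_min = 10,
                                      min_score = 30, flank = 20) {
  geometry <- read_geometry(reads)
  seqs <- character(0); boundaries <- integer(0)
  for (k in names(geometry$geoms)) {
    g <- geometry$geoms[[k]]
    if (!nrow(g$ins)) next
    lo <- min(g$blocks[, "start"]); hi <- max(g$blocks[, "end"])
    for (r in seq_len(nrow(g$ins))) {
      b <- g$ins$boundary[r]; l <- g$ins$len[r]
      if (l < min_insertion_len || b < locus[1] || b >= locus[2]) next
      if (lo > b - flank || hi < b + flank) next
      idx <- which(geometry$key == k)
      qp <- g$ins$qpos[r]
      seqs <- c(seqs, as.character(
        Biostrings::subseq(reads$seq[idx], qp, qp + l - 1L)))
      boundaries <- c(boundaries, rep(b, length(idx)))
    }
  }
  if (length(seqs) < min_support)
    stopf("only %d spanning insertion read(s); min_support is %d",
          length(seqs), min_support)
  cons <- suppressMessages(consensus_sequence(seqs))
  segments <- decompose_segments(as.character(cons), library,
                                 homopolymer_min, min_score)
  boundary <- as.integer(stats::median(boundaries))
  structure(list(insertion_site = c(boundary, boundary + 1L),
                 segments = segments,
                 total_length = nchar(cons),
                 consensus = as.character(cons),
                 supporting_reads = length(seqs), mode = "genomic"),
            class = "genomic_insertion_allele")
}

#' Bracketed text form of a genomic insertion allele
#'
#' Renders the segment decomposition in an HGVS-like
#' `ins[seg1; seg2; ...]` form: literals as their sequence, homopolymers as
#' `B(xN)`, element fragments as `name:start-end` with `inv` when reversed.
#'
#' @param allele a `genomic_insertion_allele`.
#' @return character scalar.
#' @export
format_insertion_allele <- function(allele) {
  seg <- allele$segments
  parts <- vapply(seq_len(nrow(seg)), function(i) {
    if (seg$kind[i] == "literal") seg$seq[i]
    else if (seg$kind[i] == "homopolymer")
      sprintf("%s(x%d)", substr(seg$seq[i], 1, 1), seg$length[i])
    else sprintf("%s:%d-%d%s", seg$element[i], seg$elt_start[i],
                 seg$elt_end[i],
                 if (seg$orientation[i] == "reverse") "inv" else "")
  }, character(1))
  sprintf("g.%d_%dins[%s]", allele$insertion_site[1], allele$insertion_site[2],
          paste(parts, collapse = "; "))
}

#' @export
print.genomic_insertion_allele <- function(x, ...) {
  cat("<genomic_insertion_allele>", format_insertion_allele(x),
      sprintf("(%d bp, %d reads)\n", x$total_length, x$supporting_reads))
  invisible(x)
}

#' Canonical splice-donor position weight matrix (9-mer)
#'
#' Log2-odds matrix (vs uniform background) over the 9 donor positions
#' (-3..-1 exonic, +1..+6 intronic) built from literature-standard human
#' U2 donor base frequencies with a small pseudocount. A plumbing-grade
#' motif model for ranking candidate donors in inserted sequence; it makes
#' no claim of matching dedicated splice predictors.
#'
#' @return 4 x 9 numeric matrix, rows `A,C,G,T`.
#' @export
splice_donor_pwm <- function() {
  freq <- matrix(c(
    0.328, 0.598, 0.092, 0.000, 0.000, 0.595, 0.713, 0.071, 0.160,  # A
    0.373, 0.129, 0.033, 0.000, 0.000, 0.028, 0.076, 0.055, 0.165,  # C
    0.183, 0.139, 0.803, 1.000, 0.000, 0.350, 0.118, 0.814, 0.222,  # G
    0.116, 0.134, 0.072, 0.000, 1.000, 0.027, 0.093, 0.060, 0.453), # T
    nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  freq <- sweep(freq + 0.001, 2, colSums(freq + 0.001), "/")
  log2(freq / 0.25)
}

#' Scan an inserted sequence for candidate splice-donor sites
#'
#' Slides the 9-mer donor PWM along the sequence and returns the `top_k`
#' positions by log-odds score among windows whose +1/+2 intronic bases are
#' `GT` (disable with `gt_filter = FALSE`). The reported `position` is the
#' 1-based position of the last exonic base (the donor cut site).
#' Deterministic: ties are broken by position.
#'
#' @param consensus nucleotide string, at least as long as the PWM width.
#' @param pwm a 4 x w log-odds matrix (default [splice_donor_pwm()]).
#' @param top_k number of sites to report (default 5).
#' @param gt_filter require the canonical GT dinucleotide (default TRUE).
#' @return data.frame `position`, `pwm_score`, `passes_gt_rule`.
#' @export
score_donor_sites <- function(consensus, pwm = splice_donor_pwm(), top_k = 5,
                              gt_filter = TRUE) {
  w <- ncol(pwm)
  L <- nchar(consensus)
  if (L < w) stopf("sequence (%d nt) shorter than PWM width (%d)", L, w)
  base_idx <- match(strsplit(consensus, "", fixed = TRUE)[[1]],
                    c("A", "C", "G", "T"))
  starts <- seq_len(L - w + 1L)
  scores <- vapply(starts, function(s) {
    idx <- base_idx[s:(s + w - 1L)]
    if (anyNA(idx)) return(-Inf)
    sum(pwm[cbind(idx, seq_len(w))])
  }, numeric(1))
  gt <- substring(consensus, starts + 3L, starts + 4L) == "GT"
  out <- data.frame(position = starts + 2L, pwm_score = scores,
                    passes_gt_rule = gt)
  if (gt_filter) out <- out[out$passes_gt_rule, , drop = FALSE]
  out <- out[is.finite(out$pwm_score), , drop = FALSE]
  out <- out[order(-out$pwm_score, out$position), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_k)
}
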