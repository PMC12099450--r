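## Synthetic long-read amplicon generator (synthetic_data).
##
## Emits coordinate-sorted indexed BAM alignments whose aligned blocks are
## constructed exactly from each read's isoform exon structure (introns as N
## skip operations, insertion payloads as I operations at the declared
## boundary), a FASTQ of the read sequences, and a per-read truth table.
## Substitution errors never touch the two bases flanking a junction, so
## junction extraction stays exact and classification tests isolate
## classification logic; marker positions are governed separately by the
## marker-artifact rate.

#' Define one isoform of a simulation scenario
#'
#' @param name isoform name (used in truth tables).
#' @param deviations list of [splice_deviation]s (empty = canonical).
#' @param allele allele label carried by this isoform's reads, or `NA` when
#'   no phasing marker distinguishes it.
#' @param proportion fraction of reads in `[0, 1]`.
#' @return list of class `isoform_spec`.
#' @export
isoform_spec <- function(name, deviations = list(), allele = NA_character_,
                         proportion) {
  check_deviation_compat(deviations)
  structure(list(name = name, deviations = deviations, allele = allele,
                 proportion = proportion), class = "isoform_spec")
}

#' Assemble a simulation scenario
#'
#' @param name scenario name (file basename on output).
#' @param model a `transcript_model`.
#' @param amplicon an `amplicon` over `model`.
#' @param isoforms list of [isoform_spec()]s; proportions must sum to 1
#'   (tolerance 1e-9) and every deviation must lie inside the amplicon.
#' @param markers marker data.frame (see [variant_marker()]) or `NULL`.
#' @param n_reads number of reads to emit.
#' @param substitution_error_rate per-base substitution probability
#'   (default 0.002, a free parameter of the generator: the HiFi per-base
#'   error profile is not a published quantity).
#' @param marker_artifact_rate probability that an emitted marker base is
#'   replaced by one of the two non-REF non-ALT bases (sequencing-artifact
#'   model for "undefined" reads).
#' @param rq_distribution list `p_high`, `high`, `low`: a fraction `p_high`
#'   of reads draw RQ uniformly from `high`, the rest from `low`. Default:
#'   97% of reads at RQ >= 0.99, exercising the HiFi filter without
#'   dominating it.
#' @param insertion_payloads named list of nucleotide strings referenced by
#'   insertion deviations' `payload` field.
#' @param reference named [Biostrings::DNAStringSet] (or FASTA path)
#'   containing the model's chromosome.
#' @param seed integer RNG seed; runs are byte-identical under a fixed seed.
#' @param rq_tag BAM tag (float) carrying per-read quality, default `"rq"`.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(name, model, amplicon, isoforms, markers = NULL,
                            n_reads,
                            substitution_error_rate = 0.002,
                            marker_artifact_rate = 0,
                            rq_distribution = list(p_high = 0.97,
                                                   high = c(0.99, 1.0),
                                                   low = c(0.90, 0.99)),
                            insertion_payloads = list(),
                            reference, seed = 1, rq_tag = "rq") {
  if (n_reads < 1L) stopf("n_reads must be >= 1")
  p <- vapply(isoforms, function(i) i$proportion, numeric(1))
  if (abs(sum(p) - 1) > 1e-9)
    stopf("isoform proportions sum to %.12f, not 1", sum(p))
  for (r in c(substitution_error_rate, marker_artifact_rate))
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (!model$chrom %in% names(reference))
    stopf("reference lacks chromosome '%s'", model$chrom)
  cfg <- structure(list(name = name, model = model, amplicon = amplicon,
                        isoforms = isoforms, markers = markers,
                        n_reads = as.integer(n_reads),
                        substitution_error_rate = substitution_error_rate,
                        marker_artifact_rate = marker_artifact_rate,
                        rq_distribution = rq_distribution,
                        insertion_payloads = insertion_payloads,
                        reference = reference, seed = as.integer(seed),
                        rq_tag = rq_tag),
                   class = "scenario_config")
  for (iso in isoforms) build_isoform_layout(cfg, iso)  # validates coordinates
  cfg
}

## ---------------------------------------------------------------------------
## Isoform layout: genomic blocks + insertion points + CIGAR + template.

## Returns list(blocks, cigar, template, qlen, protected (1-based query
## positions shielded from substitution errors), map_q(pos0 -> 1-based query
## position or NA), insertions data.frame(boundary, qpos, len)).
build_isoform_layout <- function(cfg, iso) {
  model <- cfg$model; amp <- cfg$amplicon
  span <- amplicon_span(amp)
  ex <- amplicon_exons(amp)
  strand <- model$strand
  devs <- iso$deviations
  drop_exons <- integer(0); pes <- list(); ins <- list()
  for (d in devs) {
    if (d$kind == "exon_skip") {
      drop_exons <- c(drop_exons, d$exons)
    } else if (d$kind == "pseudoexon") {
      if (d$start <= span["start"] || d$end >= span["end"])
        stopf("pseudoexon outside amplicon")
      pes[[length(pes) + 1L]] <- c(d$start, d$end)
    } else if (d$kind %in% c("exon_truncation", "exon_elongation")) {
      i <- which(ex$exon == d$exon)
      if (length(i) != 1L) stopf("deviation exon %d outside amplicon", d$exon)
      ## transcript-orientation side -> genomic edge
      right_edge <- (strand == "+") == (d$side == "donor")
      delta <- if (d$kind == "exon_truncation") -d$delta_bp else d$delta_bp
      if (right_edge) ex$end[i] <- ex$end[i] + delta
      else ex$start[i] <- ex$start[i] - delta
      if (ex$end[i] <= ex$start[i]) stopf("truncation removes whole exon %d", d$exon)
    } else if (d$kind == "insertion") {
      payload <- cfg$insertion_payloads[[d$payload %||% ""]]
      if (is.null(payload))
        stopf("insertion payload '%s' missing for isoform '%s'",
              d$payload %||% "<unnamed>", iso$name)
      ins[[length(ins) + 1L]] <- list(boundary = d$anchor, seq = payload)
    }
  }
  ex <- ex[!ex$exon %in% drop_exons, , drop = FALSE]
  blocks <- rbind(ex[, c("start", "end")],
                  do.call(rbind, lapply(pes, function(p)
                    data.frame(start = p[1], end = p[2]))))
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  nb <- nrow(blocks)
  if (nb >= 2L && any(blocks$start[-1] <= blocks$end[-nb]))
    stopf("isoform '%s': blocks overlap or abut (introns must stay >= 1 bp)",
          iso$name)
  if (any(blocks$start < span["start"] - 0L) || any(blocks$end > span["end"]))
    stopf("isoform '%s': deviation outside amplicon", iso$name)
  ins_b <- vapply(ins, function(x) x$boundary, integer(1))
  if (length(ins)) {
    inside <- vapply(ins_b, function(b)
      any(b > blocks$start & b <= blocks$end), logical(1))
    if (any(!inside)) stopf("isoform '%s': insertion boundary outside blocks",
                            iso$name)
  }
  chrom_seq <- cfg$reference[[model$chrom]]
  pieces <- character(0); cig <- character(0)
  qoff <- 0L; protected <- integer(0)
  ins_q <- data.frame(boundary = integer(0), qpos = integer(0), len = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  block_meta <- vector("list", nb)
  for (i in seq_len(nb)) {
    s <- blocks$start[i]; e <- blocks$end[i]
    here <- which(ins_b > s & ins_b <= e)
    here <- here[order(ins_b[here])]
    cuts <- c(s, ins_b[here], e)
    shifts <- integer(0); bounds <- integer(0)
    qstart <- qoff
    for (j in seq_len(length(cuts) - 1L)) {
      a <- cuts[j]; b <- cuts[j + 1L]
      if (b > a) {
        pieces <- c(pieces, as.character(Biostrings::subseq(chrom_seq, a + 1L, b)))
        cig <- c(cig, sprintf("%dM", b - a))
        qoff <- qoff + (b - a)
      }
      if (j <= length(here)) {
        payload <- ins[[here[j]]]$seq
        pieces <- c(pieces, payload)
        cig <- c(cig, sprintf("%dI", nchar(payload)))
        ins_q <- rbind(ins_q, data.frame(boundary = cuts[j + 1L], qpos = qoff,
                                         len = nchar(payload), seq = payload,
                                         stringsAsFactors = FALSE))
        shifts <- c(shifts, nchar(payload)); bounds <- c(bounds, cuts[j + 1L])
        qoff <- qoff + nchar(payload)
      }
    }
    block_meta[[i]] <- list(start = s, end = e, qstart = qstart,
                            ins_bounds = bounds, ins_shifts = shifts)
    if (i < nb) {
      gap <- blocks$start[i + 1L] - e
      cig <- c(cig, sprintf("%dN", gap))
      protected <- c(protected, qoff - 1L, qoff, qoff + 1L, qoff + 2L)
    }
  }
  template <- paste(pieces, collapse = "")
  map_q <- function(pos0) {  # 0-based genomic -> 1-based query (NA if absent)
    out <- rep(NA_integer_, length(pos0))
    for (bm in block_meta) {
      hit <- which(pos0 >= bm$start & pos0 < bm$end)
      if (length(hit)) {
        shift <- vapply(pos0[hit], function(p)
          sum(bm$ins_shifts[bm$ins_bounds <= p]), numeric(1))
        out[hit] <- bm$qstart + (pos0[hit] - bm$start) + as.integer(shift) + 1L
      }
    }
    out
  }
  list(blocks = as.matrix(blocks), cigar = paste(cig, collapse = ""),
       template = template, qlen = nchar(template),
       pos0 = blocks$start[1], protected = protected,
       map_q = map_q, insertions = ins_q)
}

## ---------------------------------------------------------------------------

#' Simulate a scenario into BAM + FASTQ + truth table
#'
#' Draws each read's isoform from the configured mixture, applies
#' substitution errors (sparing the two bases flanking every junction and
#' all marker positions), emits the allele's base at each covered marker
#' (flipped to one of the two non-REF non-ALT bases with the configured
#' artifact rate), assigns per-read RQ from the configured mixture, and
#' writes a coordinate-sorted indexed BAM (RQ as a float tag), a FASTQ and a
#' TSV truth table. Fully deterministic under the config's seed.
#'
#' @param config a [scenario_config()].
#' @param outdir output directory (created if needed).
#' @param basename file basename, default the scenario name.
#' @return list with paths `bam`, `fastq`, `truth_path`, `reference_path`
#'   and the truth `data.frame` (`read_id`, `isoform`, `allele`, `rq`,
#'   `marker_bases`).
#' @export
simulate_scenario <- function(config, outdir, basename = config$name) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_reads
  iso_names <- vapply(config$isoforms, function(i) i$name, character(1))
  prob <- vapply(config$isoforms, function(i) i$proportion, numeric(1))
  layouts <- lapply(config$isoforms, function(i) build_isoform_layout(config, i))

  iso_idx <- sample.int(length(iso_names), n, replace = TRUE, prob = prob)
  rqd <- config$rq_distribution
  hi <- stats::runif(n) <= rqd$p_high
  rq <- ifelse(hi, stats::runif(n, rqd$high[1], rqd$high[2]),
               stats::runif(n, rqd$low[1], rqd$low[2]))
  ids <- sprintf("r%07d", seq_len(n))

  seqs <- character(n)
  marker_rec <- rep(".", n)
  mk <- config$markers
  has_mk <- !is.null(mk) && nrow(mk) > 0L
  for (k in seq_along(config$isoforms)) {
    idx <- which(iso_idx == k)
    if (!length(idx)) next
    lay <- layouts[[k]]
    tmpl <- lay$template; L <- lay$qlen
    mk_q <- if (has_mk) lay$map_q(mk$pos) else integer(0)
    elig <- setdiff(seq_len(L), c(lay$protected, mk_q[!is.na(mk_q)]))
    tmpl_chars <- strsplit(tmpl, "", fixed = TRUE)[[1]]
    m <- length(idx)
    ss <- rep(tmpl, m)
    if (config$substitution_error_rate > 0 && length(elig)) {
      k_err <- stats::rbinom(m, length(elig), config$substitution_error_rate)
      err_pos <- lapply(seq_len(m), function(j)
        if (k_err[j] > 0L) sample(elig, k_err[j]) else integer(0))
      maxk <- max(k_err)
      bases <- c("A", "C", "G", "T")
      if (maxk > 0L) for (r in seq_len(maxk)) {
        jj <- which(k_err >= r)
        p <- vapply(err_pos[jj], `[`, integer(1), r)
        cur <- tmpl_chars[p]
        nb <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
        tmp <- ss[jj]; substring(tmp, p, p) <- nb; ss[jj] <- tmp
      }
    }
    if (has_mk) {
      allele <- config$isoforms[[k]]$allele
      rec <- rep("", m)
      for (t in seq_len(nrow(mk))) {
        qp <- mk_q[t]
        if (is.na(qp)) next
        base <- if (!is.na(allele) && allele == mk$allele_label_alt[t])
          mk$alt_base[t] else mk$ref_base[t]
        emitted <- rep(base, m)
        if (config$marker_artifact_rate > 0) {
          flip <- stats::runif(m) < config$marker_artifact_rate
          if (any(flip)) {
            others <- setdiff(c("A", "C", "G", "T"),
                              c(mk$ref_base[t], mk$alt_base[t]))
            emitted[flip] <- sample(others, sum(flip), replace = TRUE)
          }
        }
        substring(ss, qp, qp) <- emitted
        rec <- paste0(rec, ifelse(nzchar(rec), ";", ""),
                      sprintf("%s:%d=%s", mk$chrom[t], to1(mk$pos[t]), emitted))
      }
      marker_rec[idx] <- ifelse(nzchar(rec), rec, ".")
    }
    seqs[idx] <- ss
  }

  alleles <- vapply(config$isoforms, function(i)
    if (is.na(i$allele)) "." else i$allele, character(1))
  truth <- data.frame(read_id = ids, isoform = iso_names[iso_idx],
                      allele = alleles[iso_idx],
                      rq = sprintf("%.6f", rq),
                      marker_bases = marker_rec, stringsAsFactors = FALSE)

  chrom <- config$model$chrom
  ref_len <- Biostrings::width(config$reference[names(config$reference) == chrom])
  prefix <- file.path(outdir, basename)
  bam <- write_sam_bam(chrom, ref_len, ids,
                       pos0 = vapply(layouts, `[[`, numeric(1), "pos0")[iso_idx],
                       cigars = vapply(layouts, `[[`, character(1), "cigar")[iso_idx],
                       seqs = seqs, rq = rq, prefix = prefix,
                       rq_tag = config$rq_tag)
  fq <- paste0(prefix, ".fastq")
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), fq)
  truth_path <- paste0(prefix, ".truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ref_path <- paste0(prefix, ".ref.fa")
  Biostrings::writeXStringSet(config$reference, ref_path)
  list(bam = bam, fastq = fq, truth_path = truth_path, truth = truth,
       reference_path = ref_path, config = config)
}

## Write alignments as SAM text, then convert/sort/index via Rsamtools.
write_sam_bam <- function(chrom, ref_len, ids, pos0, cigars, seqs, rq,
                          prefix, rq_tag = "rq") {
  sam <- paste0(prefix, ".sam")
  header <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", chrom, ref_len))
  body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\t%s:f:%.6f",
                  ids, chrom, pos0 + 1L, cigars, seqs,
                  strrep("I", nchar(seqs)), rq_tag, rq)
  con <- file(sam, "w"); writeLines(c(header, body), con); close(con)
  bam <- suppressMessages(
    Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                     indexDestination = TRUE))
  unlink(sam)
  bam
}

#' Simulate contiguous genomic reads spanning a novel insertion
#'
#' The genomic counterpart of [simulate_scenario()]: emits single-block
#' (unspliced) reads that span an insertion site with flanking anchors on
#' both sides, carrying the full inserted allele as one insertion operation.
#' Used to exercise genomic-level breakpoint resolution.
#'
#' @param reference named [Biostrings::DNAStringSet].
#' @param chrom chromosome name.
#' @param span 0-based half-open genomic interval each read covers.
#' @param boundary 0-based insertion boundary (insertion lies between
#'   `boundary - 1` and `boundary`).
#' @param payload inserted nucleotide string.
#' @param n_reads number of reads.
#' @param substitution_error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @param outdir,basename output location.
#' @return as [simulate_scenario()] (no truth table columns beyond read id).
#' @export
simulate_genomic_reads <- function(reference, chrom, span, boundary, payload,
                                   n_reads = 14, substitution_error_rate = 0,
                                   seed = 1, outdir, basename = "genomic") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (!(boundary > span[1] && boundary < span[2]))
    stopf("boundary must lie strictly inside span")
  chrom_seq <- reference[[chrom]]
  left <- as.character(Biostrings::subseq(chrom_seq, span[1] + 1L, boundary))
  right <- as.character(Biostrings::subseq(chrom_seq, boundary + 1L, span[2]))
  tmpl <- paste0(left, payload, right)
  cigar <- sprintf("%dM%dI%dM", nchar(left), nchar(payload), nchar(right))
  ids <- sprintf("g%05d", seq_len(n_reads))
  ss <- rep(tmpl, n_reads)
  if (substitution_error_rate > 0) {
    L <- nchar(tmpl)
    tmpl_chars <- strsplit(tmpl, "", fixed = TRUE)[[1]]
    for (j in seq_len(n_reads)) {
      kk <- stats::rbinom(1, L, substitution_error_rate)
      if (kk > 0L) {
        p <- sample.int(L, kk)
        for (t in seq_along(p)) {
          nb <- sample(setdiff(c("A", "C", "G", "T"), tmpl_chars[p[t]]), 1L)
          substr(ss[j], p[t], p[t]) <- nb
        }
      }
    }
  }
  prefix <- file.path(outdir, basename)
  bam <- write_sam_bam(chrom, Biostrings::width(reference[names(reference) == chrom]),
                       ids, rep(span[1], n_reads), rep(cigar, n_reads), ss,
                       rq = rep(0.999, n_reads), prefix = prefix)
  ref_path <- paste0(prefix, ".ref.fa")
  Biostrings::writeXStringSet(reference, ref_path)
  list(bam = bam, reference_path = ref_path, payload = payload,
       boundary = boundary)
}
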