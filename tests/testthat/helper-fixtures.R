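# Shared fixtures: a tiny 6-exon transcript, in-code scenario builders, an
# independent CIGAR-walking oracle for junction counts, and an exhaustive
# affine-gap local-alignment DP oracle.

make_tiny_model <- function(n_exons = 6, exon_len = 40, intron_len = 30,
                            chrom = "chrT", strand = "+") {
  starts <- 100L + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  transcript_model("TST", "TST.1", chrom, strand,
                   data.frame(start = starts, end = starts + exon_len))
}

make_tiny_reference <- function(model, flank = 100L, patches = list(),
                                seed = 4242) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  len <- max(model$exons$end) + flank
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  for (p in patches) substr(s, p[[1]] + 1L, p[[1]] + 1L) <- p[[2]]
  ref <- Biostrings::DNAStringSet(s)
  names(ref) <- model$chrom
  ref
}

tiny_scenario <- function(isoforms, n_reads = 200, seed = 1, markers = NULL,
                          err = 0, art = 0, payloads = list(),
                          model = make_tiny_model(), patches = list(),
                          rq = list(p_high = 1, high = c(0.99, 1),
                                    low = c(0.90, 0.99))) {
  scenario_config("tiny", model, amplicon(model, 1, nrow(model$exons)),
                  isoforms, markers = markers, n_reads = n_reads,
                  substitution_error_rate = err, marker_artifact_rate = art,
                  rq_distribution = rq, insertion_payloads = payloads,
                  reference = make_tiny_reference(model, patches = patches),
                  seed = seed)
}

sim <- function(cfg) simulate_scenario(cfg, tempfile("sc_"))

# Hand-built read set for unit-level phasing tests (single-block reads whose
# bases at marker positions are fully controlled).
manual_reads <- function(seqs, pos0, rq = rep(0.999, length(seqs)),
                         chrom = "chrT") {
  ampliSplice:::new_read_set(
    read_id = sprintf("m%03d", seq_along(seqs)), chrom = rep(chrom, length(seqs)),
    pos0 = rep(as.integer(pos0), length(seqs)),
    cigar = sprintf("%dM", nchar(seqs)),
    seq = Biostrings::DNAStringSet(seqs), rq = rq)
}

# Independent oracle: junction and alignment-signature counts straight from
# the BAM records via a regex CIGAR walk (no shared code with the package's
# geometry layer).
brute_force_bam_counts <- function(bam) {
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "pos", "cigar")))[[1]]
  jc <- character(0); sig <- character(length(b$qname))
  for (i in seq_along(b$qname)) {
    toks <- regmatches(b$cigar[i], gregexpr("\\d+[MIDNSHP=X]", b$cigar[i]))[[1]]
    len <- as.integer(sub(".$", "", toks)); op <- sub("^\\d+", "", toks)
    r <- b$pos[i] - 1L; js <- character(0); insl <- integer(0)
    for (t in seq_along(op)) {
      if (op[t] %in% c("M", "D", "=", "X")) r <- r + len[t]
      else if (op[t] == "N") { js <- c(js, sprintf("%d-%d", r, r + len[t]))
        r <- r + len[t] }
      else if (op[t] == "I") insl <- c(insl, len[t])
    }
    jc <- c(jc, js)
    sig[i] <- paste(c(js, if (length(insl)) paste0("I", insl)), collapse = ";")
  }
  list(junctions = table(jc), signatures = table(sig))
}

# Exhaustive affine-gap Smith-Waterman DP: a length-L gap costs
# gap_open + L * gap_ext. Returns the best local score.
sw_oracle_score <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                            gap_ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in pattern (consumes subject)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (consumes pattern)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# 3-sigma binomial recovery band around proportion p at sample size n
tol3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)

# isoform percentage (0-100 scale) of one key from a junction table
iso_pct <- function(jt, key) {
  hit <- jt$isoforms$percentage[jt$isoforms$isoform_key == key]
  if (length(hit) == 0L) 0 else hit
}
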