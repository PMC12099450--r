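## Bundled simulation presets (synthetic_data).
##
## Each preset reproduces one study condition on a synthetic mini-genome
## with the same exon-count topology as the corresponding gene; the isoform
## proportions are the percentages reported for that subject. Mini-reference
## sequences and the mobile-element entry are generated deterministically
## from fixed internal seeds, so they are identical across sessions and
## independent of the caller's RNG stream.

PRESET_NAMES <- c("P1_HGSNAT", "P2_CEP290", "P4_IMPG2_mut", "P4_IMPG2_ctrl",
                  "P5_CHM", "CARRIER_CHM", "P6_NMNAT1", "P7_NMNAT1",
                  "P8_NMNAT1", "P9_NMNAT1", "P10_NMNAT1")

## fixed internal seeds for deterministic bundled artifacts
REF_SEED <- c(P1_HGSNAT = 910001L, P2_CEP290 = 910002L, P4_IMPG2 = 910003L,
              P5_CHM = 910004L, NMNAT1 = 910005L)
ELEMENT_SEED <- 910777L

## Build a plus-strand synthetic model: exon lengths in transcript order,
## constant intron length, fixed left flank.
make_synthetic_model <- function(gene, txid, chrom, exon_lengths,
                                 intron_length, flank = 300L) {
  starts <- flank + c(0L, cumsum(exon_lengths[-length(exon_lengths)] +
                                   intron_length))
  transcript_model(gene, txid, chrom, "+",
                   data.frame(start = starts, end = starts + exon_lengths))
}

## Deterministic random reference covering the model plus flanks, with
## optional base patches (list of c(pos0, base)) so marker REF bases really
## are the reference bases at those positions.
make_reference <- function(model, seed, patches = list(), flank = 300L) {
  len <- max(model$exons$end) + flank
  seq <- with_fixed_seed(seed, random_dna(len))
  for (p in patches) substr(seq, as.integer(p[[1]]) + 1L,
                            as.integer(p[[1]]) + 1L) <- p[[2]]
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- model$chrom
  ref
}

#' The bundled synthetic SVA_F-like mobile element
#'
#' A 2,514-nt deterministic synthetic stand-in for an SVA_F retrotransposon
#' (it shares nothing with the real element beyond length scale). A
#' canonical splice-donor 9-mer (`CAGGTAAGT`) is planted so that its last
#' exonic base falls at element position 875: transcripts that include the
#' element's first 875 nt end precisely at this cryptic donor.
#'
#' @return named [Biostrings::DNAStringSet] of length 1 (`SVA_F_synthetic`).
#' @export
preset_element_library <- function() {
  seq <- with_fixed_seed(ELEMENT_SEED, random_dna(2514L))
  substr(seq, 1L, 1L) <- "G"      # avoids A/T at the termini so homopolymer
  substr(seq, 2514L, 2514L) <- "C" # boundaries in composite payloads stay crisp
  substr(seq, 873L, 881L) <- "CAGGTAAGT"  # donor: last exonic base = 875
  lib <- Biostrings::DNAStringSet(seq)
  names(lib) <- "SVA_F_synthetic"
  lib
}

#' Write the bundled element library to FASTA
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preset_element_library <- function(path) {
  Biostrings::writeXStringSet(preset_element_library(), path)
  invisible(path)
}

## shared NMNAT1-like scaffold: 5 exons, marker at the c.769-equivalent
## position in exon 5 (REF G / ALT A; ALT tags allele 1).
nmnat1_scaffold <- function() {
  model <- make_synthetic_model("NMNAT1syn", "NMSYN0005.1", "chrSynN",
                                exon_lengths = c(250L, 150L, 150L, 150L, 300L),
                                intron_length = 400L)
  mk_pos <- exon_interval(model, 5)["start"] + 69L
  reference <- make_reference(model, REF_SEED[["NMNAT1"]],
                              patches = list(list(mk_pos, "G")))
  markers <- variant_marker(model$chrom, mk_pos, "G", "A",
                            allele_label_ref = "allele2",
                            allele_label_alt = "allele1",
                            hgvs_label = "c.769G>A")
  list(model = model, amp = amplicon(model, 1, 5), reference = reference,
       markers = markers)
}

nmnat1_sva_preset <- function(name, allele1_prop, n_reads, seed) {
  sc <- nmnat1_scaffold()
  e2 <- exon_interval(sc$model, 2)
  boundary <- e2[["end"]] + 39L  # exon-2 elongation of 39 bp, then insertion
  elem <- as.character(preset_element_library()[[1]])
  payload <- substr(elem, 1L, 875L)
  rest <- (1 - allele1_prop) / 2
  scenario_config(
    name = name, model = sc$model, amplicon = sc$amp,
    isoforms = list(
      isoform_spec("WT_allele1", list(), "allele1", allele1_prop),
      isoform_spec("WT_allele2", list(), "allele2", rest),
      isoform_spec("SVA_allele2",
                   list(dev_exon_elongation(2, 39, "donor"),
                        dev_insertion(boundary, 875L, payload = "sva875")),
                   "allele2", rest)),
    markers = sc$markers, n_reads = n_reads,
    marker_artifact_rate = 0.005,
    insertion_payloads = list(sva875 = payload),
    reference = sc$reference, seed = seed)
}

#' Bundled simulation presets
#'
#' Returns a fully populated [scenario_config()] on a synthetic mini-genome.
#' Available presets (isoform proportions are the corresponding subjects'
#' reported percentages; fillers completing each mixture to 100% are
#' documented in the methods vignette):
#'
#' * `P1_HGSNAT` — 18-exon model, amplicon exons 2-18 (1,666-bp WT
#'   fragment); canonical 85.1% vs exon-4 skip 14.9%; no phasing marker.
#' * `P2_CEP290` — 54-exon model, amplicon exons 34-52; 97-nt pseudoexon
#'   inclusion (50%) whose reads all carry the deep-intronic ALT base.
#' * `P4_IMPG2_mut` / `P4_IMPG2_ctrl` — 19-exon model, amplicon exons 13-19
#'   (1,690-bp WT); canonical / exon-16 skip / exon-16+17 co-skip at
#'   39.9/13.3/16.3% (mutant) and 31.4/18.2/19.5% (control).
#' * `P5_CHM` / `CARRIER_CHM` — 15-exon model, full-length amplicon;
#'   exon-11+12 co-skip at 9.8% (affected) and 1.3% (carrier).
#' * `P6_NMNAT1` — single observable allele: allele 1 at 100% (allele 2
#'   absent).
#' * `P7_NMNAT1` — severe allelic depletion: minor (REF-base) allele at
#'   0.15%.
#' * `P8_NMNAT1`, `P9_NMNAT1`, `P10_NMNAT1` — allele-1 enrichment at
#'   90/91/92% (mean 91%); allele 2 split evenly between WT splicing and an
#'   exon-2 elongation (39 bp) followed by a 875-nt insertion drawn from the
#'   bundled SVA_F-like element; marker artifact rate 0.005.
#'
#' @param name preset name (see above).
#' @param n_reads optional override of the preset's default read count.
#' @param seed optional override of the preset's default seed.
#' @return a `scenario_config`.
#' @examples
#' cfg <- preset("P1_HGSNAT", n_reads = 200, seed = 7)
#' @export
preset <- function(name, n_reads = NULL, seed = NULL) {
  if (!name %in% PRESET_NAMES)
    stopf("unknown preset '%s' (available: %s)", name,
          paste(PRESET_NAMES, collapse = ", "))
  build <- switch(name,
    P1_HGSNAT = function(n, s) {
      model <- make_synthetic_model("HGSNATsyn", "HGSYN0018.1", "chrSynH",
                                    exon_lengths = c(120L, rep(98L, 17L)),
                                    intron_length = 250L)
      scenario_config(name, model, amplicon(model, 2, 18, 1666L),
                      isoforms = list(
                        isoform_spec("WT", list(), NA, 0.851),
                        isoform_spec("skip4", list(dev_exon_skip(4)), NA, 0.149)),
                      n_reads = n, reference = make_reference(model, REF_SEED[["P1_HGSNAT"]]),
                      seed = s)
    },
    P2_CEP290 = function(n, s) {
      model <- make_synthetic_model("CEP290syn", "CPSYN0054.1", "chrSynC",
                                    exon_lengths = rep(100L, 54L),
                                    intron_length = 220L)
      e45 <- exon_interval(model, 45)
      pe_start <- e45[["end"]] + 60L
      pe <- dev_pseudoexon(pe_start, pe_start + 97L)
      var_pos <- pe_start + 30L
      reference <- make_reference(model, REF_SEED[["P2_CEP290"]],
                                  patches = list(list(var_pos, "A")))
      markers <- variant_marker(model$chrom, var_pos, "A", "G",
                                allele_label_ref = "wt",
                                allele_label_alt = "mut",
                                hgvs_label = "deep-intronic A>G")
      scenario_config(name, model, amplicon(model, 34, 52),
                      isoforms = list(
                        isoform_spec("WT", list(), "wt", 0.5),
                        isoform_spec("PE97", list(pe), "mut", 0.5)),
                      markers = markers, n_reads = n, reference = reference,
                      seed = s)
    },
    P4_IMPG2_mut = ,
    P4_IMPG2_ctrl = function(n, s) {
      model <- make_synthetic_model("IMPG2syn", "IMSYN0019.1", "chrSynI",
                                    exon_lengths = c(rep(150L, 12L), 240L, 240L,
                                                     240L, 240L, 240L, 240L, 250L),
                                    intron_length = 260L)
      amp <- amplicon(model, 13, 19, 1690L)
      isoforms <- if (name == "P4_IMPG2_mut") list(
        isoform_spec("WT", list(), NA, 0.399),
        isoform_spec("skip16", list(dev_exon_skip(16)), NA, 0.133),
        isoform_spec("skip16_17", list(dev_exon_skip(c(16, 17))), NA, 0.163),
        isoform_spec("trunc15", list(dev_exon_truncation(15, 45, "donor")),
                     NA, 0.305)
      ) else list(
        isoform_spec("WT", list(), NA, 0.314),
        isoform_spec("skip16", list(dev_exon_skip(16)), NA, 0.182),
        isoform_spec("skip16_17", list(dev_exon_skip(c(16, 17))), NA, 0.195),
        isoform_spec("skip17", list(dev_exon_skip(17)), NA, 0.309))
      scenario_config(name, model, amp, isoforms, n_reads = n,
                      reference = make_reference(model, REF_SEED[["P4_IMPG2"]]),
                      seed = s)
    },
    P5_CHM = ,
    CARRIER_CHM = function(n, s) {
      model <- make_synthetic_model("CHMsyn", "CHSYN0015.1", "chrSynX",
                                    exon_lengths = rep(130L, 15L),
                                    intron_length = 240L)
      isoforms <- if (name == "P5_CHM") list(
        isoform_spec("skip12", list(dev_exon_skip(12)), NA, 0.820),
        isoform_spec("skip11_12", list(dev_exon_skip(c(11, 12))), NA, 0.098),
        isoform_spec("WT", list(), NA, 0.082)
      ) else list(
        isoform_spec("WT", list(), NA, 0.600),
        isoform_spec("skip12", list(dev_exon_skip(12)), NA, 0.387),
        isoform_spec("skip11_12", list(dev_exon_skip(c(11, 12))), NA, 0.013))
      scenario_config(name, model, amplicon(model, 1, 15), isoforms,
                      n_reads = n,
                      reference = make_reference(model, REF_SEED[["P5_CHM"]]),
                      seed = s)
    },
    P6_NMNAT1 = function(n, s) {
      sc <- nmnat1_scaffold()
      scenario_config(name, sc$model, sc$amp,
                      isoforms = list(isoform_spec("WT_allele1", list(),
                                                   "allele1", 1.0)),
                      markers = sc$markers, n_reads = n,
                      reference = sc$reference, seed = s)
    },
    P7_NMNAT1 = function(n, s) {
      sc <- nmnat1_scaffold()
      scenario_config(name, sc$model, sc$amp,
                      isoforms = list(
                        isoform_spec("WT_allele1", list(), "allele1", 0.9985),
                        isoform_spec("WT_allele2", list(), "allele2", 0.0015)),
                      markers = sc$markers, n_reads = n,
                      reference = sc$reference, seed = s)
    },
    P8_NMNAT1 = function(n, s) nmnat1_sva_preset(name, 0.90, n, s),
    P9_NMNAT1 = function(n, s) nmnat1_sva_preset(name, 0.91, n, s),
    P10_NMNAT1 = function(n, s) nmnat1_sva_preset(name, 0.92, n, s))
  default_n <- c(P1_HGSNAT = 50000L, P2_CEP290 = 20000L, P4_IMPG2_mut = 50000L,
                 P4_IMPG2_ctrl = 50000L, P5_CHM = 50000L, CARRIER_CHM = 50000L,
                 P6_NMNAT1 = 10000L, P7_NMNAT1 = 100000L, P8_NMNAT1 = 50000L,
                 P9_NMNAT1 = 50000L, P10_NMNAT1 = 50000L)
  default_seed <- c(P1_HGSNAT = 1L, P2_CEP290 = 11L, P4_IMPG2_mut = 2L,
                    P4_IMPG2_ctrl = 3L, P5_CHM = 4L, CARRIER_CHM = 5L,
                    P6_NMNAT1 = 12L, P7_NMNAT1 = 6L, P8_NMNAT1 = 7L,
                    P9_NMNAT1 = 8L, P10_NMNAT1 = 9L)
  build(as.integer(n_reads %||% default_n[[name]]),
        as.integer(seed %||% default_seed[[name]]))
}

#' The bundled genomic-insertion preset
#'
#' Contiguous genomic reads over the NMNAT1-like mini-genome spanning an
#' insertion in intron 2 whose allele is the composite payload
#' `[G; inverted SVA_F_synthetic (2,514 nt); A(x38); GACTAGAGAACC]`,
#' mirroring a breakpoint description of the form
#' `ins[G; element-inverted; A38; literal]`. Error-free by default so
#' breakpoint resolution can be checked byte-exactly.
#'
#' @param outdir output directory.
#' @param n_reads number of spanning reads (default 14).
#' @param seed RNG seed.
#' @param substitution_error_rate per-base substitution probability.
#' @return as [simulate_genomic_reads()], plus `locus` (0-based interval
#'   containing the insertion site) and `library` (the element library).
#' @export
preset_genomic_insertion <- function(outdir, n_reads = 14, seed = 1,
                                     substitution_error_rate = 0) {
  sc <- nmnat1_scaffold()
  e2 <- exon_interval(sc$model, 2)
  boundary <- e2[["end"]] + 39L
  lib <- preset_element_library()
  payload <- paste0("G", reverse_complement(as.character(lib[[1]])),
                    strrep("A", 38L), "GACTAGAGAACC")
  span <- c(e2[["start"]] - 150L, exon_interval(sc$model, 3)[["end"]] + 150L)
  out <- simulate_genomic_reads(sc$reference, sc$model$chrom, span, boundary,
                                payload, n_reads = n_reads,
                                substitution_error_rate = substitution_error_rate,
                                seed = seed, outdir = outdir,
                                basename = "P9_NMNAT1_genomic")
  out$locus <- c(boundary - 200L, boundary + 200L)
  out$library <- lib
  out
}
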