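---
title: "ampliSplice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliSplice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

`ampliSplice` analyzes deep targeted long-read cDNA sequencing of a single
transcript amplicon. The defining property of this data type is that every
read is a complete, end-to-end observation of one mRNA molecule over a
known exon range: the RT-PCR primers sit in the first and last exons of the
amplicon, and accurate long reads (HiFi-class, per-read quality RQ ≥ 0.99)
traverse the whole product. Three consequences shape the design:

1. **A read's splicing state is its junction chain.** A spliced aligner
   encodes each removed intron as an `N` (skip) operation; the ordered
   `(donor_end, acceptor_start)` pairs are the read's splicing fingerprint,
   and isoform classification is a comparison of that fingerprint (plus the
   aligned block layout) against the transcript model.
2. **Denominators are unambiguous.** Because reads cover the amplicon
   end-to-end, "total reads" is well defined and every event abundance is a
   junction-read percentage:
   `(reads covering a specific exon–exon junction / total reads) × 100%`.
   The denominator used throughout is the number of RQ-passing reads that
   overlap the amplicon and were classified; rejected reads are reported
   separately. This is the most reproducible reading of a "total reads"
   denominator, and reports always carry the counts next to the
   percentages so the choice is auditable.
3. **Phasing is direct.** A heterozygous SNV inside the amplicon assigns
   each read to an allele by simple base lookup, with no statistical
   haplotyping.

# Classification rules

Each read's alignment geometry is decomposed *jointly* into a set of
splicing deviations; the empty set is the canonical (WT) isoform, and the
serialized set is the read's isoform key:

* **Exon skip** — an expected exon with no overlapping aligned block.
  Adjacent skipped exons merge into one co-skip deviation (`skip:16+17`),
  which is deliberately distinct from two independent single skips: the
  read types of interest are named at the isoform level ("exon 16 and 17
  co-skipping"), and a merged deviation keeps isoform keys in one-to-one
  correspondence with those types.
* **Pseudoexon** — an aligned block fully inside an intron, bounded by
  junctions on both sides.
* **Truncation / elongation** — a junction sharing one canonical boundary
  while the other end is displaced by more than `tol` bases into the exon
  (truncation) or the intron (elongation). The displacement is reported in
  bp with the affected side (donor/acceptor, in transcript orientation).
* **Insertion** — an alignment insertion (`I`) operation of at least
  `min_insertion_len` bases; shorter insertions are ignored as indel
  noise. Insertions are read from `I` operations, not soft clips, because
  amplicon reads anchor on both sides of a novel internal segment;
  soft-clip rescue is out of scope.
* **Intron retention** (a block bridging two consecutive exons) has no
  dedicated category; it is represented as a donor-side elongation across
  the retained intron. The generator never produces it; the rule exists so
  that such reads are never silently called canonical.

Deviations compose freely: the motivating insertion allele is
`elongation(exon 2, +39 bp, donor) + insertion(875 nt)` on one read.

Classification is a pure function of `(read, model, tol,
min_insertion_len)`; reads sharing an alignment shape share their call,
which the implementation exploits by classifying unique `(position,
CIGAR)` pairs once.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `rq_threshold` | 0.99 | RQ (predicted read accuracy) | the HiFi criterion; reads lacking the tag are retained and counted separately rather than silently dropped |
| `tol` | 5 | bp, each junction end independently | source junction coordinates are exact in IGV-style inspection, but a tolerance absorbs aligner jitter without merging distinct events; raising `tol` can only reduce the number of deviant calls (tested property) |
| `min_insertion_len` | 50 | bp | separates novel-sequence insertions (the event of interest is 875 nt) from HiFi indel noise, which is short |
| `display_min_coverage` | 0 (reports), 100–1000 typical | reads | a *display* threshold only: junctions below it are flagged hidden in Sashimi renderings but always retained in the tables |
| `min_support` | 10 | reads | minimal reads per insertion event/breakpoint consensus |
| `cluster_window` | 20 | bp | single-linkage window for clustering insertion anchors |
| `homopolymer_min` | 10 | bases | terminal homopolymer runs at least this long are reported as `base(xN)` segments; chosen to capture an A(x38) tract while never triggering on random sequence |
| `alpha` | 0.01 | — | two-sided exact binomial test of allele balance; the test and the 1% `near_absent` threshold are reporting conveniences of this package, not published cutoffs |

# Phasing rules

Per marker, the observed base votes REF-allele, ALT-allele, or — when it
matches neither — *artifact*. Unanimous non-artifact votes assign the
allele; conflicting votes, or artifact-only observations, yield
`undefined`; a read covering no marker is `unphaseable`. Two deliberate
choices:

* **Undefined reads are excluded from all allele denominators.** Artifact
  bases at a heterozygous site (e.g. a C or T at a G/A site) carry no
  allele information; including them would dilute both alleles. The
  exclusion is tested as an invariant: adding any number of artifact reads
  leaves allele percentages unchanged.
* **`unphaseable` is kept distinct from `undefined`.** Absence of an
  informative variant inside the amplicon is a property of the subject,
  not a sequencing artifact, and the two situations lead to different
  scientific conclusions (no phasing possible vs. phasing with artifact
  exclusion).
* **Multi-marker conflicts are conservative.** Unanimity is required;
  conflicting markers give `undefined`. Study designs of this kind
  typically have a single informative marker per subject, so the rule is
  mostly a safety net.

When no marker distinguishes alleles, reads are never forced into a
"full/partial defect" verdict; the summary simply reports all reads as
unphaseable.

# Insertion analysis

The inserted sequences of an event are consensus-assembled by
position-wise majority over a length-anchored layout: sequences are
anchored at the insertion start and the consensus length is the median
observed length (rounded down). Ties go to the alphabetically first base
and are counted. At HiFi error rates and ≥ 10 supporting reads the
per-site majority error probability is far below 1/length, so the
consensus is effectively exact; this replaces manual read inspection with
a deterministic, testable procedure.

Element identification uses Smith–Waterman local alignment (Biostrings)
with match +2, mismatch −3 and affine gaps costing `5 + 2·L` for a gap of
length `L`, in both orientations (the reverse hit aligns the reverse
complement of the consensus); percent identity is matches over alignment
columns. The exact alignment parameters behind the original BLAST-style
identification are not published; these are conventional nucleotide
parameters, fixed and configurable, and the test suite pins the
implementation to an independent exhaustive dynamic-programming oracle on
short sequences.

Genomic breakpoint resolution selects reads whose alignments span the
insertion site with anchored flanks, consensus-assembles the inserted
allele, and decomposes it greedily: the best library hit splits the
consensus; residual chunks yield terminal homopolymer runs and literal
remainders. Segments concatenate exactly to the consensus (tested
byte-exactly on error-free data), and the reported total length is always
the computed one — printed totals from descriptions whose segment
arithmetic disagrees are never hard-coded.

Candidate donor sites in inserted sequence are ranked by a 9-mer donor
position weight matrix (log2-odds against a uniform background, built from
literature-standard human U2 donor base frequencies with a small
pseudocount), restricted to windows whose +1/+2 bases are GT. This is
plumbing for "where could the new donor be": it makes no claim of
reproducing dedicated splice-site predictors, whose scores are out of
scope.

# The synthetic generator

The generator is the package's substitute for subject data, which are not
publicly deposited for studies of this kind. It emits coordinate-sorted
indexed BAM alignments whose blocks are constructed *exactly* from each
isoform's exon structure, plus FASTQ and a per-read truth table, all
byte-reproducible under a fixed seed.

What it emulates:

* isoform mixtures at exact proportions (multinomial per read);
* allele-tagging SNV bases, flipped to one of the two non-REF non-ALT
  bases with a configurable artifact rate (drawn uniformly, mirroring
  two-sided artifact observations at a G/A site);
* uniform substitution errors at a configurable per-base rate (default
  0.002 — a free parameter; the per-base error profile of the source data
  is not published), never touching the two bases flanking a junction so
  that junction extraction stays exact and classification tests isolate
  classification logic, and never touching marker positions, which are
  governed by the artifact rate alone;
* per-read RQ from a mixture (default: 97% of reads ≥ 0.99), exercising
  the HiFi filter without dominating it;
* insertion payloads as alignment `I` operations at a declared boundary —
  matching how a spliced long-read aligner represents an internal novel
  segment — and full-length reads over the amplicon (no 5′/3′ truncation
  model), keeping denominators unambiguous.

What it does **not** emulate: chimeric/PCR artifacts, homopolymer-specific
or indel errors, reference bias, alignment ambiguity near junctions, or
real genomic context (presets use synthetic mini-genomes with the same
exon-count topology as the corresponding genes, generated deterministically
from fixed internal seeds). Passing tests therefore demonstrate the
correctness of the analysis logic under the stated error model, not
robustness to aligner behavior on real reads.

## Presets

Preset proportions are the corresponding subjects' reported percentages.
Where a source mixture does not sum to 100% (only some isoforms were
quantified), one filler isoform absorbs the remainder; fillers were chosen
once, as plausible members of each isoform catalog, and are not revisited:

* `P4_IMPG2_ctrl` — canonical 31.4, skip16 18.2, skip16+17 19.5, filler
  30.9% assigned to a natural exon-17 skip;
* `P4_IMPG2_mut` — canonical 39.9, skip16 13.3, skip16+17 16.3, filler
  30.5% assigned to a mutant-specific exon-15 truncation (45 bp);
* `P5_CHM` — co-skip 9.8% as reported; the dominant exon-12 skip set to
  82% and residual canonical 8.2% (the skip magnitude itself is not
  printed for the affected hemizygote);
* `CARRIER_CHM` — co-skip 1.3% as reported; canonical 60%, exon-12 skip
  38.7%;
* `P2_CEP290` — the pseudoexon fraction is set to 50% (a typical
  heterozygous splice defect; only the variant-on-pseudoexon property,
  not the fraction, is quantified in the source);
* `P8/P9/P10_NMNAT1` — allele-1 proportions 90/91/92%: only the
  three-subject mean (91%) is printed, so the presets spread ±1 point
  around it; allele 2 splits evenly between WT splicing and the
  elongation+insertion isoform (the reported ≈50/50 split); marker
  artifact rate 0.005 so the undefined class is exercised.

The bundled element (`SVA_F_synthetic`, 2,514 nt) is a deterministic
synthetic stand-in for an SVA_F retrotransposon — it shares only the
length scale, not the sequence. A canonical donor 9-mer is planted so its
cut site falls at element position 875; the cDNA insertion payload is the
element's first 875 nt (the transcript ends at that cryptic donor), and
the exon-2 elongation is 39 bp, consistent with a donor 914 bp beyond the
exon-2 boundary at the genomic level. The genomic preset's inserted allele
is the composite `[G; inverted element; A(x38); GACTAGAGAACC]`.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open (BED semantics) everywhere;
  reports are 1-based inclusive. A single conversion point prevents
  off-by-one drift; minus-strand transcripts keep all arithmetic genomic
  and only translate exon numbering.
* `junction_percentage` computes `100 * j / t` (multiplication first), so
  `(149, 1000)` yields exactly `14.9`; a zero denominator is an explicit
  error, never `NaN`.
* An empty pseudoexon read set yields an explicit empty-set record
  (`fraction = NA`), not 0 — "no evidence" and "variant absent" must not
  be conflated.
* Reads lacking an RQ tag are retained with a warning and counted
  separately; silently dropping them would bias denominators on data from
  pipelines that strip tags.
* Consensus ties break to the alphabetically first base, with the tie
  count logged; median-of-even-lengths rounds down.
* All percentages are reported with their counts; `audit_run_report()`
  recomputes every percentage from those counts and is run in the tests.

# Problem sizes

The test suite validates preset recovery at n = 50,000 reads per scenario
(the 3σ binomial band at that depth is ±0.48 percentage points for a 14.9%
event) and uses 200–2,000-read scenarios for unit-level checks; the
acceptance script simulates 50,000–100,000 reads per preset. These sizes
were chosen so each scenario runs in well under two minutes on one CPU
while keeping recovery bands a fraction of a percentage point.

# Known limitations

* One transcript model per run (MANE-style); no isoform-database support,
  no de-novo spliced alignment, no NMD-magnitude modeling, no
  protein-consequence prediction beyond deviation frame offsets.
* Partial (5′/3′-truncated) reads are not modeled; on real data they would
  inflate skip calls and should be filtered upstream.
* The donor PWM ranks motifs; it is not a splice-site predictor.
* The depletion test assumes defined reads are independent draws, which
  PCR amplification violates in real libraries; treat its p-values as
  descriptive.
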