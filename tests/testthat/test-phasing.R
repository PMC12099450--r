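# Markers used throughout: a G/A site (ALT tags allele1) and, where a second
# marker is needed, a C/T site downstream on the same read span.
mk1 <- variant_marker("chrT", 105L, "G", "A", "allele2", "allele1", "m1")
mk2 <- variant_marker("chrT", 110L, "C", "T", "allele2", "allele1", "m2")

test_that("single-marker votes follow REF/ALT with artifact bases undefined", {
  # read bases at pos0 105 (6th base of a read starting at 100)
  reads <- manual_reads(c("TTTTTATTTTTT",   # ALT A -> allele1
                          "TTTTTGTTTTTT",   # REF G -> allele2
                          "TTTTTCTTTTTT"),  # C: neither -> undefined
                        pos0 = 100)
  a <- assign_alleles(reads, mk1)
  expect_equal(a$label, c("allele1", "allele2", "undefined"))
  one <- assign_allele(reads[3], mk1)
  expect_equal(one$label, "undefined")
  # a read not covering the marker is unphaseable, not undefined
  far <- manual_reads("TTTT", pos0 = 500)
  expect_equal(assign_alleles(far, mk1)$label, "unphaseable")
})

test_that("conflicting markers yield undefined; unanimity resolves", {
  # marker offsets within a read starting at pos0 100: 105 -> base 6,
  # 110 -> base 11
  seqs <- c(agree1 = "TTTTTATTTTTT",  # 105=A (allele1), 110=T (allele1)
            confl  = "TTTTTATTTTCT",  # 105=A (allele1), 110=C (allele2)
            agree2 = "TTTTTGTTTTCT")  # 105=G (allele2), 110=C (allele2)
  reads <- manual_reads(unname(seqs), pos0 = 100)
  a <- assign_alleles(reads, rbind(mk1, mk2))
  expect_equal(a$label, c("allele1", "undefined", "allele2"))
})

test_that("undefined reads never move allele percentages (exclusion rule)", {
  base <- c(rep("TTTTTATTTTTT", 60), rep("TTTTTGTTTTTT", 40))
  for (k in c(0L, 5L, 50L)) {
    seqs <- c(base, rep("TTTTTCTTTTTT", k))
    a <- assign_alleles(manual_reads(seqs, pos0 = 100), mk1)
    calls <- structure(data.frame(read_id = sprintf("m%03d", seq_along(seqs)),
                                  isoform_key = "canonical",
                                  canonical = TRUE, n_deviations = 0L),
                       class = c("isoform_calls", "data.frame"),
                       deviation_sets = list(canonical = list()),
                       rejected = data.frame())
    s <- allele_summary(a, calls)
    expect_equal(s$alleles$percentage[s$alleles$label == "allele1"], 60)
    expect_equal(s$alleles$percentage[s$alleles$label == "allele2"], 40)
    expect_equal(s$undefined, k)
    expect_equal(sum(s$alleles$percentage), 100)
  }
})

test_that("with no artifacts and full coverage, truth alleles are recovered exactly", {
  m <- make_tiny_model()
  pos <- exon_interval(m, 2)[["start"]] + 7L
  mk <- variant_marker(m$chrom, pos, "G", "A", "allele2", "allele1")
  cfg <- tiny_scenario(list(
    isoform_spec("iso1", list(), "allele1", 0.7),
    isoform_spec("iso2", list(dev_exon_skip(4)), "allele2", 0.3)),
    n_reads = 300, markers = mk, patches = list(list(pos, "G")))
  res <- sim(cfg)
  reads <- read_alignments(res$bam)
  a <- assign_alleles(reads, mk)
  truth <- setNames(res$truth$allele, res$truth$read_id)
  expect_equal(a$label, unname(truth[a$read_id]))
  # allele percentages are invariant under read order permutation
  calls <- classify_reads(reads, m)
  s1 <- allele_summary(a, calls)
  perm <- sample(length(reads))
  s2 <- allele_summary(assign_alleles(reads[perm], mk), calls)
  expect_equal(s1$alleles, s2$alleles)
  # within-allele isoform split: allele2 reads are all aberrant
  wt <- s1$wt_split
  expect_equal(wt$aberrant_percentage[wt$label == "allele2"], 100)
  expect_equal(wt$wt_percentage[wt$label == "allele1"], 100)
})

test_that("allelic depletion flags absent, near-absent and balanced alleles", {
  # absent: single observable allele
  a_abs <- assign_alleles(manual_reads(rep("TTTTTATTTTTT", 50), pos0 = 100), mk1)
  calls <- function(n) structure(
    data.frame(read_id = sprintf("m%03d", seq_len(n)),
               isoform_key = "canonical", canonical = TRUE,
               n_deviations = 0L),
    class = c("isoform_calls", "data.frame"),
    deviation_sets = list(canonical = list()), rejected = data.frame())
  d <- detect_allelic_depletion(allele_summary(a_abs, calls(50)))
  expect_equal(d$flag[d$label == "allele2"], "absent")
  # near-absent: 3 of 2000 reads (0.15%)
  seqs <- c(rep("TTTTTATTTTTT", 1997), rep("TTTTTGTTTTTT", 3))
  d2 <- detect_allelic_depletion(
    allele_summary(assign_alleles(manual_reads(seqs, pos0 = 100), mk1),
                   calls(2000)))
  expect_equal(d2$flag[d2$label == "allele2"], "near_absent")
  expect_equal(d2$fraction[d2$label == "allele2"], 0.0015)
  # balanced 50/50 at n = 1000
  seqs <- c(rep("TTTTTATTTTTT", 500), rep("TTTTTGTTTTTT", 500))
  d3 <- detect_allelic_depletion(
    allele_summary(assign_alleles(manual_reads(seqs, pos0 = 100), mk1),
                   calls(1000)))
  expect_true(all(d3$flag == "balanced"))
  expect_true(all(d3$p_value > 0.01))
})

test_that("phasing requires markers and defined reads", {
  reads <- manual_reads("TTTT", pos0 = 100)
  expect_error(assign_alleles(reads, NULL), "at least one marker")
  a <- assign_alleles(manual_reads(rep("TTTTTCTTTTTT", 4), pos0 = 100), mk1)
  calls <- structure(data.frame(read_id = sprintf("m%03d", 1:4),
                                isoform_key = "canonical", canonical = TRUE,
                                n_deviations = 0L),
                     class = c("isoform_calls", "data.frame"),
                     deviation_sets = list(canonical = list()),
                     rejected = data.frame())
  expect_error(allele_summary(a, calls), "no defined reads")
})
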