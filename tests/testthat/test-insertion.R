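test_that("consensus takes the position-wise majority with alphabetical ties", {
  expect_equal(as.character(consensus_sequence(c("ACGT", "ACGT", "ACCT"))),
               "ACGT")
  expect_equal(as.character(consensus_sequence("TTAA")), "TTAA")
  # tie at every position: alphabetically first base wins, ties are counted
  expect_message(cons <- consensus_sequence(c("AA", "CC")), "2 ambiguous")
  expect_equal(as.character(cons), "AA")
  expect_equal(attr(cons, "n_ambiguous"), 2L)
  # consensus length is the median observed length
  expect_equal(nchar(consensus_sequence(c("AAAA", "AAAA", "AA"))), 4L)
  expect_error(consensus_sequence(character(0)), "no supporting")
})

test_that("insertion events are clustered by anchor and support-filtered", {
  m <- make_tiny_model()
  e2 <- exon_interval(m, 2); e5 <- exon_interval(m, 5)
  p1 <- random_seq(120); p2 <- random_seq(70)
  cfg <- tiny_scenario(list(
    isoform_spec("insA", list(dev_insertion(e2[["end"]], 120L, payload = "a")),
                 NA, 0.5),
    isoform_spec("insB", list(dev_insertion(e5[["start"]] + 10L, 70L,
                                            payload = "b")), NA, 0.5)),
    n_reads = 60, payloads = list(a = p1, b = p2))
  res <- sim(cfg)
  reads <- read_alignments(res$bam)
  ev <- collect_insertion_reads(reads, min_support = 5)
  expect_equal(length(ev), 2L)  # two payloads far apart -> two events
  lens <- sort(vapply(ev, function(e) e$length_stats[["median"]], numeric(1)))
  expect_equal(lens, c(70, 120))
  # error-free: consensus equals the configured payload exactly
  cons <- vapply(ev, `[[`, character(1), "consensus")
  expect_setequal(cons, c(p1, p2))
  # insufficient support yields no events; no insertions yield an empty list
  expect_equal(length(collect_insertion_reads(reads, min_support = 1e6)), 0L)
  cfg2 <- tiny_scenario(list(isoform_spec("WT", list(), NA, 1.0)), n_reads = 10)
  expect_equal(collect_insertion_reads(read_alignments(sim(cfg2)$bam)), list())
})

test_that("element identification is exact and orientation-symmetric", {
  lib <- preset_element_library()
  elem <- as.character(lib[[1]])
  sub <- substr(elem, 301, 800)
  fwd <- identify_element(sub, lib)
  expect_true(fwd$hit)
  expect_equal(fwd$percent_identity, 100)
  expect_equal(fwd$orientation, "forward")
  expect_equal(fwd$element_span, c(301L, 800L))
  rev <- identify_element(ampliSplice:::reverse_complement(sub), lib)
  expect_equal(rev$orientation, "reverse")
  expect_equal(rev$score, fwd$score)
  expect_equal(rev$percent_identity, fwd$percent_identity)
  expect_equal(rev$element_span, fwd$element_span)
  # random junk below the score threshold: explicit no-hit
  none <- identify_element("ACGT", lib, min_score = 30)
  expect_false(none$hit)
})

test_that("local alignment scores agree with the exhaustive DP oracle", {
  set.seed(99)
  for (i in 1:25) {
    a <- random_seq(sample(8:50, 1)); b <- random_seq(sample(8:50, 1))
    aln <- ampliSplice:::sw_align(a, b)
    expect_equal(Biostrings::score(aln), sw_oracle_score(a, b),
                 info = sprintf("pair %d: %s vs %s", i, a, b))
  }
  # a pair that forces an internal gap
  a <- paste0(strrep("A", 10), strrep("G", 10), strrep("T", 10))
  b <- paste0(strrep("A", 10), strrep("G", 10), strrep("C", 5), strrep("T", 10))
  expect_equal(Biostrings::score(ampliSplice:::sw_align(a, b)),
               sw_oracle_score(a, b))
  expect_equal(sw_oracle_score(a, b), 45)  # 30 matches - (5 + 2 * 5)
})

test_that("genomic insertion alleles are reconstructed byte-exactly", {
  g <- preset_genomic_insertion(tempfile("gen_"))
  reads <- read_alignments(g$bam)
  allele <- resolve_genomic_insertion(reads, g$locus, g$library)
  expect_equal(paste(allele$segments$seq, collapse = ""), g$payload)
  expect_equal(allele$total_length, nchar(g$payload))
  expect_equal(sum(allele$segments$length), allele$total_length)
  expect_equal(allele$segments$kind,
               c("literal", "element_fragment", "homopolymer", "literal"))
  expect_equal(allele$segments$orientation[2], "reverse")
  expect_equal(allele$supporting_reads, 14L)
  expect_match(format_insertion_allele(allele), "^g\\.\\d+_\\d+ins\\[")
  # under min_support the error names the observed count
  expect_error(resolve_genomic_insertion(reads[1:3], g$locus, g$library),
               "only 3")
  # pure forward payload: a single element_fragment segment
  sc <- ampliSplice:::nmnat1_scaffold()
  e2 <- exon_interval(sc$model, 2)
  pf <- as.character(g$library[[1]])
  g2 <- simulate_genomic_reads(sc$reference, sc$model$chrom,
                               c(e2[["start"]] - 100L, e2[["end"]] + 500L),
                               e2[["end"]] + 39L, pf, n_reads = 12,
                               seed = 2, outdir = tempfile("gen2_"))
  a2 <- resolve_genomic_insertion(read_alignments(g2$bam),
                                  c(e2[["end"]], e2[["end"]] + 80L), g$library)
  expect_equal(a2$segments$kind, "element_fragment")
  expect_equal(a2$segments$orientation, "forward")
  expect_equal(a2$consensus, pf)
})

test_that("consensus identity to the source never increases with error rate", {
  lib <- preset_element_library()
  sc <- ampliSplice:::nmnat1_scaffold()
  e2 <- exon_interval(sc$model, 2)
  pf <- substr(as.character(lib[[1]]), 1, 400)
  ident <- vapply(c(0, 0.05, 0.2), function(rate) {
    g <- simulate_genomic_reads(sc$reference, sc$model$chrom,
                                c(e2[["start"]] - 80L, e2[["end"]] + 300L),
                                e2[["end"]] + 10L, pf, n_reads = 3,
                                substitution_error_rate = rate, seed = 31,
                                outdir = tempfile("err_"))
    ev <- collect_insertion_reads(read_alignments(g$bam), min_support = 3)
    identify_element(ev[[1]]$consensus, lib)$percent_identity
  }, numeric(1))
  expect_equal(ident[1], 100)
  expect_true(all(diff(ident) <= 0))
})

test_that("donor-site scanning ranks a planted canonical donor first", {
  set.seed(7)
  s <- random_seq(300)
  substr(s, 150, 158) <- "CAGGTAAGT"  # last exonic base lands at 152
  hits <- score_donor_sites(s, top_k = 5)
  expect_equal(hits$position[1], 152L)
  expect_true(all(hits$passes_gt_rule))
  # all-A sequence: nothing passes the GT rule
  expect_equal(nrow(score_donor_sites(strrep("A", 50))), 0L)
  expect_error(score_donor_sites("ACGT"), "shorter than PWM width")
  # the bundled element carries its donor at position 875
  elem <- as.character(preset_element_library()[[1]])
  expect_true(875L %in% score_donor_sites(elem, top_k = 3)$position)
})
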