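test_that("RQ filtering keeps reads at or above the threshold", {
  reads <- manual_reads(c("ACGTACGT", "ACGTACGT", "ACGTACGT"), pos0 = 100,
                        rq = c(0.995, 0.99, 0.989))
  kept <- filter_by_rq(reads, 0.99)
  expect_equal(length(kept), 2L)
  expect_equal(attr(kept, "rq_dropped"), 1L)
  expect_equal(length(filter_by_rq(reads, 0)), 3L)
  # reads without an RQ tag are retained with a warning, counted separately
  reads$rq[2] <- NA
  expect_warning(kept <- filter_by_rq(reads, 0.99), "lack an RQ tag")
  expect_equal(length(kept), 2L)
  expect_equal(attr(kept, "rq_missing"), 1L)
  expect_error(filter_by_rq(reads, 1.2), "\\[0, 1\\]")
})

test_that("junction chains reflect skips and pseudoexons", {
  m <- make_tiny_model()
  cfg <- tiny_scenario(list(
    isoform_spec("WT", list(), NA, 0.4),
    isoform_spec("skip3", list(dev_exon_skip(3)), NA, 0.3),
    isoform_spec("pe", list(dev_pseudoexon(exon_interval(m, 4)[["end"]] + 10L,
                                           exon_interval(m, 4)[["end"]] + 25L)),
                 NA, 0.3)), n_reads = 60)
  res <- sim(cfg)
  reads <- read_alignments(res$bam)
  canon <- canonical_junctions(m)
  e2 <- exon_interval(m, 2); e3 <- exon_interval(m, 3); e4 <- exon_interval(m, 4)
  for (i in seq_len(length(reads))) {
    chain <- extract_junction_chain(reads[i])
    iso <- res$truth$isoform[res$truth$read_id == reads$read_id[i]]
    if (iso == "WT") {
      expect_equal(nrow(chain), 5L)
    } else if (iso == "skip3") {
      # both exon-3 junctions absent, replaced by (end of ex2, start of ex4)
      expect_equal(nrow(chain), 4L)
      expect_true(any(chain$donor_end == e2[["end"]] &
                        chain$acceptor_start == e4[["start"]]))
      expect_false(any(chain$acceptor_start == e3[["start"]]))
    } else {
      # pseudoexon: two junctions flank an intra-intronic block
      expect_equal(nrow(chain), 6L)
      expect_true(any(chain$acceptor_start == e4[["end"]] + 10L))
      expect_true(any(chain$donor_end == e4[["end"]] + 25L))
    }
  }
})

test_that("classification decomposes reads into composed deviation sets", {
  m <- make_tiny_model()
  e2 <- exon_interval(m, 2)
  payload <- random_seq(80)
  cfg <- tiny_scenario(list(
    isoform_spec("WT", list(), NA, 0.2),
    isoform_spec("coskip", list(dev_exon_skip(c(3, 4))), NA, 0.2),
    isoform_spec("trunc", list(dev_exon_truncation(5, 12, "acceptor")), NA, 0.2),
    isoform_spec("pe", list(dev_pseudoexon(exon_interval(m, 4)[["end"]] + 8L,
                                           exon_interval(m, 4)[["end"]] + 24L)),
                 NA, 0.2),
    isoform_spec("elong_ins",
                 list(dev_exon_elongation(2, 10, "donor"),
                      dev_insertion(e2[["end"]] + 10L, 80L, payload = "p")),
                 NA, 0.2)),
    n_reads = 150, payloads = list(p = payload))
  res <- sim(cfg)
  reads <- read_alignments(res$bam)
  calls <- classify_reads(reads, m)
  truth_by_id <- setNames(res$truth$isoform, res$truth$read_id)
  expected_key <- c(
    WT = "canonical", coskip = "skip:3+4",
    trunc = "trunc:5:acceptor:12",
    pe = sprintf("pe:%d-%d", exon_interval(m, 4)[["end"]] + 9L,
                 exon_interval(m, 4)[["end"]] + 24L),
    elong_ins = sprintf("elong:2:donor:10|ins:%d:80", e2[["end"]] + 11L))
  expect_equal(unname(expected_key[truth_by_id[calls$read_id]]),
               calls$isoform_key)
  # canonical flag <=> empty deviation set
  expect_equal(calls$canonical, calls$n_deviations == 0L)
  # a single-read call carries the deviation objects
  one <- classify_read(reads[which(truth_by_id[reads$read_id] == "coskip")[1]], m)
  expect_equal(length(one$deviations), 1L)
  expect_equal(one$deviations[[1]]$exons, c(3L, 4L))
})

test_that("sub-threshold insertions are ignored as indel noise", {
  m <- make_tiny_model()
  e2 <- exon_interval(m, 2)
  cfg <- tiny_scenario(list(
    isoform_spec("smallins", list(dev_insertion(e2[["end"]], 20L, payload = "p")),
                 NA, 1.0)), n_reads = 20, payloads = list(p = random_seq(20)))
  res <- sim(cfg)
  calls <- classify_reads(read_alignments(res$bam), m, min_insertion_len = 50)
  expect_true(all(calls$canonical))
  calls2 <- classify_reads(read_alignments(res$bam), m, min_insertion_len = 10)
  expect_true(all(!calls2$canonical))
})

test_that("raising tol never increases deviant calls; classification is pure", {
  m <- make_tiny_model()
  cfg <- tiny_scenario(list(
    isoform_spec("WT", list(), NA, 0.4),
    isoform_spec("t3", list(dev_exon_truncation(3, 3, "donor")), NA, 0.3),
    isoform_spec("t4", list(dev_exon_truncation(4, 8, "donor")), NA, 0.3)),
    n_reads = 120)
  res <- sim(cfg)
  reads <- read_alignments(res$bam)
  deviant <- vapply(c(0, 2, 5, 10), function(tol)
    sum(!classify_reads(reads, m, tol = tol)$canonical), integer(1))
  expect_true(all(diff(deviant) <= 0))
  # 3-bp truncation is within the default 5-bp tolerance, 8-bp is not
  calls5 <- classify_reads(reads, m, tol = 5)
  truth_by_id <- setNames(res$truth$isoform, res$truth$read_id)
  expect_true(all(calls5$canonical[truth_by_id[calls5$read_id] == "t3"]))
  expect_true(all(!calls5$canonical[truth_by_id[calls5$read_id] == "t4"]))
  expect_identical(classify_reads(reads, m, tol = 5), calls5)
})

test_that("junction percentage implements the formula exactly", {
  expect_identical(junction_percentage(149, 1000), 14.9)
  expect_identical(junction_percentage(0, 1000), 0)
  expect_error(junction_percentage(1, 0), "total_reads is 0")
  expect_error(junction_percentage(5, 3), "junction_reads <= total_reads")
})

test_that("junction tables conserve reads and flag hidden junctions", {
  cfg <- preset("P4_IMPG2_mut", n_reads = 400, seed = 13)
  res <- sim(cfg)
  reads <- suppressWarnings(filter_by_rq(read_alignments(res$bam)))
  calls <- classify_reads(reads, cfg$model, cfg$amplicon)
  jt <- build_junction_table(calls, reads, display_min_coverage = 100)
  expect_equal(sum(jt$isoforms$count), jt$total_reads)
  expect_true(all(jt$junctions$percentage >= 0 & jt$junctions$percentage <= 100))
  expect_equal(jt$junctions$hidden, jt$junctions$count < 100)
  # hidden junctions stay in the table
  expect_true(all(table(jt$junctions$hidden) > 0))
  expect_error(build_junction_table(calls, reads[1:5]), "mismatched read ids")
  # all-canonical scenario: a single isoform key at 100%
  cfg2 <- tiny_scenario(list(isoform_spec("WT", list(), NA, 1.0)), n_reads = 25)
  res2 <- sim(cfg2)
  reads2 <- read_alignments(res2$bam)
  jt2 <- build_junction_table(classify_reads(reads2, cfg2$model), reads2)
  expect_equal(jt2$isoforms$isoform_key, "canonical")
  expect_equal(jt2$isoforms$percentage, 100)
})

test_that("junction counts match a brute-force CIGAR walk", {
  cfg <- preset("P4_IMPG2_mut", n_reads = 300, seed = 21)
  res <- sim(cfg)
  reads <- read_alignments(res$bam)
  calls <- classify_reads(reads, cfg$model, cfg$amplicon)
  jt <- build_junction_table(calls, reads)
  oracle <- brute_force_bam_counts(res$bam)
  got <- setNames(jt$junctions$count,
                  sprintf("%d-%d", jt$junctions$donor_end,
                          jt$junctions$acceptor_start))
  expect_mapequal(as.list(got), as.list(unclass(oracle$junctions)))
})

test_that("the deep-intronic variant rides on every pseudoexon read", {
  cfg <- preset("P2_CEP290", n_reads = 300, seed = 11)
  res <- sim(cfg)
  reads <- suppressWarnings(filter_by_rq(read_alignments(res$bam)))
  mk <- cfg$markers
  pe <- c(mk$pos - 30L, mk$pos - 30L + 97L)
  chk <- variant_in_pseudoexon_check(reads, pe, mk)
  expect_false(chk$empty)
  expect_equal(chk$fraction, 1.0)
  # all-canonical data: explicit empty-set result, not zero
  cfg2 <- tiny_scenario(list(isoform_spec("WT", list(), NA, 1.0)), n_reads = 20)
  res2 <- sim(cfg2)
  m <- make_tiny_model()
  pe2 <- c(exon_interval(m, 2)[["end"]] + 5L, exon_interval(m, 2)[["end"]] + 20L)
  v <- variant_marker("chrT", pe2[1] + 3L, "A", "G")
  chk2 <- variant_in_pseudoexon_check(read_alignments(res2$bam), pe2, v)
  expect_true(chk2$empty)
  expect_true(is.na(chk2$fraction))
  expect_error(variant_in_pseudoexon_check(read_alignments(res2$bam), pe2,
                                           variant_marker("chrT", 1L, "A", "G")),
               "not inside the pseudoexon")
})
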