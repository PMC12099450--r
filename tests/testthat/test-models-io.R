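test_that("BED12 round trip preserves the model on both strands", {
  for (strand in c("+", "-")) {
    m <- make_tiny_model(n_exons = 5, strand = strand)
    path <- tempfile(fileext = ".bed")
    write_bed12(m, path)
    m2 <- load_transcript_model(path, "BED12")
    expect_equal(m2$exons, m$exons)
    expect_equal(m2$strand, m$strand)
    expect_equal(m2$chrom, m$chrom)
    expect_equal(m2$transcript_id, m$transcript_id)
    expect_equal(m2$gene_symbol, m$gene_symbol)
  }
})

test_that("exon numbering follows transcript orientation", {
  plus <- make_tiny_model(strand = "+")
  minus <- make_tiny_model(strand = "-")
  # exon 1 is leftmost on plus, rightmost on minus
  expect_equal(exon_interval(plus, 1)[["start"]], min(plus$exons$start))
  expect_equal(exon_interval(minus, 1)[["start"]], max(minus$exons$start))
  # numbering <-> genomic order is a bijection on both strands
  for (m in list(plus, minus))
    expect_setequal(m$exons$exon, seq_len(nrow(m$exons)))
})

test_that("malformed or unsorted BED12 records are rejected with location", {
  bad <- tempfile(fileext = ".bed")
  writeLines("chrT\t0\t100\tTX\t0\t+", bad)  # 6 fields only
  expect_error(load_transcript_model(bad, "BED12"), "line 1")
  unsorted <- tempfile(fileext = ".bed")
  writeLines(paste("chrT", 0, 300, "TX", 0, "+", 0, 0, "0,0,0", 2,
                   "50,50,", "200,0,", sep = "\t"), unsorted)
  expect_error(load_transcript_model(unsorted, "BED12"))
})

test_that("GFF3 exons grouped by Parent load with minus-strand numbering", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrT\tsrc\tgene\t1\t500\t.\t-\t.\tID=g1;gene_name=TSTG",
               "chrT\tsrc\tmRNA\t1\t500\t.\t-\t.\tID=tx1;Parent=g1",
               "chrT\tsrc\texon\t101\t140\t.\t-\t.\tParent=tx1",
               "chrT\tsrc\texon\t201\t240\t.\t-\t.\tParent=tx1"), gff)
  m <- load_transcript_model(gff, "GFF3", transcript_id = "tx1")
  expect_equal(nrow(m$exons), 2L)
  expect_equal(m$strand, "-")
  # exon 1 is the genomically rightmost interval (0-based 200-240)
  expect_equal(exon_interval(m, 1)[["start"]], 200L)
  expect_error(load_transcript_model(gff, "GFF3", transcript_id = "nope"),
               "unknown transcript_id")
})

test_that("amplicon validation enforces exon range and WT length", {
  m <- make_tiny_model(n_exons = 6, exon_len = 40)
  expect_error(amplicon(m, 4, 4), "first_exon < last_exon")
  expect_error(amplicon(m, 2, 5, expected_wt_length = 100), "summed exon")
  a <- amplicon(m, 2, 5, expected_wt_length = 160)
  expect_equal(a$expected_wt_length, 160L)
  expect_equal(nrow(canonical_junctions(m, a)), 3L)
  expect_equal(nrow(canonical_junctions(m)), 5L)
})

test_that("marker loading keeps in-amplicon SNVs and rejects indels", {
  m <- make_tiny_model()
  amp <- amplicon(m, 1, 6)
  path <- tempfile(fileext = ".tsv")
  inside <- exon_interval(m, 3)[["start"]] + 5L
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tINFO",
               sprintf("chrT\t%d\tsnv1\tG\tA\tALLELES=a2,a1", inside + 1L),
               "chrT\t10000\tfar\tC\tT\tALLELES=a2,a1"), path)
  expect_warning(mk <- load_markers(path, amp), "outside the amplicon")
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$pos, inside)          # 1-based file -> 0-based internal
  expect_equal(mk$allele_label_alt, "a1")
  writeLines("chrT\t150\tins1\tG\tGA\t.", path)
  expect_error(load_markers(path, amp), "SNV markers only")
})

test_that("marker round trip through the tab format is lossless", {
  m <- make_tiny_model()
  mk <- variant_marker("chrT", 155L, "G", "A", "wt", "mut", "c.10G>A")
  path <- tempfile(fileext = ".tsv")
  write_markers(mk, path)
  mk2 <- load_markers(path, amplicon(m, 1, 6))
  expect_equal(mk2, mk, ignore_attr = TRUE)
})

test_that("element library loading validates names and case", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">el1", "acgtacgt"), fa)
  lib <- load_element_library(fa)
  expect_equal(as.character(lib[["el1"]]), "ACGTACGT")
  writeLines(c(">dup", "ACGT", ">dup", "TTTT"), fa)
  expect_error(load_element_library(fa), "duplicate element name")
  writeLines(character(0), fa)
  expect_error(load_element_library(fa))
})
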