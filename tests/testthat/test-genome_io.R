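test_that("read_replicons folds case, preserves order, validates alphabet", {
  p <- write_fasta_tmp(list(r1 = "acgt"))
  reps <- read_replicons(p)
  expect_length(reps, 1)
  expect_equal(reps[[1]]$sequence, "ACGT")
  expect_equal(reps[[1]]$length, 4)

  p2 <- write_fasta_tmp(list(alpha = "ACGTACGT", beta = "ggcc"))
  reps2 <- read_replicons(p2)
  expect_equal(vapply(reps2, `[[`, "", "id"), c("alpha", "beta"))

  p3 <- write_fasta_tmp(list(bad = "ACGTACXT"))
  expect_error(read_replicons(p3), "position 7")
  expect_error(read_replicons(tempfile()), "no such file")
})

test_that("read_features converts GFF3 coordinates, phase and strand", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t9\t.\t+\t0\tID=a",
               "chr\tx\tCDS\t11\t19\t.\t-\t2\tID=b",
               "chr\tx\tCDS\t21\t29\t.\t.\t0\tID=c"), gff)
  expect_message(ft <- read_features(gff), "unknown strand")
  expect_equal(nrow(ft), 2)
  expect_equal(ft$start, c(0L, 10L))
  expect_equal(ft$end, c(9L, 19L))
  expect_equal(ft$frame_offset, c(0L, 2L))
  expect_equal(ft$strand, c("+", "-"))
})

test_that("out-of-bounds features warn and drop, or raise in strict mode", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t9\t.\t+\t0\tID=a",
               "chr\tx\tCDS\t5\t50\t.\t+\t0\tID=b"), gff)
  expect_warning(ft <- read_features(gff, seq_lengths = c(chr = 20L)),
                 "beyond replicon length")
  expect_equal(nrow(ft), 1)
  expect_error(read_features(gff, seq_lengths = c(chr = 20L), strict = TRUE),
               "beyond replicon length")
})

test_that("GenBank records parse: topology, completeness, CDS locations", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTREC                   60 bp    DNA     circular BCT 01-JAN-2026",
    "DEFINITION  Test organism chromosome, complete genome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             4..15",
    "                     /codon_start=1",
    "     CDS             complement(20..31)",
    "                     /codon_start=2",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), gb)
  reps <- read_replicons(gb, "genbank")
  expect_equal(reps[[1]]$id, "TESTREC")
  expect_equal(reps[[1]]$topology, "circular")
  expect_equal(reps[[1]]$completeness, "complete")
  expect_equal(reps[[1]]$length, 60)
  ft <- read_features(gb, "genbank")
  expect_equal(ft$start, c(3L, 19L))
  expect_equal(ft$end, c(15L, 31L))
  expect_equal(ft$strand, c("+", "-"))
  expect_equal(ft$frame_offset, c(0L, 1L))
})

test_that("codon labels follow reading frame on both strands", {
  r <- replicon("r", "ACGTAC")
  plus <- feature_table("r", 0L, 6L, "+", 0L)
  expect_equal(build_position_labels(r, plus)$codon_label,
               c(1L, 2L, 3L, 1L, 2L, 3L))
  minus <- feature_table("r", 0L, 6L, "-", 0L)
  expect_equal(build_position_labels(r, minus)$codon_label,
               c(3L, 2L, 1L, 3L, 2L, 1L))
  # frame offset skips bases before the first full codon
  off <- feature_table("r", 0L, 6L, "+", 1L)
  expect_equal(build_position_labels(r, off)$codon_label,
               c(0L, 1L, 2L, 3L, 1L, 2L))
  # features shorter than one codon after the offset contribute nothing
  short <- feature_table("r", 0L, 4L, "+", 2L)
  expect_equal(build_position_labels(r, short)$codon_label, rep(0L, 6))
})

test_that("overlap priority and strand cover match the brute-force labeler", {
  for (seed in 1:8) {
    r <- random_replicon(60, seed)
    ft <- random_features("rnd", 60, 5, seed + 100)
    got <- build_position_labels(r, ft)
    want <- brute_labels(r, ft)
    expect_equal(got$codon_label, want$codon_label,
                 info = paste("seed", seed))
    expect_equal(got$strand_cover, want$strand_cover,
                 info = paste("seed", seed))
  }
})

test_that("label map invariants hold", {
  r <- random_replicon(300, 42)
  ft <- random_features("rnd", 300, 6, 43, disjoint = TRUE)
  lab <- build_position_labels(r, ft)
  expect_length(lab$codon_label, 300)
  expect_length(lab$strand_cover, 300)
  covered <- logical(300)
  for (i in seq_len(nrow(ft)))
    covered[(ft$start[i] + 1):ft$end[i]] <- TRUE
  expect_true(all(lab$codon_label[!covered] == 0L))
  # a single in-frame CDS yields equal counts of the three codon labels
  len <- 30L
  one <- feature_table("rnd", 10L, 10L + len, "+", 0L)
  l1 <- build_position_labels(r, one)$codon_label
  expect_equal(sum(l1 == 1L), sum(l1 == 2L))
  expect_equal(sum(l1 == 2L), sum(l1 == 3L))
})

test_that("feature tables round-trip through GFF3", {
  ft <- random_features("chr", 500, 7, 7)
  path <- tempfile(fileext = ".gff3")
  write_features_gff3(ft, path)
  back <- read_features(path)
  expect_equal(back$start, ft$start)
  expect_equal(back$end, ft$end)
  expect_equal(back$strand, ft$strand)
  expect_equal(back$frame_offset, ft$frame_offset)
})

test_that("mismatched feature tables are rejected", {
  r <- replicon("a", "ACGTACGT")
  expect_error(build_position_labels(r, feature_table("b", 0L, 6L, "+", 0L)),
               "replicon ids")
  expect_error(build_position_labels(r, feature_table("a", 0L, 20L, "+", 0L)),
               "out of bounds")
})
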