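# Gene-model parsing and projection of introns into protein coordinates.

make_gff <- function(lines, file = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), file)
  file
}

test_that("GFF3 coordinates convert to 0-based half-open intervals", {
  f <- make_gff(c(
    "chr1\tsrc\tgene\t101\t260\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t260\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t160\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\tsrc\texon\t201\t260\t.\t+\t.\tID=t1.e2;Parent=t1",
    "chr1\tsrc\tCDS\t101\t160\t.\t+\t0\tID=t1.c;Parent=t1",
    "chr1\tsrc\tCDS\t201\t260\t.\t+\t0\tID=t1.c;Parent=t1"))
  models <- parse_gff(f, species = "human")
  expect_length(models, 1L)
  m <- models[["t1"]]
  expect_equal(m$exons, matrix(c(100L, 200L, 160L, 260L), ncol = 2))
  expect_equal(m$strand, "+")
  expect_equal(m$species, "human")
})

test_that("minus-strand exons are reordered into transcription order", {
  f <- make_gff(c(
    "chr1\tsrc\tmRNA\t101\t260\t.\t-\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t160\t.\t-\t.\tID=t1.e1;Parent=t1",
    "chr1\tsrc\texon\t201\t260\t.\t-\t.\tID=t1.e2;Parent=t1",
    "chr1\tsrc\tCDS\t101\t160\t.\t-\t0\tID=t1.c;Parent=t1",
    "chr1\tsrc\tCDS\t201\t260\t.\t-\t0\tID=t1.c;Parent=t1"))
  m <- parse_gff(f)[["t1"]]
  # first exon in transcription order is the genomically-rightmost one
  expect_equal(m$exons[1, ], c(200L, 260L))
  expect_equal(m$exons[2, ], c(100L, 160L))
})

test_that("CDS length not divisible by 3 is a malformed-model error", {
  f <- make_gff(c(
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=tbad;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=tbad.e1;Parent=tbad",
    "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=tbad.c;Parent=tbad"))
  expect_error(parse_gff(f), "tbad")
})

test_that("a transcript without CDS is skipped with a warning", {
  f <- make_gff(c(
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=tnc;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=tnc.e1;Parent=tnc"))
  expect_warning(models <- parse_gff(f), "no CDS")
  expect_length(models, 0L)
})

test_that("intron marks: phase arithmetic and the left-of rule", {
  # CDS split 12 + 18 nt: c = 12, phase 0, X between residues 4 and 5
  m <- gene_model("s", "g", "t", "c", "+",
                  exons = rbind(c(0, 12), c(100, 118)),
                  cds = rbind(c(0, 12), c(100, 118)))
  mk <- intron_marks(m)
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$coding_offset, 12)
  expect_equal(mk$phase, 0)
  expect_equal(mk$protein_index, 5)
  expect_equal(mk$intron_length, 88)

  # CDS split 13 + 17: c = 13, phase 1, X left of residue 5
  m2 <- gene_model("s", "g", "t", "c", "+",
                   exons = rbind(c(0, 13), c(100, 117)),
                   cds = rbind(c(0, 13), c(100, 117)))
  mk2 <- intron_marks(m2)
  expect_equal(mk2$coding_offset, 13)
  expect_equal(mk2$phase, 1)
  expect_equal(mk2$protein_index, 5)

  # single-exon gene: no marks
  m3 <- gene_model("s", "g", "t", "c", "+",
                   exons = rbind(c(0, 30)), cds = rbind(c(0, 30)))
  expect_equal(nrow(intron_marks(m3)), 0L)
})

test_that("X insertion follows the left-of rule, including mid-codon", {
  mk0 <- data.frame(ordinal = 1, coding_offset = 6, protein_index = 3,
                    phase = 0, intron_length = 100, start = 0, end = 100)
  expect_equal(mark_protein("MKVLQ", mk0)$marked, "MKXVLQ")
  expect_equal(mark_protein("MKVLQ", mk0[0, ])$marked, "MKVLQ")

  # two marks, phases 0 and 2, at c = 6 and c = 11
  mk2 <- data.frame(ordinal = 1:2, coding_offset = c(6, 11),
                    protein_index = c(3, 4), phase = c(0, 2),
                    intron_length = c(100, 100), start = c(0, 0),
                    end = c(100, 100))
  got <- mark_protein("MKVLQ", mk2)$marked
  expect_equal(got, "MKXVXLQ")
  # cross-check with the codon-walk oracle: CDS pieces of 6, 5, 7 nt
  expect_equal(got, oracle_marked_from_pieces("MKVLQ", c(6, 5, 7)))
})

test_that("marks beyond the protein end are rejected as out of range", {
  mk <- data.frame(ordinal = 1, coding_offset = 15, protein_index = 6,
                   phase = 0, intron_length = 50, start = 0, end = 50)
  expect_error(mark_protein("MKVLQ", mk), "out of range")
})

test_that("mark/unmark round-trips on random proteins", {
  set.seed(101)
  aa <- aa_alphabet()
  for (i in 1:50) {
    L <- sample(20:200, 1)
    p <- paste(sample(aa, L, replace = TRUE), collapse = "")
    n_introns <- sample(0:6, 1)
    c_offs <- sort(sample(seq(3, 3 * L - 3), n_introns))
    n <- length(c_offs)
    mk <- data.frame(ordinal = seq_len(n), coding_offset = c_offs,
                     protein_index = c_offs %/% 3 + 1, phase = c_offs %% 3,
                     intron_length = rep(90, n), start = rep(0, n),
                     end = rep(90, n))
    mp <- mark_protein(p, mk)
    expect_equal(nchar(mp$marked), L + n_introns)
    expect_identical(unmark_protein(mp), p)
  }
})

test_that("expected gap residues is one third of the intron length", {
  expect_equal(expected_gap_residues(300), 100)
  expect_equal(expected_gap_residues(90), 30)
  expect_equal(expected_gap_residues(91), 30)  # nearest, ties to even
  expect_error(expected_gap_residues(0), "positive")
})

test_that("exon tables read into equivalent gene models", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "transcript\tchrom\tstrand\texon_start\texon_end\tcds_start\tcds_end",
    "t1\tchr2\t+\t101\t160\t101\t160",
    "t1\tchr2\t+\t201\t260\t201\t260"), f)
  m <- read_exon_table(f, species = "s")[["t1"]]
  expect_equal(m$exons, matrix(c(100L, 200L, 160L, 260L), ncol = 2))
  expect_equal(nrow(intron_marks(m)), 1L)
})
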