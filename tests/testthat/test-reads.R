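mkRecords <- function(strand = "+") {
  set.seed(33)
  s <- randomRna(100)
  PrecursorSet(data.frame(id = "p1", chrom = "c1", start = 101L, end = 200L,
                          strand = strand, sources = "db"),
               c(p1 = s))
}

test_that("read stacks keep contained reads in precursor coordinates", {
  aln <- data.frame(sample = "s1", chrom = "c1",
                    start = c(111L, 111L, 95L, 195L), # last two overhang
                    end = c(131L, 131L, 120L, 215L),
                    strand = "+", count = c(3L, 2L, 1L, 1L))
  stk <- buildReadStack(aln, mkRecords("+"), "p1")
  e <- stackEntries(stk)
  expect_equal(nrow(e), 1L)               # overhanging reads excluded
  expect_equal(e$offset, 11L)             # 111 on a precursor starting 101
  expect_equal(e$length, 21L)
  expect_equal(e$count, 5)                # counts summed per key
})

test_that("minus-strand stacks flip coordinates from the 3' genomic end", {
  aln <- data.frame(sample = "s1", chrom = "c1", start = 111L, end = 131L,
                    strand = "-", count = 1L)
  stk <- buildReadStack(aln, mkRecords("-"), "p1")
  expect_equal(stackEntries(stk)$offset, 200L - 131L + 1L)
})

test_that("stacking an unlocated or unknown precursor errors", {
  ps <- PrecursorSet(data.frame(id = "u1", chrom = NA_character_,
                                start = NA_integer_, end = NA_integer_,
                                strand = NA_character_, sources = "db"),
                     c(u1 = "ACGUACGUACGUACGUACGUACGU"))
  aln <- data.frame(sample = "s1", chrom = "c1", start = 1L, end = 21L,
                    strand = "+", count = 1L)
  expect_error(buildReadStack(aln, ps, "u1"), "unlocated")
  expect_error(buildReadStack(aln, ps, "nope"), "unknown")
})

test_that("TPM follows count / total * 1e6 and errors on zero totals", {
  counts <- matrix(c(5, 95, 0, 100), nrow = 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  tpm <- computeTpm(counts, c(s1 = 100, s2 = 100))
  expect_equal(tpm["a", "s1"], 50000)
  expect_equal(tpm["b", "s1"], 950000)
  expect_equal(tpm["a", "s2"], 0)
  expect_equal(tpm["b", "s2"], 1e6)  # one entity holding all reads
  expect_error(computeTpm(counts, c(s1 = 100, s2 = 0)), "s2")
  expect_error(computeTpm(counts, c(s1 = 100)), "s2")
  # conservation: columns sum to 1e6 when entities partition the library
  expect_equal(unname(colSums(tpm)), c(1e6, 1e6))
})

test_that("expression breadth uses a strict fraction cutoff", {
  tpm <- rbind(broad = c(rep(2, 98), rep(0, 97)),
               boundary = c(rep(2, 98), rep(0, 98)) [1:195],
               silent = rep(0, 195))
  tpm["boundary", ] <- c(rep(2, 97), rep(0, 98))  # below half
  half <- rbind(half = c(rep(2, 5), rep(0, 5)))
  br <- expressionBreadth(tpm, tpmMin = 1, fracMin = 0.5)
  expect_true(br$broad[br$id == "broad"])          # 98/195 > 0.5
  expect_false(br$broad[br$id == "boundary"])
  expect_equal(br$breadth[br$id == "silent"], 0)
  expect_false(br$broad[br$id == "silent"])
  brHalf <- expressionBreadth(half, tpmMin = 1, fracMin = 0.5)
  expect_equal(brHalf$breadth, 0.5)
  expect_false(brHalf$broad)                       # exactly half: not broad
})

test_that("locus discovery clusters by gap, flanks, and drops long clusters", {
  set.seed(44)
  genome <- c(c1 = chartr("U", "T", randomRna(2000)))
  aln <- data.frame(sample = "s1", chrom = "c1",
                    start = c(501L, 532L, 1401L),
                    end = c(521L, 552L, 1421L),
                    strand = "+", count = 1L)
  ps <- discoverLoci(aln, genome, maxGap = 50L, flank = 20L)
  expect_equal(length(ps), 2L)
  info <- precursorInfo(ps)
  expect_equal(info$start[1], 501L - 20L)
  expect_equal(info$end[1], 552L + 20L)
  expect_true(all(info$sources == "predicted"))
  # reads 200 nt apart with maxGap 50 stay separate loci
  aln2 <- data.frame(sample = "s1", chrom = "c1",
                     start = c(501L, 701L), end = c(521L, 721L),
                     strand = "+", count = 1L)
  expect_equal(length(discoverLoci(aln2, genome, maxGap = 50L)), 2L)
  # a 400-nt cluster is discarded at maxLocusLen 300
  aln3 <- data.frame(sample = "s1", chrom = "c1",
                     start = seq(501L, 880L, by = 20L),
                     end = seq(521L, 900L, by = 20L),
                     strand = "+", count = 1L)
  expect_equal(length(discoverLoci(aln3, genome, maxGap = 50L,
                                   maxLocusLen = 300L)), 0L)
  # minus-strand cluster yields the transcribed-strand sequence
  aln4 <- data.frame(sample = "s1", chrom = "c1", start = 501L, end = 521L,
                     strand = "-", count = 1L)
  ps4 <- discoverLoci(aln4, genome, maxGap = 50L, flank = 10L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(genome[["c1"]], 491, 531))))
  expect_equal(unname(ps4@sequences[1]), chartr("T", "U", rc))
})

test_that("SAM alignments parse with collapsed-count query names", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:c1\tLN:1000",
    paste("read1_x7", 0, "c1", 101, 255, "21M", "*", 0, 0,
          "ACGTACGTACGTACGTACGTA", "*", sep = "\t"),
    paste("read2", 16, "c1", 201, 255, "22M", "*", 0, 0,
          "ACGTACGTACGTACGTACGTAC", "*", sep = "\t")), sam)
  aln <- readAlignments(sam, sample = "lib1")
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$count, c(7L, 1L))
  expect_equal(aln$start, c(101L, 201L))
  expect_equal(aln$end, c(121L, 222L))
  expect_equal(aln$strand, c("+", "-"))
  expect_true(all(aln$sample == "lib1"))
})

test_that("stack counts aggregate to arm and precursor level", {
  ps <- mkRecords("+")
  aln <- data.frame(sample = c("s1", "s1", "s2"), chrom = "c1",
                    start = c(111L, 161L, 111L), end = c(131L, 181L, 131L),
                    strand = "+", count = c(10L, 4L, 6L))
  stacks <- buildReadStacks(aln, ps)
  pc <- stackCounts(stacks, ps, c("s1", "s2"), level = "precursor")
  expect_equal(unname(pc["p1", ]), c(14, 6))
  ac <- stackCounts(stacks, ps, c("s1", "s2"), level = "arm")
  expect_equal(unname(ac["p1|5p", ]), c(10, 6))
  expect_equal(unname(ac["p1|3p", ]), c(4, 0))
})
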