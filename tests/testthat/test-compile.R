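test_that("GFF3 parsing nests matures and reverse-complements minus-strand", {
  ann <- tinyAnnotation()
  ps <- parseAnnotationSource(ann$gff, ann$genome, source = "dbX")
  expect_s4_class(ps, "PrecursorSet")
  expect_equal(length(ps), 2L)
  mt <- matures(ps)
  expect_equal(sum(mt$precursor_id == "mirA"), 2L)
  # plus strand: sequence is the genome substring, T -> U
  expect_equal(ps@sequences[["mirA"]],
               chartr("T", "U", substr(ann$genome[["chr1"]], 101, 180)))
  # minus strand: reverse complement of the genomic window
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ann$genome[["chr2"]], 201, 280))))
  expect_equal(ps@sequences[["mirB"]], chartr("T", "U", rc))
  # minus-strand mature offset counts from the precursor 3' genomic end
  mB <- mt[mt$precursor_id == "mirB", ]
  expect_equal(mB$offset, 280L - 241L + 1L)
  expect_equal(mB$sequence,
               substr(ps@sequences[["mirB"]], mB$offset, mB$offset + 20L))
})

test_that("a mature without a covering precursor is rejected by name", {
  ann <- tinyAnnotation()
  bad <- tempfile(fileext = ".gff3")
  writeLines(c(readLines(ann$gff),
    "chr1\tsrc\tmiRNA\t501\t521\t.\t+\t.\tID=orphan;Name=orphan"), bad)
  expect_error(parseAnnotationSource(bad, ann$genome), "orphan")
})

test_that("a chromosome absent from the genome errors", {
  ann <- tinyAnnotation()
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr9\tsrc\tmiRNA_primary_transcript\t1\t60\t.\t+\t.\tID=p;Name=p"), bad)
  expect_error(parseAnnotationSource(bad, ann$genome), "chr9")
})

test_that("locatePrecursor finds planted sites on both strands and honours k", {
  set.seed(101)
  core <- randomRna(50)
  left <- chartr("U", "T", randomRna(100))
  right <- chartr("U", "T", randomRna(100))
  genome <- c(c1 = paste0(left, chartr("U", "T", core), right))
  hits <- locatePrecursor(core, genome, maxMismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 101L)
  expect_equal(hits$end, 150L)
  expect_equal(hits$strand, "+")
  # reverse complement planted -> minus-strand hit
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", core))))
  genome2 <- c(c1 = paste0(left, rc, right))
  hits2 <- locatePrecursor(core, genome2, maxMismatch = 0)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 101L)
  # exactly 3 substitutions: absent at k = 2, found at k = 3
  mut <- core
  for (p in c(5L, 20L, 35L)) {
    cur <- substr(core, p, p)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "U"), cur)[1]
  }
  expect_equal(nrow(locatePrecursor(mut, genome, maxMismatch = 2)), 0L)
  expect_equal(nrow(locatePrecursor(mut, genome, maxMismatch = 3)), 1L)
  # hit order is invariant under contig order
  g3 <- c(genome, c2 = genome2[[1]])
  g4 <- c(c2 = genome2[[1]], genome)
  expect_identical(locatePrecursor(core, g3), locatePrecursor(core, g4))
})

test_that("aggregation merges reciprocal-overlap loci, unions sources, dedups matures", {
  mkSet <- function(id, start, end, src, seq) {
    PrecursorSet(data.frame(id = id, chrom = "c1", start = start, end = end,
                            strand = "+", sources = src),
                 stats::setNames(seq, id),
                 data.frame(precursor_id = id, name = paste0(id, "-m"),
                            arm = "5p", offset = 5L, length = 21L,
                            sequence = substr(seq, 5, 25)))
  }
  set.seed(5)
  s <- randomRna(80)
  a <- mkSet("locus1", 101L, 180L, "db1", s)
  b <- mkSet("locus1b", 101L, 180L, "db2", s)
  agg <- aggregateCandidates(list(a, b))
  expect_equal(length(agg$records), 1L)
  expect_equal(precursorInfo(agg$records)$sources, "db1,db2")
  expect_equal(nrow(matures(agg$records)), 1L) # deduplicated by offset/length
  expect_setequal(names(agg$catalog), c("db1", "db2"))

  # disjoint loci stay separate
  c2 <- mkSet("locus2", 401L, 480L, "db1", s)
  agg2 <- aggregateCandidates(list(a, c2))
  expect_equal(length(agg2$records), 2L)

  # idempotence: aggregating the aggregate changes nothing
  agg3 <- aggregateCandidates(list(agg$records))
  expect_equal(length(agg3$records), length(agg$records))
  expect_equal(matures(agg3$records), matures(agg$records))

  # both arms of a two-mature record survive aggregation
  two <- PrecursorSet(
    data.frame(id = "p2", chrom = "c1", start = 601L, end = 680L,
               strand = "+", sources = "db1"),
    c(p2 = s),
    data.frame(precursor_id = "p2", name = c("p2-5p", "p2-3p"),
               arm = c("5p", "3p"), offset = c(5L, 50L), length = 21L,
               sequence = substring(s, c(5L, 50L), c(25L, 70L))))
  agg4 <- aggregateCandidates(list(two))
  expect_equal(nrow(matures(agg4$records)), 2L)

  # order invariance
  aggR <- aggregateCandidates(list(b, a))
  expect_equal(length(aggR$records), 1L)
  expect_equal(precursorInfo(aggR$records)$sources, "db1,db2")
})

test_that("published-scale set reconstruction: 365 + 435 with 133 shared gives 667", {
  n1 <- 365L; n2 <- 435L; shared <- 133L
  mkLoci <- function(ids, starts, src) {
    seqs <- vapply(seq_along(ids), function(i) {
      set.seed(1000L + starts[i]); randomRna(80) }, "")
    PrecursorSet(data.frame(id = ids, chrom = "c1", start = starts,
                            end = starts + 79L, strand = "+", sources = src),
                 stats::setNames(seqs, ids))
  }
  starts1 <- seq(1L, by = 200L, length.out = n1)
  annotated <- mkLoci(sprintf("ann%03d", 1:n1), starts1, "db")
  # predicted: first 133 coincide with annotated loci, the rest are new
  starts2 <- c(starts1[seq_len(shared)],
               seq(200L * n1, by = 200L, length.out = n2 - shared))
  predicted <- mkLoci(sprintf("prd%03d", 1:n2), starts2, "predicted")
  agg <- aggregateCandidates(list(annotated, predicted))
  expect_equal(length(agg$records), 667L)
  counts <- sourceRegionCounts(agg$catalog)
  expect_equal(unname(counts[["db&predicted"]]), 133L)
  expect_equal(unname(counts[["predicted"]]), 302L)
  expect_equal(sum(counts), 667L)
})

test_that("uniform naming keeps database names and numbers novel families", {
  set.seed(9)
  seqs <- vapply(1:3, function(i) randomRna(80), "")
  info <- data.frame(id = c("ath-MIR156b", "cand1", "cand2"),
                     chrom = "c1", start = c(100L, 400L, 700L),
                     end = c(179L, 479L, 779L), strand = "+",
                     sources = c("db1", "predicted", "predicted"))
  ps <- PrecursorSet(info, stats::setNames(seqs, info$id))
  named <- assignUniformNames(ps, "zma")
  expect_true("ath-MIR156b" %in% names(named))
  expect_true(all(c("zma-MIR_N1a", "zma-MIR_N2a") %in% names(named)))
  # paralogous second member (same sequence) takes the b suffix
  info2 <- rbind(info, data.frame(id = "cand3", chrom = "c1", start = 1000L,
                                  end = 1079L, strand = "+",
                                  sources = "predicted"))
  ps2 <- PrecursorSet(info2, stats::setNames(c(seqs, seqs[2]), info2$id))
  named2 <- assignUniformNames(ps2, "zma")
  expect_true("zma-MIR_N1b" %in% names(named2))
  # mature names carry the miR_ prefix and arm suffix
  mt <- data.frame(precursor_id = "cand1", name = "x", arm = "5p",
                   offset = 5L, length = 21L,
                   sequence = substr(seqs[2], 5, 25))
  ps3 <- PrecursorSet(info[2, ], stats::setNames(seqs[2], "cand1"), mt)
  named3 <- assignUniformNames(ps3, "zma")
  expect_equal(matures(named3)$name, "zma-miR_N1a-5p")
})

test_that("source region counts cover every membership pattern and sum to the union", {
  counts <- sourceRegionCounts(list(S1 = "x", S2 = c("x", "y")))
  expect_equal(unname(counts[["S1&S2"]]), 1L)
  expect_equal(unname(counts[["S2"]]), 1L)
  # four disjoint singletons
  c4 <- sourceRegionCounts(list(A = "a", B = "b", C = "c", D = "d"))
  expect_equal(length(c4), 4L)
  expect_true(all(c4 == 1L))
  # identical sources collapse to the full intersection
  ids <- sprintf("id%02d", 1:7)
  cAll <- sourceRegionCounts(list(A = ids, B = ids, C = ids, D = ids))
  expect_equal(unname(cAll[["A&B&C&D"]]), 7L)
  expect_equal(sum(cAll), 7L)
})

test_that("GFF3 + FASTA round trip reproduces the aggregated record set", {
  cfg <- fixtureConfig(seed = 21, nTrue = 6, nDecoys = 0, nSamples = 2,
                       depth = 20)
  b <- makeFixture(cfg)
  dir <- tempfile()
  paths <- writeBundle(b, dir)
  ps2 <- parseAnnotationSource(paths[["annotation"]], paths[["genome"]],
                               source = "plantedDB")
  ps1 <- b@precursors
  expect_setequal(names(ps2), names(ps1))
  ord <- match(names(ps1), names(ps2))
  expect_equal(ps2@sequences[ord], ps1@sequences)
  m1 <- matures(ps1); m2 <- matures(ps2)
  m2 <- m2[order(m2$precursor_id, m2$offset), ]
  m1 <- m1[order(m1$precursor_id, m1$offset), ]
  expect_equal(m2$offset, m1$offset)
  expect_equal(m2$sequence, m1$sequence)
  # re-aggregating the re-parse is a fixed point
  agg <- aggregateCandidates(list(plantedDB = ps2))
  expect_equal(length(agg$records), length(ps2))
})
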