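#' Configuration for the synthetic fixture generator
#'
#' Defaults describe a desk-scale but structurally realistic plant sRNA
#' study: 50 planted true hairpins and 50 dinucleotide-shuffled decoys, a
#' 30-nt perfect stem with an 8-nt loop (precursor 68 nt, inside the plant
#' 60--300 nt norm), 21-nt matures, 4 libraries at 50 reads per locus and
#' sample, processing precision 0.95, modest isomiR rates and a 2-nt
#' end-jitter model matching the add5/sub5/add3/sub3 classes.
#'
#' @param seed integer master seed; every downstream draw derives from it.
#' @param nTrue,nDecoys planted true and decoy locus counts.
#' @param stemLen,loopLen,matureLen hairpin geometry in nt.
#' @param depth reads per locus per sample.
#' @param precision planted processing precision in (0, 1].
#' @param isoformRates named probabilities for add5/sub5/add3/sub3 reads
#'   (drawn from the precise fraction's complement).
#' @param nSamples number of libraries.
#' @param armSwitchFraction fraction of true loci whose dominant arm flips
#'   between the first and second half of the samples.
#' @param armDominance read fraction on the dominant arm.
#' @param flankLen plain-sequence flank around each planted locus.
#' @param subgenomes contig-name suffixes cycled over loci (wheat-style
#'   labels by default).
#' @return a validated config list.
#' @export
fixtureConfig <- function(seed = 42L, nTrue = 50L, nDecoys = 50L,
                          stemLen = 30L, loopLen = 8L, matureLen = 21L,
                          depth = 50L, precision = 0.95,
                          isoformRates = c(add5 = 0.05, sub5 = 0.05,
                                           add3 = 0.1, sub3 = 0.1),
                          nSamples = 4L, armSwitchFraction = 0,
                          armDominance = 0.7, flankLen = 100L,
                          subgenomes = c("A", "B", "D")) {
  stopifnot(precision > 0, precision <= 1, stemLen >= matureLen,
            loopLen >= 3L, all(isoformRates >= 0), sum(isoformRates) <= 1,
            armDominance >= 0.5, armDominance <= 1)
  list(seed = as.integer(seed), nTrue = as.integer(nTrue),
       nDecoys = as.integer(nDecoys), stemLen = as.integer(stemLen),
       loopLen = as.integer(loopLen), matureLen = as.integer(matureLen),
       depth = as.integer(depth), precision = precision,
       isoformRates = isoformRates, nSamples = as.integer(nSamples),
       armSwitchFraction = armSwitchFraction, armDominance = armDominance,
       flankLen = as.integer(flankLen), subgenomes = subgenomes)
}

randBases <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

#' Plant one synthetic hairpin
#'
#' Builds \code{stem + loop + reverse-complement(stem)}: a perfect hairpin.
#' The mature sits on the 5' arm; the star is its canonical duplex partner
#' with 2-nt 3' overhangs on both strands.
#'
#' @param cfg \code{\link{fixtureConfig}} (RNG state is taken as-is; seed
#'   the session or use \code{\link{makeFixture}}).
#' @return list: \code{sequence}, \code{matureOffset}, \code{matureLength},
#'   \code{starOffset}, \code{starLength} (all precursor-local, 1-based).
#' @export
plantHairpin <- function(cfg = fixtureConfig()) {
  stem <- randBases(cfg$stemLen)
  loop <- randBases(cfg$loopLen)
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(stem, "")[[1]]),
                                     collapse = ""))
  seq <- paste0(stem, loop, rc)
  n <- nchar(seq)
  # keep the mature inside the stem with room for the 2-nt overhang shift
  mOff <- sample(3:(cfg$stemLen - cfg$matureLen + 1L), 1L)
  mEnd <- mOff + cfg$matureLen - 1L
  # perfect stem pair table: i pairs with n - i + 1
  starStart <- n - (mEnd - 2L) + 1L
  starEnd <- (n - mOff + 1L) + 2L
  list(sequence = seq, matureOffset = mOff, matureLength = cfg$matureLen,
       starOffset = as.integer(starStart),
       starLength = as.integer(starEnd - starStart + 1L))
}

dinucShuffle <- function(seq) {
  # composition-preserving shuffle at dinucleotide scale: shuffle the
  # sequence of non-overlapping dinucleotides
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pairs <- split(ch, ceiling(seq_len(n) / 2))
  paste(unlist(pairs[sample(length(pairs))]), collapse = "")
}

#' Generate a complete synthetic fixture bundle
#'
#' Plants \code{nTrue} hairpins and \code{nDecoys} dinucleotide-shuffled
#' decoys on separate contigs (one locus per contig, subgenome-style
#' suffixes cycled), simulates multi-sample read stacks with the planted
#' precision, isomiR rates and arm dominance, and records the full truth
#' table. All randomness flows from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{fixtureConfig}}.
#' @return a \linkS4class{FixtureBundle}.
#' @export
makeFixture <- function(cfg = fixtureConfig()) {
  set.seed(cfg$seed)
  nAll <- cfg$nTrue + cfg$nDecoys
  genome <- character(0)
  info <- list(); seqs <- character(0); mt <- list(); truth <- list()
  switchFlags <- rep(FALSE, cfg$nTrue)
  if (cfg$armSwitchFraction > 0 && cfg$nTrue > 0)
    switchFlags[sample(cfg$nTrue, round(cfg$armSwitchFraction * cfg$nTrue))] <- TRUE
  for (i in seq_len(nAll)) {
    isTrue <- i <= cfg$nTrue
    hp <- plantHairpin(cfg)
    pseq <- if (isTrue) hp$sequence else dinucShuffle(hp$sequence)
    sub <- cfg$subgenomes[((i - 1L) %% length(cfg$subgenomes)) + 1L]
    contig <- sprintf("ctg%03d%s", i, sub)
    strand <- if (i %% 2L == 0L) "-" else "+"
    left <- randBases(cfg$flankLen); right <- randBases(cfg$flankLen)
    ts <- if (strand == "+") pseq
          else chartr("ACGU", "UGCA", paste(rev(strsplit(pseq, "")[[1]]),
                                            collapse = ""))
    contigSeq <- chartr("U", "T", paste0(left, ts, right))
    genome[contig] <- contigSeq
    gStart <- cfg$flankLen + 1L
    gEnd <- cfg$flankLen + nchar(pseq)
    id <- sprintf("%s%03d", if (isTrue) "true" else "decoy", i)
    info[[i]] <- data.frame(id = id, chrom = contig, start = gStart,
                            end = gEnd, strand = strand,
                            sources = "plantedDB", stringsAsFactors = FALSE)
    seqs[id] <- pseq
    # decoys keep a nominal mature annotation (a bogus database entry);
    # true loci additionally carry their star arm
    offs <- if (isTrue) c(hp$matureOffset, hp$starOffset) else hp$matureOffset
    lens <- if (isTrue) c(hp$matureLength, hp$starLength) else hp$matureLength
    mt[[i]] <- data.frame(
      precursor_id = id,
      name = paste0(id, c("-5p", "-3p")[seq_along(offs)]),
      arm = c("5p", "3p")[seq_along(offs)],
      offset = offs, length = lens,
      sequence = substring(pseq, offs, offs + lens - 1L),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      id = id, true_locus = isTrue, chrom = contig, start = gStart,
      end = gEnd, strand = strand,
      mature_offset = if (isTrue) hp$matureOffset else NA_integer_,
      mature_length = if (isTrue) hp$matureLength else NA_integer_,
      star_offset = if (isTrue) hp$starOffset else NA_integer_,
      star_length = if (isTrue) hp$starLength else NA_integer_,
      precision = if (isTrue) cfg$precision else NA_real_,
      arm_switch = if (isTrue) switchFlags[i] else FALSE,
      stringsAsFactors = FALSE)
  }
  info <- do.call(rbind, info)
  truth <- do.call(rbind, truth)
  mats <- if (length(mt)) do.call(rbind, mt[!vapply(mt, is.null, TRUE)])
          else emptyMatures()
  precursors <- PrecursorSet(info, seqs, mats)
  alignments <- simulateReads(truth, precursors, cfg)
  new("FixtureBundle", genome = genome, precursors = precursors,
      alignments = alignments, truth = truth, config = cfg)
}

#' Simulate multi-sample read alignments from a truth table
#'
#' Per true locus and sample: \code{depth} reads, a fraction
#' \code{precision} with exact mature/star ends (split between arms by
#' \code{armDominance}, flipped in the second half of the samples for
#' arm-switch loci), isomiR reads with 1--2 nt template end shifts per
#' \code{isoformRates}, and the remainder at uniform offsets. Decoy loci
#' receive no reads.
#'
#' @param truth truth table from \code{\link{makeFixture}}.
#' @param precursors the planted \linkS4class{PrecursorSet}.
#' @param cfg the \code{\link{fixtureConfig}}.
#' @return alignment data.frame (\code{sample}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{count}).
#' @export
simulateReads <- function(truth, precursors, cfg) {
  rows <- list()
  samples <- sprintf("s%02d", seq_len(cfg$nSamples))
  isoNames <- names(cfg$isoformRates)
  for (i in which(truth$true_locus)) {
    tr <- truth[i, ]
    plen <- tr$end - tr$start + 1L
    for (si in seq_along(samples)) {
      if (cfg$depth == 0L) next
      dom5 <- cfg$armDominance
      if (tr$arm_switch && si > cfg$nSamples / 2) dom5 <- 1 - dom5
      nPrecise <- stats::rbinom(1L, cfg$depth, cfg$precision)
      nRest <- cfg$depth - nPrecise
      n5 <- stats::rbinom(1L, nPrecise, dom5)
      local <- data.frame(offset = integer(0), length = integer(0))
      if (n5 > 0) local <- rbind(local,
        data.frame(offset = rep(tr$mature_offset, n5),
                   length = rep(tr$mature_length, n5)))
      if (nPrecise - n5 > 0) local <- rbind(local,
        data.frame(offset = rep(tr$star_offset, nPrecise - n5),
                   length = rep(tr$star_length, nPrecise - n5)))
      if (nRest > 0) {
        clsProb <- c(cfg$isoformRates,
                     uniform = max(0, 1 - sum(cfg$isoformRates)))
        cls <- sample(names(clsProb), nRest, replace = TRUE, prob = clsProb)
        off <- integer(nRest); len <- integer(nRest)
        for (k in seq_len(nRest)) {
          base <- if (stats::runif(1) < dom5)
            c(tr$mature_offset, tr$mature_length)
          else c(tr$star_offset, tr$star_length)
          shift <- sample(1:2, 1L)
          ol <- switch(cls[k],
            add5 = c(base[1] - shift, base[2] + shift),
            sub5 = c(base[1] + shift, base[2] - shift),
            add3 = c(base[1], base[2] + shift),
            sub3 = c(base[1], base[2] - shift),
            uniform = c(sample(seq_len(max(1L, plen - 24L)), 1L),
                        sample(20:24, 1L)))
          off[k] <- ol[1]; len[k] <- ol[2]
        }
        ok <- off >= 1L & off + len - 1L <= plen
        local <- rbind(local, data.frame(offset = off[ok], length = len[ok]))
      }
      if (!nrow(local)) next
      gs <- if (tr$strand == "+") tr$start + local$offset - 1L
            else tr$end - (local$offset + local$length - 1L) + 1L
      agg <- stats::aggregate(count ~ start + end,
        data.frame(start = gs, end = gs + local$length - 1L, count = 1L),
        sum)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[si], chrom = tr$chrom, start = agg$start,
        end = agg$end, strand = tr$strand, count = agg$count,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), count = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$sample, out$chrom, out$start, out$end), , drop = FALSE]
}

#' Write a fixture bundle to disk (FASTA + GFF3 + TSV alignments + truth)
#'
#' Files re-read through the package parsers reproduce the in-memory
#' bundle; output bytes are deterministic given the config seed.
#'
#' @param bundle a \linkS4class{FixtureBundle}.
#' @param dir output directory.
#' @return invisibly, the named file paths.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gff3"),
             alignments = file.path(dir, "alignments.tsv"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle@genome),
                              paths["genome"])
  writePrecursorGff3(bundle@precursors, paths["annotation"])
  utils::write.table(bundle@alignments, paths["alignments"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle@truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
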