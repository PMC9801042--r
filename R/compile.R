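#' Parse one miRNA annotation source (GFF3 + genome) into a PrecursorSet
#'
#' Reads precursor and mature features from a GFF3 file, extracts the
#' transcribed-strand RNA sequence of each precursor from the genome, and
#' nests mature features under their precursor by coordinate containment.
#'
#' @param gff path to a GFF3 file. Precursors are rows whose type matches
#'   \code{precursorType}; matures match \code{matureType}.
#' @param genome path to a genome FASTA, or a named character vector /
#'   \code{DNAStringSet} of contig sequences.
#' @param source tag recorded for every parsed precursor.
#' @param precursorType,matureType GFF3 feature types (miRBase dialect
#'   defaults).
#' @return a \linkS4class{PrecursorSet}.
#' @examples
#' gen <- c(chr1 = paste(rep("ACGT", 60), collapse = ""))
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tx\tmiRNA_primary_transcript\t1\t60\t.\t+\t.\tID=p1;Name=p1",
#'   "chr1\tx\tmiRNA\t11\t31\t.\t+\t.\tID=m1;Name=p1-5p;Derives_from=p1"),
#'   gff)
#' parseAnnotationSource(gff, gen, source = "demo")
#' @export
parseAnnotationSource <- function(gff, genome, source = "annotated",
                                  precursorType = "miRNA_primary_transcript",
                                  matureType = "miRNA") {
  genome <- loadGenome(genome)
  feats <- rtracklayer::import(gff, format = "gff3")
  pre <- feats[feats$type == precursorType]
  mat <- feats[feats$type == matureType]
  if (!length(pre)) {
    return(PrecursorSet(emptyInfo(), character(0)))
  }
  chroms <- as.character(GenomicRanges::seqnames(pre))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome FASTA: ",
         paste(missing, collapse = ", "))
  ids <- featureName(pre)
  seqs <- extractTranscribed(genome, chroms, GenomicRanges::start(pre),
                             GenomicRanges::end(pre),
                             as.character(GenomicRanges::strand(pre)))
  info <- data.frame(id = ids, chrom = chroms,
                     start = GenomicRanges::start(pre),
                     end = GenomicRanges::end(pre),
                     strand = as.character(GenomicRanges::strand(pre)),
                     sources = source, stringsAsFactors = FALSE)
  mrows <- emptyMatures()
  if (length(mat)) {
    ov <- GenomicRanges::findOverlaps(mat, pre, type = "within")
    orphan <- setdiff(seq_along(mat), S4Vectors::queryHits(ov))
    # a mature must sit on the same strand inside some precursor
    okStrand <- as.character(GenomicRanges::strand(mat))[S4Vectors::queryHits(ov)] ==
      as.character(GenomicRanges::strand(pre))[S4Vectors::subjectHits(ov)]
    ov <- ov[okStrand]
    covered <- unique(S4Vectors::queryHits(ov))
    orphan <- union(orphan, setdiff(seq_along(mat), covered))
    if (length(orphan))
      stop("mature feature(s) not contained in any precursor: ",
           paste(featureName(mat[orphan]), collapse = ", "))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    pStrand <- info$strand[sh]
    off <- ifelse(pStrand == "+",
                  GenomicRanges::start(mat)[qh] - info$start[sh] + 1L,
                  info$end[sh] - GenomicRanges::end(mat)[qh] + 1L)
    len <- GenomicRanges::width(mat)[qh]
    mrows <- data.frame(precursor_id = ids[sh],
                        name = featureName(mat)[qh],
                        arm = "unknown", offset = as.integer(off),
                        length = as.integer(len),
                        sequence = substr(seqs[sh], off, off + len - 1L),
                        stringsAsFactors = FALSE)
    mrows$arm <- armFromOffset(mrows$offset, mrows$length,
                               nchar(seqs)[sh])
  }
  PrecursorSet(info, stats::setNames(seqs, ids), mrows)
}

featureName <- function(gr) {
  nm <- gr$Name
  if (is.null(nm)) nm <- gr$ID
  if (is.null(nm)) nm <- paste0("feat", seq_along(gr))
  ifelse(is.na(nm), paste0("feat", seq_along(gr)), as.character(nm))
}

armFromOffset <- function(offset, length, preLen) {
  mid <- (offset + length / 2)
  ifelse(mid <= preLen / 2, "5p", "3p")
}

emptyInfo <- function() {
  data.frame(id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), sources = character(),
             stringsAsFactors = FALSE)
}

loadGenome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "XStringSet")) {
    # FASTA headers may carry descriptions after the first token
    nm <- sub("\\s.*$", "", names(genome))
    genome <- stats::setNames(as.character(genome), nm)
  }
  toupper(genome)
}

extractTranscribed <- function(genome, chrom, start, end, strand) {
  seqs <- substr(genome[chrom], start, end)
  neg <- strand == "-"
  if (any(neg))
    seqs[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[neg])))
  chartr("T", "U", seqs)
}

#' Locate an RNA sequence on a genome with up to k mismatches
#'
#' Searches both strands for matches of \code{seq} with at most
#' \code{maxMismatch} substitutions (no indels) and returns all hit
#' intervals ordered by (chrom, start). An empty result is valid and marks
#' the record "unlocated" downstream.
#'
#' @param seq RNA (or DNA) sequence of length >= 40.
#' @param genome FASTA path or named sequences (see
#'   \code{\link{parseAnnotationSource}}).
#' @param maxMismatch maximum substitutions (default 2).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (1-based inclusive).
#' @export
locatePrecursor <- function(seq, genome, maxMismatch = 2L) {
  stopifnot(nchar(seq) >= 40L, maxMismatch >= 0L)
  genome <- loadGenome(genome)
  pat <- Biostrings::DNAString(chartr("U", "T", toupper(seq)))
  hits <- lapply(names(genome), function(ch) {
    subj <- Biostrings::DNAString(genome[[ch]])
    fwd <- Biostrings::matchPattern(pat, subj, max.mismatch = maxMismatch)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                    max.mismatch = maxMismatch)
    rbind(
      if (length(fwd)) data.frame(chrom = ch, start = Biostrings::start(fwd),
                                  end = Biostrings::end(fwd), strand = "+",
                                  stringsAsFactors = FALSE),
      if (length(rev)) data.frame(chrom = ch, start = Biostrings::start(rev),
                                  end = Biostrings::end(rev), strand = "-",
                                  stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate candidate precursors from several sources
#'
#' Same-strand precursors whose genomic intervals reciprocally overlap by at
#' least \code{minOverlapFraction} (of both interval widths) are merged into
#' one record: sources are unioned, matures deduplicated by (offset, length)
#' after mapping onto the representative precursor, and the longest member
#' (ties: lexicographically smallest id) represents the merged locus.
#' Unlocated records pass through as singletons. The result is independent
#' of the input order of the sets.
#'
#' @param recordSets named list of \linkS4class{PrecursorSet} objects; names
#'   are used as source tags when a set's records carry none.
#' @param minOverlapFraction reciprocal-overlap threshold (default 0.5).
#' @return list with elements \code{records} (merged PrecursorSet) and
#'   \code{catalog} (named list: source tag -> character vector of merged
#'   record ids).
#' @export
aggregateCandidates <- function(recordSets, minOverlapFraction = 0.5) {
  if (methods::is(recordSets, "PrecursorSet")) recordSets <- list(recordSets)
  sets <- lapply(seq_along(recordSets), function(k) {
    ps <- recordSets[[k]]
    tag <- names(recordSets)[k]
    if (!is.null(tag) && nzchar(tag)) {
      info <- ps@info
      info$sources <- tag
      ps <- PrecursorSet(info, ps@sequences, ps@matures)
    }
    ps
  })
  info <- do.call(rbind, lapply(sets, function(p) p@info))
  if (is.null(info) || !nrow(info))
    return(list(records = PrecursorSet(emptyInfo(), character(0)),
                catalog = list()))
  # ids may repeat across sets; make working keys unique
  key <- make.unique(as.character(info$id), sep = "#")
  seqs <- stats::setNames(unlist(lapply(sets, function(p) p@sequences),
                                 use.names = FALSE), key)
  mt <- do.call(rbind, lapply(seq_along(sets), function(k) {
    m <- sets[[k]]@matures
    if (nrow(m)) {
      off <- cumsum(c(0, vapply(sets, length, 1L)))[k]
      m$precursor_key <- key[off + match(m$precursor_id, sets[[k]]@info$id)]
    } else m$precursor_key <- character(0)
    m
  }))
  info$key <- key

  located <- which(!is.na(info$chrom))
  comp <- seq_len(nrow(info)) # union-find parents
  findRoot <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (length(located) > 1) {
    gr <- GenomicRanges::GRanges(info$chrom[located],
                                 IRanges::IRanges(info$start[located],
                                                  info$end[located]),
                                 strand = info$strand[located])
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(GenomicRanges::pintersect(gr[q], gr[s]))
      frac <- pmin(w / GenomicRanges::width(gr)[q],
                   w / GenomicRanges::width(gr)[s])
      keep <- frac >= minOverlapFraction
      for (e in which(keep)) {
        a <- findRoot(located[q[e]]); b <- findRoot(located[s[e]])
        if (a != b) comp[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_len(nrow(info)), findRoot, 1L)
  groups <- split(seq_len(nrow(info)), root)

  reps <- vapply(groups, function(g)
    g[order(-nchar(seqs[g]), info$id[g])][1], 1L)
  groupSrc <- vapply(groups, function(g)
    paste(sort(unique(unlist(strsplit(info$sources[g], ",")))),
          collapse = ","), "")
  outInfo <- info[reps, c("id", "chrom", "start", "end", "strand"),
                  drop = FALSE]
  outInfo$sources <- groupSrc
  outInfo$id <- make.unique(as.character(outInfo$id), sep = ".")
  mergedSeq <- stats::setNames(seqs[reps], outInfo$id)

  mergedMat <- list()
  for (k in seq_along(groups)) {
    g <- groups[[k]]; rep <- reps[k]
    mg <- mt[mt$precursor_key %in% info$key[g], , drop = FALSE]
    if (!nrow(mg)) next
    midx <- match(mg$precursor_key, info$key)
    if (!is.na(info$chrom[rep])) {
      gs <- ifelse(info$strand[midx] == "+",
                   info$start[midx] + mg$offset - 1L,
                   info$end[midx] - (mg$offset + mg$length - 1L) + 1L)
      newOff <- if (info$strand[rep] == "+") gs - info$start[rep] + 1L
                else info$end[rep] - (gs + mg$length - 1L) + 1L
    } else newOff <- mg$offset
    mg$offset <- as.integer(newOff)
    ok <- mg$offset >= 1L & mg$offset + mg$length - 1L <= nchar(seqs[rep])
    mg <- mg[ok, , drop = FALSE]
    mg <- mg[!duplicated(mg[c("offset", "length")]), , drop = FALSE]
    if (nrow(mg)) {
      mg$precursor_id <- outInfo$id[k]
      mg$sequence <- substring(seqs[rep], mg$offset,
                               mg$offset + mg$length - 1L)
      mg$arm <- armFromOffset(mg$offset, mg$length, nchar(seqs[rep]))
      mergedMat[[length(mergedMat) + 1L]] <- mg[names(emptyMatures())]
    }
  }
  catalog <- list()
  for (k in seq_along(groups)) {
    for (s in strsplit(groupSrc[k], ",")[[1]])
      catalog[[s]] <- c(catalog[[s]], outInfo$id[k])
  }
  ord <- order(is.na(outInfo$chrom), outInfo$chrom, outInfo$start, outInfo$id)
  outInfo <- outInfo[ord, , drop = FALSE]
  mergedSeq <- mergedSeq[ord]
  mats <- if (length(mergedMat)) do.call(rbind, mergedMat) else emptyMatures()
  catalog <- lapply(catalog, function(v) sort(unique(v)))
  list(records = PrecursorSet(outInfo, mergedSeq, mats),
       catalog = catalog[order(names(catalog))])
}

#' Assign uniform names to aggregated candidates
#'
#' Records carrying a database-derived name keep it. Novel records (tagged
#' only \code{"predicted"}) are named \code{<prefix>-MIR_N<k><letter>}: k is
#' a running family index and the letter distinguishes paralogous members of
#' the same family (identical dominant mature sequence, or identical
#' precursor sequence when no mature is annotated). Matures are renamed with
#' \code{-5p}/\code{-3p} arm suffixes.
#'
#' @param records a \linkS4class{PrecursorSet} (aggregated).
#' @param speciesPrefix lowercase 3-letter species code, e.g. \code{"ath"}.
#' @param predictedTag source tag marking novel records.
#' @return the renamed \linkS4class{PrecursorSet}.
#' @export
assignUniformNames <- function(records, speciesPrefix,
                               predictedTag = "predicted") {
  stopifnot(grepl("^[a-z]{3}$", speciesPrefix))
  info <- records@info
  seqs <- records@sequences
  mt <- records@matures
  srcList <- strsplit(info$sources, ",")
  novel <- vapply(srcList, function(s) all(s == predictedTag), TRUE)
  newIds <- as.character(info$id)
  if (any(novel)) {
    famKey <- vapply(which(novel), function(i) {
      m <- mt[mt$precursor_id == info$id[i], , drop = FALSE]
      if (nrow(m)) m$sequence[which.max(m$length)][1] else seqs[i]
    }, "")
    # families numbered by order of first genomic appearance
    fam <- match(famKey, unique(famKey))
    member <- stats::ave(seq_along(fam), fam, FUN = seq_along)
    newIds[novel] <- paste0(speciesPrefix, "-MIR_N", fam,
                            letters[pmin(member, 26L)])
  }
  if (anyDuplicated(newIds))
    stop("uniform naming produced duplicate ids: ",
         paste(unique(newIds[duplicated(newIds)]), collapse = ", "))
  if (nrow(mt)) {
    mt$precursor_id <- newIds[match(mt$precursor_id, info$id)]
    base <- sub("^MIR", "miR", sub(paste0("^", speciesPrefix, "-MIR"),
                                   paste0(speciesPrefix, "-miR"),
                                   mt$precursor_id))
    mt$name <- paste0(base, "-", mt$arm)
  }
  info$id <- newIds
  names(seqs) <- newIds
  PrecursorSet(info, seqs, mt)
}

#' Venn-region counts of a source catalog
#'
#' Counts distinct precursor ids per nonempty source-membership pattern;
#' the counts sum to the number of distinct ids.
#'
#' @param catalog named list: source tag -> character vector of ids.
#' @return named integer vector; names are \code{"&"}-joined source tags.
#' @examples
#' sourceRegionCounts(list(S1 = "x", S2 = c("x", "y")))
#' @export
sourceRegionCounts <- function(catalog) {
  stopifnot(length(catalog) >= 1)
  ids <- unique(unlist(catalog))
  pattern <- vapply(ids, function(id) {
    paste(names(catalog)[vapply(catalog, function(v) id %in% v, TRUE)],
          collapse = "&")
  }, "")
  tab <- table(pattern)
  stats::setNames(as.integer(tab), names(tab))
}
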