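#' Read collapsed sRNA alignments
#'
#' Two dialects are supported: SAM (mapped, unspliced; converted through
#' \pkg{Rsamtools}) and a 6-column TSV (\code{sample}, \code{chrom},
#' \code{start}, \code{end}, \code{strand}, \code{count}; 1-based inclusive
#' coordinates). Collapsed-read counts may be encoded in SAM query names as
#' \code{name_xN} (N = multiplicity), the common collapser convention;
#' otherwise each record counts once.
#'
#' @param path alignment file (\code{.sam} or \code{.tsv}).
#' @param sample sample identifier for SAM input (TSV carries its own).
#' @param format \code{"auto"}, \code{"sam"} or \code{"tsv"}.
#' @return data.frame: \code{sample}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{count}.
#' @export
readAlignments <- function(path, sample = "s1", format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  if (format == "tsv") {
    aln <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("sample", "chrom", "start", "end", "strand", "count")
    stopifnot(all(need %in% names(aln)))
    return(aln[need])
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "qwidth", "strand"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1", rec$qname)))
  cnt[is.na(cnt)] <- 1L
  data.frame(sample = sample, chrom = as.character(rec$rname),
             start = rec$pos, end = rec$pos + rec$qwidth - 1L,
             strand = as.character(rec$strand), count = cnt,
             stringsAsFactors = FALSE)
}

alignmentsToGRanges <- function(aln) {
  gr <- GenomicRanges::GRanges(aln$chrom,
                               IRanges::IRanges(aln$start, aln$end),
                               strand = aln$strand)
  gr$count <- aln$count
  gr$sample <- aln$sample
  gr
}

#' Build the read stack of one precursor
#'
#' Keeps exactly the reads fully contained in the precursor interval on its
#' strand, re-expresses them in precursor-local 1-based coordinates
#' (strand-aware flip on minus-strand precursors), and sums counts per
#' (offset, length, sample).
#'
#' @param aln alignment data.frame (see \code{\link{readAlignments}}).
#' @param records a \linkS4class{PrecursorSet}.
#' @param id precursor id (must be located).
#' @return a \linkS4class{ReadStack}.
#' @export
buildReadStack <- function(aln, records, id) {
  info <- records@info[records@info$id == id, , drop = FALSE]
  if (!nrow(info)) stop("unknown precursor id: ", id)
  if (is.na(info$chrom)) stop("precursor is unlocated: ", id)
  keep <- aln$chrom == info$chrom & aln$strand == info$strand &
    aln$start >= info$start & aln$end <= info$end
  sub <- aln[keep, , drop = FALSE]
  if (nrow(sub)) {
    off <- if (info$strand == "+") sub$start - info$start + 1L
           else info$end - sub$end + 1L
    ent <- stats::aggregate(count ~ offset + length + sample,
                            data.frame(offset = as.integer(off),
                                       length = sub$end - sub$start + 1L,
                                       sample = sub$sample,
                                       count = sub$count), sum)
    ent <- ent[order(ent$offset, ent$length, ent$sample), , drop = FALSE]
    rownames(ent) <- NULL
  } else {
    ent <- data.frame(offset = integer(), length = integer(),
                      count = numeric(), sample = character(),
                      stringsAsFactors = FALSE)
  }
  new("ReadStack", precursorId = id, entries = ent)
}

#' Build read stacks for every located precursor
#'
#' @inheritParams buildReadStack
#' @return named list of \linkS4class{ReadStack} objects.
#' @export
buildReadStacks <- function(aln, records) {
  ids <- records@info$id[!is.na(records@info$chrom)]
  stats::setNames(lapply(ids, buildReadStack, aln = aln, records = records),
                  ids)
}

#' Per-sample library sizes from an alignment table
#'
#' Total mapped read count per sample: the TPM denominator.
#'
#' @param aln alignment data.frame.
#' @return named numeric vector, sample -> total count.
#' @export
libraryStats <- function(aln) {
  if (!nrow(aln)) return(stats::setNames(numeric(0), character(0)))
  tapply(aln$count, aln$sample, sum)
}

#' Transcripts-per-million normalization
#'
#' \code{TPM(e, s) = count(e, s) / total(s) * 1e6}.
#'
#' @param counts numeric matrix, entities x samples.
#' @param totals named totals per sample (\code{\link{libraryStats}}); every
#'   column of \code{counts} must be present with a positive total.
#' @return TPM matrix of the same shape.
#' @export
computeTpm <- function(counts, totals) {
  counts <- as.matrix(counts)
  miss <- setdiff(colnames(counts), names(totals))
  if (length(miss)) stop("no library total for sample(s): ",
                         paste(miss, collapse = ", "))
  tot <- totals[colnames(counts)]
  if (any(tot <= 0)) stop("zero library total for sample(s): ",
                          paste(colnames(counts)[tot <= 0], collapse = ", "))
  sweep(counts, 2, tot, "/") * 1e6
}

#' Count mature-level (or precursor-level) expression from read stacks
#'
#' A stack read is attributed to a precursor arm by the 5' half / 3' half of
#' the precursor it starts in; \code{level = "precursor"} sums the whole
#' stack.
#'
#' @param stacks named list of \linkS4class{ReadStack}.
#' @param records the matching \linkS4class{PrecursorSet}.
#' @param samples character vector fixing the column set/order.
#' @param level \code{"precursor"} or \code{"arm"}.
#' @return counts matrix (entities x samples); arm-level rownames are
#'   \code{<id>|5p} and \code{<id>|3p}.
#' @export
stackCounts <- function(stacks, records, samples, level = c("precursor", "arm")) {
  level <- match.arg(level)
  plen <- stats::setNames(nchar(records@sequences), records@info$id)
  rows <- list()
  for (id in names(stacks)) {
    e <- stacks[[id]]@entries
    if (!nrow(e)) next
    if (level == "precursor") {
      agg <- tapply(e$count, e$sample, sum)
      rows[[id]] <- agg
    } else {
      arm <- ifelse(e$offset + e$length / 2 <= plen[id] / 2, "5p", "3p")
      for (a in c("5p", "3p")) {
        sel <- arm == a
        if (any(sel))
          rows[[paste0(id, "|", a)]] <- tapply(e$count[sel], e$sample[sel], sum)
      }
    }
  }
  out <- matrix(0, nrow = length(rows), ncol = length(samples),
                dimnames = list(names(rows), samples))
  for (r in names(rows)) {
    v <- rows[[r]]
    out[r, intersect(names(v), samples)] <- v[intersect(names(v), samples)]
  }
  out
}

#' Expression breadth across samples
#'
#' Breadth is the fraction of samples in which an entity reaches
#' \code{tpmMin}; the broad flag requires breadth strictly greater than
#' \code{fracMin} (so exactly half of the samples is not "broad").
#'
#' @param tpm TPM matrix, entities x samples.
#' @param tpmMin expression floor (default 1 TPM).
#' @param fracMin breadth cutoff (default 0.5).
#' @return data.frame: \code{id}, \code{breadth}, \code{broad}.
#' @export
expressionBreadth <- function(tpm, tpmMin = 1, fracMin = 0.5) {
  tpm <- as.matrix(tpm)
  stopifnot(ncol(tpm) >= 1)
  breadth <- rowMeans(tpm >= tpmMin)
  data.frame(id = rownames(tpm), breadth = unname(breadth),
             broad = unname(breadth > fracMin), stringsAsFactors = FALSE)
}

#' Discover candidate precursor loci from read clusters
#'
#' Same-strand reads separated by at most \code{maxGap} nt are clustered;
#' clusters longer than \code{maxLocusLen} are discarded, the rest are
#' extended by \code{flank} nt on both sides (clipped at contig ends) and
#' excised from the transcribed strand as \code{"predicted"} candidates.
#'
#' @param aln alignment data.frame.
#' @param genome FASTA path or named contig sequences.
#' @param maxGap maximum within-cluster read gap (default 200 nt).
#' @param flank extension on both sides (default 100 nt).
#' @param maxLocusLen maximum cluster span before flanking (default 300 nt).
#' @param idPrefix prefix for candidate ids.
#' @return a \linkS4class{PrecursorSet} with source \code{"predicted"}.
#' @export
discoverLoci <- function(aln, genome, maxGap = 200L, flank = 100L,
                         maxLocusLen = 300L, idPrefix = "pred") {
  genome <- loadGenome(genome)
  if (!nrow(aln)) return(PrecursorSet(emptyInfo(), character(0)))
  gr <- alignmentsToGRanges(aln)
  cl <- GenomicRanges::reduce(gr, min.gapwidth = maxGap + 1L)
  cl <- cl[GenomicRanges::width(cl) <= maxLocusLen]
  if (!length(cl)) return(PrecursorSet(emptyInfo(), character(0)))
  chrom <- as.character(GenomicRanges::seqnames(cl))
  start <- pmax(1L, GenomicRanges::start(cl) - flank)
  end <- pmin(nchar(genome)[chrom], GenomicRanges::end(cl) + flank)
  strand <- as.character(GenomicRanges::strand(cl))
  ord <- order(chrom, start, strand)
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
  strand <- strand[ord]
  ids <- sprintf("%s%03d", idPrefix, seq_along(chrom))
  seqs <- extractTranscribed(genome, chrom, start, end, strand)
  PrecursorSet(data.frame(id = ids, chrom = chrom, start = start, end = end,
                          strand = strand, sources = "predicted",
                          stringsAsFactors = FALSE),
               stats::setNames(seqs, ids))
}

#' Infer a mature record from a read stack
#'
#' The most abundant (offset, length) read form with a length inside
#' \code{lenRange} becomes the putative mature; used for predicted loci that
#' carry no database mature annotation.
#'
#' @param stack a \linkS4class{ReadStack}.
#' @param records the matching \linkS4class{PrecursorSet}.
#' @param lenRange acceptable mature lengths (default 20:24).
#' @return one-row mature data.frame, or NULL when no read qualifies.
#' @export
inferMature <- function(stack, records, lenRange = 20:24) {
  e <- stack@entries
  e <- e[e$length %in% lenRange, , drop = FALSE]
  if (!nrow(e)) return(NULL)
  agg <- stats::aggregate(count ~ offset + length, e, sum)
  top <- agg[order(-agg$count, agg$offset, agg$length), ][1, ]
  id <- stack@precursorId
  seq <- records@sequences[[id]]
  data.frame(precursor_id = id, name = paste0(id, "-m"),
             arm = armFromOffset(top$offset, top$length, nchar(seq)),
             offset = as.integer(top$offset), length = as.integer(top$length),
             sequence = substr(seq, top$offset, top$offset + top$length - 1L),
             stringsAsFactors = FALSE)
}
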