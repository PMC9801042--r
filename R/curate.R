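#' Classify an isomiR read against its mature
#'
#' Template (coordinate-shift) variants only: \code{add5} = 5' template
#' addition, \code{sub5} = 5' template deletion, \code{add3}/\code{sub3}
#' analogous at the 3' end. Canonical iff both ends coincide with the
#' mature. Read and mature coordinates are precursor-local 1-based.
#'
#' @param readOffset,readLength stack entry coordinates.
#' @param matureOffset,matureLength mature coordinates.
#' @return list: \code{add5}, \code{sub5}, \code{add3}, \code{sub3},
#'   \code{canonical}.
#' @examples
#' classifyIsoform(9, 21, 11, 19)  # add5 = 2
#' @export
classifyIsoform <- function(readOffset, readLength, matureOffset, matureLength) {
  readEnd <- readOffset + readLength - 1L
  matureEnd <- matureOffset + matureLength - 1L
  add5 <- max(0L, matureOffset - readOffset)
  sub5 <- max(0L, readOffset - matureOffset)
  add3 <- max(0L, readEnd - matureEnd)
  sub3 <- max(0L, matureEnd - readEnd)
  list(add5 = add5, sub5 = sub5, add3 = add3, sub3 = sub3,
       canonical = add5 == 0L && sub5 == 0L && add3 == 0L && sub3 == 0L)
}

#' Tally isomiR classes over a read stack
#'
#' Reads are attributed to the nearest mature on the same arm (5' end within
#' the mature's half of the precursor) and classified; per-class read counts
#' are returned.
#'
#' @param stack a \linkS4class{ReadStack}.
#' @param matureTable mature rows (\code{offset}, \code{length}) of this
#'   precursor.
#' @param precursorLength nt.
#' @return named numeric vector: canonical, add5, sub5, add3, sub3 counts.
#' @export
tallyIsoforms <- function(stack, matureTable, precursorLength) {
  out <- c(canonical = 0, add5 = 0, sub5 = 0, add3 = 0, sub3 = 0)
  e <- stack@entries
  if (!nrow(e) || is.null(matureTable) || !nrow(matureTable)) return(out)
  mArm <- armFromOffset(matureTable$offset, matureTable$length,
                        precursorLength)
  for (k in seq_len(nrow(e))) {
    rArm <- if (e$offset[k] <= precursorLength / 2) "5p" else "3p"
    cand <- which(mArm == rArm)
    if (!length(cand)) next
    d <- abs(matureTable$offset[cand] - e$offset[k])
    m <- cand[which.min(d)]
    iso <- classifyIsoform(e$offset[k], e$length[k],
                           matureTable$offset[m], matureTable$length[m])
    if (iso$canonical) out["canonical"] <- out["canonical"] + e$count[k]
    else {
      for (cls in c("add5", "sub5", "add3", "sub3"))
        if (iso[[cls]] > 0) out[cls] <- out[cls] + e$count[k]
    }
  }
  out
}

#' Detect arm-switching (arm selection) events
#'
#' For each precursor, an event is emitted when some sample has the 5p arm
#' dominant (ratio >= \code{ratioMin}, both arms >= \code{floor} TPM) while
#' another sample has the 3p arm dominant under the same conditions. The
#' witness pair reported maximizes the smaller of the two dominance ratios.
#'
#' @param armTpm data.frame with columns \code{id}, \code{sample},
#'   \code{tpm_5p}, \code{tpm_3p}.
#' @param floor minimum TPM on both arms in implicated samples (default 1).
#' @param ratioMin minimum dominance fold change (default 2).
#' @return data.frame of events: \code{id}, \code{sample_5p_dominant},
#'   \code{sample_3p_dominant}, \code{ratio_5p}, \code{ratio_3p}.
#' @export
detectArmSwitching <- function(armTpm, floor = 1, ratioMin = 2) {
  stopifnot(all(c("id", "sample", "tpm_5p", "tpm_3p") %in% names(armTpm)))
  events <- list()
  for (id in unique(armTpm$id)) {
    a <- armTpm[armTpm$id == id, , drop = FALSE]
    if (nrow(a) < 2) next
    ok <- a$tpm_5p >= floor & a$tpm_3p >= floor
    r5 <- ifelse(ok, a$tpm_5p / a$tpm_3p, NA)
    r3 <- ifelse(ok, a$tpm_3p / a$tpm_5p, NA)
    dom5 <- which(ok & r5 >= ratioMin)
    dom3 <- which(ok & r3 >= ratioMin)
    if (length(dom5) && length(dom3)) {
      s <- dom5[which.max(r5[dom5])]
      t <- dom3[which.max(r3[dom3])]
      events[[length(events) + 1L]] <- data.frame(
        id = id, sample_5p_dominant = a$sample[s],
        sample_3p_dominant = a$sample[t],
        ratio_5p = r5[s], ratio_3p = r3[t], stringsAsFactors = FALSE)
    }
  }
  if (!length(events))
    return(data.frame(id = character(), sample_5p_dominant = character(),
                      sample_3p_dominant = character(), ratio_5p = numeric(),
                      ratio_3p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, events)
}

#' Genomic-context label of a precursor interval
#'
#' The highest-precedence label among annotated features covering at least
#' \code{minFraction} of the precursor; \code{"intergenic"} when none does.
#' Transposable-element subclasses (TIR, Helitron, LINE, LTR, ...) present
#' in the feature annotation are honoured when listed in the precedence.
#'
#' @param interval one-row data.frame (\code{chrom}, \code{start},
#'   \code{end}) or a \code{GRanges} of length 1.
#' @param features a \code{GRanges} of genome features with a \code{label}
#'   metadata column (see \code{\link{featureLabels}}).
#' @param precedence ordered labels, most specific first.
#' @param minFraction minimum overlap fraction of the precursor (default 0.5).
#' @return list: \code{label}, \code{overlapFraction}.
#' @export
genomicContext <- function(interval, features,
                           precedence = c("TIR", "Helitron", "LINE", "LTR",
                                          "TE", "lncRNA", "intron", "exon"),
                           minFraction = 0.5) {
  if (!methods::is(interval, "GRanges"))
    interval <- GenomicRanges::GRanges(interval$chrom,
      IRanges::IRanges(interval$start, interval$end))
  ov <- GenomicRanges::findOverlaps(interval, features, ignore.strand = TRUE)
  if (!length(ov)) return(list(label = "intergenic", overlapFraction = 0))
  sh <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    rep(interval, length(sh)), features[sh], ignore.strand = TRUE))
  frac <- w / GenomicRanges::width(interval)
  lab <- as.character(features$label[sh])
  keep <- frac >= minFraction & lab %in% precedence
  if (!any(keep)) return(list(label = "intergenic", overlapFraction = 0))
  ordr <- order(match(lab[keep], precedence), -frac[keep])[1]
  list(label = lab[keep][ordr], overlapFraction = unname(frac[keep][ordr]))
}

#' Load a feature GFF3 and map types to context labels
#'
#' @param gff path to a genome-annotation GFF3.
#' @param typeMap named character vector mapping GFF3 types to context
#'   labels.
#' @return \code{GRanges} with a \code{label} column.
#' @export
featureLabels <- function(gff, typeMap = c(exon = "exon", intron = "intron",
                                           lnc_RNA = "lncRNA",
                                           lncRNA = "lncRNA",
                                           transposable_element = "TE",
                                           TIR = "TIR", Helitron = "Helitron",
                                           LINE = "LINE", LTR = "LTR")) {
  gr <- rtracklayer::import(gff, format = "gff3")
  keep <- as.character(gr$type) %in% names(typeMap)
  gr <- gr[keep]
  gr$label <- unname(typeMap[as.character(gr$type)])
  gr
}

#' Build the curation summary and report bundle
#'
#' One row per candidate with the numbers a curator inspects: coordinates,
#' sources, lengths, fold energy/AMFE, criteria flags, SVM score, breadth,
#' genomic context, isomiR tallies and arm-switch count. Candidates listed
#' in \code{remove} are excluded and the export regenerates
#' deterministically.
#'
#' @param records \linkS4class{PrecursorSet} of candidates.
#' @param selection \code{\link{selectFinal}} output.
#' @param structures named list of \linkS4class{SecondaryStructure}.
#' @param stacks named list of \linkS4class{ReadStack} (may lack ids).
#' @param breadth \code{\link{expressionBreadth}} output, or NULL.
#' @param contexts named list of \code{\link{genomicContext}} results, or
#'   NULL.
#' @param remove character vector of ids removed during curation.
#' @return data.frame summary, one row per retained candidate.
#' @export
buildSummary <- function(records, selection, structures, stacks = list(),
                         breadth = NULL, contexts = NULL,
                         remove = character(0)) {
  ids <- names(records)
  orphans <- setdiff(selection$id, ids)
  if (length(orphans))
    stop("selection refers to unknown candidate id(s): ",
         paste(orphans, collapse = ", "))
  miss <- setdiff(ids, selection$id)
  if (length(miss))
    stop("candidate(s) missing from selection: ", paste(miss, collapse = ", "))
  ids <- setdiff(ids, remove)
  info <- records@info
  rows <- lapply(ids, function(id) {
    i <- match(id, info$id)
    st <- structures[[id]]
    n <- nchar(records@sequences[[id]])
    mt <- records@matures[records@matures$precursor_id == id, , drop = FALSE]
    sel <- selection[selection$id == id, ]
    stk <- stacks[[id]]
    iso <- if (!is.null(stk)) tallyIsoforms(stk, mt, n)
           else c(canonical = 0, add5 = 0, sub5 = 0, add3 = 0, sub3 = 0)
    br <- if (!is.null(breadth) && id %in% breadth$id)
      breadth$breadth[breadth$id == id] else NA_real_
    ctx <- if (!is.null(contexts) && !is.null(contexts[[id]]))
      contexts[[id]]$label else NA_character_
    data.frame(id = id, chrom = info$chrom[i], start = info$start[i],
               end = info$end[i], strand = info$strand[i],
               sources = info$sources[i], precursor_len = n,
               n_matures = nrow(mt),
               mature_len = if (nrow(mt)) max(mt$length) else NA_integer_,
               mfe = if (!is.null(st)) st@energy else NA_real_,
               amfe = if (!is.null(st)) amfe(st@energy, n) else NA_real_,
               ht_pass = sel$ht_pass, svm_score = sel$svm_score,
               svm_pass = sel$svm_pass, selected = sel$selected,
               breadth = br, context = ctx,
               reads_canonical = unname(iso["canonical"]),
               reads_add5 = unname(iso["add5"]),
               reads_sub5 = unname(iso["sub5"]),
               reads_add3 = unname(iso["add3"]),
               reads_sub3 = unname(iso["sub3"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export the curated annotation (TSV + GFF3 + FASTA + per-candidate reports)
#'
#' Writes \code{summary.tsv}, \code{annotation.gff3},
#' \code{precursors.fa}, \code{matures.fa} and one markdown report with a
#' JSON sidecar per candidate under \code{dir/reports/}. Output is
#' byte-deterministic for identical inputs.
#'
#' @param summary \code{\link{buildSummary}} output.
#' @param records the matching \linkS4class{PrecursorSet}.
#' @param structures named list of structures (for the report dot-bracket).
#' @param stacks named list of stacks (for the report read layout).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
exportAnnotation <- function(summary, records, structures = list(),
                             stacks = list(), dir) {
  dir.create(file.path(dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  keep <- records[summary$id]
  tsv <- file.path(dir, "summary.tsv")
  utils::write.table(summary, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writePrecursorGff3(keep, file.path(dir, "annotation.gff3"))
  writeFasta(stats::setNames(keep@sequences, names(keep)),
             file.path(dir, "precursors.fa"))
  mt <- keep@matures
  writeFasta(stats::setNames(mt$sequence, mt$name),
             file.path(dir, "matures.fa"))
  paths <- c(tsv, file.path(dir, "annotation.gff3"),
             file.path(dir, "precursors.fa"), file.path(dir, "matures.fa"))
  for (id in summary$id) {
    md <- file.path(dir, "reports", paste0(id, ".md"))
    row <- summary[summary$id == id, ]
    lines <- c(paste0("# ", id), "",
               paste0("- location: ", row$chrom, ":", row$start, "-",
                      row$end, " (", row$strand, ")"),
               paste0("- sources: ", row$sources),
               paste0("- MFE: ", row$mfe, "  AMFE: ",
                      formatC(row$amfe, digits = 6, format = "g")),
               paste0("- selected: ", row$selected, " (HT ", row$ht_pass,
                      ", SVM ", row$svm_pass, ")"))
    st <- structures[[id]]
    if (!is.null(st)) lines <- c(lines, "", "```",
                                 as.character(keep@sequences[[id]]),
                                 st@dotbracket, "```")
    stk <- stacks[[id]]
    if (!is.null(stk) && nrow(stk@entries)) {
      e <- stk@entries
      lines <- c(lines, "", "Read stack (offset/length/sample/count):", "```",
                 sprintf("%3d %2d %s %g", e$offset, e$length, e$sample,
                         e$count), "```")
    }
    writeLines(lines, md)
    jsonlite::write_json(as.list(row), file.path(dir, "reports",
                                                 paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, md)
  }
  invisible(paths)
}

writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

#' Write a PrecursorSet as GFF3 (precursor + nested mature rows)
#'
#' @param records a \linkS4class{PrecursorSet} (located records only are
#'   written).
#' @param path output file.
#' @export
writePrecursorGff3 <- function(records, path) {
  info <- records@info[!is.na(records@info$chrom), , drop = FALSE]
  mt <- records@matures[records@matures$precursor_id %in% info$id, ,
                        drop = FALSE]
  pre <- GenomicRanges::GRanges(info$chrom,
                                IRanges::IRanges(info$start, info$end),
                                strand = info$strand,
                                type = "miRNA_primary_transcript",
                                ID = info$id, Name = info$id,
                                sources = gsub(",", "|", info$sources))
  all <- pre
  if (nrow(mt)) {
    i <- match(mt$precursor_id, info$id)
    gs <- ifelse(info$strand[i] == "+", info$start[i] + mt$offset - 1L,
                 info$end[i] - (mt$offset + mt$length - 1L) + 1L)
    mat <- GenomicRanges::GRanges(info$chrom[i],
                                  IRanges::IRanges(gs, gs + mt$length - 1L),
                                  strand = info$strand[i], type = "miRNA",
                                  ID = mt$name, Name = mt$name,
                                  sources = NA_character_)
    mat$Derives_from <- mt$precursor_id
    pre$Derives_from <- NA_character_
    all <- c(pre, mat)
  }
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
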