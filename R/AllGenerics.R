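#' Accessors for package classes
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("precursorInfo", function(x) standardGeneric("precursorInfo"))
#' @rdname accessors
#' @export
setGeneric("precursorSeqs", function(x) standardGeneric("precursorSeqs"))
#' @rdname accessors
#' @export
setGeneric("matures", function(x) standardGeneric("matures"))
#' @rdname accessors
#' @export
setGeneric("precursorRanges", function(x) standardGeneric("precursorRanges"))
#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))
#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setGeneric("foldEnergy", function(x) standardGeneric("foldEnergy"))
#' @rdname accessors
#' @export
setGeneric("stackEntries", function(x) standardGeneric("stackEntries"))

#' @describeIn PrecursorSet-class number of precursors.
#' @param x a PrecursorSet.
#' @export
setMethod("length", "PrecursorSet", function(x) nrow(x@info))

#' @describeIn PrecursorSet-class precursor identifiers.
#' @export
setMethod("names", "PrecursorSet", function(x) as.character(x@info$id))

#' @describeIn PrecursorSet-class the per-precursor metadata table.
#' @export
setMethod("precursorInfo", "PrecursorSet", function(x) x@info)

#' @describeIn PrecursorSet-class named RNA sequences as an
#'   \code{RNAStringSet}.
#' @export
setMethod("precursorSeqs", "PrecursorSet",
          function(x) Biostrings::RNAStringSet(x@sequences))

#' @describeIn PrecursorSet-class the nested mature records.
#' @export
setMethod("matures", "PrecursorSet", function(x) x@matures)

#' @describeIn PrecursorSet-class located precursors as a \code{GRanges}
#'   (unlocated records are dropped; ids kept as names).
#' @export
setMethod("precursorRanges", "PrecursorSet", function(x) {
  info <- x@info[!is.na(x@info$chrom), , drop = FALSE]
  gr <- GenomicRanges::GRanges(info$chrom,
                               IRanges::IRanges(info$start, info$end),
                               strand = info$strand)
  names(gr) <- info$id
  gr$sources <- info$sources
  gr
})

#' @describeIn PrecursorSet-class subset by index, logical or id.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PrecursorSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$id)
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  mt <- x@matures[x@matures$precursor_id %in% info$id, , drop = FALSE]
  rownames(mt) <- NULL
  PrecursorSet(info, x@sequences[i], mt)
})

setMethod("show", "PrecursorSet", function(object) {
  n <- length(object)
  located <- sum(!is.na(object@info$chrom))
  srcs <- sort(unique(unlist(strsplit(object@info$sources, ","))))
  cat("PrecursorSet with", n, "precursors (", located, "located ),",
      nrow(object@matures), "matures\n")
  cat("  sources:", paste(srcs, collapse = ", "), "\n")
  if (n) cat("  ids:", paste(utils::head(names(object), 4), collapse = ", "),
             if (n > 4) "..." else "", "\n")
})

#' @describeIn SecondaryStructure-class the dot-bracket string.
#' @param x a SecondaryStructure.
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotbracket)

#' @describeIn SecondaryStructure-class integer pair table (0 = unpaired).
#' @export
setMethod("pairTable", "SecondaryStructure", function(x) x@pairs)

#' @describeIn SecondaryStructure-class fold energy.
#' @export
setMethod("foldEnergy", "SecondaryStructure", function(x) x@energy)

setMethod("show", "SecondaryStructure", function(object) {
  cat("SecondaryStructure (", length(object@pairs), "nt, energy",
      object@energy, ")\n ", object@dotbracket, "\n")
})

#' @describeIn ReadStack-class the aggregated entry table.
#' @param x a ReadStack.
#' @export
setMethod("stackEntries", "ReadStack", function(x) x@entries)

setMethod("show", "ReadStack", function(object) {
  cat("ReadStack for", object@precursorId, ":", nrow(object@entries),
      "entries,", sum(object@entries$count), "reads in",
      length(unique(object@entries$sample)), "samples\n")
})

setMethod("show", "OneClassModel", function(object) {
  cat("OneClassModel: nu =", object@nu, ", gamma =",
      signif(object@gamma, 4), ",", length(object@featureNames),
      "features (", length(object@dropped), "dropped )\n")
})

setMethod("show", "FixtureBundle", function(object) {
  cat("FixtureBundle:", length(object@genome), "contigs,",
      length(object@precursors), "planted loci,",
      nrow(object@alignments), "alignment rows\n")
})
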