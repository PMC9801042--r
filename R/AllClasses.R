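#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings RNAStringSet DNAStringSet reverseComplement
NULL

#' PrecursorSet: a collection of candidate miRNA precursor loci
#'
#' The central container of the package. Each precursor carries a uniform
#' identifier, an optional genomic location (1-based inclusive, stranded),
#' its transcribed-strand RNA sequence, the set of source tags that
#' contributed it (database names or \code{"predicted"}), and zero or more
#' mature records nested by precursor-local coordinates.
#'
#' @slot info data.frame with one row per precursor: \code{id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (\code{NA} chrom when
#'   unlocated), and \code{sources} (comma-separated tags).
#' @slot sequences named character vector of RNA sequences (U alphabet),
#'   parallel to \code{info$id}.
#' @slot matures data.frame with columns \code{precursor_id}, \code{name},
#'   \code{arm} (\code{"5p"}, \code{"3p"} or \code{"unknown"}), \code{offset}
#'   (1-based start on the precursor), \code{length}, \code{sequence}.
#'
#' @examples
#' ps <- PrecursorSet(
#'   info = data.frame(id = "mir1", chrom = "chr1", start = 101, end = 120,
#'                     strand = "+", sources = "dbA"),
#'   sequences = c(mir1 = "ACGUACGUACGUACGUACGU"),
#'   matures = data.frame(precursor_id = "mir1", name = "mir1-5p",
#'                        arm = "5p", offset = 1, length = 8,
#'                        sequence = "ACGUACGU"))
#' ps
#' @export
setClass("PrecursorSet",
  representation(info = "data.frame", sequences = "character",
                 matures = "data.frame"))

setValidity("PrecursorSet", function(object) {
  msgs <- character()
  info <- object@info
  need <- c("id", "chrom", "start", "end", "strand", "sources")
  if (!all(need %in% names(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(info$id)) msgs <- c(msgs, "duplicate precursor ids")
  if (!identical(names(object@sequences), as.character(info$id)))
    msgs <- c(msgs, "sequences must be named by info$id, in order")
  if (any(nchar(object@sequences) == 0L))
    msgs <- c(msgs, "empty precursor sequence")
  if (any(!is.na(info$strand) & !info$strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be + or -")
  located <- !is.na(info$chrom)
  if (any(located & !(info$start >= 1 & info$end >= info$start)))
    msgs <- c(msgs, "located precursors need 1 <= start <= end")
  if (any(located &
          (info$end - info$start + 1L) != nchar(object@sequences)))
    msgs <- c(msgs, "sequence length must equal interval width")
  if (any(!nzchar(info$sources)))
    msgs <- c(msgs, "every precursor needs at least one source tag")
  mt <- object@matures
  if (nrow(mt)) {
    if (!all(mt$precursor_id %in% info$id))
      msgs <- c(msgs, "mature rows reference unknown precursors")
    plen <- nchar(object@sequences)[match(mt$precursor_id, info$id)]
    if (any(mt$offset < 1L | mt$offset + mt$length - 1L > plen))
      msgs <- c(msgs, "mature outside its precursor")
    sub <- substr(object@sequences[match(mt$precursor_id, info$id)],
                  mt$offset, mt$offset + mt$length - 1L)
    if (any(sub != mt$sequence))
      msgs <- c(msgs, "mature sequence differs from precursor subsequence")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @rdname PrecursorSet-class
#' @param info,sequences,matures see the class slots.
#' @export
PrecursorSet <- function(info, sequences, matures = emptyMatures()) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  rownames(info) <- NULL
  if (is.null(names(sequences))) names(sequences) <- info$id
  sequences <- toupper(chartr("T", "U", sequences))[as.character(info$id)]
  if (nrow(matures)) {
    matures$sequence <- toupper(chartr("T", "U", matures$sequence))
    matures <- matures[order(match(matures$precursor_id, info$id),
                             matures$offset, matures$length), , drop = FALSE]
    rownames(matures) <- NULL
  }
  new("PrecursorSet", info = info, sequences = sequences, matures = matures)
}

emptyMatures <- function() {
  data.frame(precursor_id = character(), name = character(),
             arm = character(), offset = integer(), length = integer(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' SecondaryStructure: dot-bracket, pair table and energy of one fold
#'
#' @slot dotbracket character, Vienna dot-bracket notation.
#' @slot pairs integer vector; \code{pairs[i]} is the 1-based partner of
#'   position i, or 0 when unpaired.
#' @slot energy numeric, total energy under the active pair-weight model
#'   (kcal/mol-like, non-positive).
#' @export
setClass("SecondaryStructure",
  representation(dotbracket = "character", pairs = "integer",
                 energy = "numeric"))

setValidity("SecondaryStructure", function(object) {
  p <- object@pairs
  n <- length(p)
  if (nchar(object@dotbracket) != n) return("dotbracket/pairs length mismatch")
  idx <- which(p > 0L)
  if (any(p[idx] < 1L | p[idx] > n)) return("pair index out of range")
  if (!all(p[p[idx]] == idx)) return("pair table not symmetric")
  if (object@energy > 1e-9) return("energy must be <= 0")
  TRUE
})

#' ReadStack: per-precursor aggregated read evidence
#'
#' Reads fully contained in one precursor, re-expressed in precursor-local
#' coordinates (1-based) and aggregated by (offset, length, sample).
#'
#' @slot precursorId character scalar.
#' @slot entries data.frame with columns \code{offset}, \code{length},
#'   \code{count}, \code{sample}.
#' @export
setClass("ReadStack",
  representation(precursorId = "character", entries = "data.frame"))

setValidity("ReadStack", function(object) {
  e <- object@entries
  need <- c("offset", "length", "count", "sample")
  if (!all(need %in% names(e)))
    return(paste("entries needs columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$offset < 1L)) return("offsets are 1-based")
    if (any(e$count < 1)) return("counts must be >= 1")
    if (anyDuplicated(e[c("offset", "length", "sample")]))
      return("entries must be aggregated by (offset, length, sample)")
  }
  TRUE
})

#' CriteriaThresholds: configuration of the high-throughput selection rules
#'
#' Defaults encode consensus plant miRNA calling practice: mature length
#' 20--24 nt, precursor at most 300 nt, at most 5 duplex mismatches and 3 nt
#' of asymmetric bulge, 2-nt 3' overhangs (tolerance 1 nt), processing
#' precision at least 0.75, expression in at least 2 libraries, and star
#' reads or replication required.
#'
#' @export
setClass("CriteriaThresholds",
  representation(matureLenMin = "integer", matureLenMax = "integer",
                 maxPrecursorLen = "integer", maxMismatches = "integer",
                 maxAsymBulge = "integer", overhang = "integer",
                 overhangTol = "integer", minPrecision = "numeric",
                 minLibraries = "integer", requireStarOrReplication = "logical"),
  prototype(matureLenMin = 20L, matureLenMax = 24L, maxPrecursorLen = 300L,
            maxMismatches = 5L, maxAsymBulge = 3L, overhang = 2L,
            overhangTol = 1L, minPrecision = 0.75, minLibraries = 2L,
            requireStarOrReplication = TRUE))

setValidity("CriteriaThresholds", function(object) {
  if (object@minPrecision <= 0 || object@minPrecision > 1)
    return("minPrecision must be in (0, 1]")
  if (object@matureLenMin < 1L || object@matureLenMax < object@matureLenMin)
    return("invalid mature length range")
  if (object@maxPrecursorLen < 1L) return("maxPrecursorLen must be positive")
  TRUE
})

#' @rdname CriteriaThresholds-class
#' @param ... slot overrides, e.g. \code{minPrecision = 0.8}.
#' @export
criteriaThresholds <- function(...) new("CriteriaThresholds", ...)

#' OneClassModel: a fitted one-class SVM over a feature registry
#'
#' @slot fit the underlying \pkg{e1071} one-classification SVM.
#' @slot center,scale per-feature standardization learned from training.
#' @slot featureNames registry feature names, in order.
#' @slot dropped names of zero-variance features removed before fitting.
#' @slot nu,gamma hyperparameters.
#' @slot threshold decision-value cutoff (default 0, the SVM boundary).
#' @slot seed RNG seed recorded at fit time.
#' @export
setClass("OneClassModel",
  representation(fit = "ANY", center = "numeric", scale = "numeric",
                 featureNames = "character", dropped = "character",
                 nu = "numeric", gamma = "numeric", threshold = "numeric",
                 seed = "integer"))

#' FixtureBundle: a synthetic genome + annotation + alignments with truth
#'
#' @slot genome named character vector of DNA contig sequences.
#' @slot precursors the planted loci as a \linkS4class{PrecursorSet}
#'   (true hairpins and decoys, with mature/star truth in \code{truth}).
#' @slot alignments data.frame of aligned reads: \code{sample},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{count}
#'   (1-based inclusive).
#' @slot truth data.frame of planted ground truth per locus.
#' @slot config the \code{fixtureConfig()} list used.
#' @export
setClass("FixtureBundle",
  representation(genome = "character", precursors = "PrecursorSet",
                 alignments = "data.frame", truth = "data.frame",
                 config = "list"))
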