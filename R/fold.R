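#' Pair-weight parameters for the built-in folder
#'
#' The default energy model is a weighted Nussinov base-pair maximization:
#' GC pairs score -3, AU -2, GU (wobble) -1, with a minimum hairpin loop of
#' 3 unpaired nt. The units are kcal/mol-like model units; they order
#' structures the same way stacking-free thermodynamic models do at hairpin
#' scale while keeping the optimum exactly computable and testable by
#' exhaustive enumeration.
#'
#' @param wGC,wAU,wGU pair weights, all <= 0.
#' @param minLoop minimum hairpin loop size, >= 3.
#' @return a list of folding parameters.
#' @export
foldParams <- function(wGC = -3, wAU = -2, wGU = -1, minLoop = 3L) {
  stopifnot(wGC <= 0, wAU <= 0, wGU <= 0, minLoop >= 3L)
  list(wGC = wGC, wAU = wAU, wGU = wGU, minLoop = as.integer(minLoop))
}

encodeBases <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(v)) stop("non-ACGU(T) character in sequence: ", seq)
  v
}

#' Fold a hairpin with the built-in weighted Nussinov folder
#'
#' Dynamic programming over nested pairings, minimizing total pair energy
#' under the active \code{\link{foldParams}}. The traceback is
#' deterministic: pairing position i is preferred over leaving it unpaired,
#' and among equal-energy partners the smallest bifurcation point wins. A
#' pre-computed structure from an external thermodynamic folder can be
#' supplied instead via \code{\link{secondaryStructure}}.
#'
#' @param seq RNA (or DNA) text.
#' @param params see \code{\link{foldParams}}.
#' @return a \linkS4class{SecondaryStructure}.
#' @examples
#' foldHairpin("GGGAAACCC")  # (((...))), energy -9
#' @export
foldHairpin <- function(seq, params = foldParams()) {
  v <- encodeBases(seq)
  stopifnot(length(v) >= params$minLoop + 2L)
  res <- .nussinov_fold(v, params$wGC, params$wAU, params$wGU, params$minLoop)
  pairs <- res$pairs
  db <- rep(".", length(v))
  db[pairs > 0 & seq_along(pairs) < pairs] <- "("
  db[pairs > 0 & seq_along(pairs) > pairs] <- ")"
  new("SecondaryStructure", dotbracket = paste(db, collapse = ""),
      pairs = as.integer(pairs), energy = res$energy)
}

#' Wrap an externally computed dot-bracket as a SecondaryStructure
#'
#' Entry point for pluggable thermodynamic folders: the dot-bracket is taken
#' verbatim and the pair table derived from it. When \code{energy} is
#' omitted it is recomputed from the pairs under \code{params}, so the
#' internal invariant (energy consistent with the pair table) always holds.
#'
#' @param seq the folded sequence.
#' @param dotbracket Vienna dot-bracket string, same length as \code{seq}.
#' @param energy reported energy (optional).
#' @param params \code{\link{foldParams}} used when recomputing energy.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
secondaryStructure <- function(seq, dotbracket, energy = NULL,
                               params = foldParams()) {
  n <- nchar(dotbracket)
  stopifnot(nchar(seq) == n)
  ch <- strsplit(dotbracket, "")[[1]]
  stopifnot(all(ch %in% c("(", ")", ".")))
  pairs <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket")
      j <- open[length(open)]; open <- open[-length(open)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket")
  if (is.null(energy)) energy <- pairEnergy(seq, pairs, params)
  new("SecondaryStructure", dotbracket = dotbracket,
      pairs = pairs, energy = energy)
}

pairEnergy <- function(seq, pairs, params = foldParams()) {
  v <- encodeBases(seq)
  idx <- which(pairs > seq_along(pairs))
  if (!length(idx)) return(0)
  a <- v[idx]; b <- v[pairs[idx]]
  w <- ifelse((a == 2 & b == 1) | (a == 1 & b == 2), params$wGC,
         ifelse((a == 0 & b == 3) | (a == 3 & b == 0), params$wAU,
           ifelse((a == 2 & b == 3) | (a == 3 & b == 2), params$wGU, 0)))
  sum(w)
}

#' Adjusted minimal free energy
#'
#' AMFE = energy / length * 100, i.e. the fold energy normalized per 100 nt
#' so hairpins of different lengths are comparable.
#'
#' @param energy fold energy (<= 0).
#' @param length sequence length in nt (> 0).
#' @return AMFE value.
#' @export
amfe <- function(energy, length) {
  if (length <= 0) stop("length must be positive")
  energy / length * 100
}

#' Duplex statistics of a mature miRNA within its hairpin
#'
#' Infers the star strand from the pair table using canonical Dicer/DCL1
#' geometry (the duplex leaves 2-nt 3' overhangs on both strands) and
#' measures: \code{mismatches}, the mature positions unpaired or paired
#' outside the star span; \code{asymBulgeNt}, total asymmetric-bulge nt in
#' interior loops between the two duplex strands; and the realized 3'
#' overhang on each arm.
#'
#' @param structure a \linkS4class{SecondaryStructure} of the precursor.
#' @param matureOffset,matureLength 1-based mature start and length on the
#'   precursor.
#' @return list: \code{mismatches}, \code{asymBulgeNt},
#'   \code{overhang3pMatureArm}, \code{overhang3pStarArm},
#'   \code{starOffset}, \code{starLength}.
#' @export
extractDuplex <- function(structure, matureOffset, matureLength) {
  pt <- structure@pairs
  n <- length(pt)
  mIdx <- matureOffset:(matureOffset + matureLength - 1L)
  stopifnot(matureOffset >= 1L, max(mIdx) <= n)
  partners <- pt[mIdx]
  inside <- partners != 0L & partners >= min(mIdx) & partners <= max(mIdx)
  if (any(inside)) stop("loop-spanning mature: it straddles the terminal loop")
  paired <- which(partners != 0L) # local indices 1..matureLength
  if (!length(paired)) stop("mature is entirely unpaired; no duplex")

  # Canonical geometry: the star pairs with mature positions 1..(len-2) and
  # carries its own 2-nt 3' overhang past the partner of the mature 5' end.
  # Unpaired anchors are projected from the nearest paired position.
  anchor5 <- paired[1]
  q <- matureLength - 2L # mature position expected to pair with star 5' end
  below <- paired[paired <= q]
  if (length(below)) {
    p <- below[length(below)]
    starStart <- pt[mIdx[p]] - (q - p)
  } else {
    p <- paired[1]
    starStart <- pt[mIdx[p]] + (p - q)
  }
  starEnd <- pt[mIdx[anchor5]] + (anchor5 - 1L) + 2L
  starStart <- max(1L, starStart)
  starEnd <- min(n, max(starEnd, starStart))
  star <- starStart:starEnd

  # mismatches are counted over the duplex-forming part of the mature
  # (excluding its own 2-nt 3' overhang)
  dupIdx <- seq_len(max(1L, matureLength - 2L))
  dupPartners <- partners[dupIdx]
  mismatches <- sum(dupPartners == 0L) +
    sum(dupPartners != 0L & !(dupPartners %in% star))

  # asymmetric bulges: between consecutive paired duplex positions compare
  # unpaired run lengths on the two strands
  pairedDup <- dupIdx[dupPartners != 0L]
  asym <- 0L
  if (length(pairedDup) > 1) {
    for (k in seq_len(length(pairedDup) - 1L)) {
      i1 <- pairedDup[k]; i2 <- pairedDup[k + 1L]
      gapM <- i2 - i1 - 1L
      gapS <- abs(partners[i1] - partners[i2]) - 1L
      asym <- asym + abs(gapM - gapS)
    }
  }
  inStar <- paired[partners[paired] %in% star]
  pLast <- if (length(inStar)) inStar[length(inStar)] else paired[length(paired)]
  overhangMature <- matureLength - pLast
  overhangStar <- starEnd - pt[mIdx[anchor5]]
  list(mismatches = as.integer(mismatches), asymBulgeNt = as.integer(asym),
       overhang3pMatureArm = as.integer(overhangMature),
       overhang3pStarArm = as.integer(overhangStar),
       starOffset = as.integer(starStart),
       starLength = as.integer(length(star)))
}

#' Precision of processing from a read stack
#'
#' The fraction of stacked read counts whose 5' and 3' ends both fall
#' within \code{tol} nt of the ends of an annotated mature or the inferred
#' star. A hallmark of genuine DCL processing.
#'
#' @param stack a \linkS4class{ReadStack} (nonempty).
#' @param matureTable data.frame with \code{offset}, \code{length}
#'   (precursor-local, 1-based) of annotated matures.
#' @param star optional list/row with \code{starOffset}, \code{starLength}.
#' @param tol end tolerance in nt (default 1).
#' @return precision ratio in [0, 1].
#' @export
precisionOfProcessing <- function(stack, matureTable, star = NULL, tol = 1L) {
  e <- stack@entries
  if (!nrow(e)) stop("no read support: empty stack for ", stack@precursorId)
  refs <- data.frame(start = matureTable$offset,
                     end = matureTable$offset + matureTable$length - 1L)
  if (!is.null(star))
    refs <- rbind(refs, data.frame(start = star$starOffset,
                                   end = star$starOffset + star$starLength - 1L))
  if (!nrow(refs)) stop("no reference mature/star coordinates")
  rs <- e$offset; re <- e$offset + e$length - 1L
  ok <- rep(FALSE, nrow(e))
  for (r in seq_len(nrow(refs)))
    ok <- ok | (abs(rs - refs$start[r]) <= tol & abs(re - refs$end[r]) <= tol)
  sum(e$count[ok]) / sum(e$count)
}

#' The default feature registry
#'
#' Ordered feature names for \code{\link{extractFeatures}}: 84 sequence
#' features (mono-, di- and tri-nucleotide frequencies), GC content,
#' precursor and dominant-mature length, structure features (paired
#' fraction, energy, AMFE, stem length, loop size, duplex statistics, a
#' 20-bin per-position pairing profile) and 3 expression summaries.
#'
#' @return character vector of feature names, fixed order.
#' @export
featureRegistry <- function() {
  bases <- c("A", "C", "G", "U")
  kmers <- c(bases,
             as.vector(outer(bases, bases, paste0)),
             as.vector(outer(as.vector(outer(bases, bases, paste0)),
                             bases, paste0)))
  c(paste0("freq_", kmers), "gc_content", "precursor_len", "mature_len",
    "paired_fraction", "mfe", "amfe", "stem_len", "loop_size",
    "duplex_mismatches", "duplex_asym_bulge", "overhang_mature",
    "overhang_star", paste0("pairprofile_", 1:20),
    "expr_max_tpm", "expr_mean_tpm", "expr_breadth")
}

#' Extract the feature vector of one candidate
#'
#' Deterministic numeric vector over the active registry. Expression
#' summaries default to zero when no expression evidence exists; duplex
#' statistics default to zero when no mature is annotated.
#'
#' @param seq precursor RNA sequence.
#' @param structure its \linkS4class{SecondaryStructure}.
#' @param duplex optional \code{\link{extractDuplex}} result.
#' @param matureLength dominant mature length (0 when unknown).
#' @param exprSummary optional list: \code{maxTpm}, \code{meanTpm},
#'   \code{breadth}.
#' @return named numeric vector following \code{\link{featureRegistry}}.
#' @export
extractFeatures <- function(seq, structure, duplex = NULL, matureLength = 0L,
                            exprSummary = NULL) {
  seq <- chartr("T", "U", toupper(seq))
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  feats <- numeric(0)
  for (k in 1:3) {
    grams <- if (k == 1) ch else
      vapply(seq_len(n - k + 1L), function(i)
        paste(ch[i:(i + k - 1L)], collapse = ""), "")
    bases <- c("A", "C", "G", "U")
    allk <- switch(k, bases,
                   as.vector(outer(bases, bases, paste0)),
                   as.vector(outer(as.vector(outer(bases, bases, paste0)),
                                   bases, paste0)))
    tab <- table(factor(grams, levels = allk))
    feats <- c(feats, as.numeric(tab) / max(1L, length(grams)))
  }
  gc <- mean(ch %in% c("G", "C"))
  pt <- structure@pairs
  pairedFrac <- mean(pt != 0L)
  loop <- terminalLoopSize(pt)
  stemLen <- sum(pt > seq_along(pt))
  dup <- if (is.null(duplex))
    list(mismatches = 0L, asymBulgeNt = 0L, overhang3pMatureArm = 0L,
         overhang3pStarArm = 0L) else duplex
  bins <- cut(seq_len(n), breaks = 20, labels = FALSE)
  profile <- tapply(pt != 0L, bins, mean)
  profile <- as.numeric(profile[as.character(1:20)])
  profile[is.na(profile)] <- 0
  ex <- if (is.null(exprSummary)) list(maxTpm = 0, meanTpm = 0, breadth = 0)
        else exprSummary
  out <- c(feats, gc, n, matureLength, pairedFrac, structure@energy,
           amfe(structure@energy, n), stemLen, loop, dup$mismatches,
           dup$asymBulgeNt, dup$overhang3pMatureArm, dup$overhang3pStarArm,
           profile, ex$maxTpm, ex$meanTpm, ex$breadth)
  stats::setNames(out, featureRegistry())
}

terminalLoopSize <- function(pt) {
  idx <- which(pt > seq_along(pt))
  if (!length(idx)) return(length(pt))
  # innermost pair = the one with the smallest enclosed span
  spans <- pt[idx] - idx
  k <- idx[which.min(spans)]
  pt[k] - k - 1L
}
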