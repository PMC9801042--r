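#' Analyze a candidate set end to end
#'
#' Folds every precursor, extracts duplex statistics from its dominant
#' mature, builds read stacks and TPM/breadth summaries from the
#' alignments, extracts feature vectors and evaluates the high-throughput
#' criteria. This is the per-candidate evidence bundle behind selection and
#' curation.
#'
#' @param records a \linkS4class{PrecursorSet}.
#' @param alignments alignment data.frame (may be empty).
#' @param thresholds a \linkS4class{CriteriaThresholds}.
#' @param params \code{\link{foldParams}}.
#' @param inferMissingMatures infer a mature from the read stack for
#'   candidates without one (default TRUE).
#' @return list: \code{records} (possibly with inferred matures),
#'   \code{structures}, \code{duplexes}, \code{stacks}, \code{tpm},
#'   \code{breadth}, \code{features} (matrix), \code{criteria}
#'   (data.frame of per-rule flags), \code{htPass} (named logical).
#' @export
analyzeCandidates <- function(records, alignments = NULL,
                              thresholds = criteriaThresholds(),
                              params = foldParams(),
                              inferMissingMatures = TRUE) {
  ids <- names(records)
  emptyAln <- is.null(alignments) || !nrow(alignments)
  stacks <- if (emptyAln) list() else buildReadStacks(alignments, records)

  if (inferMissingMatures && !emptyAln) {
    withMat <- unique(records@matures$precursor_id)
    extra <- list()
    for (id in setdiff(names(stacks), withMat)) {
      m <- inferMature(stacks[[id]], records)
      if (!is.null(m)) extra[[id]] <- m
    }
    if (length(extra)) {
      mt <- rbind(records@matures, do.call(rbind, extra))
      records <- PrecursorSet(records@info, records@sequences, mt)
    }
  }

  structures <- lapply(ids, function(id)
    foldHairpin(records@sequences[[id]], params))
  names(structures) <- ids
  duplexes <- lapply(ids, function(id) {
    mt <- records@matures[records@matures$precursor_id == id, , drop = FALSE]
    if (!nrow(mt)) return(NULL)
    m <- mt[which.max(mt$length), ]
    tryCatch(extractDuplex(structures[[id]], m$offset, m$length),
             error = function(e) NULL)
  })
  names(duplexes) <- ids

  tpm <- NULL; breadth <- NULL
  if (!emptyAln) {
    samples <- sort(unique(alignments$sample))
    counts <- stackCounts(stacks, records, samples, level = "precursor")
    if (nrow(counts)) {
      tpm <- computeTpm(counts, libraryStats(alignments))
      breadth <- expressionBreadth(tpm)
    }
  }

  features <- t(vapply(ids, function(id) {
    mt <- records@matures[records@matures$precursor_id == id, , drop = FALSE]
    mlen <- if (nrow(mt)) max(mt$length) else 0L
    ex <- NULL
    if (!is.null(tpm) && id %in% rownames(tpm)) {
      v <- tpm[id, ]
      br <- breadth$breadth[breadth$id == id]
      ex <- list(maxTpm = max(v), meanTpm = mean(v), breadth = br)
    }
    extractFeatures(records@sequences[[id]], structures[[id]],
                    duplexes[[id]], mlen, ex)
  }, numeric(length(featureRegistry()))))
  rownames(features) <- ids

  crit <- lapply(ids, function(id) {
    mt <- records@matures[records@matures$precursor_id == id, , drop = FALSE]
    applyCriteria(records@sequences[[id]], structures[[id]], duplexes[[id]],
                  stacks[[id]], mt, thresholds)
  })
  rulesTab <- do.call(rbind, lapply(crit, function(x)
    as.data.frame(t(x$rules))))
  rulesTab <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), rulesTab)
  rulesTab$pass <- vapply(crit, `[[`, TRUE, "pass")
  htPass <- stats::setNames(rulesTab$pass, ids)

  list(records = records, structures = structures, duplexes = duplexes,
       stacks = stacks, tpm = tpm, breadth = breadth, features = features,
       criteria = rulesTab, htPass = htPass)
}

#' Run the full selection over an analyzed candidate set
#'
#' Fits the one-class SVM on the chosen training subset, scores every
#' candidate and combines both routes.
#'
#' @param analysis \code{\link{analyzeCandidates}} output.
#' @param trainOn \code{"annotated"} (records whose sources include a
#'   database tag, i.e. not only \code{"predicted"} — the published usage),
#'   \code{"ht_pass"} (criteria-passing subset; for when the annotation
#'   source itself is untrusted), or a character vector of training ids.
#' @param nu,seed one-class SVM parameters.
#' @param mode combination mode, see \code{\link{selectFinal}}.
#' @return list: \code{selection} (\code{\link{selectFinal}} table),
#'   \code{model}.
#' @export
runSelection <- function(analysis, trainOn = "annotated", nu = 0.05,
                         seed = 42L, mode = "union") {
  ids <- rownames(analysis$features)
  trainIds <- if (length(trainOn) == 1 && trainOn == "annotated") {
    info <- analysis$records@info
    info$id[vapply(strsplit(info$sources, ","),
                   function(s) any(s != "predicted"), TRUE)]
  } else if (length(trainOn) == 1 && trainOn == "ht_pass") {
    names(which(analysis$htPass))
  } else trainOn
  trainIds <- intersect(trainIds, ids)
  model <- fitOneClass(analysis$features[trainIds, , drop = FALSE],
                       nu = nu, seed = seed)
  scores <- scoreCandidates(model, analysis$features)
  list(selection = selectFinal(analysis$htPass, scores, mode = mode),
       model = model)
}
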