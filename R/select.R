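#' Evaluate the high-throughput criteria for one candidate bundle
#'
#' Each rule is evaluated independently and reported; the overall pass is
#' their conjunction. Candidates without read evidence fail the
#' evidence-dependent rules (precision, libraries, star/replication) rather
#' than erroring, mirroring how database-only entries are carried forward.
#'
#' @param seq precursor sequence.
#' @param structure \linkS4class{SecondaryStructure}.
#' @param duplex \code{\link{extractDuplex}} result, or NULL.
#' @param stack \linkS4class{ReadStack}, or NULL.
#' @param matureTable mature rows of this precursor (may be empty).
#' @param thresholds a \linkS4class{CriteriaThresholds}.
#' @param tol end tolerance passed to \code{\link{precisionOfProcessing}}.
#' @return list: \code{rules} (named logical vector) and \code{pass}.
#' @export
applyCriteria <- function(seq, structure, duplex = NULL, stack = NULL,
                          matureTable = NULL, thresholds = criteriaThresholds(),
                          tol = 1L) {
  t <- thresholds
  n <- nchar(seq)
  hasMature <- !is.null(matureTable) && nrow(matureTable) > 0
  mlen <- if (hasMature) matureTable$length[which.max(matureTable$length)] else NA
  hasStack <- !is.null(stack) && nrow(stack@entries) > 0

  rules <- c(
    mature_len = hasMature && mlen >= t@matureLenMin && mlen <= t@matureLenMax,
    precursor_len = n <= t@maxPrecursorLen,
    mismatches = !is.null(duplex) && duplex$mismatches <= t@maxMismatches,
    asym_bulge = !is.null(duplex) && duplex$asymBulgeNt <= t@maxAsymBulge,
    overhangs = !is.null(duplex) &&
      abs(duplex$overhang3pMatureArm - t@overhang) <= t@overhangTol &&
      abs(duplex$overhang3pStarArm - t@overhang) <= t@overhangTol,
    precision = FALSE,
    libraries = FALSE,
    star_or_replication = FALSE)

  if (hasStack && hasMature) {
    prec <- precisionOfProcessing(stack, matureTable, star = duplex, tol = tol)
    rules["precision"] <- prec >= t@minPrecision
  }
  if (hasStack) {
    nlib <- length(unique(stack@entries$sample))
    rules["libraries"] <- nlib >= t@minLibraries
    if (!t@requireStarOrReplication) {
      rules["star_or_replication"] <- TRUE
    } else {
      starReads <- FALSE
      if (!is.null(duplex)) {
        e <- stack@entries
        starReads <- any(abs(e$offset - duplex$starOffset) <= tol &
                         abs((e$offset + e$length - 1L) -
                             (duplex$starOffset + duplex$starLength - 1L)) <= tol)
      }
      rules["star_or_replication"] <- starReads || nlib >= 2L
    }
  }
  list(rules = rules, pass = all(rules))
}

#' Fit a one-class SVM on annotated-positive feature vectors
#'
#' Features are standardized with center/scale learned from the training
#' set only; zero-variance features are dropped with a warning and recorded
#' in the model. The underlying machine is an RBF one-classification SVM;
#' nu bounds the training-outlier fraction.
#'
#' @param train numeric matrix (rows = training vectors, columns = named
#'   registry features); at least 10 rows.
#' @param nu one-class nu (default 0.05).
#' @param gamma RBF width; default \code{1/n_features} after dropping.
#' @param threshold decision-value cutoff for \code{svm_pass} (default 0).
#' @param seed RNG seed recorded and applied at fit time (default 42).
#' @return a \linkS4class{OneClassModel}.
#' @export
fitOneClass <- function(train, nu = 0.05, gamma = NULL, threshold = 0,
                        seed = 42L) {
  train <- as.matrix(train)
  stopifnot(nrow(train) >= 10, nu > 0, nu < 1)
  if (is.null(colnames(train)))
    colnames(train) <- paste0("f", seq_len(ncol(train)))
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  dropped <- colnames(train)[scl == 0 | !is.finite(scl)]
  if (length(dropped))
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
  keep <- setdiff(colnames(train), dropped)
  if (!length(keep)) stop("all features are degenerate")
  z <- sweep(sweep(train[, keep, drop = FALSE], 2, ctr[keep]), 2,
             scl[keep], "/")
  if (is.null(gamma)) gamma <- 1 / length(keep)
  set.seed(seed)
  fit <- e1071::svm(z, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma, scale = FALSE)
  new("OneClassModel", fit = fit, center = ctr[keep], scale = scl[keep],
      featureNames = keep, dropped = dropped, nu = nu, gamma = gamma,
      threshold = threshold, seed = as.integer(seed))
}

#' Score candidate feature vectors with a fitted one-class model
#'
#' Vectors are standardized with the training parameters; \code{svm_pass}
#' is \code{score >= threshold}. The vector registry must match the
#' training registry by names (order-insensitive; columns are realigned).
#'
#' @param model a \linkS4class{OneClassModel}.
#' @param vectors numeric matrix with named columns and rownames = ids.
#' @return data.frame: \code{id}, \code{score}, \code{svm_pass}.
#' @export
scoreCandidates <- function(model, vectors) {
  vectors <- as.matrix(vectors)
  have <- colnames(vectors)
  needed <- c(model@featureNames, model@dropped)
  if (is.null(have) || !all(needed %in% have))
    stop("feature registry mismatch: vectors lack ",
         paste(setdiff(needed, have), collapse = ", "))
  z <- sweep(sweep(vectors[, model@featureNames, drop = FALSE], 2,
                   model@center), 2, model@scale, "/")
  dv <- attr(stats::predict(model@fit, z, decision.values = TRUE),
             "decision.values")
  score <- as.numeric(dv)
  data.frame(id = rownames(vectors) %||% seq_len(nrow(vectors)),
             score = score, svm_pass = score >= model@threshold,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine the two selection routes into the final set
#'
#' @param htPass named logical vector: id -> high-throughput criteria pass.
#' @param svmScores data.frame from \code{\link{scoreCandidates}} over the
#'   same ids.
#' @param mode \code{"union"} (default, the relation consistent with the
#'   published set arithmetic), \code{"intersection"}, \code{"ht_only"} or
#'   \code{"svm_only"}.
#' @return data.frame: \code{id}, \code{ht_pass}, \code{svm_pass},
#'   \code{svm_score}, \code{selected}.
#' @export
selectFinal <- function(htPass, svmScores,
                        mode = c("union", "intersection", "ht_only", "svm_only")) {
  mode <- match.arg(mode)
  if (!setequal(names(htPass), svmScores$id))
    stop("id sets differ between criteria results and SVM scores")
  ids <- sort(names(htPass))
  ht <- unname(htPass[ids])
  sv <- svmScores[match(ids, svmScores$id), ]
  selected <- switch(mode,
    union = ht | sv$svm_pass,
    intersection = ht & sv$svm_pass,
    ht_only = ht,
    svm_only = sv$svm_pass)
  data.frame(id = ids, ht_pass = ht, svm_pass = sv$svm_pass,
             svm_score = sv$score, selected = selected,
             stringsAsFactors = FALSE)
}
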