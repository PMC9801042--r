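#' Assign a subgenome label from a chromosome name
#'
#' The default pattern map targets hexaploid wheat naming (1A..7D, with or
#' without a "chr" prefix): the trailing subgenome letter decides. The first
#' matching label wins; anything else is \code{"unplaced"}.
#'
#' @param chrom chromosome name(s).
#' @param patterns named character vector label -> regular expression.
#' @return character vector of labels.
#' @examples
#' assignSubgenome(c("3B", "chr7D", "chrUn"))
#' @export
assignSubgenome <- function(chrom,
                            patterns = c(A = "[0-9]A$", B = "[0-9]B$",
                                         D = "[0-9]D$")) {
  vapply(as.character(chrom), function(ch) {
    for (lab in names(patterns))
      if (grepl(patterns[[lab]], ch)) return(lab)
    "unplaced"
  }, "", USE.NAMES = FALSE)
}

#' Group homologous miRNAs by mature-sequence similarity
#'
#' Single-linkage clustering of mature sequences under Levenshtein edit
#' distance at most \code{maxDistance}. The partition is independent of
#' input order; group ids are assigned from the lexicographically smallest
#' member id.
#'
#' @param ids member identifiers.
#' @param sequences mature sequences, parallel to \code{ids}.
#' @param labels subgenome labels, parallel to \code{ids}.
#' @param maxDistance edit-distance threshold (default 2).
#' @return data.frame: \code{group}, \code{id}, \code{sequence},
#'   \code{label}.
#' @export
groupHomologs <- function(ids, sequences, labels, maxDistance = 2L) {
  n <- length(ids)
  stopifnot(n >= 1, length(sequences) == n, length(labels) == n)
  ord <- order(as.character(ids))
  ids <- as.character(ids)[ord]
  sequences <- as.character(sequences)[ord]
  labels <- as.character(labels)[ord]
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # cheap length pre-filter: edit distance >= length difference
  lens <- nchar(sequences)
  for (i in seq_len(n - 1L)) {
    js <- which(seq_len(n) > i & abs(lens - lens[i]) <= maxDistance)
    if (!length(js)) next
    d <- utils::adist(sequences[i], sequences[js])[1, ]
    for (j in js[d <= maxDistance]) {
      a <- findRoot(i); b <- findRoot(j)
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), findRoot, 1L)
  groupId <- ids[root] # lexicographically smallest member (ids are sorted)
  out <- data.frame(group = groupId, id = ids, sequence = sequences,
                    label = labels, stringsAsFactors = FALSE)
  out[order(out$group, out$id), , drop = FALSE]
}

#' Classify the A:B:D configuration of one homolog group
#'
#' Per-subgenome member counts give \code{"a:b:d"} when every count is at
#' most 1 and no member is unplaced; otherwise \code{"others"}. A
#' \code{"1:1:1"} group is a triad (one copy per subgenome).
#'
#' @param labels member subgenome labels.
#' @param subgenomes ordered label set (default A, B, D).
#' @return list: \code{configuration}, \code{triad}.
#' @export
classifyConfiguration <- function(labels, subgenomes = c("A", "B", "D")) {
  counts <- table(factor(labels, levels = subgenomes))
  unplaced <- sum(!labels %in% subgenomes)
  if (unplaced > 0 || any(counts > 1))
    return(list(configuration = "others", triad = FALSE))
  cfg <- paste(as.integer(counts), collapse = ":")
  list(configuration = cfg, triad = all(counts == 1L))
}

#' Configuration table of a homolog grouping
#'
#' @param groups \code{\link{groupHomologs}} output.
#' @param subgenomes ordered label set.
#' @return data.frame: \code{group}, \code{configuration}, \code{triad},
#'   \code{n_members}.
#' @export
configurationTable <- function(groups, subgenomes = c("A", "B", "D")) {
  sp <- split(groups$label, groups$group)
  rows <- lapply(names(sp), function(g) {
    cc <- classifyConfiguration(sp[[g]], subgenomes)
    data.frame(group = g, configuration = cc$configuration,
               triad = cc$triad, n_members = length(sp[[g]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$group), , drop = FALSE]
}

#' Fraction of homolog groups that are triads
#'
#' A triad has exactly one member per subgenome (configuration 1:1:1).
#'
#' @param configTable \code{\link{configurationTable}} output.
#' @return ratio of triad groups to all groups.
#' @export
triadFraction <- function(configTable) {
  if (!nrow(configTable)) stop("no homolog groups")
  mean(configTable$triad)
}

#' Chi-squared test for subgenome bias
#'
#' Goodness-of-fit of the per-subgenome precursor counts against expected
#' proportions (equal by default; configurable, e.g. subgenome sizes), with
#' no continuity correction.
#'
#' @param counts named counts per subgenome.
#' @param p expected proportions (default equal).
#' @return list: \code{statistic}, \code{df}, \code{p_value}.
#' @examples
#' subgenomeBiasTest(c(A = 611, B = 744, D = 571))
#' @export
subgenomeBiasTest <- function(counts, p = rep(1 / length(counts),
                                              length(counts))) {
  stopifnot(length(counts) >= 2)
  if (sum(counts) <= 0) stop("zero total count")
  ct <- stats::chisq.test(counts, p = p)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Ternary expression coordinates of a triad
#'
#' Componentwise division of (A, B, D) expression by their sum; the result
#' sums to 1 and places the triad in a ternary plot.
#'
#' @param a,b,d non-negative expression values (e.g. TPM).
#' @return list: \code{a}, \code{b}, \code{d}, \code{defined} (FALSE when
#'   the sum is zero, in which case the coordinates are NA).
#' @export
ternaryCoordinates <- function(a, b, d) {
  s <- a + b + d
  if (s <= 0)
    return(list(a = NA_real_, b = NA_real_, d = NA_real_, defined = FALSE))
  list(a = a / s, b = b / s, d = d / s, defined = TRUE)
}
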