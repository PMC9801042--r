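mkBundle <- function(seed = 55, precision = 1, nSamples = 3L) {
  cfg <- fixtureConfig(seed = seed, nTrue = 1, nDecoys = 0, depth = 100L,
                       precision = precision, nSamples = nSamples,
                       isoformRates = c(add5 = 0, sub5 = 0, add3 = 0,
                                        sub3 = 0))
  b <- makeFixture(cfg)
  ps <- b@precursors
  id <- names(ps)[1]
  st <- foldHairpin(ps@sequences[[id]])
  mt <- matures(ps)
  m <- mt[mt$arm == "5p", ]
  d <- extractDuplex(st, m$offset, m$length)
  stk <- buildReadStack(b@alignments, ps, id)
  list(seq = ps@sequences[[id]], st = st, d = d, stk = stk, mt = mt)
}

test_that("a planted perfect candidate passes every default rule", {
  bu <- mkBundle()
  res <- applyCriteria(bu$seq, bu$st, bu$d, bu$stk, bu$mt)
  expect_true(res$pass)
  expect_true(all(res$rules))
  expect_equal(res$pass, all(res$rules)) # pass is the conjunction
})

test_that("single-rule perturbations fail only their own rule", {
  bu <- mkBundle()
  # degrade precision: half the reads at an off-site position (offset 28
  # is far from both the planted mature, near the 5' end, and the star)
  half <- new("ReadStack", precursorId = bu$stk@precursorId,
              entries = data.frame(offset = c(bu$mt$offset[1], 28L),
                                   length = c(bu$mt$length[1], 21L),
                                   count = c(5, 5),
                                   sample = c("s01", "s01")))
  resHalf <- applyCriteria(bu$seq, bu$st, bu$d, half, bu$mt)
  expect_false(resHalf$rules[["precision"]])
  expect_true(resHalf$rules[["mature_len"]])
  expect_true(resHalf$rules[["mismatches"]])
  # a 25-nt mature fails the length rule only
  longMat <- bu$mt
  longMat$length[1] <- 25L
  longMat$sequence[1] <- substr(bu$seq, longMat$offset[1],
                                longMat$offset[1] + 24L)
  resLong <- applyCriteria(bu$seq, bu$st, bu$d, bu$stk, longMat)
  expect_false(resLong$rules[["mature_len"]])
  expect_true(resLong$rules[["precursor_len"]])
})

test_that("evidence-free candidates fail evidence rules without erroring", {
  bu <- mkBundle()
  res <- applyCriteria(bu$seq, bu$st, bu$d, stack = NULL,
                       matureTable = bu$mt)
  expect_false(res$rules[["precision"]])
  expect_false(res$rules[["libraries"]])
  expect_false(res$rules[["star_or_replication"]])
  expect_true(res$rules[["mature_len"]])
  expect_false(res$pass)
})

test_that("relaxing any single threshold never shrinks the pass set", {
  cfg <- fixtureConfig(seed = 66, nTrue = 12, nDecoys = 12, depth = 40L,
                       precision = 0.8, nSamples = 2L)
  b <- makeFixture(cfg)
  an <- analyzeCandidates(b@precursors, b@alignments)
  base <- an$htPass
  relaxed <- list(
    criteriaThresholds(matureLenMin = 18L, matureLenMax = 26L),
    criteriaThresholds(maxPrecursorLen = 500L),
    criteriaThresholds(maxMismatches = 10L),
    criteriaThresholds(maxAsymBulge = 8L),
    criteriaThresholds(overhangTol = 3L),
    criteriaThresholds(minPrecision = 0.5),
    criteriaThresholds(minLibraries = 1L),
    criteriaThresholds(requireStarOrReplication = FALSE))
  for (t in relaxed) {
    anR <- analyzeCandidates(b@precursors, b@alignments, thresholds = t)
    expect_true(all(anR$htPass[base])) # every passer still passes
  }
  # purity: re-evaluation is identical
  an2 <- analyzeCandidates(b@precursors, b@alignments)
  expect_identical(an$htPass, an2$htPass)
  expect_identical(an$criteria, an2$criteria)
})

test_that("the one-class nu-property bounds the training outlier fraction", {
  set.seed(314)
  train <- matrix(rnorm(2000), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2")))
  model <- fitOneClass(train, nu = 0.05, seed = 99L)
  sc <- scoreCandidates(model, train)
  frac <- mean(!sc$svm_pass)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
  # the training centroid is an inlier; a far point is an outlier
  probe <- rbind(centroid = colMeans(train), far = c(100, 100))
  colnames(probe) <- c("f1", "f2")
  sp <- scoreCandidates(model, probe)
  expect_true(sp$svm_pass[sp$id == "centroid"])
  expect_false(sp$svm_pass[sp$id == "far"])
})

test_that("a shifted cloud rejects the origin and registries must match", {
  set.seed(11)
  train <- matrix(rnorm(400, mean = 10), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2")))
  model <- fitOneClass(train, nu = 0.05)
  zero <- matrix(0, 1, 2, dimnames = list("z", c("f1", "f2")))
  expect_false(scoreCandidates(model, zero)$svm_pass)
  wrong <- matrix(0, 1, 2, dimnames = list("z", c("g1", "g2")))
  expect_error(scoreCandidates(model, wrong), "registry mismatch")
})

test_that("zero-variance features are dropped with a warning and recorded", {
  set.seed(12)
  train <- cbind(matrix(rnorm(200), ncol = 2), 5)
  colnames(train) <- c("a", "b", "flat")
  expect_warning(model <- fitOneClass(train), "flat")
  expect_equal(model@dropped, "flat")
  # scoring still accepts vectors that carry the dropped column
  sc <- scoreCandidates(model, train)
  expect_equal(nrow(sc), 100L)
})

test_that("selection set algebra reproduces the published union arithmetic", {
  ids <- sprintf("c%04d", 1:886)
  set1 <- ids[1:588]                      # high-throughput criteria
  set2 <- ids[c(1:406, 589:886)]          # SVM: 406 shared + 298 unique
  expect_equal(length(set2), 704L)
  ht <- stats::setNames(ids %in% set1, ids)
  svm <- data.frame(id = ids, score = ifelse(ids %in% set2, 1, -1),
                    svm_pass = ids %in% set2)
  un <- selectFinal(ht, svm, mode = "union")
  expect_equal(sum(un$selected), 886L)
  expect_equal(sum(selectFinal(ht, svm, "intersection")$selected), 406L)
  expect_equal(sum(selectFinal(ht, svm, "ht_only")$selected), 588L)
  expect_equal(sum(selectFinal(ht, svm, "svm_only")$selected), 704L)
  expect_error(selectFinal(ht[-1], svm), "id sets differ")
})

test_that("ht criteria separate planted hairpins from shuffled decoys", {
  cfg <- fixtureConfig(seed = 123, nTrue = 50, nDecoys = 50, depth = 30L,
                       precision = 0.95, nSamples = 3L)
  b <- makeFixture(cfg)
  an <- analyzeCandidates(b@precursors, b@alignments)
  truth <- b@truth
  ht <- an$htPass[truth$id]
  sens <- mean(ht[truth$true_locus])
  fpr <- mean(ht[!truth$true_locus])
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.1)
})

test_that("a one-class model on true hairpin features rejects most decoys", {
  cfg <- fixtureConfig(seed = 200, nTrue = 200, nDecoys = 200, depth = 0L,
                       nSamples = 1L)
  b <- makeFixture(cfg)
  an <- analyzeCandidates(b@precursors, alignments = NULL)
  truth <- b@truth
  trueIds <- truth$id[truth$true_locus]
  decoyIds <- truth$id[!truth$true_locus]
  model <- suppressWarnings(
    fitOneClass(an$features[trueIds, , drop = FALSE], nu = 0.05, seed = 42L))
  sc <- scoreCandidates(model, an$features[decoyIds, , drop = FALSE])
  expect_gte(mean(!sc$svm_pass), 0.7)
})
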