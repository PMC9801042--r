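# Independent brute-force folding oracle: recursively enumerates every
# nested pairing (position-by-position, no memoization) and returns the
# minimum total pair energy. Only usable at tiny n.
bruteForceFoldEnergy <- function(seq, params = foldParams()) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  w <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "")
    switch(key, "CG" = params$wGC, "AU" = params$wAU, "GU" = params$wGU, NA)
  }
  rec <- function(i, j) {
    if (i >= j) return(0)
    best <- rec(i + 1, j)
    for (k in seq(i + params$minLoop + 1, j)) {
      if (k > j) break
      pw <- w(ch[i], ch[k])
      if (is.na(pw)) next
      cand <- pw + rec(i + 1, k - 1) + (if (k < j) rec(k + 1, j) else 0)
      if (cand < best) best <- cand
    }
    best
  }
  if (length(ch) < 2) 0 else rec(1, length(ch))
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

# perfect-hairpin fixture: stem + loop + revcomp(stem)
perfectHairpin <- function(stem, loop = "AAAAAAAA") {
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(stem, "")[[1]]),
                                     collapse = ""))
  paste0(stem, loop, rc)
}

# tiny two-locus annotation + genome for parser tests
tinyAnnotation <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  genome <- c(chr1 = paste(rep("ACGTTGCA", 50), collapse = ""),
              chr2 = paste(rep("GGCATTCC", 50), collapse = ""))
  gff <- file.path(dir, "ann.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tmiRNA_primary_transcript\t101\t180\t.\t+\t.\tID=mirA;Name=mirA",
    "chr1\tsrc\tmiRNA\t111\t131\t.\t+\t.\tID=mirA-5p;Name=mirA-5p;Derives_from=mirA",
    "chr1\tsrc\tmiRNA\t151\t171\t.\t+\t.\tID=mirA-3p;Name=mirA-3p;Derives_from=mirA",
    "chr2\tsrc\tmiRNA_primary_transcript\t201\t280\t.\t-\t.\tID=mirB;Name=mirB",
    "chr2\tsrc\tmiRNA\t221\t241\t.\t-\t.\tID=mirB-3p;Name=mirB-3p;Derives_from=mirB"),
    gff)
  list(gff = gff, genome = genome)
}
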