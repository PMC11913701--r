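test_that("globalAlign reproduces simple closed-form scores", {
  # three A/A matches under BLOSUM62 (4 each), no gaps
  al <- globalAlign("AAA", "AAA")
  expect_equal(al$score, 12)
  expect_equal(al$a, "AAA")
  expect_equal(al$b, "AAA")
  # any sequence against itself aligns without gaps
  set.seed(2)
  for (i in 1:10) {
    s <- random_aa(sample(3:40, 1))
    al <- globalAlign(s, s)
    expect_equal(al$a, s)
    expect_equal(al$b, s)
  }
})

test_that("short alignments match the exhaustive-enumeration optimum", {
  set.seed(4)
  for (i in 1:60) {
    a <- random_aa(sample(1:5, 1))
    b <- random_aa(sample(1:5, 1))
    expect_equal(globalAlign(a, b)$score, brute_force_score(a, b),
                 info = paste(a, b))
  }
})

test_that("scores agree with an independent aligner on longer pairs", {
  # Biostrings charges open + L*ext per gap, ours open + (L-1)*ext, so
  # gapOpening = 9, gapExtension = 1 makes the two conventions coincide
  set.seed(8)
  for (i in 1:20) {
    a <- random_aa(sample(10:60, 1))
    b <- random_aa(sample(10:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = blosum62,
      gapOpening = 9, gapExtension = 1, type = "global")
    expect_equal(globalAlign(a, b)$score, Biostrings::score(ref))
  }
})

test_that("alignment score is optimal, symmetric, and rejects bad residues", {
  a <- "MKVLWAALLV"; b <- "MKVWALLV"
  al <- globalAlign(a, b)
  # never below any specific hand-written alignment
  expect_gte(al$score, score_alignment("MKVLWAALLV", "MKV-WA-LLV"))
  expect_gte(al$score, score_alignment("MKVLWAALLV", "MKVWALLV--"))
  expect_equal(al$score, score_alignment(al$a, al$b))
  expect_equal(globalAlign(a, b)$score, globalAlign(b, a)$score)
  expect_error(globalAlign("MK1", "MK"), "residue.*1")
  expect_error(globalAlign("", "MK"), "non-empty")
})

test_that("progressiveMSA handles identical, shifted and degenerate inputs", {
  m <- progressiveMSA(c(x = "MKVLW", y = "MKVLW", z = "MKVLW"))
  expect_false(any(grepl("-", as.character(m), fixed = TRUE)))
  # one insertion is optimal for the shorter of a nested pair
  m <- progressiveMSA(c(a = "MKV", b = "MKKV"))
  rows <- as.character(m)
  expect_equal(unique(nchar(rows)), 4L)
  expect_equal(sum(strsplit(rows[["a"]], "")[[1]] == "-"), 1)
  expect_false(grepl("-", rows[["b"]]))
  expect_warning(m1 <- progressiveMSA(c(solo = "MKV")), "single sequence")
  expect_equal(unname(as.character(m1)), "MKV")
})

test_that("de-gapping alignment rows reproduces the input sequences", {
  set.seed(9)
  seqs <- stats::setNames(vapply(sample(20:60, 6, replace = TRUE),
                                 random_aa, ""), paste0("s", 1:6))
  m <- progressiveMSA(seqs)
  degapped <- gsub("-", "", as.character(m), fixed = TRUE)
  expect_equal(degapped, seqs)
  expect_equal(names(m), names(seqs))   # row order = input order
})

test_that("percent identity follows the co-residue definition", {
  msa <- new("ProteinAlignment",
             Biostrings::AAStringSet(c(r1 = "MK-V", r2 = "MKAV")))
  p <- percentIdentityMatrix(msa)
  expect_equal(pimValues(p)["r1", "r2"], 100)   # 3 of 3 co-residue columns
  msa <- new("ProteinAlignment",
             Biostrings::AAStringSet(c(r1 = "AAAA", r2 = "TTTT")))
  expect_equal(pimValues(percentIdentityMatrix(msa))["r1", "r2"], 0)
  msa <- new("ProteinAlignment",
             Biostrings::AAStringSet(c(r1 = "MKV-", r2 = "MKVA")))
  expect_equal(pimValues(percentIdentityMatrix(msa,
                                               "shorter"))["r1", "r2"], 100)
  expect_equal(pimValues(percentIdentityMatrix(msa,
                                               "alignment"))["r1", "r2"], 75)
})

test_that("PIM has a 100 diagonal, symmetry and permutation equivariance", {
  set.seed(10)
  seqs <- stats::setNames(vapply(rep(30, 5), random_aa, ""),
                          paste0("s", 1:5))
  m <- progressiveMSA(seqs)
  p <- pimValues(percentIdentityMatrix(m))
  expect_equal(unname(diag(p)), rep(100, 5))
  expect_equal(p, t(p))
  # permuting the alignment rows permutes the matrix identically
  perm <- c(3, 1, 5, 2, 4)
  m2 <- new("ProteinAlignment",
            Biostrings::AAStringSet(as.character(m)[perm]))
  p2 <- pimValues(percentIdentityMatrix(m2))
  expect_equal(p2[names(seqs), names(seqs)], p, tolerance = 1e-9)
})

test_that("disjoint residue pairs score zero with a warning", {
  msa <- new("ProteinAlignment",
             Biostrings::AAStringSet(c(r1 = "MK--", r2 = "--VA")))
  expect_warning(p <- percentIdentityMatrix(msa), "no co-residue")
  expect_equal(pimValues(p)["r1", "r2"], 0)
})

test_that("scoringScheme validates its invariants", {
  expect_error(scoringScheme(gapOpen = 1, gapExtend = 2), "gapExtend")
  asym <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("A", "C"), c("A", "C")))
  expect_error(scoringScheme(asym), "symmetric")
})
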