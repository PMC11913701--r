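test_that("readProteins parses records and pipe-delimited headers", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">jgi|ChlNC64A|41714|g1", "MKV"), f)
  ps <- readProteins(f)
  expect_s4_class(ps, "ProteinSet")
  expect_length(ps, 1)
  info <- labelInfo(ps)
  expect_equal(info$source_tag, "jgi")
  expect_equal(info$species_code, "ChlNC64A")
  expect_equal(info$protein_id, "41714")
  expect_equal(info$group_id, "g1")
  expect_equal(as.character(ps), c(`jgi|ChlNC64A|41714|g1` = "MKV"))
  expect_equal(info$origin_file, basename(f))
})

test_that("multi-line sequences are concatenated and order preserved", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "MKVA", "WLLY", "GH",
               ">r2", "AAA", "CCC", "DDD"), f)
  ps <- readProteins(f)
  expect_equal(unname(as.character(ps)), c("MKVAWLLYGH", "AAACCCDDD"))
  expect_equal(labelInfo(ps)$raw_header, c("r1", "r2"))
})

test_that("degenerate FASTA inputs raise the documented errors", {
  empty <- tempfile(); file.create(empty)
  expect_error(readProteins(empty), "no records")
  noheader <- tempfile()
  writeLines(c("MKV", ">r1", "MKV"), noheader)
  expect_error(readProteins(noheader), "before the first header")
  emptyseq <- tempfile()
  writeLines(c(">r1", "MKV", ">r2", ">r3", "AA"), emptyseq)
  expect_error(readProteins(emptyseq), "empty sequence")
})

test_that("sequences are uppercased and trailing stops stripped", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "mkvx*", ">r2", "ABZU"), f)
  ps <- readProteins(f)
  expect_equal(unname(as.character(ps)), c("MKVX", "ABZU"))
})

test_that("duplicate headers warn and get disambiguated internal keys", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">dup", "MKV", ">dup", "AAA"), f)
  expect_warning(ps <- readProteins(f), "duplicate headers")
  expect_equal(anyDuplicated(names(ps)), 0L)
  expect_equal(labelInfo(ps)$raw_header, c("dup", "dup"))
})

test_that("parseLabel is positional, lenient and order-configurable", {
  p <- parseLabel("jgi|ChloA99|x|y")
  expect_equal(p$species_code, "ChloA99")
  p <- parseLabel("plainheader")
  expect_true(all(is.na(p[, c("source_tag", "species_code",
                              "protein_id", "group_id")])))
  expect_equal(p$raw_header, "plainheader")
  # default order: species | protein | group
  p <- parseLabel("jgi|Chloso1602|41714|8")
  expect_equal(p$protein_id, "41714")
  expect_equal(p$group_id, "8")
  # alternative order: species | group | protein
  p <- parseLabel("jgi|Chloso1602|8|41714",
                  fieldOrder = "species_group_protein")
  expect_equal(p$protein_id, "41714")
  expect_equal(p$group_id, "8")
  # >= 2 pipes populate species and protein (default order)
  p <- parseLabel("jgi|sp|123")
  expect_false(is.na(p$species_code))
  expect_false(is.na(p$protein_id))
  # whitespace around fields is stripped
  p <- parseLabel("jgi | sp1 | 99")
  expect_equal(p$species_code, "sp1")
})

test_that("renderLabel inverts parseLabel on convention headers", {
  set.seed(7)
  for (i in 1:50) {
    nfield <- sample(2:4, 1)
    hdr <- paste(replicate(nfield,
                           paste(sample(c(LETTERS, letters, 0:9),
                                        sample(1:8, 1), replace = TRUE),
                                 collapse = "")),
                 collapse = "|")
    for (ord in fieldOrderPresets())
      expect_equal(renderLabel(parseLabel(hdr, ord), ord), hdr)
  }
})

test_that("write/read round-trip preserves headers and sequences exactly", {
  f <- tempfile(fileext = ".fasta")
  set.seed(11)
  n <- 20
  seqs <- vapply(sample(5:200, n, replace = TRUE), random_aa, "")
  headers <- paste0("jgi|sp", seq_len(n), "|", seq_len(n) * 7, "|", seq_len(n))
  ps <- ProteinSet(seqs, headers = headers)
  writeProteins(ps, f, wrap = 60)
  back <- readProteins(f)
  expect_equal(unname(as.character(back)), unname(seqs))
  expect_equal(labelInfo(back)$raw_header, headers)
})

test_that("wrap width controls sequence line count", {
  f <- tempfile(fileext = ".fasta")
  ps <- ProteinSet(random_aa(130), headers = "r1")
  writeProteins(ps, f, wrap = 60)
  lines <- readLines(f)
  expect_equal(sum(!startsWith(lines, ">")), 3)  # ceil(130/60)
  expect_error(writeProteins(ps[0], f), "empty")
})

test_that("directory totals equal the sum of per-file counts", {
  d <- tempfile(); dir.create(d)
  counts <- c(3, 5, 2)
  for (i in seq_along(counts)) {
    ps <- ProteinSet(replicate(counts[i], random_aa(10)),
                     headers = paste0("jgi|sp", i, "|", seq_len(counts[i])))
    writeProteins(ps, file.path(d, paste0("sp", i, ".fasta")))
  }
  all_ps <- readProteomeDir(d)
  expect_length(all_ps, sum(counts))
  expect_equal(unname(table(labelInfo(all_ps)$origin_file)),
               unname(table(rep(seq_along(counts), counts))))
  expect_equal(sort(unique(labelInfo(all_ps)$file_species)),
               c("sp1", "sp2", "sp3"))
})

test_that("ProteinSet validity rejects gapped or empty sequences", {
  expect_error(ProteinSet("MK-V", headers = "h"), "gap|invalid")
  expect_error(suppressWarnings(ProteinSet("", headers = "h")))
})
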