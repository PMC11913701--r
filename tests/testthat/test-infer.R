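make_proteome_set <- function(tbl) {
  # tbl: data.frame(species, id, seq)
  ProteinSet(tbl$seq,
             headers = paste("jgi", tbl$species, tbl$id, sep = "|"))
}

test_that("identical proteins across two species are mutual best hits", {
  s <- random_aa(40)
  ps <- make_proteome_set(data.frame(species = c("spA", "spB"),
                                     id = c("p1", "p1"), seq = s))
  hits <- allVsAll(ps)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$norm_score, c(1, 1))
})

test_that("the best hit is the higher-scoring target, ties by protein id", {
  set.seed(31)
  fam <- random_aa(60)
  other <- random_aa(60)
  ps <- make_proteome_set(data.frame(
    species = c("spA", "spB", "spB"),
    id = c("p1", "p1", "p2"),
    seq = c(fam, fam, other)))
  hits <- allVsAll(ps)
  a_to_b <- hits[hits$query_species == "spA", ]
  expect_equal(a_to_b$target_id, "p1")
})

test_that("inference preconditions are enforced", {
  ps <- make_proteome_set(data.frame(species = "spA",
                                     id = c("p1", "p2"),
                                     seq = c(random_aa(10), random_aa(10))))
  expect_error(allVsAll(ps), "at least 2 species")
  dup <- suppressWarnings(
    make_proteome_set(data.frame(species = c("spA", "spA", "spB"),
                                 id = c("p1", "p1", "p2"),
                                 seq = replicate(3, random_aa(10)))))
  expect_error(allVsAll(dup), "duplicate")
})

test_that("one conserved family across three species forms one group", {
  set.seed(32)
  fam <- random_aa(80)
  mutate1 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(seq_along(ch), 1)
    ch[i] <- sample(setdiff(AA, ch[i]), 1)
    paste(ch, collapse = "")
  }
  ps <- make_proteome_set(data.frame(
    species = c("spA", "spB", "spC"),
    id = c("p1", "p2", "p3"),
    seq = c(fam, mutate1(fam), mutate1(fam))))
  tab <- clusterOrthologs(allVsAll(ps))
  expect_length(groupIds(tab), 1)
  expect_equal(nrow(groupMembers(tab)), 3)
})

test_that("unrelated families form disjoint groups (partition)", {
  set.seed(33)
  f1 <- random_aa(80); f2 <- random_aa(80)
  ps <- make_proteome_set(data.frame(
    species = rep(c("spA", "spB"), each = 2),
    id = c("a1", "a2", "b1", "b2"),
    seq = c(f1, f2, f1, f2)))
  tab <- clusterOrthologs(allVsAll(ps))
  expect_length(groupIds(tab), 2)
  m <- groupMembers(tab)
  expect_equal(anyDuplicated(paste(m$species_code, m$protein_id)), 0L)
})

test_that("minScore = 1 filters out all diverged pairs", {
  set.seed(34)
  f <- random_aa(50)
  ch <- strsplit(f, "")[[1]]
  ch[1:10] <- vapply(ch[1:10], function(r) sample(setdiff(AA, r), 1), "")
  ps <- make_proteome_set(data.frame(species = c("spA", "spB"),
                                     id = c("p1", "p2"),
                                     seq = c(f, paste(ch, collapse = ""))))
  hits <- allVsAll(ps)
  tab <- clusterOrthologs(hits, minScore = 1)
  expect_equal(nrow(groupMembers(tab)), 0)
})

test_that("raising minScore never grows any group", {
  set.seed(35)
  sim <- simulateProteomes(simulationSpec(nFamilies = 2, familyLength = 50,
                                          seed = 35))
  hits <- allVsAll(sim$records)
  sizes <- function(tab) {
    m <- groupMembers(tab)
    if (!nrow(m)) return(integer(0))
    sort(table(m$group_id), decreasing = TRUE)
  }
  prev <- NULL
  for (ms in c(0.05, 0.5, 0.8, 0.95)) {
    cur <- sizes(clusterOrthologs(hits, minScore = ms))
    if (!is.null(prev)) {
      expect_lte(sum(cur), sum(prev))
      if (length(cur)) expect_lte(max(cur), max(prev))
    }
    prev <- cur
  }
})

test_that("inference recovers the true families on low-divergence fixtures", {
  sim <- simulateProteomes(simulationSpec(nFamilies = 3, familyLength = 100,
                                          indelRate = 0.005, seed = 42))
  tab <- inferGroups(sim$dir)
  truth <- sim$truth
  key <- function(t) {
    m <- groupMembers(t)
    unname(lapply(split(paste(m$species_code, m$protein_id), m$group_id),
                  sort))
  }
  got <- key(tab); want <- key(truth)
  expect_equal(length(got), length(want))
  expect_setequal(vapply(got, paste, "", collapse = ";"),
                  vapply(want, paste, "", collapse = ";"))
})
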