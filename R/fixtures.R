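#' @include AllClasses.R seqio.R groups.R phylo.R
NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default 8-species fixture tree
#'
#' A fixed 8-leaf species tree with low per-branch divergence (expected
#' substitutions per site between 0.02 and 0.08), the regime in which
#' single-copy families stay well separated and recovery of the generating
#' topology is expected.
#'
#' @return a `phylo` tree with tip labels `sp1..sp8`.
#' @export
defaultSpeciesTree <- function() {
  fromNewick(paste0(
    "(((sp1:0.02,sp2:0.03):0.03,(sp3:0.04,sp4:0.02):0.04):0.03,",
    "((sp5:0.05,sp6:0.03):0.05,(sp7:0.06,sp8:0.04):0.03):0.04);"))
}

#' Specify a proteome simulation
#'
#' Protein families are evolved down a known species tree: every branch
#' applies indels first (per-site deletion/insertion, probability
#' `indelRate` split evenly between the two), then substitutions (each
#' site replaced with probability equal to the branch length, drawing
#' uniformly from the 19 other residues, so the expected fraction of sites
#' changed on a branch equals its length).  One protein per family per
#' species (single copy), so the true group table and family trees are
#' known exactly.  Identical specs produce byte-identical output.
#'
#' @param speciesTree a `phylo` tree (branch lengths = expected
#'   substitutions per site); default [defaultSpeciesTree()].
#' @param nFamilies number of protein families.
#' @param familyLength root sequence length per family (residues).
#' @param indelRate per-site indel probability per branch.
#' @param seed integer RNG seed.
#' @param sourceTag header source field (default `"jgi"`).
#' @return a `SimulationSpec` list.
#' @export
simulationSpec <- function(speciesTree = defaultSpeciesTree(),
                           nFamilies = 3, familyLength = 120,
                           indelRate = 0.01, seed = 1,
                           sourceTag = "jgi") {
  if (nFamilies < 1 || familyLength < 1)
    stop("nFamilies and familyLength must be positive", call. = FALSE)
  if (indelRate < 0 || indelRate > 1)
    stop("indelRate must lie in [0, 1]", call. = FALSE)
  if (any(speciesTree$edge.length < 0) || any(speciesTree$edge.length > 1))
    stop("branch lengths must lie in [0, 1] (substitution probabilities)",
         call. = FALSE)
  structure(list(speciesTree = speciesTree, nFamilies = nFamilies,
                 familyLength = familyLength, indelRate = indelRate,
                 seed = as.integer(seed), sourceTag = sourceTag),
            class = "SimulationSpec")
}

.evolve_branch <- function(seq, sub_p, indel_p) {
  n <- length(seq)
  if (indel_p > 0 && n > 0) {
    del <- stats::runif(n) < indel_p / 2
    ins <- stats::runif(n) < indel_p / 2
    out <- vector("list", n)
    for (i in seq_len(n)) {
      keep <- if (del[i]) character(0) else seq[i]
      if (ins[i]) keep <- c(keep, sample(AA20, 1))
      out[[i]] <- keep
    }
    seq <- unlist(out)
    if (!length(seq)) seq <- sample(AA20, 1)   # never extinguish a protein
  }
  n <- length(seq)
  hit <- stats::runif(n) < sub_p
  if (any(hit)) {
    seq[hit] <- vapply(seq[hit], function(r)
      sample(setdiff(AA20, r), 1), "", USE.NAMES = FALSE)
  }
  seq
}

#' Simulate proteomes down a species tree
#'
#' Writes one FASTA file per leaf species (file stem = species code,
#' headers `source|species|protein|group` in the default field order) and
#' returns the ground truth: the generating group table, the per-family
#' species tree, and all node sequences (useful for checking per-branch
#' divergence).
#'
#' @param spec a [simulationSpec()].
#' @param dir output directory for the FASTA files (created if needed).
#' @return list with elements `dir`, `files`, `truth`
#'   ([OrthologGroupTable-class]), `familyTrees` (list of `phylo`),
#'   `records` ([ProteinSet] of the leaf proteins) and `nodeSequences`
#'   (per family, a list of residue vectors for every tree node).
#' @export
simulateProteomes <- function(spec, dir = tempfile("proteomes")) {
  stopifnot(inherits(spec, "SimulationSpec"))
  tree <- spec$speciesTree
  ntips <- length(tree$tip.label)
  nnode <- ntips + tree$Nnode
  root <- ntips + 1L
  if (is.null(attr(tree, "order")) || attr(tree, "order") != "cladewise")
    tree <- stats::reorder(tree)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  node_seqs <- .with_seed(spec$seed, {
    lapply(seq_len(spec$nFamilies), function(fam) {
      seqs <- vector("list", nnode)
      seqs[[root]] <- sample(AA20, spec$familyLength, replace = TRUE)
      # cladewise edge order guarantees parents are visited first
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        seqs[[ch]] <- .evolve_branch(seqs[[p]], tree$edge.length[e],
                                     spec$indelRate)
      }
      seqs
    })
  })

  rows <- list()
  files <- character(0)
  for (ti in seq_len(ntips)) {
    sp <- tree$tip.label[ti]
    headers <- character(0); seqs <- character(0)
    for (fam in seq_len(spec$nFamilies)) {
      pid <- sprintf("%d", 1000L * fam + ti)
      headers <- c(headers, paste(spec$sourceTag, sp, pid, fam, sep = "|"))
      seqs <- c(seqs, paste(node_seqs[[fam]][[ti]], collapse = ""))
      rows[[length(rows) + 1]] <- data.frame(
        group_id = as.character(fam), species_code = sp, protein_id = pid,
        member_score = NA_real_, stringsAsFactors = FALSE)
    }
    path <- file.path(dir, paste0(sp, ".fasta"))
    ps <- ProteinSet(seqs, headers = headers,
                     origin_file = paste0(sp, ".fasta"))
    writeProteins(ps, path)
    files <- c(files, path)
  }

  truth <- OrthologGroupTable(do.call(rbind, rows),
                              speciesRoster = tree$tip.label)
  records <- readProteomeDir(dir)
  list(dir = dir, files = files, truth = truth,
       familyTrees = rep(list(tree), spec$nFamilies),
       records = records, nodeSequences = node_seqs)
}
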