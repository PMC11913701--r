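# Independent oracles and small random-instance generators used across the
# suite.  Nothing here calls the implementation paths it is used to check.

AA <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")

random_aa <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive-enumeration optimum of global affine alignment: recursively
# enumerates every monotone alignment path, scoring gaps as
# open + (L-1)*extend (terminal gaps included).  Exponential - only for
# sequences of length <= ~6.
brute_force_score <- function(a, b, mat = blosum62, open = 10, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  # state: 0 = last column was a residue pair, 1 = gap in b, 2 = gap in a
  rec <- function(i, j, state, score) {
    if (i == n && j == m) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, 0L, score + mat[ca[i + 1], cb[j + 1]])
    if (i < n)
      rec(i + 1, j, 1L, score - if (state == 1L) ext else open)
    if (j < m)
      rec(i, j + 1, 2L, score - if (state == 2L) ext else open)
  }
  rec(0L, 0L, -1L, 0)
  best
}

# Score of one specific hand-written gapped alignment under the same rules.
score_alignment <- function(ga, gb, mat = blosum62, open = 10, ext = 1) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  s <- 0; state <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] != "-" && cb[k] != "-") {
      s <- s + mat[ca[k], cb[k]]; state <- 0L
    } else if (cb[k] == "-") {
      s <- s - if (state == 1L) ext else open; state <- 1L
    } else {
      s <- s - if (state == 2L) ext else open; state <- 2L
    }
  }
  s
}

# Random tree with positive branch lengths; its cophenetic matrix is
# additive by construction, and the tree itself is the recovery oracle.
random_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, d = stats::cophenetic(tr))
}

# Root-to-leaf path lengths of a rooted phylo.
root_depths <- function(phy) {
  d <- ape::node.depth.edgelength(phy)
  stats::setNames(d[seq_along(phy$tip.label)], phy$tip.label)
}

random_group_table <- function(n_groups = 3, n_species = 4) {
  species <- paste0("sp", seq_len(n_species))
  rows <- list()
  pid <- 0
  for (g in seq_len(n_groups)) {
    for (sp in species) {
      # first species always contributes, so no group is empty
      k <- if (sp == species[1]) sample(1:2, 1) else sample(0:2, 1)
      for (j in seq_len(k)) {
        pid <- pid + 1
        rows[[length(rows) + 1]] <- data.frame(
          group_id = as.character(g), species_code = sp,
          protein_id = sprintf("p%04d", pid),
          member_score = if (stats::runif(1) < 0.5)
            round(stats::runif(1), 3) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  OrthologGroupTable(df, speciesRoster = species)
}

write_query_fasta <- function(seqs, headers, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}
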