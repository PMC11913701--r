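#' @include AllClasses.R align.R groups.R
NULL

#' All-vs-all best-hit graph across species
#'
#' For every protein and every *other* species, records the
#' highest-scoring target under [globalAlign()] as that protein's best hit
#' in the target species, with the score normalized by the query's
#' self-alignment score (so identical sequences score 1 and the value is
#' length-robust).  Score ties are broken by lexicographic target protein
#' id.
#'
#' This is the pairwise stage of the built-in small-scale ortholog
#' inference; see [clusterOrthologs()] for the grouping stage.
#'
#' @param proteomes a [ProteinSet] covering >= 2 species (the
#'   `file_species` metadata column, falling back to `species_code`,
#'   identifies each record's species), or a list of per-species
#'   [ProteinSet]s.
#' @param scheme a [scoringScheme()].
#' @return data.frame of directed best-hit edges: `query_species`,
#'   `query_id`, `target_species`, `target_id`, `score`, `norm_score`.
#' @export
allVsAll <- function(proteomes, scheme = scoringScheme()) {
  if (is.list(proteomes) && !is(proteomes, "ProteinSet")) {
    parts <- lapply(proteomes, function(p) {
      data.frame(species = .species_of(p), id = proteinId(p),
                 seq = as.character(p), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, parts)
  } else {
    tab <- data.frame(species = .species_of(proteomes),
                      id = proteinId(proteomes),
                      seq = as.character(proteomes),
                      stringsAsFactors = FALSE)
  }
  if (any(is.na(tab$species)) || any(is.na(tab$id)))
    stop("every record needs a species code and a protein id", call. = FALSE)
  if (anyDuplicated(paste(tab$species, tab$id, sep = "\r")))
    stop("duplicate (species, protein_id) keys in input", call. = FALSE)
  species <- unique(tab$species)
  if (length(species) < 2)
    stop("best-hit inference needs at least 2 species", call. = FALSE)

  self_score <- vapply(tab$seq, function(s)
    globalAlign(s, s, scheme)$score, 0, USE.NAMES = FALSE)

  edges <- list()
  for (qi in seq_len(nrow(tab))) {
    for (sp in setdiff(species, tab$species[qi])) {
      targets <- which(tab$species == sp)
      targets <- targets[order(tab$id[targets])]   # tie-break order
      sc <- vapply(targets, function(ti)
        globalAlign(tab$seq[qi], tab$seq[ti], scheme)$score, 0)
      best <- targets[which.max(sc)]
      edges[[length(edges) + 1]] <- data.frame(
        query_species = tab$species[qi], query_id = tab$id[qi],
        target_species = sp, target_id = tab$id[best],
        score = max(sc),
        norm_score = min(1, max(0, max(sc) / self_score[qi])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, edges)
}

.species_of <- function(p) {
  mc <- mcols(p)
  if (!is.null(mc$file_species)) {
    sp <- mc$file_species
    sp[is.na(sp)] <- mc$species_code[is.na(sp)]
    sp
  } else mc$species_code
}

#' Cluster reciprocal best hits into ortholog groups
#'
#' Keeps edges that are reciprocal (A's best hit in B's species is B and
#' vice versa) with both normalized scores at least `minScore`, then takes
#' connected components of the reciprocal-hit graph as groups.  Group ids
#' are ordinals assigned by each group's lexicographically smallest
#' `species|protein` member key; singleton proteins are excluded.
#'
#' This is a deliberately simple stand-in for full orthology inference
#' engines (compatible output schema, simplified inference): in-paralog
#' expansion and domain-aware scoring are out of scope, and the flat-file
#' parser ([parseGroupFile()]) remains the fidelity path for real upstream
#' output.
#'
#' @param hits best-hit edges from [allVsAll()].
#' @param minScore minimum normalized score in `[0, 1]` for both
#'   directions (default 0.05, deliberately permissive for exploratory
#'   screening).
#' @param speciesRoster optional roster for the output table (defaults to
#'   the species seen in `hits`).
#' @return an [OrthologGroupTable-class] (possibly empty).
#' @export
clusterOrthologs <- function(hits, minScore = 0.05, speciesRoster = NULL) {
  stopifnot(is.data.frame(hits))
  if (is.null(speciesRoster))
    speciesRoster <- sort(unique(c(hits$query_species, hits$target_species)))
  key <- function(sp, id) paste(sp, id, sep = "|")
  fwd <- key(hits$query_species, hits$query_id)
  rev <- key(hits$target_species, hits$target_id)
  edge_id <- paste(fwd, rev)
  back_id <- paste(rev, fwd)
  recip <- edge_id %in% back_id & hits$norm_score >= minScore
  # both directions must clear the threshold
  ok <- recip & back_id %in% edge_id[recip]
  kept <- hits[ok, , drop = FALSE]
  if (!nrow(kept))
    return(OrthologGroupTable(
      data.frame(group_id = character(0), species_code = character(0),
                 protein_id = character(0), member_score = numeric(0)),
      speciesRoster = speciesRoster))

  g <- igraph::graph_from_data_frame(
    data.frame(from = key(kept$query_species, kept$query_id),
               to = key(kept$target_species, kept$target_id)),
    directed = FALSE)
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  membership <- membership[vapply(membership, length, 0L) > 1]
  # deterministic ordinals by smallest member key
  smallest <- vapply(membership, function(m) min(m), "")
  membership <- membership[order(smallest)]

  norm_by_key <- stats::aggregate(norm_score ~ fk, FUN = max,
                                  data = data.frame(fk = key(kept$query_species,
                                                             kept$query_id),
                                                    norm_score = kept$norm_score))
  score_of <- stats::setNames(norm_by_key$norm_score, norm_by_key$fk)

  rows <- lapply(seq_along(membership), function(i) {
    ks <- sort(membership[[i]])
    bits <- strsplit(ks, "|", fixed = TRUE)
    data.frame(group_id = as.character(i),
               species_code = vapply(bits, `[`, "", 1),
               protein_id = vapply(bits, `[`, "", 2),
               member_score = unname(score_of[ks]),
               stringsAsFactors = FALSE)
  })
  OrthologGroupTable(do.call(rbind, rows), speciesRoster = speciesRoster)
}

#' Infer ortholog groups from a proteome directory
#'
#' Convenience wrapper: [readProteomeDir()] then [allVsAll()] then
#' [clusterOrthologs()].
#'
#' @param dir proteome FASTA directory (one file per species; file stem =
#'   species code).
#' @param scheme a [scoringScheme()].
#' @param minScore see [clusterOrthologs()].
#' @inheritParams parseLabel
#' @return an [OrthologGroupTable-class].
#' @export
inferGroups <- function(dir, scheme = scoringScheme(), minScore = 0.05,
                        fieldOrder = "species_protein_group") {
  prot <- readProteomeDir(dir, fieldOrder = fieldOrder)
  hits <- allVsAll(prot, scheme)
  roster <- sort(unique(.species_of(prot)))
  clusterOrthologs(hits, minScore = minScore, speciesRoster = roster)
}
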