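#' @include AllClasses.R seqio.R groups.R align.R phylo.R infer.R
NULL

# sequence store: lookup table keyed species|protein over a proteome set
.seq_store <- function(proteomes) {
  sp <- .species_of(proteomes)
  id <- proteinId(proteomes)
  data.frame(species = sp, id = id, key = paste(sp, id, sep = "|"),
             seq = as.character(proteomes),
             header = mcols(proteomes)$raw_header,
             stringsAsFactors = FALSE)
}

#' Match query proteins to ortholog groups
#'
#' Per-query matching cascade:
#' 1. *exact-sequence*: the query sequence is byte-identical to a group
#'    member's sequence;
#' 2. *header*: the query header's `(species_code, protein_id)` equals a
#'    member's;
#' 3. *best-alignment*: the best [globalAlign()] hit among all member
#'    sequences, accepted when its percent identity (co-residue
#'    denominator) reaches `threshold`.
#'
#' Queries matching nothing are reported with mode `"unmatched"`; that is a
#' reported state, not an error.
#'
#' @param queries a [ProteinSet] of query proteins.
#' @param table an [OrthologGroupTable-class].
#' @param proteomes a [ProteinSet] holding the member sequences.
#' @param threshold percent-identity acceptance threshold for the
#'   alignment fallback (default 90).
#' @param scheme a [scoringScheme()].
#' @return data.frame with columns `query` (raw header), `group_id` (`NA`
#'   when unmatched) and `mode`.
#' @export
matchQueries <- function(queries, table, proteomes, threshold = 90,
                         scheme = scoringScheme()) {
  if (!length(queries)) stop("no query sequences", call. = FALSE)
  store <- .seq_store(proteomes)
  members <- groupMembers(table)
  members$key <- paste(members$species_code, members$protein_id, sep = "|")
  hit <- match(members$key, store$key)
  members$seq <- store$seq[hit]

  qinfo <- labelInfo(queries)
  out <- data.frame(query = qinfo$raw_header,
                    group_id = NA_character_,
                    mode = "unmatched",
                    stringsAsFactors = FALSE)
  resolved <- members[!is.na(members$seq), , drop = FALSE]
  for (qi in seq_along(queries)) {
    qseq <- as.character(queries[qi])
    m <- which(resolved$seq == qseq)
    if (length(m)) {
      out$group_id[qi] <- resolved$group_id[m[1]]
      out$mode[qi] <- "exact-sequence"
      next
    }
    qkey <- paste(qinfo$species_code[qi], qinfo$protein_id[qi], sep = "|")
    m <- which(members$key == qkey)
    if (!is.na(qinfo$species_code[qi]) && length(m)) {
      out$group_id[qi] <- members$group_id[m[1]]
      out$mode[qi] <- "header"
      next
    }
    if (nrow(resolved)) {
      pid <- vapply(resolved$seq, function(s) {
        al <- globalAlign(qseq, s, scheme)
        p <- .pair_identity(strsplit(al$a, "")[[1]], strsplit(al$b, "")[[1]])
        if (is.na(p)) 0 else p
      }, 0, USE.NAMES = FALSE)
      if (max(pid) >= threshold) {
        best <- which(pid == max(pid))
        best <- best[order(resolved$key[best])][1]
        out$group_id[qi] <- resolved$group_id[best]
        out$mode[qi] <- "best-alignment"
      }
    }
  }
  out
}

#' Run the full ortholog-query pipeline
#'
#' End-to-end composition: read the proteome directory and queries, obtain
#' the group table (from a flat file or via built-in reciprocal-best-hit
#' inference), match each query to its group, collect and resolve the
#' matched groups' member sequences, align everything with
#' [progressiveMSA()], compute the [percentIdentityMatrix()], convert it
#' to distances and build the neighbor-joining tree, midpoint-rooted by
#' default.
#'
#' Members whose sequence cannot be resolved in the proteome directory are
#' dropped with a warning and listed in the provenance.  Zero resolvable
#' sequences is a hard error; a single sequence yields a degenerate result
#' (no PIM/tree) with a warning.
#'
#' @param proteomeDir directory of proteome FASTA files (file stem =
#'   species code).
#' @param groupsSource path to a group flat file, an
#'   [OrthologGroupTable-class], or the string `"infer"` to run the
#'   built-in inference.
#' @param queryPath FASTA file of one or more query proteins.
#' @param threshold percent-identity threshold of the match fallback.
#' @param scheme a [scoringScheme()].
#' @param midpoint root the tree at the midpoint (default `TRUE`;
#'   `FALSE` keeps the unrooted neighbor-joining tree).
#' @param denominator percent-identity denominator, see
#'   [percentIdentityMatrix()].
#' @param includeUnmatched carry unmatched queries into the alignment.
#' @param dialect group-file [groupDialect()].
#' @param fieldOrder header [fieldOrderPresets()].
#' @param minScore inference threshold, see [clusterOrthologs()].
#' @return a [QueryResult-class].
#' @export
runQueryPipeline <- function(proteomeDir, groupsSource, queryPath,
                             threshold = 90, scheme = scoringScheme(),
                             midpoint = TRUE, denominator = "coresidue",
                             includeUnmatched = FALSE,
                             dialect = groupDialect(),
                             fieldOrder = "species_protein_group",
                             minScore = 0.05) {
  proteomes <- readProteomeDir(proteomeDir, fieldOrder = fieldOrder)
  queries <- readProteins(queryPath, fieldOrder = fieldOrder)
  table <- if (is(groupsSource, "OrthologGroupTable")) {
    groupsSource
  } else if (identical(groupsSource, "infer")) {
    clusterOrthologs(allVsAll(proteomes, scheme), minScore = minScore,
                     speciesRoster = sort(unique(.species_of(proteomes))))
  } else {
    parseGroupFile(groupsSource, dialect)
  }

  matches <- matchQueries(queries, table, proteomes, threshold, scheme)
  warnings <- character(0)
  unmatched <- matches$query[matches$mode == "unmatched"]
  if (length(unmatched))
    warnings <- c(warnings, paste0("unmatched query: ", unmatched))

  gids <- unique(stats::na.omit(matches$group_id))
  store <- .seq_store(proteomes)
  members <- groupMembers(table)
  members <- members[members$group_id %in% gids, , drop = FALSE]
  members$key <- paste(members$species_code, members$protein_id, sep = "|")
  hit <- match(members$key, store$key)
  dropped <- members$key[is.na(hit)]
  if (length(dropped)) {
    warning("member sequence(s) not resolvable in the proteome directory: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    warnings <- c(warnings, paste0("dropped member: ", dropped))
  }
  members <- members[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]

  # labels: source|species|protein|group (configured order) for members,
  # raw header for queries
  mem_seqs <- store$seq[hit]
  mem_headers <- store$header[hit]
  src <- parseLabel(mem_headers, fieldOrder)$source_tag
  src[is.na(src)] <- "seq"
  mem_labels <- renderLabel(
    data.frame(source_tag = src, species_code = members$species_code,
               protein_id = members$protein_id, group_id = members$group_id,
               stringsAsFactors = FALSE),
    fieldOrder)

  qinfo <- labelInfo(queries)
  keep_q <- matches$mode != "unmatched" | includeUnmatched
  q_seqs <- as.character(queries)[keep_q]
  q_labels <- qinfo$raw_header[keep_q]
  # a query byte-identical to a resolved member is already represented by
  # that member's row; adding it again would duplicate a sequence
  dup_q <- q_seqs %in% mem_seqs
  q_seqs <- q_seqs[!dup_q]
  q_labels <- q_labels[!dup_q]

  all_seqs <- c(q_seqs, mem_seqs)
  all_labels <- make.unique(c(q_labels, mem_labels), sep = "#")
  if (!length(all_seqs))
    stop("no resolvable orthologs: ", length(queries), " queries, ",
         sum(matches$mode != "unmatched"), " matched, ",
         length(dropped), " dropped members", call. = FALSE)

  orthologs <- ProteinSet(all_seqs, headers = all_labels,
                          origin_file = NA_character_,
                          fieldOrder = fieldOrder)

  alignment <- NULL; pim <- NULL; tree <- NULL
  if (length(all_seqs) >= 2) {
    named <- stats::setNames(all_seqs, all_labels)
    alignment <- progressiveMSA(named, scheme)
    pim <- percentIdentityMatrix(alignment, denominator)
    if (length(all_seqs) >= 3) {
      d <- distanceFromPIM(pim)
      tree <- njTree(d)
      if (midpoint) tree <- midpointRoot(tree)
    } else {
      warnings <- c(warnings, "fewer than 3 sequences: tree skipped")
    }
  } else {
    warning("fewer than 2 resolvable sequences: alignment, PIM and tree ",
            "skipped", call. = FALSE)
    warnings <- c(warnings, "fewer than 2 sequences: PIM/tree skipped")
    alignment <- suppressWarnings(progressiveMSA(
      stats::setNames(all_seqs, all_labels), scheme))
  }

  prov <- list(
    proteome_dir = proteomeDir,
    groups_source = if (is.character(groupsSource)) groupsSource
                    else "<in-memory table>",
    query_path = queryPath,
    parameters = list(threshold = threshold, midpoint = midpoint,
                      denominator = denominator,
                      gap_open = scheme$gapOpen,
                      gap_extend = scheme$gapExtend,
                      field_order = fieldOrder, min_score = minScore,
                      include_unmatched = includeUnmatched),
    version = as.character(utils::packageVersion("OrthoQuery")),
    warnings = warnings,
    dropped_members = dropped,
    counts = list(queries = length(queries),
                  matched = sum(matches$mode != "unmatched"),
                  groups = length(gids),
                  orthologs = length(all_seqs),
                  dropped = length(dropped)))

  new("QueryResult", queries = queries, matches = matches,
      orthologs = orthologs, alignment = alignment, pim = pim,
      tree = tree, provenance = prov)
}
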