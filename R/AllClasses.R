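#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
NULL

GAP_CHAR <- "-"
# Residues tolerated on input: the 20 standard amino acids plus the
# ambiguity/rare codes common in proteome dumps.
AA_OK <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
           "S","T","V","W","Y","X","B","Z","U","O","J","*")

#' ProteinSet: protein sequences with parsed header fields
#'
#' A set of amino-acid sequences together with the structured fields parsed
#' from their pipe-delimited FASTA headers (JGI-style convention:
#' `source|species|protein|group`).  Extends
#' [Biostrings::AAStringSet]; the parsed fields live in `mcols()` with
#' columns `raw_header`, `source_tag`, `species_code`, `protein_id`,
#' `group_id` and `origin_file` (`NA` where a field is absent).
#'
#' @slot .Data inherited from `AAStringSet`.
#' @seealso [readProteins()], [parseLabel()]
#' @export
setClass("ProteinSet", contains = "AAStringSet")

.label_cols <- c("raw_header", "source_tag", "species_code", "protein_id",
                 "group_id", "origin_file")

setValidity("ProteinSet", function(object) {
  msg <- character()
  mc <- mcols(object)
  if (is.null(mc) || !all(.label_cols %in% colnames(mc)))
    msg <- c(msg, paste("mcols must contain columns:",
                        paste(.label_cols, collapse = ", ")))
  if (length(object)) {
    if (any(width(object) == 0))
      msg <- c(msg, "all sequences must be non-empty")
    if (any(grepl("-", as.character(object), fixed = TRUE)))
      msg <- c(msg, "sequences must not contain gap characters")
  }
  if (length(msg)) msg else TRUE
})

#' OrthologGroupTable: tidy ortholog-group membership
#'
#' Long-format membership table mapping ortholog group ids to their member
#' proteins, one row per member: columns `group_id`, `species_code`,
#' `protein_id` and `member_score` (a confidence in `[0, 1]`, `NA` when the
#' source carries none).  The `speciesRoster` slot preserves the species
#' column order of the source flat file.
#'
#' @slot members data.frame with the four columns above.
#' @slot speciesRoster character vector of species codes (source column
#'   order).
#' @seealso [parseGroupFile()], [clusterOrthologs()]
#' @export
setClass("OrthologGroupTable",
         representation(members = "data.frame", speciesRoster = "character"))

setValidity("OrthologGroupTable", function(object) {
  m <- object@members
  msg <- character()
  need <- c("group_id", "species_code", "protein_id", "member_score")
  if (!all(need %in% colnames(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (nrow(m)) {
    key3 <- paste(m$group_id, m$species_code, m$protein_id, sep = "\r")
    if (anyDuplicated(key3))
      msg <- c(msg, "duplicate (group_id, species_code, protein_id) rows")
    key2 <- paste(m$species_code, m$protein_id, sep = "\r")
    dup <- key2[duplicated(key2)]
    if (length(dup)) {
      # group membership must partition the proteins
      msg <- c(msg, paste0("proteins assigned to more than one group: ",
                           paste(unique(gsub("\r", "|", dup)), collapse = ", ")))
    }
    if (!all(m$species_code %in% object@speciesRoster))
      msg <- c(msg, "species_code values missing from speciesRoster")
    sc <- m$member_score
    if (any(!is.na(sc) & (sc < 0 | sc > 1)))
      msg <- c(msg, "member_score must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ProteinAlignment: a gapped multiple sequence alignment
#'
#' Equal-length gapped rows over the amino-acid alphabet plus `-`.
#' Extends [Biostrings::AAStringSet]; row names are the sequence labels.
#'
#' @export
setClass("ProteinAlignment", contains = "AAStringSet")

setValidity("ProteinAlignment", function(object) {
  if (!length(object)) return("alignment must contain at least one row")
  if (length(unique(width(object))) != 1L)
    return("all alignment rows must have equal length")
  if (is.null(names(object)) || anyDuplicated(names(object)))
    return("rows must carry unique labels")
  mat <- do.call(rbind, strsplit(as.character(object), ""))
  if (any(colSums(mat != GAP_CHAR) == 0))
    return("alignment contains an all-gap column")
  TRUE
})

#' PercentIdentityMatrix: pairwise percent identity from an alignment
#'
#' Symmetric matrix of pairwise percent sequence identity in `[0, 100]`
#' with a diagonal of 100, labelled by the alignment row labels.  This is
#' the quantity rendered as the similarity heatmap.
#'
#' @slot values numeric matrix with identical dimnames on both margins.
#' @export
setClass("PercentIdentityMatrix", representation(values = "matrix"))

setValidity("PercentIdentityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column labels must be identical")
  if (any(v < 0 | v > 100)) msg <- c(msg, "values must lie in [0, 100]")
  if (nrow(v) && any(abs(diag(v) - 100) > 1e-9))
    msg <- c(msg, "diagonal must equal 100")
  if (any(abs(v - t(v)) > 1e-9)) msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' QueryResult: everything one ortholog query run produces
#'
#' @slot queries [ProteinSet] of the query records.
#' @slot matches data.frame with columns `query`, `group_id`, `mode`
#'   (`exact-sequence`, `header`, `best-alignment` or `unmatched`).
#' @slot orthologs [ProteinSet] of the resolved group members plus queries.
#' @slot alignment [ProteinAlignment] (may have 1 row for degenerate runs).
#' @slot pim [PercentIdentityMatrix].
#' @slot tree the `phylo` tree (or `NULL` when fewer than 3 sequences).
#' @slot provenance list: input paths, parameters, warnings, counts.
#' @export
setClass("QueryResult",
         representation(queries = "ProteinSet",
                        matches = "data.frame",
                        orthologs = "ProteinSet",
                        alignment = "ANY",
                        pim = "ANY",
                        tree = "ANY",
                        provenance = "list"))

setValidity("QueryResult", function(object) {
  msg <- character()
  if (!is.null(object@pim) && !is.null(object@tree)) {
    if (!setequal(pimLabels(object@pim), object@tree$tip.label))
      msg <- c(msg, "PIM labels and tree leaves must be identical sets")
  }
  if (length(msg)) msg else TRUE
})
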