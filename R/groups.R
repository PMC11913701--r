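#' @include AllClasses.R
NULL

#' Ortholog-group flat-file dialects
#'
#' Upstream orthology tools emit group tables in slightly different
#' non-standard flavours, so the parser is driven by a dialect object
#' rather than hard-coded separators.  The `"default"` (SonicParanoid-like)
#' dialect is: tab-separated; first column the group id; one column per
#' species named in the header row; cells hold comma-separated member
#' protein ids, each optionally suffixed `:score` with a confidence in
#' `[0, 1]`; `*` marks a species with no member.
#'
#' @param name a registered dialect name (currently `"default"` and the
#'   alias `"sonicparanoid"`), or pass the fields directly.
#' @param sep column separator.
#' @param memberSep separator between members within one cell.
#' @param scoreSep separator between a protein id and its confidence.
#' @param placeholder token marking an empty cell.
#' @return a `GroupDialect` list.
#' @export
groupDialect <- function(name = "default", sep = "\t", memberSep = ",",
                         scoreSep = ":", placeholder = "*") {
  if (!missing(name)) {
    name <- match.arg(name, c("default", "sonicparanoid"))
  }
  structure(list(sep = sep, memberSep = memberSep, scoreSep = scoreSep,
                 placeholder = placeholder),
            class = "GroupDialect")
}

#' Construct an OrthologGroupTable
#'
#' @param members data.frame with columns `group_id`, `species_code`,
#'   `protein_id` and optionally `member_score`.
#' @param speciesRoster ordered character vector of species codes; defaults
#'   to the species seen in `members`.
#' @return an [OrthologGroupTable-class].
#' @export
OrthologGroupTable <- function(members,
                               speciesRoster = unique(members$species_code)) {
  if (!"member_score" %in% colnames(members))
    members$member_score <- NA_real_
  members <- members[, c("group_id", "species_code", "protein_id",
                         "member_score")]
  members[1:3] <- lapply(members[1:3], as.character)
  members$member_score <- as.numeric(members$member_score)
  rownames(members) <- NULL
  new("OrthologGroupTable", members = members,
      speciesRoster = as.character(speciesRoster))
}

#' Parse an ortholog-group flat file
#'
#' Reads a SonicParanoid-style group file into a tidy
#' [OrthologGroupTable-class]: each input row (one putative ortholog
#' group) fans out to one output row per member protein.  Placeholder
#' cells produce no rows; `id:score` suffixes are split into `protein_id`
#' and `member_score`.
#'
#' @param path the flat file; its first line must be a header naming the
#'   group-id column and then one column per species.
#' @param dialect a [groupDialect()].
#' @return an [OrthologGroupTable-class] whose `speciesRoster` preserves
#'   the file's species column order.
#' @export
parseGroupFile <- function(path, dialect = groupDialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty group file: ", path, call. = FALSE)
  header <- strsplit(lines[1], dialect$sep, fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("group file header must name a group-id column and at least one ",
         "species column", call. = FALSE)
  roster <- header[-1]
  rows <- list()
  for (ln in seq_along(lines)[-1]) {
    cells <- strsplit(lines[ln], dialect$sep, fixed = TRUE)[[1]]
    if (length(cells) != length(header))
      stop("group file format error at line ", ln, ": expected ",
           length(header), " columns, found ", length(cells), call. = FALSE)
    gid <- trimws(cells[1])
    for (s in seq_along(roster)) {
      cell <- trimws(cells[s + 1])
      if (!nzchar(cell) || cell == dialect$placeholder) next
      members <- trimws(strsplit(cell, dialect$memberSep, fixed = TRUE)[[1]])
      for (mem in members) {
        bits <- strsplit(mem, dialect$scoreSep, fixed = TRUE)[[1]]
        score <- NA_real_
        if (length(bits) == 2) {
          score <- suppressWarnings(as.numeric(bits[2]))
          if (is.na(score))
            stop("group file format error at line ", ln,
                 ": invalid member score '", bits[2], "'", call. = FALSE)
        }
        rows[[length(rows) + 1]] <- data.frame(
          group_id = gid, species_code = roster[s],
          protein_id = bits[1], member_score = score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    stop("group file contains no members: ", path, call. = FALSE)
  OrthologGroupTable(do.call(rbind, rows), speciesRoster = roster)
}

#' Write / read the tidy long-format group table
#'
#' `writeGroupTable()` writes the long TSV (columns `group_id`,
#' `species_code`, `protein_id`, `member_score`) in a deterministic order:
#' by group id, then species-roster order, then protein id.  Absent scores
#' are written as empty cells, not 0.  `readGroupTable()` reads it back;
#' the two are inverse up to row order normalization.
#'
#' @param x an [OrthologGroupTable-class].
#' @param path output/input TSV path.
#' @return `path` invisibly / an [OrthologGroupTable-class].
#' @export
writeGroupTable <- function(x, path) {
  m <- groupMembers(x)
  if (!nrow(m)) stop("cannot write an empty group table", call. = FALSE)
  sp <- match(m$species_code, speciesRoster(x))
  m <- m[order(m$group_id, sp, m$protein_id), ]
  out <- m
  out$member_score <- ifelse(is.na(m$member_score), "",
                             format(m$member_score, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeGroupTable
#' @export
readGroupTable <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character",
                                        "character", "numeric"),
                         na.strings = "")
  OrthologGroupTable(m)
}

#' Look up the members of one group
#'
#' @param x an [OrthologGroupTable-class].
#' @param group_id a group id present in the table.
#' @return data.frame of the group's members (`species_code`,
#'   `protein_id`, `member_score`) in deterministic order (species-roster
#'   order, then protein id).
#' @export
lookupGroup <- function(x, group_id) {
  m <- groupMembers(x)
  hit <- m[m$group_id == as.character(group_id), , drop = FALSE]
  if (!nrow(hit))
    stop("group not found: ", group_id, call. = FALSE)
  sp <- match(hit$species_code, speciesRoster(x))
  hit <- hit[order(sp, hit$protein_id), c("species_code", "protein_id",
                                          "member_score")]
  rownames(hit) <- NULL
  hit
}

#' Flag cross-species groups
#'
#' @param x an [OrthologGroupTable-class].
#' @return named logical vector: `TRUE` for groups spanning >= 2 species.
#' @export
crossSpeciesGroups <- function(x) {
  m <- groupMembers(x)
  vapply(split(m$species_code, m$group_id),
         function(s) length(unique(s)) > 1, logical(1))
}

#' Write an OrthologGroupTable back to the flat-file dialect
#'
#' Inverse of [parseGroupFile()]: one line per group, one column per
#' roster species, members comma-joined, scores re-attached as `:score`
#' suffixes, placeholder for species without a member.
#' `parseGroupFile(makeGroupFile(x))` reproduces `x`.
#'
#' @param x an [OrthologGroupTable-class].
#' @param path output path.
#' @param dialect a [groupDialect()].
#' @param groupColumn header name for the group-id column.
#' @return `path`, invisibly.
#' @export
makeGroupFile <- function(x, path, dialect = groupDialect(),
                          groupColumn = "group_id") {
  m <- groupMembers(x)
  roster <- speciesRoster(x)
  gids <- unique(m$group_id)
  lines <- paste(c(groupColumn, roster), collapse = dialect$sep)
  for (g in gids) {
    gm <- m[m$group_id == g, , drop = FALSE]
    cells <- vapply(roster, function(sp) {
      sm <- gm[gm$species_code == sp, , drop = FALSE]
      if (!nrow(sm)) return(dialect$placeholder)
      sm <- sm[order(sm$protein_id), ]
      toks <- ifelse(is.na(sm$member_score), sm$protein_id,
                     paste0(sm$protein_id, dialect$scoreSep,
                            format(sm$member_score, trim = TRUE)))
      paste(toks, collapse = dialect$memberSep)
    }, "")
    lines <- c(lines, paste(c(g, cells), collapse = dialect$sep))
  }
  writeLines(lines, path)
  invisible(path)
}
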