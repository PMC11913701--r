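#' @include AllClasses.R
NULL

#' Pipe-delimited header field orders
#'
#' Proteome FASTA headers follow a pipe-delimited convention whose first
#' field is the sequence source (e.g. `jgi`).  Two field orders for the
#' remaining fields are in circulation, so the order is a named preset
#' rather than a constant:
#'
#' * `"species_protein_group"` (default):
#'   `source|species|protein|group`
#' * `"species_group_protein"`:
#'   `source|species|group|protein`
#'
#' @return Character vector of the preset names.
#' @export
fieldOrderPresets <- function() c("species_protein_group",
                                  "species_group_protein")

.field_slots <- function(fieldOrder) {
  fieldOrder <- match.arg(fieldOrder, fieldOrderPresets())
  switch(fieldOrder,
         species_protein_group = c("species_code", "protein_id", "group_id"),
         species_group_protein = c("species_code", "group_id", "protein_id"))
}

#' Parse pipe-delimited sequence labels
#'
#' Splits a header such as `"jgi|ChlNC64A|41714|8"` on `|`, strips
#' surrounding whitespace and maps the pieces positionally: field 1 is the
#' source tag, the rest follow `fieldOrder`.  The parser is lenient: a
#' header with fewer than two fields yields all-`NA` structured fields and
#' is retained verbatim as `raw_header`.
#'
#' @param headers character vector of raw header lines (without `>`).
#' @param fieldOrder one of [fieldOrderPresets()].
#' @return data.frame with columns `raw_header`, `source_tag`,
#'   `species_code`, `protein_id`, `group_id`.
#' @examples
#' parseLabel("jgi|ChlNC64A|41714|g1")
#' @export
parseLabel <- function(headers, fieldOrder = "species_protein_group") {
  slots <- .field_slots(fieldOrder)
  headers <- as.character(headers)
  out <- data.frame(raw_header = headers,
                    source_tag = rep(NA_character_, length(headers)),
                    species_code = rep(NA_character_, length(headers)),
                    protein_id = rep(NA_character_, length(headers)),
                    group_id = rep(NA_character_, length(headers)),
                    stringsAsFactors = FALSE)
  parts <- strsplit(out$raw_header, "|", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) < 2) next
    out$source_tag[i] <- p[1]
    extra <- p[-1]
    for (k in seq_along(slots)) {
      if (k <= length(extra)) out[[slots[k]]][i] <- extra[k]
    }
  }
  out
}

#' Render parsed label fields back to a pipe-delimited header
#'
#' Inverse of [parseLabel()] for headers that matched the convention:
#' joins the non-missing fields with `|` in the configured order, dropping
#' absent trailing fields.
#'
#' @param fields data.frame with columns `source_tag`, `species_code`,
#'   `protein_id`, `group_id` (as from [parseLabel()]).
#' @inheritParams parseLabel
#' @return character vector of headers.
#' @export
renderLabel <- function(fields, fieldOrder = "species_protein_group") {
  slots <- c("source_tag", .field_slots(fieldOrder))
  vapply(seq_len(nrow(fields)), function(i) {
    vals <- vapply(slots, function(s) fields[[s]][i], "")
    keep <- !is.na(vals)
    # drop only absent *trailing* fields; internal absences cannot be
    # rendered faithfully and become empty fields
    if (any(keep)) vals <- vals[seq_len(max(which(keep)))]
    vals[is.na(vals)] <- ""
    paste(vals, collapse = "|")
  }, "")
}

.check_fasta_head <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0)
      stop("no records in FASTA file: ", path, call. = FALSE)
    if (nzchar(trimws(ln))) {
      if (!startsWith(trimws(ln), ">"))
        stop("FASTA format error in ", path,
             ": sequence data before the first header line", call. = FALSE)
      return(invisible(TRUE))
    }
  }
}

#' Read a proteome FASTA file
#'
#' Reads one FASTA file into a [ProteinSet].  Sequences are uppercased,
#' a trailing stop codon `*` is stripped, and headers are parsed with
#' [parseLabel()].  Duplicate headers within one file are kept but warned
#' about and disambiguated with an occurrence suffix in `names()` (the
#' `raw_header` column stays verbatim).
#'
#' @param path FASTA file path.
#' @inheritParams parseLabel
#' @return a [ProteinSet].
#' @export
readProteins <- function(path, fieldOrder = "species_protein_group") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .check_fasta_head(path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("no records in FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs)))
    stop("FASTA format error in ", path, ": record with empty sequence (",
         paste(names(raw)[!nzchar(seqs)], collapse = ", "), ")",
         call. = FALSE)
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), AA_OK)
  if (length(bad))
    stop("invalid residue(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  ProteinSet(seqs, headers = names(raw),
             origin_file = basename(path), fieldOrder = fieldOrder)
}

#' Construct a ProteinSet from sequences and headers
#'
#' @param sequences character vector or `AAStringSet` of ungapped
#'   amino-acid sequences.
#' @param headers raw FASTA headers (defaults to `names(sequences)`).
#' @param origin_file file name to record per record.
#' @inheritParams parseLabel
#' @return a [ProteinSet].
#' @export
ProteinSet <- function(sequences, headers = names(sequences),
                       origin_file = NA_character_,
                       fieldOrder = "species_protein_group") {
  seqs <- if (is(sequences, "XStringSet")) as.character(sequences)
          else as.character(sequences)
  if (is.null(headers)) stop("headers are required")
  info <- parseLabel(headers, fieldOrder)
  info$origin_file <- rep_len(as.character(origin_file), length(seqs))
  keys <- headers
  if (anyDuplicated(keys)) {
    warning("duplicate headers found; internal keys disambiguated with ",
            "an occurrence suffix", call. = FALSE)
    keys <- make.unique(keys, sep = "#")
  }
  x <- AAStringSet(seqs)
  names(x) <- keys
  mcols(x) <- DataFrame(info)
  new("ProteinSet", x)
}

#' Write a ProteinSet to FASTA
#'
#' Writes the raw headers byte-for-byte, so
#' `readProteins(writeProteins(x))` reproduces headers and sequences
#' exactly.
#'
#' @param x a [ProteinSet] (or any `AAStringSet`).
#' @param path output file.
#' @param wrap line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
writeProteins <- function(x, path, wrap = 60L) {
  if (length(x) == 0) stop("cannot write an empty record set", call. = FALSE)
  stopifnot(wrap >= 1)
  out <- AAStringSet(as.character(x))
  hdr <- if (!is.null(mcols(x)) && "raw_header" %in% colnames(mcols(x)))
    mcols(x)$raw_header else names(x)
  names(out) <- hdr
  writeXStringSet(out, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Read a directory of proteome FASTA files
#'
#' Reads every FASTA file in `dir` (one file per species/strain) into a
#' single [ProteinSet].  The file stem is recorded in the `file_species`
#' metadata column; by convention it equals the species code used in
#' ortholog-group tables.
#'
#' @param dir directory containing `.fa` / `.faa` / `.fasta` files.
#' @param pattern file-name regexp to include.
#' @inheritParams parseLabel
#' @return a [ProteinSet] covering all files.
#' @export
readProteomeDir <- function(dir, pattern = "\\.(fa|faa|fasta)$",
                            fieldOrder = "species_protein_group") {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files))
    stop("no FASTA files found in ", dir, call. = FALSE)
  sets <- lapply(files, readProteins, fieldOrder = fieldOrder)
  stems <- tools::file_path_sans_ext(basename(files))
  for (i in seq_along(sets))
    mcols(sets[[i]])$file_species <- stems[i]
  seqs <- unlist(lapply(sets, as.character), use.names = FALSE)
  keys <- unlist(lapply(sets, names), use.names = FALSE)
  mc <- do.call(rbind, lapply(sets, function(s) as.data.frame(mcols(s))))
  if (anyDuplicated(keys)) keys <- make.unique(keys, sep = "#")
  x <- AAStringSet(seqs)
  names(x) <- keys
  mcols(x) <- DataFrame(mc, row.names = NULL)
  new("ProteinSet", x)
}
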