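#' @include AllClasses.R pipeline.R
NULL

.log <- function(...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  msg
}

#' Write a percent identity matrix as TSV (and optional heatmap)
#'
#' The TSV always carries a header row and a header column of labels, with
#' values printed to one decimal place (`77.1`-style).  When `format` is
#' `"png"` a heatmap image is written next to the TSV (requires the
#' pheatmap package); `"html"` writes a simple self-contained colored
#' table.  When a tree is supplied, rows/columns follow its leaf order.
#'
#' @param pim a [PercentIdentityMatrix-class].
#' @param path output TSV path.
#' @param format `"tsv"`, `"png"` or `"html"`.
#' @param tree optional `phylo` tree fixing the label order.
#' @return character vector of the files written, invisibly.
#' @export
writeHeatmap <- function(pim, path, format = c("tsv", "png", "html"),
                         tree = NULL) {
  format <- match.arg(format)
  v <- pimValues(pim)
  if (!is.null(tree)) {
    ord <- match(tree$tip.label, rownames(v))
    if (!anyNA(ord)) v <- v[ord, ord, drop = FALSE]
  }
  txt <- matrix(sprintf("%.1f", v), nrow(v),
                dimnames = dimnames(v))
  df <- data.frame(label = rownames(txt), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- path

  if (format == "png") {
    if (!requireNamespace("pheatmap", quietly = TRUE))
      stop("png output requires the pheatmap package", call. = FALSE)
    png_path <- sub("\\.tsv$", ".png", path)
    if (identical(png_path, path)) png_path <- paste0(path, ".png")
    grDevices::png(png_path, width = 1200, height = 1000, res = 120)
    pheatmap::pheatmap(v, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = nrow(v) <= 20,
                       number_format = "%.1f",
                       main = "Percent identity (%)")
    grDevices::dev.off()
    written <- c(written, png_path)
  } else if (format == "html") {
    html_path <- sub("\\.tsv$", ".html", path)
    if (identical(html_path, path)) html_path <- paste0(path, ".html")
    shade <- function(x) sprintf("background-color: rgb(%d,%d,255)",
                                 round(255 - 1.5 * x), round(255 - 1.2 * x))
    rows <- vapply(seq_len(nrow(v)), function(i) {
      cells <- vapply(seq_len(ncol(v)), function(j)
        sprintf("<td style='%s'>%.1f</td>", shade(v[i, j]), v[i, j]), "")
      paste0("<tr><th>", rownames(v)[i], "</th>",
             paste(cells, collapse = ""), "</tr>")
    }, "")
    head_row <- paste0("<tr><th></th>",
                       paste0("<th>", colnames(v), "</th>", collapse = ""),
                       "</tr>")
    writeLines(c("<html><body><table border='1' style='border-collapse:collapse'>",
                 head_row, rows, "</table></body></html>"), html_path)
    written <- c(written, html_path)
  }
  invisible(written)
}

#' Write all artifacts of a query run
#'
#' Writes, under `outDir`: `orthologs.tsv` (tidy member table with match
#' provenance), `pim.tsv` (+ optional image), `alignment.afa` (aligned
#' FASTA), `tree.nwk` (Newick), `run.log`, and `manifest.json` (written
#' last; parameters, input digests, output list, warnings and counts).
#'
#' @param result a [QueryResult-class].
#' @param outDir output directory (created if needed).
#' @param format heatmap format, see [writeHeatmap()].
#' @return the manifest, invisibly.
#' @export
writeQueryResult <- function(result, outDir, format = "tsv") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log <- character(0)

  ortho_path <- file.path(outDir, "orthologs.tsv")
  info <- as.data.frame(labelInfo(result@orthologs))
  tab <- data.frame(label = info$raw_header,
                    species_code = info$species_code,
                    protein_id = info$protein_id,
                    group_id = info$group_id,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, ortho_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  outputs <- c(outputs, ortho_path)
  log <- c(log, .log("wrote ", ortho_path, " (", nrow(tab), " records)"))

  if (!is.null(result@alignment)) {
    afa <- file.path(outDir, "alignment.afa")
    aln <- AAStringSet(as.character(result@alignment))
    names(aln) <- names(result@alignment)
    writeXStringSet(aln, afa, width = 60L)
    outputs <- c(outputs, afa)
    log <- c(log, .log("wrote ", afa))
  }
  if (!is.null(result@pim)) {
    pim_path <- file.path(outDir, "pim.tsv")
    outputs <- c(outputs,
                 writeHeatmap(result@pim, pim_path, format,
                              tree = result@tree))
    log <- c(log, .log("wrote ", pim_path))
  }
  if (!is.null(result@tree)) {
    nwk <- file.path(outDir, "tree.nwk")
    writeLines(toNewick(result@tree), nwk)
    outputs <- c(outputs, nwk)
    log <- c(log, .log("wrote ", nwk))
  }
  for (w in result@provenance$warnings)
    log <- c(log, .log("warning: ", w))

  log_path <- file.path(outDir, "run.log")
  writeLines(log, log_path)
  outputs <- c(outputs, log_path)

  inputs <- c(result@provenance$query_path,
              if (file.exists(result@provenance$groups_source %||% ""))
                result@provenance$groups_source)
  digests <- as.list(tools::md5sum(inputs[file.exists(inputs)]))

  manifest_path <- file.path(outDir, "manifest.json")
  manifest <- list(parameters = result@provenance$parameters,
                   inputs = list(proteome_dir = result@provenance$proteome_dir,
                                 groups_source = result@provenance$groups_source,
                                 query_path = result@provenance$query_path,
                                 digests = digests),
                   outputs = c(outputs, manifest_path),
                   warnings = result@provenance$warnings,
                   counts = result@provenance$counts,
                   version = result@provenance$version)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

.usage <- function() {
  paste(c(
    "usage: orthoquery --proteomes DIR --query FASTA (--groups FILE | --infer)",
    "                  --out DIR [options]",
    "",
    "options:",
    "  --proteomes DIR        directory of proteome FASTA files (required)",
    "  --query FASTA          query protein sequences (required)",
    "  --groups FILE          ortholog-group flat file",
    "  --infer                infer groups by reciprocal best hits instead",
    "  --out DIR              output directory (required)",
    "  --threshold FLOAT      match fallback %-identity threshold (default 90)",
    "  --no-midpoint-root     emit the unrooted neighbor-joining tree",
    "  --include-unmatched    keep unmatched queries in the alignment",
    "  --format FMT           tsv | png | html (default tsv)",
    "  --config FILE          YAML file of parameter overrides"),
    collapse = "\n")
}

.parse_argv <- function(argv) {
  opts <- list(threshold = 90, midpoint = TRUE, format = "tsv",
               include_unmatched = FALSE, infer = FALSE,
               denominator = "coresidue", field_order = "species_protein_group",
               gap_open = 10, gap_extend = 1, min_score = 0.05)
  i <- 1
  need <- function() {
    if (i + 1 > length(argv)) stop("missing value for ", argv[i], call. = FALSE)
    i <<- i + 1
    argv[i]
  }
  while (i <= length(argv)) {
    a <- argv[i]
    switch(a,
           "--proteomes" = opts$proteomes <- need(),
           "--query" = opts$query <- need(),
           "--groups" = opts$groups <- need(),
           "--infer" = opts$infer <- TRUE,
           "--out" = opts$out <- need(),
           "--threshold" = opts$threshold <- as.numeric(need()),
           "--no-midpoint-root" = opts$midpoint <- FALSE,
           "--include-unmatched" = opts$include_unmatched <- TRUE,
           "--format" = opts$format <- need(),
           "--config" = opts$config <- need(),
           stop("unknown flag: ", a, call. = FALSE))
    i <- i + 1
  }
  opts
}

.apply_config <- function(opts) {
  if (is.null(opts$config)) return(opts)
  cfg <- yaml::read_yaml(opts$config)
  known <- c("threshold", "midpoint", "format", "denominator",
             "field_order", "gap_open", "gap_extend", "min_score",
             "include_unmatched")
  for (k in intersect(names(cfg), known)) opts[[k]] <- cfg[[k]]
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    warning("ignoring unknown config keys: ", paste(bad, collapse = ", "),
            call. = FALSE)
  opts
}

#' Command-line entry point
#'
#' Thin shell over [runQueryPipeline()] and [writeQueryResult()]; a
#' launcher script is installed at `system.file("scripts", "orthoquery.R",
#' package = "OrthoQuery")`.
#'
#' Exit codes: 0 on success with at least one ortholog; 2 on usage errors
#' (missing/unknown flags, unknown format); 1 on pipeline errors
#' (unreadable inputs, malformed group file, zero resolvable orthologs).
#'
#' @param argv character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return the exit code, invisibly.
#' @export
cliMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  opts <- tryCatch({
    o <- .parse_argv(argv)
    o <- .apply_config(o)
    if (is.null(o$proteomes) || is.null(o$query) || is.null(o$out) ||
        (is.null(o$groups) && !o$infer))
      stop("missing required flags", call. = FALSE)
    if (!o$format %in% c("tsv", "png", "html"))
      stop("unknown format: ", o$format, call. = FALSE)
    o
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(.usage())
    NULL
  })
  if (is.null(opts)) return(invisible(2L))

  status <- tryCatch({
    scheme <- scoringScheme(gapOpen = opts$gap_open,
                            gapExtend = opts$gap_extend)
    result <- runQueryPipeline(
      proteomeDir = opts$proteomes,
      groupsSource = if (opts$infer) "infer" else opts$groups,
      queryPath = opts$query,
      threshold = opts$threshold,
      scheme = scheme,
      midpoint = opts$midpoint,
      denominator = opts$denominator,
      includeUnmatched = opts$include_unmatched,
      fieldOrder = opts$field_order,
      minScore = opts$min_score)
    writeQueryResult(result, opts$out, format = opts$format)
    0L
  }, error = function(e) {
    message("pipeline error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
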