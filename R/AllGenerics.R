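#' @include AllClasses.R
NULL

#' Accessors for OrthoQuery classes
#'
#' `labelInfo()` returns the parsed header fields of a [ProteinSet] as a
#' `DataFrame`; `speciesCode()` and `proteinId()` extract single columns.
#' `groupMembers()` returns the long membership table of an
#' [OrthologGroupTable] and `speciesRoster()` its species column order.
#' `groupIds()` lists the distinct group ids.  `pimValues()` returns the
#' numeric matrix inside a [PercentIdentityMatrix] and `pimLabels()` its
#' labels.
#'
#' @param x an OrthoQuery object.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("labelInfo", function(x) standardGeneric("labelInfo"))

#' @rdname accessors
#' @export
setGeneric("speciesCode", function(x) standardGeneric("speciesCode"))

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))

#' @rdname accessors
#' @export
setGeneric("speciesRoster", function(x) standardGeneric("speciesRoster"))

#' @rdname accessors
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname accessors
#' @export
setGeneric("pimValues", function(x) standardGeneric("pimValues"))

#' @rdname accessors
#' @export
setGeneric("pimLabels", function(x) standardGeneric("pimLabels"))

#' @rdname accessors
setMethod("labelInfo", "ProteinSet", function(x) mcols(x))

#' @rdname accessors
setMethod("speciesCode", "ProteinSet", function(x) mcols(x)$species_code)

#' @rdname accessors
setMethod("proteinId", "ProteinSet", function(x) mcols(x)$protein_id)

#' @rdname accessors
setMethod("groupMembers", "OrthologGroupTable", function(x) x@members)

#' @rdname accessors
setMethod("speciesRoster", "OrthologGroupTable", function(x) x@speciesRoster)

#' @rdname accessors
setMethod("groupIds", "OrthologGroupTable",
          function(x) unique(x@members$group_id))

#' @rdname accessors
setMethod("pimValues", "PercentIdentityMatrix", function(x) x@values)

#' @rdname accessors
setMethod("pimLabels", "PercentIdentityMatrix", function(x) rownames(x@values))

setMethod("show", "ProteinSet", function(object) {
  cat("ProteinSet with", length(object), "sequences from",
      length(unique(mcols(object)$origin_file)), "file(s)\n")
  sp <- unique(stats::na.omit(mcols(object)$species_code))
  if (length(sp))
    cat("  species codes:", paste(utils::head(sp, 8), collapse = ", "),
        if (length(sp) > 8) "..." else "", "\n")
  callNextMethod()
})

setMethod("show", "OrthologGroupTable", function(object) {
  m <- object@members
  ng <- length(unique(m$group_id))
  cs <- sum(vapply(split(m$species_code, m$group_id),
                   function(s) length(unique(s)) > 1, logical(1)))
  cat("OrthologGroupTable:", nrow(m), "members in", ng, "groups",
      sprintf("(%d cross-species) over %d species\n",
              cs, length(object@speciesRoster)))
})

setMethod("show", "ProteinAlignment", function(object) {
  cat("ProteinAlignment:", length(object), "rows x",
      width(object)[1], "columns\n")
})

setMethod("show", "PercentIdentityMatrix", function(object) {
  v <- object@values
  cat("PercentIdentityMatrix:", nrow(v), "x", ncol(v), "\n")
  if (nrow(v) > 1) {
    off <- v[upper.tri(v)]
    cat(sprintf("  off-diagonal identity: %.1f - %.1f%%\n",
                min(off), max(off)))
  }
})

setMethod("show", "QueryResult", function(object) {
  cat("QueryResult:", length(object@queries), "queries,",
      length(object@orthologs), "sequences in the result set\n")
  tab <- table(object@matches$mode)
  cat("  match modes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(object@tree))
    cat("  tree:", length(object@tree$tip.label), "leaves,",
        if (ape::is.rooted(object@tree)) "rooted" else "unrooted", "\n")
})
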