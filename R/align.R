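#' @include AllClasses.R seqio.R
#' @useDynLib OrthoQuery, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct an alignment scoring scheme
#'
#' Bundles a symmetric substitution matrix with affine gap penalties.  A
#' gap of length `L` costs `gapOpen + (L - 1) * gapExtend`; terminal gaps
#' are penalized like internal ones.  The default is BLOSUM62 with gap
#' open 10 and gap extension 1, the classic protein global-alignment
#' setting.
#'
#' @param matrix a square symmetric numeric substitution matrix with
#'   residue dimnames, or the name `"BLOSUM62"`.
#' @param gapOpen non-negative cost of the first gap position.
#' @param gapExtend non-negative cost of each further gap position; must
#'   not exceed `gapOpen`.
#' @return list with elements `matrix`, `gapOpen`, `gapExtend` of class
#'   `ScoringScheme`.
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gapOpen = 10, gapExtend = 1) {
  if (is.character(matrix)) {
    name <- match.arg(matrix, c("BLOSUM62"))
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    matrix <- get(name, envir = e)
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (gapOpen < 0 || gapExtend < 0 || gapExtend > gapOpen)
    stop("need 0 <= gapExtend <= gapOpen", call. = FALSE)
  structure(list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend),
            class = "ScoringScheme")
}

.score_residues <- function(chars, scheme, what = "sequence") {
  bad <- setdiff(unique(chars), rownames(scheme$matrix))
  if (length(bad))
    stop("residue(s) absent from the substitution matrix in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment of two protein sequences under a
#' [scoringScheme()].  The traceback is deterministic: score ties prefer
#' the diagonal move, then a gap in `b`, then a gap in `a`.
#'
#' @param a,b ungapped amino-acid strings (or `AAString`s).
#' @param scheme a [scoringScheme()].
#' @return list with `a` and `b` (gapped strings of equal length) and
#'   `score` (the optimal global score).
#' @examples
#' globalAlign("MKV", "MKKV")
#' @export
globalAlign <- function(a, b, scheme = scoringScheme()) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  .score_residues(ca, scheme, "first sequence")
  .score_residues(cb, scheme, "second sequence")
  S <- scheme$matrix[ca, cb, drop = FALSE]
  res <- .nw_affine_path(S, scheme$gapOpen, scheme$gapExtend)
  ga <- ifelse(res$a_idx > 0, ca[pmax(res$a_idx, 1)], GAP_CHAR)
  gb <- ifelse(res$b_idx > 0, cb[pmax(res$b_idx, 1)], GAP_CHAR)
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = res$score)
}

#' Percent identity of one aligned pair
#'
#' Identity of two gapped rows: identical-residue columns over columns
#' where both rows carry a residue (the default denominator; see
#' [percentIdentityMatrix()] for the alternatives).
#' @noRd
.pair_identity <- function(ca, cb, denominator = "coresidue") {
  both <- ca != GAP_CHAR & cb != GAP_CHAR
  idn <- sum(ca == cb & both)
  den <- switch(denominator,
                coresidue = sum(both),
                shorter = min(sum(ca != GAP_CHAR), sum(cb != GAP_CHAR)),
                alignment = length(ca))
  if (den == 0) return(NA_real_)
  100 * idn / den
}

.profile_of <- function(mat, residues) {
  # per-column residue frequencies over non-gap residues
  freq <- matrix(0, ncol(mat), length(residues),
                 dimnames = list(NULL, residues))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col != GAP_CHAR]
    if (length(col)) {
      tab <- table(factor(col, levels = residues))
      freq[j, ] <- as.numeric(tab) / length(col)
    }
  }
  freq
}

.align_profiles <- function(m1, m2, scheme) {
  residues <- rownames(scheme$matrix)
  f1 <- .profile_of(m1, residues)
  f2 <- .profile_of(m2, residues)
  # expected substitution score between column residue distributions
  S <- f1 %*% scheme$matrix %*% t(f2)
  res <- .nw_affine_path(S, scheme$gapOpen, scheme$gapExtend)
  L <- length(res$a_idx)
  out1 <- matrix(GAP_CHAR, nrow(m1), L)
  out2 <- matrix(GAP_CHAR, nrow(m2), L)
  out1[, res$a_idx > 0] <- m1[, res$a_idx[res$a_idx > 0], drop = FALSE]
  out2[, res$b_idx > 0] <- m2[, res$b_idx[res$b_idx > 0], drop = FALSE]
  mat <- rbind(out1, out2)
  keep <- colSums(mat != GAP_CHAR) > 0
  mat[, keep, drop = FALSE]
}

#' Progressive multiple sequence alignment
#'
#' Classic progressive alignment: a neighbor-joining guide tree is built
#' from pairwise p-distances (one [globalAlign()] per pair), then profiles
#' are merged bottom-up in guide-tree order by profile-profile global
#' alignment, scoring each column pair by the expected substitution score
#' between the two column residue distributions.  Output row order equals
#' input order.
#'
#' @param x a [ProteinSet] or a named character vector of ungapped
#'   sequences (names become row labels; unnamed input is labelled
#'   `seq1..seqN`).
#' @param scheme a [scoringScheme()].
#' @return a [ProteinAlignment].
#' @export
progressiveMSA <- function(x, scheme = scoringScheme()) {
  seqs <- as.character(x)
  labs <- names(x)
  if (is.null(labs)) labs <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(labs))
    stop("sequence labels must be unique", call. = FALSE)
  names(seqs) <- labs
  k <- length(seqs)
  if (k == 0) stop("no sequences to align", call. = FALSE)
  if (any(!nzchar(seqs))) stop("sequences must be non-empty", call. = FALSE)
  if (k == 1) {
    warning("single sequence: returning a degenerate one-row alignment",
            call. = FALSE)
    out <- AAStringSet(seqs)
    return(new("ProteinAlignment", out))
  }

  mats <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1]], nrow = 1))
  if (k == 2) {
    merged <- .align_profiles(mats[[1]], mats[[2]], scheme)
    rownames(merged) <- labs
  } else {
    # guide tree from NJ on pairwise p-distances
    D <- matrix(0, k, k, dimnames = list(labs, labs))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        al <- globalAlign(seqs[i], seqs[j], scheme)
        pid <- .pair_identity(strsplit(al$a, "")[[1]],
                              strsplit(al$b, "")[[1]])
        d <- if (is.na(pid)) 1 else 1 - pid / 100
        D[i, j] <- D[j, i] <- d
      }
    }
    guide <- njTree(D)
    merged <- .merge_by_tree(guide, mats, labs, scheme)
  }
  merged <- merged[labs, , drop = FALSE]   # restore input order
  rows <- apply(merged, 1, paste, collapse = "")
  out <- AAStringSet(rows)
  names(out) <- labs
  new("ProteinAlignment", out)
}

.merge_by_tree <- function(guide, mats, labs, scheme) {
  n <- length(guide$tip.label)
  kids <- split(guide$edge[, 2], guide$edge[, 1])
  rec <- function(node) {
    if (node <= n) {
      m <- mats[[match(guide$tip.label[node], labs)]]
      rownames(m) <- guide$tip.label[node]
      return(m)
    }
    parts <- lapply(kids[[as.character(node)]], rec)
    Reduce(function(a, b) {
      rn <- c(rownames(a), rownames(b))
      m <- .align_profiles(a, b, scheme)
      rownames(m) <- rn
      m
    }, parts)
  }
  rec(n + 1L)
}

#' Percent identity matrix of a multiple alignment
#'
#' For every row pair, the percentage of alignment columns with identical
#' residues.  The denominator is configurable because conventions differ:
#'
#' * `"coresidue"` (default): columns where both rows carry a residue;
#'   identical sequences score exactly 100 regardless of gaps induced by
#'   other rows.
#' * `"shorter"`: the shorter ungapped sequence length.
#' * `"alignment"`: the full alignment width.
#'
#' Pairs with no co-residue column score 0 with a warning.
#'
#' @param msa a [ProteinAlignment].
#' @param denominator one of `"coresidue"`, `"shorter"`, `"alignment"`.
#' @return a [PercentIdentityMatrix].
#' @export
percentIdentityMatrix <- function(msa,
                                  denominator = c("coresidue", "shorter",
                                                  "alignment")) {
  denominator <- match.arg(denominator)
  stopifnot(is(msa, "ProteinAlignment"))
  mat <- do.call(rbind, strsplit(as.character(msa), ""))
  labs <- names(msa)
  k <- nrow(mat)
  v <- matrix(100, k, k, dimnames = list(labs, labs))
  if (k > 1) {
    warned <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        pid <- .pair_identity(mat[i, ], mat[j, ], denominator)
        if (is.na(pid)) {
          if (!warned) {
            warning("pair(s) with no co-residue columns score 0",
                    call. = FALSE)
            warned <- TRUE
          }
          pid <- 0
        }
        v[i, j] <- v[j, i] <- pid
      }
    }
  }
  new("PercentIdentityMatrix", values = v)
}
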