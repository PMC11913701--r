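#' @include AllClasses.R
#' @importFrom ape is.rooted
NULL

#' Distance matrix from a percent identity matrix
#'
#' Converts percent identity to evolutionary distance.  The default is the
#' simple p-distance `d = 1 - pim/100`; a Kimura-style correction for
#' multiple substitutions, `d = -log(1 - p - 0.2 p^2)`, is available but
#' off by default.
#'
#' @param pim a [PercentIdentityMatrix].
#' @param correction `"none"` (p-distance, default) or `"kimura"`.
#' @return square symmetric numeric matrix with zero diagonal.
#' @export
distanceFromPIM <- function(pim, correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  d <- 1 - pimValues(pim) / 100
  if (correction == "kimura") {
    p <- pmin(d, 0.85)   # correction diverges as p -> ~0.854
    d <- -log(1 - p - 0.2 * p^2)
  }
  diag(d) <- 0
  d
}

.check_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry identical row/column labels",
         call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  invisible(TRUE)
}

# Renumber arbitrary integer node ids into ape's phylo convention
# (tips 1..n, root n+1, internal nodes in preorder) and emit a cladewise
# edge matrix.  `edges` is a data.frame(parent, child, length) where child
# ids 1..n are the tips matching tip_labels.
.build_phylo <- function(edges, tip_labels, root) {
  n <- length(tip_labels)
  maxid <- max(edges$parent, edges$child, n)
  newnum <- integer(maxid)
  newnum[seq_len(n)] <- seq_len(n)
  counter <- n
  out_p <- integer(0); out_c <- integer(0); out_l <- numeric(0)
  by_parent <- split(seq_len(nrow(edges)), edges$parent)
  visit <- function(old) {
    if (newnum[old] == 0L) {
      counter <<- counter + 1L
      newnum[old] <<- counter
    }
    me <- newnum[old]
    for (e in by_parent[[as.character(old)]]) {
      child <- edges$child[e]
      if (child > n && newnum[child] == 0L) {
        counter <<- counter + 1L
        newnum[child] <<- counter
      }
      out_p <<- c(out_p, me)
      out_c <<- c(out_c, newnum[child])
      out_l <<- c(out_l, edges$length[e])
      if (child > n) visit(child)
    }
  }
  visit(root)
  phy <- list(edge = cbind(out_p, out_c), edge.length = out_l,
              tip.label = tip_labels, Nnode = counter - n)
  dimnames(phy$edge) <- NULL
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining: iteratively join the pair that
#' minimizes the Q-criterion, with branch lengths from the standard
#' two-point formulas.  Q ties are broken by the lowest (row, column)
#' index pair, so the result is bitwise reproducible.  Negative branch
#' lengths are clamped to zero with the deficit transferred to the sibling
#' edge, keeping the joined pair's summed length equal to their distance.
#' The result is unrooted, represented with a trifurcating top node (a
#' single edge for two taxa).
#'
#' @param d labelled square symmetric non-negative matrix with zero
#'   diagonal, size >= 2.
#' @return an unrooted `phylo` tree whose leaves are the matrix labels.
#' @export
njTree <- function(d) {
  .check_dist(d)
  n <- nrow(d)
  labs <- rownames(d)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2) {
    edges <- data.frame(parent = c(3L, 3L), child = c(1L, 2L),
                        length = rep(d[1, 2] / 2, 2))
    return(.build_phylo(edges, labs, root = 3L))
  }

  active <- seq_len(n)          # node ids of live clusters
  D <- d
  dimnames(D) <- NULL
  nextid <- n
  ep <- integer(0); ec <- integer(0); el <- numeric(0)

  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (i, j), i < j, among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    nextid <- nextid + 1L
    ep <- c(ep, nextid, nextid)
    ec <- c(ec, active[i], active[j])
    el <- c(el, li, lj)

    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newd <- pmax(newd[-c(i, j)], 0)
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    active <- c(active[-c(i, j)], nextid)
  }

  # join the final three clusters at a trifurcating node
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nextid <- nextid + 1L
  ep <- c(ep, rep(nextid, 3))
  ec <- c(ec, active)
  el <- c(el, pmax(c(lx, ly, lz), 0))

  edges <- data.frame(parent = ep, child = ec, length = el)
  .build_phylo(edges, labs, root = nextid)
}

# undirected adjacency list of a phylo: for each node, (neighbor, length)
.adjacency <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]; l <- phy$edge.length[e]
    adj[[p]] <- rbind(adj[[p]], c(c, l))
    adj[[c]] <- rbind(adj[[c]], c(p, l))
  }
  adj
}

# orient an undirected adjacency from `root`, suppressing internal nodes
# left with a single child (merging their edge lengths)
.orient <- function(adj, root, ntips) {
  ep <- integer(0); ec <- integer(0); el <- numeric(0)
  # adj_parent: neighbor we came from; attach: ancestor the emitted edge
  # hangs off (differs from adj_parent across spliced degree-2 nodes)
  emit <- function(node, adj_parent, attach, carried) {
    nb <- adj[[node]]
    sel <- nb[, 1] != adj_parent
    kids <- nb[sel, 1]
    lens <- nb[sel, 2]
    if (node > ntips && length(kids) == 1) {
      # degree-2 internal node: splice out, merging edge lengths
      emit(kids[1], node, attach, carried + lens[1])
      return(invisible(NULL))
    }
    ep <<- c(ep, attach); ec <<- c(ec, node); el <<- c(el, carried)
    for (k in seq_along(kids)) emit(kids[k], node, node, lens[k])
  }
  # the root itself may legitimately have degree 2 (a rooted root)
  nb <- adj[[root]]
  for (k in seq_len(nrow(nb)))
    emit(nb[k, 1], root, root, nb[k, 2])
  data.frame(parent = ep, child = ec, length = el)
}

.tip_distances <- function(phy) {
  # leaf-to-leaf path lengths via accumulated depths (cophenetic)
  stats::cophenetic(phy)
}

#' Midpoint rooting
#'
#' Roots an unrooted tree at the midpoint of the path between its two most
#' distant leaves, equidistant from both; if the midpoint falls exactly on
#' an internal node the tree is rooted there.  Total branch length is
#' conserved.  Ties for the most distant pair are broken by alphabetical
#' leaf labels so the result is deterministic.
#'
#' @param phy a `phylo` tree with non-negative branch lengths and >= 2
#'   leaves.
#' @return a rooted `phylo` tree.
#' @export
midpointRoot <- function(phy) {
  ntips <- length(phy$tip.label)
  if (ntips < 2) stop("need at least 2 leaves to midpoint-root",
                      call. = FALSE)
  if (any(phy$edge.length < 0))
    stop("branch lengths must be non-negative", call. = FALSE)
  D <- .tip_distances(phy)
  dmax <- max(D)
  pairs <- which(D == dmax, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  la <- rownames(D)[pairs[, 1]]
  lb <- colnames(D)[pairs[, 2]]
  ord <- order(pmin(la, lb), pmax(la, lb))
  a <- match(la[ord[1]], phy$tip.label)
  b <- match(lb[ord[1]], phy$tip.label)

  path <- ape::nodepath(phy, a, b)
  # edge lengths along the path
  key <- paste(pmin(phy$edge[, 1], phy$edge[, 2]),
               pmax(phy$edge[, 1], phy$edge[, 2]))
  elen <- stats::setNames(phy$edge.length, key)
  seglen <- vapply(seq_len(length(path) - 1), function(k) {
    elen[[paste(min(path[k], path[k + 1]), max(path[k], path[k + 1]))]]
  }, 0)
  target <- dmax / 2
  cum <- c(0, cumsum(seglen))
  k <- max(which(cum <= target + 1e-12))
  k <- min(k, length(seglen))
  u <- path[k]; v <- path[k + 1]
  pos <- target - cum[k]           # distance from u along edge (u, v)
  ulen <- seglen[k]

  adj <- .adjacency(phy)
  eps <- 1e-12
  if (pos <= eps && u > ntips) {
    root <- u
  } else if (pos >= ulen - eps && v > ntips) {
    root <- v
  } else {
    # split edge (u, v) at pos from u with a new root node
    root <- length(adj) + 1L
    drop_uv <- function(node, other) {
      nb <- adj[[node]]
      hit <- which(nb[, 1] == other)[1]
      adj[[node]] <<- nb[-hit, , drop = FALSE]
    }
    drop_uv(u, v); drop_uv(v, u)
    adj[[root]] <- rbind(c(u, pos), c(v, ulen - pos))
    adj[[u]] <- rbind(adj[[u]], c(root, pos))
    adj[[v]] <- rbind(adj[[v]], c(root, ulen - pos))
  }
  edges <- .orient(adj, root, ntips)
  # .build_phylo renumbers the (possibly sparse) node ids
  .build_phylo(edges, phy$tip.label, root = root)
}

.newick_reserved <- "][(){},;:'\"|[:space:]"

.quote_label <- function(x) {
  needs <- grepl(paste0("[", .newick_reserved, "]"), x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs], fixed = TRUE), "'")
  x
}

#' Serialize a tree to Newick
#'
#' Writes standard Newick with branch lengths (6 significant digits).
#' Labels containing reserved characters (parentheses, brackets, commas,
#' colons, semicolons, quotes, pipes or whitespace) are single-quoted with
#' internal quotes doubled, so pipe-delimited sequence labels survive the
#' round trip.
#'
#' @param phy a `phylo` tree.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string ending in `;`.
#' @export
toNewick <- function(phy, digits = 6) {
  n <- length(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    if (is.null(es)) return(.quote_label(phy$tip.label[node]))
    inner <- vapply(es, function(e)
      paste0(rec(phy$edge[e, 2]), ":", fmt(phy$edge.length[e])), "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(rec(n + 1L), ";")
}

#' Parse a Newick string
#'
#' Recursive-descent parser for Newick trees with branch lengths and
#' single-quoted labels.  Malformed input (unbalanced parentheses,
#' dangling commas, trailing garbage) raises an error naming the character
#' position.  Missing branch lengths default to 0.
#'
#' @param text a Newick string.
#' @return a `phylo` tree.
#' @export
fromNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- strsplit(text, "")[[1]]
  pos <- 1L
  fail <- function(msg, at = pos)
    stop("Newick parse error at position ", at, ": ", msg, call. = FALSE)
  peek <- function() if (pos <= length(s)) s[pos] else ""
  advance <- function() pos <<- pos + 1L
  skip_ws <- function() while (pos <= length(s) && grepl("\\s", s[pos]))
    advance()

  tip_labels <- character(0)
  edges <- list(parent = integer(0), child = integer(0), length = numeric(0))
  next_internal <- 0L   # internal nodes get negative ids, remapped later

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      advance()
      out <- character(0)
      repeat {
        if (pos > length(s)) fail("unterminated quoted label")
        ch <- s[pos]
        if (ch == "'") {
          if (pos + 1 <= length(s) && s[pos + 1] == "'") {
            out <- c(out, "'"); pos <<- pos + 2L
          } else { advance(); break }
        } else { out <- c(out, ch); advance() }
      }
      return(paste(out, collapse = ""))
    }
    out <- character(0)
    while (pos <= length(s) && !s[pos] %in% c("(", ")", ",", ":", ";")) {
      out <- c(out, s[pos]); advance()
    }
    paste(trimws(paste(out, collapse = "")), collapse = "")
  }

  read_length <- function() {
    skip_ws()
    if (peek() != ":") return(0)
    advance()
    skip_ws()
    start <- pos
    while (pos <= length(s) &&
           grepl("[-+0-9.eE]", s[pos])) advance()
    if (pos == start) fail("expected a branch length after ':'")
    val <- suppressWarnings(as.numeric(paste(s[start:(pos - 1)],
                                             collapse = "")))
    if (is.na(val)) fail("invalid branch length", start)
    val
  }

  read_subtree <- function() {
    skip_ws()
    if (peek() == "(") {
      open_at <- pos
      advance()
      next_internal <<- next_internal - 1L
      me <- next_internal
      repeat {
        skip_ws()
        if (peek() %in% c(",", ")"))
          fail("dangling comma or empty subtree")
        child <- read_subtree()
        len <- read_length()
        edges$parent <<- c(edges$parent, me)
        edges$child <<- c(edges$child, child)
        edges$length <<- c(edges$length, len)
        skip_ws()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        fail(paste0("unbalanced parenthesis opened at position ", open_at))
      }
      read_label()   # internal labels parsed and discarded
      return(me)
    }
    lab <- read_label()
    if (!nzchar(lab)) fail("expected a leaf label")
    tip_labels <<- c(tip_labels, lab)
    length(tip_labels)
  }

  root <- read_subtree()
  read_length()
  skip_ws()
  if (peek() != ";") fail("expected ';' at end of tree")
  advance()
  skip_ws()
  if (pos <= length(s)) fail("trailing characters after ';'")
  if (root > 0) fail("tree must contain at least one internal node", 1L)
  if (anyDuplicated(tip_labels))
    fail("duplicate leaf labels", 1L)

  n <- length(tip_labels)
  remap <- function(id) ifelse(id < 0, n - id, id)
  df <- data.frame(parent = remap(edges$parent),
                   child = remap(edges$child),
                   length = edges$length)
  .build_phylo(df, tip_labels, root = remap(root))
}
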