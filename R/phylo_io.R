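# Conversion between the internal graph and ape's phylo, plus Newick I/O.
#
# Parsing goes through ape::read.tree. Serialization is done here so that
# output is canonical: at every node children are ordered by their smallest
# descendant taxon, which makes write_newick() deterministic down to the
# byte for a given topology regardless of input rotation.

g_from_phylo <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object", call. = FALSE)
  ntip <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  nnode <- phy$Nnode
  g <- g_new()
  g$adj <- vector("list", ntip + nnode)
  for (i in seq_len(ntip + nnode)) g$adj[[i]] <- integer(0)
  g$lab <- c(phy$tip.label, rep(NA_character_, nnode))
  g$alive <- rep(TRUE, ntip + nnode)
  has_len <- !is.null(phy$edge.length)
  for (r in seq_len(nrow(phy$edge))) {
    len <- if (has_len) phy$edge.length[r] else NA_real_
    g <- g_add_edge(g, phy$edge[r, 1L], phy$edge[r, 2L], len)
  }
  g_suppress_degree2(g)
}

# Build a phylo whose edge matrix lists children in canonical order
# (smallest descendant taxon first), so ape operations on it are
# reproducible. Root: the internal node adjacent to the pendant edge of
# the overall smallest taxon; trees with < 3 leaves are special-cased.
g_to_phylo <- function(g) {
  leaves <- g_leaves(g)
  nl <- length(leaves)
  if (nl == 0L) stop("tree has no leaves", call. = FALSE)
  labs <- g$lab[leaves]
  if (nl == 1L) {
    return(structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = labs, Nnode = 1L),
      class = "phylo", order = "cladewise"))
  }
  ord <- order(labs, method = "radix")
  leaves <- leaves[ord]
  labs <- labs[ord]
  rank <- integer(length(g$adj))
  rank[leaves] <- seq_len(nl)

  rt <- g_rooted(g, root = g$adj[[leaves[1L]]][1L])
  mr <- g_min_ranks(g, rt)

  # assign phylo ids: tips 1..nl in label order, internals nl+1, ...
  pid <- integer(length(g$adj))
  pid[leaves] <- seq_len(nl)
  next_id <- nl + 1L

  from <- integer(0); to <- integer(0); elen <- numeric(0)
  has_any_len <- !is.null(g$elen) && length(g$elen) > 0L
  # iterative preorder with canonical child ordering
  if (is.na(g$lab[rt$root])) {
    pid[rt$root] <- next_id; next_id <- next_id + 1L
    stack <- rt$root
  } else {
    # 2-leaf tree (single edge): emulate a root of degree 2
    a <- leaves[1L]; b <- leaves[2L]
    len <- g_edge_len(g, a, b)
    edge <- matrix(c(3L, 3L, 1L, 2L), 2L, 2L)
    res <- list(edge = edge, tip.label = labs, Nnode = 1L)
    if (!is.na(len)) res$edge.length <- c(len / 2, len / 2)
    return(structure(res, class = "phylo", order = "cladewise"))
  }
  nnode_count <- 1L
  # DFS emitting edges in cladewise order; stack holds c(parent, node)
  stack <- list()
  kids0 <- g$adj[[rt$root]]
  kids0 <- kids0[order(mr$minbelow[kids0], method = "radix")]
  for (u in rev(kids0)) stack[[length(stack) + 1L]] <- c(rt$root, u)
  while (length(stack) > 0L) {
    pv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- pv[1L]; u <- pv[2L]
    if (is.na(g$lab[u])) {
      pid[u] <- next_id; next_id <- next_id + 1L
      nnode_count <- nnode_count + 1L
    }
    from <- c(from, pid[v]); to <- c(to, pid[u])
    elen <- c(elen, g_edge_len(g, v, u))
    if (is.na(g$lab[u])) {
      kids <- g$adj[[u]][g$adj[[u]] != v]
      kids <- kids[order(mr$minbelow[kids], method = "radix")]
      for (w in rev(kids)) stack[[length(stack) + 1L]] <- c(u, w)
    }
  }
  res <- list(edge = cbind(from, to), tip.label = labs, Nnode = nnode_count)
  if (has_any_len) res$edge.length <- elen
  structure(res, class = "phylo")
}

needs_quoting <- function(x) !grepl("^[A-Za-z0-9_.+-]+$", x)

quote_label <- function(x) {
  bad <- needs_quoting(x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

fmt_len <- function(len) {
  if (is.na(len)) "" else paste0(":", format(len, digits = 15, scientific = FALSE, trim = TRUE))
}

# Canonical newick text for a graph; children ordered by smallest
# descendant taxon, NA branch lengths omitted.
g_write_newick <- function(g) {
  leaves <- g_leaves(g)
  nl <- length(leaves)
  if (nl == 0L) stop("tree has no leaves", call. = FALSE)
  labs <- g$lab[leaves]
  if (nl == 1L) return(paste0("(", quote_label(labs), ");"))
  ord <- order(labs, method = "radix")
  leaves <- leaves[ord]
  if (nl == 2L) {
    a <- leaves[1L]; b <- leaves[2L]
    len <- g_edge_len(g, a, b)
    return(paste0("(", quote_label(g$lab[a]), ",",
                  quote_label(g$lab[b]), fmt_len(len), ");"))
  }
  root <- g$adj[[leaves[1L]]][1L]
  rt <- g_rooted(g, root = root)
  mr <- g_min_ranks(g, rt)
  # iterative postorder rendering
  txt <- character(length(g$adj))
  for (v in rev(rt$order)) {
    if (!is.na(g$lab[v])) {
      txt[v] <- quote_label(g$lab[v])
    } else {
      kids <- g$adj[[v]][g$adj[[v]] != rt$parent[v]]
      kids <- kids[order(mr$minbelow[kids], method = "radix")]
      parts <- vapply(kids, function(u) paste0(txt[u], fmt_len(g_edge_len(g, v, u))),
                      character(1))
      txt[v] <- paste0("(", paste(parts, collapse = ","), ")")
    }
  }
  paste0(txt[root], ";")
}

#' Parse a Newick string into an unrooted tree
#'
#' Reads standard Newick (quoted labels, optional branch lengths and
#' internal labels) via \code{\link[ape]{read.tree}} and returns an
#' unrooted \code{phylo}: a degree-2 root is suppressed, internal
#' degree-2 nodes are fused, and leaf labels are checked for uniqueness.
#' Internal node labels are topologically inert and dropped.
#'
#' @param text a single Newick string, terminated by \code{";"}.
#' @return an unrooted \code{phylo} object in canonical child order.
#' @examples
#' parse_newick("(a,(b,c));")   # 3-leaf star once unrooted
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string", call. = FALSE)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed newick: ", text, call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  # ape keeps the surrounding quotes of quoted labels; strip and unescape
  quoted <- grepl("^'.*'$", phy$tip.label)
  if (any(quoted)) {
    phy$tip.label[quoted] <-
      gsub("''", "'", sub("^'(.*)'$", "\\1", phy$tip.label[quoted]))
  }
  g_to_phylo(g_from_phylo(phy))
}

#' Write a tree as canonical Newick
#'
#' Serializes an unrooted tree deterministically: at every node children
#' are ordered by their smallest descendant taxon, and the tree is
#' rendered rooted at the internal node adjacent to the overall smallest
#' taxon. Re-parsing the output yields the identical bipartition set.
#' Branch lengths are carried through where present; edges created by
#' tree surgery carry none and are written without one.
#'
#' @param t a \code{phylo} object.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when \code{file} is given.
#' @examples
#' write_newick(parse_newick("((c,b),a);"))  # "(a,b,c);"
#' @export
write_newick <- function(t, file = NULL) {
  s <- g_write_newick(as_graph(t))
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read one or more Newick trees from a file
#'
#' One tree per line; blank lines ignored.
#'
#' @param file path to a Newick file.
#' @return a single \code{phylo} if the file holds one tree, otherwise a
#'   list of \code{phylo} objects.
#' @export
read_newick <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no trees in ", file, call. = FALSE)
  trees <- lapply(lines, parse_newick)
  if (length(trees) == 1L) trees[[1L]] else trees
}

# Accept either a phylo or an internal graph at function boundaries.
as_graph <- function(t) {
  if (inherits(t, "phylo")) g_from_phylo(t) else t
}
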