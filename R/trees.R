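# User-facing tree operations: restriction, edge collapse, disjoint join.

#' Leafset of a tree
#'
#' @param t a \code{phylo} object.
#' @return sorted character vector of taxon names.
#' @export
leafset <- function(t) {
  if (inherits(t, "phylo")) sort.int(t$tip.label, method = "radix")
  else g_leafset(t)
}

#' Homeomorphic restriction of a tree to a taxon subset
#'
#' Returns the subtree induced by \code{taxa} with all degree-2 nodes
#' suppressed, so that every nontrivial split of the result is the
#' restriction of a split of \code{t}. Branch lengths, where present,
#' are summed across suppressed nodes (via \code{\link[ape]{keep.tip}}).
#'
#' @param t a \code{phylo} object.
#' @param taxa character vector, a nonempty subset of \code{leafset(t)}.
#' @return a \code{phylo} on \code{taxa}, in canonical order.
#' @examples
#' cat8 <- parse_newick("(1,(2,(3,(4,(5,(6,(7,8)))))));")
#' write_newick(restrict(cat8, c("1", "5", "6", "7")))  # "(1,(5,(6,7)));"
#' @export
restrict <- function(t, taxa) {
  stopifnot(inherits(t, "phylo"), is.character(taxa))
  taxa <- unique(taxa)
  missing <- setdiff(taxa, t$tip.label)
  if (length(missing) > 0L) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(taxa) == 0L) stop("empty taxon set", call. = FALSE)
  if (length(taxa) == 1L) {
    return(structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = taxa, Nnode = 1L),
      class = "phylo", order = "cladewise"))
  }
  if (length(taxa) == length(t$tip.label)) return(g_to_phylo(as_graph(t)))
  kept <- ape::keep.tip(t, taxa)
  g_to_phylo(g_from_phylo(kept))
}

# Locate the edges of g matching each split in `splits` (list of character
# vectors, each one side of a split over g's full leafset). Returns an
# edge matrix aligned with splits; errors identify the offender.
g_match_splits <- function(g, splits) {
  taxa <- g_leafset(g)
  keys <- g_split_keys(g, include_trivial = TRUE)
  em <- attr(keys, "edges")
  nl <- length(taxa)
  out <- matrix(integer(0), 0L, 2L)
  for (s in splits) {
    s <- unique(as.character(s))
    bad <- setdiff(s, taxa)
    if (length(bad) > 0L) {
      stop("split names taxa not in tree: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    ranks <- match(s, taxa)
    key <- key_from_ranks(ranks, taxa)
    hit <- which(keys == key)
    if (length(hit) == 0L) {
      stop("no edge induces the split {", paste(s, collapse = ","), "} | rest",
           call. = FALSE)
    }
    out <- rbind(out, em[hit[1L], , drop = FALSE])
  }
  out
}

#' Collapse internal edges of a tree
#'
#' Removes the internal edges inducing the given splits, merging their
#' endpoints (creating polytomies). The leafset is unchanged and the
#' split set of the result is exactly the input's minus the collapsed
#' splits.
#'
#' @param t a \code{phylo} object.
#' @param splits a list of character vectors, each naming one side of a
#'   nontrivial split of \code{t} (a single character vector is treated
#'   as one split).
#' @return a \code{phylo}, possibly multifurcating.
#' @export
collapse_splits <- function(t, splits) {
  if (is.character(splits)) splits <- list(splits)
  g <- as_graph(t)
  if (length(splits) == 0L) return(g_to_phylo(g))
  nl <- g_n_leaves(g)
  taxa <- g_leafset(g)
  for (s in splits) {
    sz <- length(unique(s))
    if (min(sz, nl - sz) <= 1L) {
      stop("cannot collapse a trivial (pendant) split", call. = FALSE)
    }
  }
  em <- g_match_splits(g, splits)
  g_to_phylo(g_collapse_edges(g, em))
}

# --- disjoint join ---------------------------------------------------------

# Disjoint union of two graphs; returns the combined graph and the node-id
# offset applied to g2.
g_union <- function(g1, g2) {
  off <- length(g1$adj)
  g <- g1
  g$adj <- c(g1$adj, lapply(g2$adj, function(v) v + off))
  g$lab <- c(g1$lab, g2$lab)
  g$alive <- c(g1$alive, g2$alive)
  if (!is.null(g2$elen) && length(g2$elen) > 0L) {
    parts <- strsplit(names(g2$elen), "|", fixed = TRUE)
    nm <- vapply(parts, function(p) {
      ekey(as.integer(p[1L]) + off, as.integer(p[2L]) + off)
    }, character(1))
    e2 <- g2$elen
    names(e2) <- nm
    g$elen <- c(g1$elen, e2)
  }
  list(g = g, off = off)
}

# Subdivide edge (i, j) with a fresh node; both halves lose any length
# (new edges are purely topological). Returns list(g, id).
g_subdivide <- function(g, i, j) {
  g <- g_del_edge(g, i, j)
  an <- g_add_node(g)
  g <- an$g
  g <- g_add_edge(g, i, an$id)
  g <- g_add_edge(g, an$id, j)
  list(g = g, id = an$id)
}

# Join two disjoint graphs with a new edge. site1/site2: an edge c(i, j)
# to subdivide, or a single node id for vertex attachment (single-node
# components). Node ids of g2 are interpreted pre-offset.
g_join_at <- function(g1, site1, g2, site2) {
  u <- g_union(g1, g2)
  g <- u$g
  attach_pt <- function(g, site) {
    if (length(site) == 2L) {
      sd <- g_subdivide(g, site[1L], site[2L])
      list(g = sd$g, id = sd$id)
    } else {
      list(g = g, id = site)
    }
  }
  p1 <- attach_pt(g, site1)
  g <- p1$g
  site2 <- site2 + u$off
  p2 <- attach_pt(g, site2)
  g <- p2$g
  g_add_edge(g, p1$id, p2$id)
}

# Resolve a user-level attachment designation within graph g: NULL picks
# the sole vertex (single-node tree) or the unique edge; a character
# vector names one side of the (possibly trivial) split of the edge.
g_resolve_site <- function(g, at, what = "tree") {
  nl <- g_n_leaves(g)
  if (is.null(at)) {
    if (nl == 1L) return(g_leaves(g))
    ne <- g_n_edges(g)
    if (ne == 1L) {
      em <- g_edges(g)
      return(as.integer(em[1L, ]))
    }
    stop("attachment site required for a ", what, " with more than one edge",
         call. = FALSE)
  }
  if (nl == 1L) stop("single-node ", what, " has no edges", call. = FALSE)
  em <- g_match_splits(g, list(at))
  as.integer(em[1L, ])
}

#' Join two leaf-disjoint trees with a new edge
#'
#' Subdivides one edge in each tree (creating two new internal nodes) and
#' connects the new nodes, producing a tree on the union of the leafsets
#' whose restriction to either input leafset reproduces that input
#' exactly. Single-node trees attach directly at their vertex.
#'
#' @param t1,t2 \code{phylo} objects on disjoint leafsets.
#' @param at1,at2 attachment edges, each named by a character vector
#'   giving one side of the split the edge induces in its tree (a single
#'   taxon for a pendant edge). \code{NULL} selects the unique edge of a
#'   one-edge tree or the vertex of a single-node tree.
#' @return a \code{phylo} on \code{union(leafset(t1), leafset(t2))}.
#' @examples
#' q1 <- parse_newick("(a,b);"); q2 <- parse_newick("(c,d);")
#' write_newick(join_trees(q1, q2))   # "((a,b),(c,d)) as an unrooted quartet"
#' @export
join_trees <- function(t1, t2, at1 = NULL, at2 = NULL) {
  g1 <- as_graph(t1); g2 <- as_graph(t2)
  shared <- intersect(g_leafset(g1), g_leafset(g2))
  if (length(shared) > 0L) {
    stop("leafsets overlap: ", paste(shared, collapse = ", "), call. = FALSE)
  }
  s1 <- g_resolve_site(g1, at1, "t1")
  s2 <- g_resolve_site(g2, at2, "t2")
  g_to_phylo(g_join_at(g1, s1, g2, s2))
}
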