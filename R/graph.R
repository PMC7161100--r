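# Internal adjacency-list representation of an unrooted leaf-labeled tree.
#
# A graph `g` is a plain list:
#   adj   - list of integer vectors, adj[[i]] = neighbors of node i
#   lab   - character vector, taxon name for leaves, NA for internal nodes
#   alive - logical vector; dead slots are left behind by surgery
#   elen  - named numeric vector of branch lengths keyed "i|j" with i < j,
#           or NULL when the tree carries no lengths; edges created by
#           surgery have no entry and are written without a length.
#
# All topological work in the package happens on this structure; `phylo`
# objects appear only at the API boundary (see phylo_io.R).

g_new <- function() {
  list(adj = list(), lab = character(0), alive = logical(0), elen = NULL)
}

g_add_node <- function(g, label = NA_character_) {
  i <- length(g$adj) + 1L
  g$adj[[i]] <- integer(0)
  g$lab[i] <- label
  g$alive[i] <- TRUE
  list(g = g, id = i)
}

ekey <- function(i, j) {
  if (i < j) paste0(i, "|", j) else paste0(j, "|", i)
}

g_add_edge <- function(g, i, j, len = NA_real_) {
  g$adj[[i]] <- c(g$adj[[i]], j)
  g$adj[[j]] <- c(g$adj[[j]], i)
  if (!is.na(len)) g$elen[ekey(i, j)] <- len
  g
}

g_del_edge <- function(g, i, j) {
  g$adj[[i]] <- g$adj[[i]][g$adj[[i]] != j]
  g$adj[[j]] <- g$adj[[j]][g$adj[[j]] != i]
  if (!is.null(g$elen)) g$elen <- g$elen[names(g$elen) != ekey(i, j)]
  g
}

g_edge_len <- function(g, i, j) {
  if (is.null(g$elen)) return(NA_real_)
  v <- g$elen[ekey(i, j)]
  if (length(v) == 0L || is.na(names(v))) NA_real_ else unname(v)
}

g_nodes <- function(g) which(g$alive)

g_leaves <- function(g) which(g$alive & !is.na(g$lab))

g_leafset <- function(g) {
  sort.int(g$lab[g_leaves(g)], method = "radix")
}

g_n_leaves <- function(g) sum(g$alive & !is.na(g$lab))

g_degree <- function(g, i) length(g$adj[[i]])

# Edge matrix (each undirected edge once, i < j), over alive nodes.
g_edges <- function(g) {
  ii <- g_nodes(g)
  from <- rep.int(ii, lengths(g$adj[ii]))
  to <- unlist(g$adj[ii], use.names = FALSE)
  if (length(from) == 0L) return(matrix(integer(0), 0L, 2L))
  keep <- from < to
  cbind(from[keep], to[keep])
}

g_n_edges <- function(g) {
  ii <- g_nodes(g)
  sum(lengths(g$adj[ii])) %/% 2L
}

# Suppress alive internal degree-2 nodes, fusing their two incident edges.
# Branch lengths are summed when both halves carry one, dropped otherwise
# (same convention as ape's collapse.singles).
g_suppress_degree2 <- function(g) {
  repeat {
    cand <- which(g$alive & is.na(g$lab) & lengths(g$adj) == 2L)
    if (length(cand) == 0L) break
    v <- cand[1L]
    ab <- g$adj[[v]]
    a <- ab[1L]; b <- ab[2L]
    la <- g_edge_len(g, a, v); lb <- g_edge_len(g, v, b)
    g <- g_del_edge(g, a, v)
    g <- g_del_edge(g, v, b)
    g$alive[v] <- FALSE
    newlen <- if (!is.na(la) && !is.na(lb)) la + lb else NA_real_
    g <- g_add_edge(g, a, b, newlen)
  }
  g
}

# Delete edge (i, j) and return the two component graphs (same node id
# space; the side not reached is marked dead).
g_split_components <- function(g, i, j) {
  g <- g_del_edge(g, i, j)
  side_i <- g_reachable(g, i)
  g1 <- g
  g1$alive <- g$alive & side_i
  g2 <- g
  g2$alive <- g$alive & !side_i
  # drop lengths that belong to the other side so each half is standalone
  list(g1, g2)
}

# Logical vector: nodes reachable from `start` (iterative BFS).
g_reachable <- function(g, start) {
  seen <- logical(length(g$adj))
  queue <- integer(length(g$adj))
  queue[1L] <- start
  head <- 1L; tail <- 1L
  seen[start] <- TRUE
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (u in g$adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        tail <- tail + 1L
        queue[tail] <- u
      }
    }
  }
  seen
}

# Collapse a set of edges simultaneously (union-find over endpoints, then
# adjacency rebuilt through the representatives). Collapsed bipartitions
# disappear; all other edges, and their lengths, survive.
g_collapse_edges <- function(g, em) {
  if (nrow(em) == 0L) return(g)
  n <- length(g$adj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(em))) {
    a <- find(em[r, 1L]); b <- find(em[r, 2L])
    if (a != b) parent[b] <- a
  }
  all_em <- g_edges(g)
  keep <- logical(nrow(all_em))
  new_from <- integer(nrow(all_em)); new_to <- integer(nrow(all_em))
  for (r in seq_len(nrow(all_em))) {
    a <- find(all_em[r, 1L]); b <- find(all_em[r, 2L])
    if (a != b) {
      keep[r] <- TRUE
      new_from[r] <- a; new_to[r] <- b
    }
  }
  g2 <- g
  g2$adj <- vector("list", n)
  for (i in seq_len(n)) g2$adj[[i]] <- integer(0)
  g2$elen <- NULL
  for (r in which(keep)) {
    len <- g_edge_len(g, all_em[r, 1L], all_em[r, 2L])
    g2 <- g_add_edge(g2, new_from[r], new_to[r], len)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  g2$alive <- g$alive & (roots == seq_len(n))
  # a leaf merged into an internal node keeps its label only if it was
  # the representative; collapsing never merges two leaves (internal
  # edges only), and a leaf is never an endpoint of an internal edge.
  g2
}

# Rooted scaffolding for one traversal: BFS order, parent pointers.
# Root defaults to the lowest-id alive internal node (or lowest-id node).
g_rooted <- function(g, root = NULL) {
  alive <- g_nodes(g)
  if (is.null(root)) {
    internal <- alive[is.na(g$lab[alive])]
    root <- if (length(internal) > 0L) internal[1L] else alive[1L]
  }
  n <- length(g$adj)
  parent <- integer(n)
  order <- integer(length(alive))
  seen <- logical(n)
  order[1L] <- root; seen[root] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order[head]; head <- head + 1L
    for (u in g$adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        tail <- tail + 1L
        order[tail] <- u
      }
    }
  }
  list(root = root, order = order[seq_len(tail)], parent = parent)
}

# Leaf sets below every non-root node, as integer ranks into the sorted
# leafset. Returns list(taxa, below) where below[[v]] is the rank set of
# leaves in the subtree rooted at v (relative to `rt`). O(n^2) total.
g_below_sets <- function(g, rt = NULL) {
  if (is.null(rt)) rt <- g_rooted(g)
  taxa <- g_leafset(g)
  rank <- seq_along(taxa)
  names(rank) <- taxa
  n <- length(g$adj)
  below <- vector("list", n)
  for (v in rev(rt$order)) {
    if (!is.na(g$lab[v])) {
      below[[v]] <- rank[[g$lab[v]]]
    } else {
      kids <- g$adj[[v]][g$adj[[v]] != rt$parent[v]]
      if (v == rt$root) kids <- g$adj[[v]]
      below[[v]] <- unlist(below[kids], use.names = FALSE)
    }
  }
  list(taxa = taxa, below = below, rt = rt)
}

# Minimum leaf rank below each node, and minimum leaf rank outside the
# subtree of each node ("above"), used for deterministic tie-breaking.
# Ranks are positions in the sorted leafset of g.
g_min_ranks <- function(g, rt) {
  n <- length(g$adj)
  rank <- match(g$lab, g_leafset(g))
  minbelow <- rep.int(.Machine$integer.max, n)
  for (v in rev(rt$order)) {
    if (!is.na(g$lab[v])) {
      minbelow[v] <- rank[v]
    } else {
      kids <- g$adj[[v]][g$adj[[v]] != rt$parent[v]]
      if (v == rt$root) kids <- g$adj[[v]]
      if (length(kids) > 0L) minbelow[v] <- min(minbelow[kids])
    }
  }
  minabove <- rep.int(.Machine$integer.max, n)
  for (v in rt$order) {
    kids <- g$adj[[v]][g$adj[[v]] != rt$parent[v]]
    if (v == rt$root) kids <- g$adj[[v]]
    if (length(kids) == 0L) next
    here <- if (!is.na(g$lab[v])) minbelow[v] else .Machine$integer.max
    mb <- minbelow[kids]
    for (idx in seq_along(kids)) {
      others <- if (length(kids) > 1L) min(mb[-idx]) else .Machine$integer.max
      minabove[kids[idx]] <- min(minabove[v], here, others)
    }
  }
  list(minbelow = minbelow, minabove = minabove)
}
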