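# The guide-tree merge: input validation, guide-edge classification,
# the collapse phase, and the recursive rejoin that assembles the optimal
# unblended compatibility supertree.

gtm_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gtm_error")))
}

#' Validate a guide tree against a set of constraint trees
#'
#' Checks that the constraint leafsets are pairwise disjoint and that
#' their union is exactly the guide's leafset, the precondition of the
#' merge.
#'
#' @param guide a \code{phylo} on the full taxon set.
#' @param constraints a list of \code{phylo} objects on disjoint subsets.
#' @return invisibly, the taxon-to-constraint map: an integer vector
#'   named by taxon, giving the index of the constraint tree holding it.
#' @export
validate_gtm_inputs <- function(guide, constraints) {
  if (inherits(constraints, "phylo")) constraints <- list(constraints)
  if (length(constraints) < 1L) {
    gtm_error("need at least one constraint tree", "gtm_validation_error")
  }
  sets <- lapply(constraints, leafset)
  all_taxa <- unlist(sets, use.names = FALSE)
  dup <- unique(all_taxa[duplicated(all_taxa)])
  if (length(dup) > 0L) {
    gtm_error(paste0("constraint leafsets overlap at: ",
                     paste(dup, collapse = ", ")), "gtm_validation_error")
  }
  gl <- leafset(guide)
  missing <- setdiff(gl, all_taxa)
  extra <- setdiff(all_taxa, gl)
  if (length(missing) > 0L || length(extra) > 0L) {
    gtm_error(paste0(
      "constraint union does not match guide leafset",
      if (length(missing) > 0L)
        paste0("; missing from constraints: ", paste(missing, collapse = ", ")),
      if (length(extra) > 0L)
        paste0("; not in guide: ", paste(extra, collapse = ", "))),
      "gtm_validation_error")
  }
  cmap <- rep(seq_along(sets), lengths(sets))
  names(cmap) <- all_taxa
  invisible(cmap)
}

# Per-edge constraint-set spanning structure of graph g under taxon map
# cmap (named integer, values 1..k). Every non-root node v of the rooted
# scaffold stands for the edge (parent(v), v).
g_classify <- function(g, cmap) {
  rt <- g_rooted(g)
  n <- length(g$adj)
  k <- max(cmap)
  bm <- matrix(0L, n, k)
  cnt <- integer(n)
  cv <- unname(cmap[g$lab])              # vectorized taxon -> set lookup
  for (v in rev(rt$order)) {
    if (!is.na(g$lab[v])) {
      bm[v, cv[v]] <- 1L
      cnt[v] <- 1L
    } else {
      kids <- g$adj[[v]][g$adj[[v]] != rt$parent[v]]
      if (length(kids) == 1L) {
        bm[v, ] <- bm[kids, ]
        cnt[v] <- cnt[kids]
      } else {
        bm[v, ] <- colSums(bm[kids, , drop = FALSE])
        cnt[v] <- sum(cnt[kids])
      }
    }
  }
  if (!is.na(g$lab[rt$root])) {          # leaf root (trees with < 3 leaves)
    kids <- g$adj[[rt$root]]
    if (length(kids) > 0L) {
      bm[rt$root, ] <- bm[rt$root, ] + colSums(bm[kids, , drop = FALSE])
      cnt[rt$root] <- cnt[rt$root] + sum(cnt[kids])
    }
  }
  setsz <- bm[rt$root, ]
  spanned <- bm > 0L & sweep(bm, 2L, setsz, "<")
  spancnt <- rowSums(spanned)
  spancnt[rt$root] <- 0L
  list(rt = rt, bm = bm, cnt = cnt, setsz = setsz,
       spanned = spanned, spancnt = spancnt, k = k)
}

#' Classify the edges of a guide tree against constraint sets
#'
#' Each guide edge is classified by how many constraint sets have leaves
#' on both of its sides: none (a bridge edge, separating constraint
#' sets), exactly one (the edge lies within that set), or two or more
#' (the edge violates convexity and can never survive the merge).
#'
#' @inheritParams validate_gtm_inputs
#' @return a data frame with one row per guide edge: \code{split} (the
#'   canonical split key, including trivial splits), \code{class} (one of
#'   \code{"BRIDGE"}, \code{"WITHIN"}, \code{"VIOLATES_CONVEXITY"}) and
#'   \code{constraint} (the set index for WITHIN edges, otherwise NA).
#' @export
classify_edges <- function(guide, constraints) {
  if (inherits(constraints, "phylo")) constraints <- list(constraints)
  cmap <- validate_gtm_inputs(guide, constraints)
  g <- as_graph(guide)
  cl <- g_classify(g, cmap)
  keys <- g_split_keys(g, include_trivial = TRUE)
  em <- attr(keys, "edges")
  cls <- character(nrow(em))
  cidx <- rep(NA_integer_, nrow(em))
  for (r in seq_len(nrow(em))) {
    v <- em[r, 2L]
    sc <- cl$spancnt[v]
    if (sc == 0L) {
      cls[r] <- "BRIDGE"
    } else if (sc == 1L) {
      cls[r] <- "WITHIN"
      cidx[r] <- which(cl$spanned[v, ])
    } else {
      cls[r] <- "VIOLATES_CONVEXITY"
    }
  }
  data.frame(split = as.character(keys), class = cls, constraint = cidx,
             stringsAsFactors = FALSE)
}

#' Does a bipartition violate a constraint tree?
#'
#' A bipartition A|B of a superset of the constraint tree's leafset
#' violates it when the restriction of the bipartition to that leafset is
#' nontrivial and is not a split of the constraint tree.
#'
#' @param side_a,side_b disjoint character vectors forming the
#'   bipartition; their union must contain the constraint's leafset.
#' @param t a constraint tree (\code{phylo}).
#' @return logical.
#' @export
violates_constraint <- function(side_a, side_b, t) {
  if (length(intersect(side_a, side_b)) > 0L) {
    gtm_error("bipartition sides overlap", "gtm_validation_error")
  }
  lt <- leafset(t)
  if (!all(lt %in% c(side_a, side_b))) {
    gtm_error("bipartition does not cover the constraint leafset",
              "gtm_validation_error")
  }
  ra <- intersect(lt, side_a)
  if (min(length(ra), length(lt) - length(ra)) <= 1L) return(FALSE)
  key <- key_from_ranks(match(ra, lt), lt)
  !(key %in% g_keyset(as_graph(t)))
}

# The collapse phase: remove every guide edge that violates a constraint
# tree, then every edge that violates convexity. Returns the collapsed
# graph and the counts of edges removed by each cause.
g_collapse_phase <- function(g, cgs, csets, cmap) {
  cl <- g_classify(g, cmap)
  rt <- cl$rt
  n <- length(g$adj)
  nonroot <- rt$order[rt$order != rt$root]
  ckeys <- lapply(cgs, g_keyset)

  viol <- logical(n)
  for (i in seq_along(cgs)) {
    ni <- cl$setsz[i]
    if (ni < 4L) next                     # no nontrivial restriction possible
    taxa_i <- csets[[i]]
    rank_i <- integer(n)                  # per-leaf rank within set i
    # postorder accumulation of set-i leaf ranks below each spanned node
    below_i <- vector("list", n)
    for (v in rev(rt$order)) {
      bi <- cl$bm[v, i]
      if (bi == 0L || bi == ni) next      # empty or full: restriction trivial
      if (!is.na(g$lab[v])) {
        below_i[[v]] <- match(g$lab[v], taxa_i)
      } else {
        kids <- g$adj[[v]][g$adj[[v]] != rt$parent[v]]
        kids <- kids[cl$bm[kids, i] > 0L]
        below_i[[v]] <- unlist(below_i[kids], use.names = FALSE)
      }
      if (v != rt$root && bi >= 2L && bi <= ni - 2L) {
        key <- key_from_ranks(below_i[[v]], taxa_i)
        if (!(key %in% ckeys[[i]])) viol[v] <- TRUE
      }
    }
  }
  convex <- cl$spancnt >= 2L
  drop <- nonroot[viol[nonroot] | convex[nonroot]]
  n_viol <- sum(viol[nonroot])
  n_convex <- sum(convex[nonroot] & !viol[nonroot])
  if (length(drop) > 0L) {
    em <- cbind(rt$parent[drop], drop)
    g <- g_collapse_edges(g, em)
  }
  list(g = g, n_constraint = n_viol, n_convexity = n_convex)
}

# Deterministic or seeded-random choice helpers for tie situations.
pick_one <- function(x, random) {
  if (length(x) == 1L) return(x[1L])
  if (random) x[sample.int(length(x), 1L)] else x[1L]
}

# Select the neighbor edge of `endpoint` used as attachment target within
# component graph gS (the connecting edge has already been deleted).
# Returns list(kind = "vertex") or list(kind = "edge", side = <chr>).
g_pick_attach <- function(gS, endpoint, random) {
  nbrs <- gS$adj[[endpoint]]
  if (length(nbrs) == 0L) return(list(kind = "vertex"))
  if (random) {
    w <- nbrs[sample.int(length(nbrs), 1L)]
  } else {
    rtS <- g_rooted(gS, root = endpoint)
    mr <- g_min_ranks(gS, rtS)
    w <- nbrs[order(mr$minbelow[nbrs], method = "radix")][1L]
  }
  tmp <- g_del_edge(gS, endpoint, w)
  reach <- g_reachable(tmp, w)
  side <- gS$lab[which(reach & gS$alive & !is.na(gS$lab))]
  list(kind = "edge", side = sort.int(side, method = "radix"))
}

# Locate in graph R the edge inducing the bipartition whose one side is
# `side` (character taxa), via subtree hash signatures (random taxon
# weights summed below each edge), verifying candidates exactly.
# Returns an edge c(parent, child) or, for kind "vertex", the sole node.
g_locate_site <- function(R, target, weights) {
  if (target$kind == "vertex") {
    nodes <- g_nodes(R)
    if (length(nodes) != 1L) {
      gtm_error("vertex attachment into a multi-node component",
                "gtm_internal_error")
    }
    return(nodes)
  }
  side <- target$side
  taxa <- g_leafset(R)
  rt <- g_rooted(R)
  n <- length(R$adj)
  sig <- numeric(n)
  wl <- weights[R$lab]
  count_hash_ops(length(taxa))
  for (v in rev(rt$order)) {
    if (!is.na(R$lab[v])) {
      sig[v] <- wl[v]
    } else {
      kids <- R$adj[[v]][R$adj[[v]] != rt$parent[v]]
      sig[v] <- sum(sig[kids])
    }
  }
  tgt <- sum(weights[side])
  tot <- sum(weights[taxa])
  tol <- 1e-8
  for (v in rt$order) {
    if (v == rt$root) next
    flip <- abs(sig[v] - (tot - tgt)) < tol
    if (abs(sig[v] - tgt) < tol || flip) {
      tmp <- g_del_edge(R, rt$parent[v], v)
      reach <- g_reachable(tmp, v)
      below <- sort.int(R$lab[which(reach & R$alive & !is.na(R$lab))],
                        method = "radix")
      want <- if (abs(sig[v] - tgt) < tol) side
              else sort.int(setdiff(taxa, side), method = "radix")
      if (length(below) == length(want) && all(below == want)) {
        return(c(rt$parent[v], v))
      }
    }
  }
  gtm_error(paste0("no attachment edge induces the required bipartition {",
                   paste(side, collapse = ","), "} | rest"),
            "gtm_internal_error")
}

#' Find the edge of a tree inducing a given bipartition
#'
#' Looks the bipartition up through the subtree hash index used by the
#' merge itself; absence is an error (inside the merge it would mean a
#' broken invariant). For a single-taxon tree the sole vertex is
#' designated by an empty split.
#'
#' @param t a \code{phylo} object.
#' @param side character vector: one side of the target bipartition
#'   (possibly a single taxon, selecting a pendant edge).
#' @return the canonical split key of the matching edge.
#' @export
find_attachment_edge <- function(t, side) {
  g <- as_graph(t)
  taxa <- g_leafset(g)
  bad <- setdiff(side, taxa)
  if (length(bad) > 0L) {
    gtm_error(paste0("split names taxa not in tree: ",
                     paste(bad, collapse = ", ")), "gtm_validation_error")
  }
  weights <- gtm_taxon_weights(taxa)
  em <- g_locate_site(g, list(kind = "edge", side = sort.int(side, method = "radix")),
                      weights)
  key_from_ranks(match(side, taxa), taxa)
}

# Fixed pseudo-random taxon weights (independent of the user's RNG
# stream) used for subtree hashing.
gtm_taxon_weights <- function(taxa) {
  w <- with_preserved_seed(20240511L, stats::runif(length(taxa), 1, 2))
  names(w) <- taxa
  w
}

# The recursive rejoin. g: current (post-collapse) guide component;
# cgs/csets: constraint graphs and their sorted leafsets; cmap: taxon ->
# constraint index; weights: taxon hash weights; random: random-tie mode;
# logenv: environment accumulating the attachment log.
g_rejoin <- function(g, cgs, csets, cmap, weights, random, logenv) {
  labs <- g$lab[g_leaves(g)]
  present <- unique(cmap[labs])
  if (length(present) == 1L) {
    i <- present[1L]
    if (length(labs) != length(csets[[i]])) {
      gtm_error("component leafset is not a whole constraint set",
                "gtm_internal_error")
    }
    return(cgs[[i]])
  }
  cl <- g_classify(g, cmap)
  rt <- cl$rt
  nonroot <- rt$order[rt$order != rt$root]
  bridges <- nonroot[cl$spancnt[nonroot] == 0L]
  if (length(bridges) > 0L) {
    if (random) {
      b <- bridges[sample.int(length(bridges), 1L)]
    } else {
      mr <- g_min_ranks(g, rt)
      farmin <- ifelse(mr$minbelow[bridges] == 1L,
                       mr$minabove[bridges], mr$minbelow[bridges])
      tot <- cl$cnt[rt$root]
      sz <- pmin(cl$cnt[bridges], tot - cl$cnt[bridges])
      b <- bridges[order(farmin, sz, method = "radix")][1L]
    }
    enda <- rt$parent[b]
    endb <- b
  } else {
    # no bridge: find a junction node where two constraint sets meet,
    # and refine it to manufacture the separating edge
    n <- length(g$adj)
    ws <- integer(n)                      # within-set index per edge (node)
    for (v in nonroot) {
      if (cl$spancnt[v] == 1L) ws[v] <- which(cl$spanned[v, ])
    }
    inc <- vector("list", n)              # constraint sets incident at node
    for (v in nonroot) {
      if (ws[v] == 0L) next
      p <- rt$parent[v]
      inc[[p]] <- c(inc[[p]], ws[v])
      inc[[v]] <- c(inc[[v]], ws[v])
    }
    junctions <- rt$order[vapply(rt$order, function(v) {
      length(unique(inc[[v]])) >= 2L
    }, logical(1))]
    if (length(junctions) == 0L) {
      gtm_error("no bridge edge and no junction node in rejoin",
                "gtm_internal_error")
    }
    v <- pick_one(junctions, random)
    sets_at_v <- sort.int(unique(inc[[v]]), method = "radix")
    if (random) {
      i <- sets_at_v[sample.int(length(sets_at_v), 1L)]
    } else {
      # the set whose smallest member taxon is smallest
      mins <- vapply(sets_at_v, function(s) csets[[s]][1L], character(1))
      i <- sets_at_v[order(mins, method = "radix")][1L]
    }
    # neighbors of v whose shared edge lies within set i
    movers <- integer(0)
    for (u in g$adj[[v]]) {
      edge_node <- if (rt$parent[u] == v) u else v   # node standing for (v,u)
      if (ws[edge_node] == i) movers <- c(movers, u)
    }
    if (length(movers) == 0L) {
      gtm_error("junction refinement found no edges to separate",
                "gtm_internal_error")
    }
    an <- g_add_node(g)
    g <- an$g
    vp <- an$id
    for (u in movers) {
      len <- g_edge_len(g, v, u)
      g <- g_del_edge(g, v, u)
      g <- g_add_edge(g, vp, u, len)
    }
    g <- g_add_edge(g, v, vp)
    enda <- v
    endb <- vp
  }
  parts <- g_split_components(g, enda, endb)
  gA <- if (parts[[1L]]$alive[enda]) parts[[1L]] else parts[[2L]]
  gB <- if (parts[[1L]]$alive[endb]) parts[[1L]] else parts[[2L]]
  tgA <- g_pick_attach(gA, enda, random)
  tgB <- g_pick_attach(gB, endb, random)
  # the deleted edge leaves a degree-2 node at each endpoint; restore the
  # homeomorphic form before recursing (splits are unaffected)
  gA <- g_suppress_degree2(gA)
  gB <- g_suppress_degree2(gB)
  lsA <- g_leafset(gA)
  lsB <- g_leafset(gB)
  RA <- g_rejoin(gA, cgs, csets, cmap, weights, random, logenv)
  RB <- g_rejoin(gB, cgs, csets, cmap, weights, random, logenv)
  siteA <- g_locate_site(RA, tgA, weights)
  siteB <- g_locate_site(RB, tgB, weights)
  merged <- g_join_at(RA, siteA, RB, siteB)
  entry <- list(
    leafsets = list(lsA, lsB),
    attachments = c(
      if (tgA$kind == "vertex") "<vertex>"
      else key_from_ranks(match(tgA$side, lsA), lsA),
      if (tgB$kind == "vertex") "<vertex>"
      else key_from_ranks(match(tgB$side, lsB), lsB)))
  logenv$log[[length(logenv$log) + 1L]] <- entry
  merged
}

#' Merge leaf-disjoint constraint trees guided by a tree on all taxa
#'
#' Builds the compatibility supertree of the constraint trees that, among
#' all supertrees formed by adding connecting edges between them
#' (unblended mergers), has the minimum false-negative distance to the
#' guide tree: the fewest guide bipartitions missing from the result.
#' The algorithm collapses every guide edge that violates a constraint
#' tree or violates convexity, then recursively splits the collapsed
#' guide at bridge edges (refining polytomies where constraint sets
#' meet) and reconnects the constraint trees at edges that reproduce the
#' guide's bipartitions. It runs in O(N^2) time via subtree hashing.
#'
#' @param guide a \code{phylo} on the full taxon set; may be
#'   multifurcating.
#' @param constraints a list of \code{phylo} objects on pairwise-disjoint
#'   leafsets whose union is the guide's leafset; may be multifurcating.
#' @param random_ties \code{NULL} for the deterministic tie-break policy
#'   (byte-reproducible output), or an integer seed to draw every
#'   tie-break (border node, separated set, neighbor edges) uniformly at
#'   random; any choice yields an optimal merger.
#' @return an object of class \code{gtm_merge} with components
#'   \code{supertree} (the merged \code{phylo}), \code{fn_to_guide} (its
#'   FN distance to the guide), \code{collapsed_constraint_violations}
#'   and \code{collapsed_convexity_violations} (guide edges removed in
#'   the collapse phase, by cause), and \code{attachment_log} (one entry
#'   per added edge: the two component leafsets and the split keys of the
#'   subdivided attachment edges).
#' @examples
#' guide <- parse_newick("(1,(2,(3,(4,(5,(6,(7,8)))))));")
#' t1 <- parse_newick("(1,(5,(6,7)));")
#' t2 <- parse_newick("(2,(3,(4,8)));")
#' m <- gtm(guide, list(t1, t2))
#' m$fn_to_guide   # 5: no caterpillar split is achievable unblended
#' @export
gtm <- function(guide, constraints, random_ties = NULL) {
  if (inherits(constraints, "phylo")) constraints <- list(constraints)
  cmap <- validate_gtm_inputs(guide, constraints)
  run <- function() {
    random <- !is.null(random_ties)
    g <- as_graph(guide)
    cgs <- lapply(constraints, as_graph)
    csets <- lapply(cgs, g_leafset)
    weights <- gtm_taxon_weights(leafset(guide))
    cp <- g_collapse_phase(g, cgs, csets, cmap)
    logenv <- new.env(parent = emptyenv())
    logenv$log <- list()
    merged <- g_rejoin(cp$g, cgs, csets, cmap, weights, random, logenv)
    fn <- sum(!(g_keyset(as_graph(guide)) %in% g_keyset(merged)))
    structure(list(
      supertree = g_to_phylo(merged),
      fn_to_guide = fn,
      collapsed_constraint_violations = cp$n_constraint,
      collapsed_convexity_violations = cp$n_convexity,
      attachment_log = logenv$log,
      n_taxa = length(cmap),
      k = length(constraints),
      random_ties = random_ties,
      call = match.call()),
      class = "gtm_merge")
  }
  if (is.null(random_ties)) run() else with_preserved_seed(random_ties, run())
}

#' @export
print.gtm_merge <- function(x, ...) {
  cat("Guide-tree merge of", x$k, "constraint trees on", x$n_taxa, "taxa\n")
  cat("  FN distance to guide:", x$fn_to_guide, "\n")
  cat("  guide edges collapsed:", x$collapsed_constraint_violations,
      "(constraint violations),", x$collapsed_convexity_violations,
      "(convexity violations)\n")
  cat("  connecting edges added:", length(x$attachment_log), "\n")
  invisible(x)
}

#' @export
summary.gtm_merge <- function(object, ...) {
  print(object)
  if (length(object$attachment_log) > 0L) {
    cat("Attachments (component sizes and subdivided edges):\n")
    for (e in object$attachment_log) {
      s1 <- length(e$leafsets[[1L]])
      s2 <- length(e$leafsets[[2L]])
      cat(sprintf("  [%d taxa] <-> [%d taxa]  at  {%s} | {%s}\n", s1, s2,
                  e$attachments[1L], e$attachments[2L]))
    }
  }
  invisible(object)
}

#' @export
plot.gtm_merge <- function(x, ...) {
  ape::plot.phylo(x$supertree, type = "unrooted", ...)
}

#' @importFrom ape as.phylo
#' @method as.phylo gtm_merge
#' @export
as.phylo.gtm_merge <- function(x, ...) x$supertree
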