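# Brute-force enumeration of unblended compatibility supertrees: the
# exactness oracle for the merge at small scale. Candidates are built by
# repeatedly connecting two current components with a new edge at every
# possible pair of attachment sites (every edge, including edges created
# by earlier additions, or the sole vertex of a single-node component);
# duplicate topologies are suppressed by their bipartition sets.

oracle_sites <- function(g) {
  em <- g_edges(g)
  if (nrow(em) == 0L) return(list(g_nodes(g)))   # single node: vertex site
  lapply(seq_len(nrow(em)), function(r) as.integer(em[r, ]))
}

# Walk all merger orders; calls visit(graph) on every completed merger.
# counter limits the number of completed mergers visited.
oracle_enum <- function(comps, visit, counter, cap) {
  kc <- length(comps)
  if (kc == 1L) {
    counter$n <- counter$n + 1L
    if (counter$n > cap) {
      gtm_error(paste0("unblended enumeration exceeded cap of ", cap,
                       " candidates"), "gtm_resource_error")
    }
    visit(comps[[1L]])
    return(invisible(NULL))
  }
  for (i in seq_len(kc - 1L)) {
    for (j in (i + 1L):kc) {
      for (s1 in oracle_sites(comps[[i]])) {
        for (s2 in oracle_sites(comps[[j]])) {
          merged <- g_join_at(comps[[i]], s1, comps[[j]], s2)
          oracle_enum(c(comps[-c(i, j)], list(merged)), visit, counter, cap)
        }
      }
    }
  }
  invisible(NULL)
}

#' Enumerate all unblended compatibility supertrees
#'
#' Generates every tree obtainable by connecting the constraint trees
#' with new edges (subdividing an existing edge at each endpoint, or
#' attaching at the vertex of a single-node tree), including attachments
#' into previously added connecting edges. Duplicates (equal bipartition
#' sets) are removed. Intended for small instances; the total number of
#' completed mergers visited is capped.
#'
#' @param constraints a list of at least 2 \code{phylo} objects on
#'   pairwise-disjoint leafsets.
#' @param cap abort with a resource error after this many candidate
#'   mergers (before deduplication).
#' @return a list of distinct \code{phylo} supertrees.
#' @examples
#' q1 <- parse_newick("((a,b),(c,d));"); q2 <- parse_newick("((e,f),(g,h));")
#' length(enumerate_unblended(list(q1, q2)))   # 25 distinct 5x5 attachments
#' @export
enumerate_unblended <- function(constraints, cap = 1e6) {
  if (length(constraints) < 2L) {
    gtm_error("enumeration needs at least 2 constraint trees",
              "gtm_validation_error")
  }
  cgs <- lapply(constraints, as_graph)
  all_taxa <- unlist(lapply(cgs, g_leafset))
  if (anyDuplicated(all_taxa)) {
    gtm_error("constraint leafsets overlap", "gtm_validation_error")
  }
  seen <- new.env(parent = emptyenv())
  out <- new.env(parent = emptyenv())
  out$trees <- list()
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  oracle_enum(cgs, function(g) {
    key <- paste(sort.int(g_keyset(g, include_trivial = TRUE),
                          method = "radix"), collapse = ";")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out$trees[[length(out$trees) + 1L]] <- g_to_phylo(g)
    }
  }, counter, cap)
  out$trees
}

#' Best unblended merger by brute force
#'
#' Scans every unblended compatibility supertree of the constraints and
#' returns one minimizing the FN distance to the guide, together with
#' that minimum. This is the independent optimality oracle for
#' \code{\link{gtm}} at small scale.
#'
#' @inheritParams enumerate_unblended
#' @param guide a \code{phylo} on the union of the constraint leafsets.
#' @return a list with \code{tree} (an optimal \code{phylo}) and
#'   \code{fn} (the minimum FN distance to the guide).
#' @export
best_unblended <- function(constraints, guide, cap = 1e6) {
  if (inherits(constraints, "phylo")) constraints <- list(constraints)
  cmap <- validate_gtm_inputs(guide, constraints)
  gk <- g_keyset(as_graph(guide))
  if (length(constraints) == 1L) {
    t1 <- g_to_phylo(as_graph(constraints[[1L]]))
    return(list(tree = t1, fn = sum(!(gk %in% g_keyset(as_graph(t1))))))
  }
  cgs <- lapply(constraints, as_graph)
  best <- new.env(parent = emptyenv())
  best$fn <- Inf
  best$tree <- NULL
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  oracle_enum(cgs, function(g) {
    fn <- sum(!(gk %in% g_keyset(g)))
    if (fn < best$fn) {
      best$fn <- fn
      best$tree <- g
    }
  }, counter, cap)
  list(tree = g_to_phylo(best$tree), fn = as.integer(best$fn))
}

#' Is a tree a compatibility supertree of a set of constraint trees?
#'
#' True when the tree's leafset is the union of the constraint leafsets
#' and its homeomorphic restriction to each constraint leafset has
#' exactly that constraint tree's bipartition set.
#'
#' @param t a \code{phylo}.
#' @param constraints a list of \code{phylo} objects.
#' @return logical.
#' @export
is_compatibility_supertree <- function(t, constraints) {
  if (inherits(constraints, "phylo")) constraints <- list(constraints)
  lt <- leafset(t)
  lc <- sort.int(unlist(lapply(constraints, leafset)), method = "radix")
  if (anyDuplicated(lc) || length(lt) != length(lc) || !all(lt == lc)) {
    return(FALSE)
  }
  for (ct in constraints) {
    lct <- leafset(ct)
    r <- restrict(t, lct)
    ka <- bipartitions(r)
    kb <- bipartitions(ct)
    if (length(ka) != length(kb) || !all(ka == kb)) return(FALSE)
  }
  TRUE
}
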