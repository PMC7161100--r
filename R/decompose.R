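# Centroid edge decomposition: split a starting tree's taxon set into
# disjoint subsets of bounded size by recursively deleting centroid
# edges, the subset-generation stage of divide-and-conquer pipelines.

# Internal: centroid edge of graph g as c(parent, child) plus the two
# sides; ties broken by smallest taxon on the smaller side, then smaller
# side size, then lexicographic smaller side.
g_centroid_edge <- function(g) {
  nl <- g_n_leaves(g)
  if (nl < 2L) {
    gtm_error("centroid edge needs a tree with at least 2 leaves",
              "gtm_validation_error")
  }
  rt <- g_rooted(g)
  mr <- g_min_ranks(g, rt)
  n <- length(g$adj)
  cnt <- integer(n)
  for (v in rev(rt$order)) {
    if (!is.na(g$lab[v])) {
      cnt[v] <- 1L
    } else {
      kids <- g$adj[[v]][g$adj[[v]] != rt$parent[v]]
      cnt[v] <- sum(cnt[kids])
    }
  }
  if (!is.na(g$lab[rt$root])) {
    kids <- g$adj[[rt$root]]
    cnt[rt$root] <- cnt[rt$root] + sum(cnt[kids])
  }
  nonroot <- rt$order[rt$order != rt$root]
  below <- cnt[nonroot]
  imb <- abs(nl - 2L * below)            # | |A| - |B| |
  best <- nonroot[imb == min(imb)]
  if (length(best) > 1L) {
    smaller_min <- vapply(best, function(v) {
      if (cnt[v] * 2L <= nl) mr$minbelow[v] else mr$minabove[v]
    }, integer(1))
    smaller_sz <- pmin(cnt[best], nl - cnt[best])
    best <- best[order(smaller_min, smaller_sz, method = "radix")]
  }
  v <- best[1L]
  list(edge = c(rt$parent[v], v), below = v)
}

#' Centroid edge of a tree
#'
#' The edge whose removal splits the leafset into two parts with the
#' smallest possible size difference. Ties are broken deterministically
#' (smallest taxon on the smaller side, then smaller side size).
#'
#' @param t a \code{phylo} with at least 2 leaves.
#' @return a list with \code{side_a} and \code{side_b}, the two taxon
#'   sets separated by the centroid edge (sorted; \code{side_a} is the
#'   side holding the smallest taxon).
#' @examples
#' cat8 <- parse_newick("(1,(2,(3,(4,(5,(6,(7,8)))))));")
#' centroid_edge(cat8)$side_a   # "1" "2" "3" "4"
#' @export
centroid_edge <- function(t) {
  g <- as_graph(t)
  ce <- g_centroid_edge(g)
  tmp <- g_del_edge(g, ce$edge[1L], ce$edge[2L])
  reach <- g_reachable(tmp, ce$edge[2L])
  taxa <- g_leafset(g)
  sb <- sort.int(g$lab[which(reach & g$alive & !is.na(g$lab))], method = "radix")
  sa <- setdiff(taxa, sb)
  if (!(taxa[1L] %in% sa)) {
    tmp2 <- sa; sa <- sb; sb <- tmp2
  }
  list(side_a = sa, side_b = sb)
}

g_centroid_decomposition <- function(g, max_size) {
  nl <- g_n_leaves(g)
  if (nl <= max_size) return(list(g_leafset(g)))
  ce <- g_centroid_edge(g)
  parts <- g_split_components(g, ce$edge[1L], ce$edge[2L])
  parts <- lapply(parts, g_suppress_degree2)
  c(g_centroid_decomposition(parts[[1L]], max_size),
    g_centroid_decomposition(parts[[2L]], max_size))
}

#' Centroid edge decomposition into bounded-size taxon subsets
#'
#' Recursively removes centroid edges until every component has at most
#' \code{max_size} leaves, partitioning the leafset into disjoint,
#' topologically local subsets. The default bound of 120 species is the
#' customary subset size in divide-and-conquer species-tree pipelines.
#'
#' @param t a \code{phylo}, the starting tree.
#' @param max_size integer bound B >= 1 on subset size.
#' @return an object of class \code{gtm_decomposition}: a list of sorted
#'   taxon-name vectors, pairwise disjoint, covering the leafset, each of
#'   size at most \code{max_size}; ordered by their smallest taxon.
#' @examples
#' cat8 <- parse_newick("(1,(2,(3,(4,(5,(6,(7,8)))))));")
#' centroid_decomposition(cat8, 4)   # {1,2,3,4}, {5,6,7,8}
#' @export
centroid_decomposition <- function(t, max_size = 120L) {
  if (!is.numeric(max_size) || length(max_size) != 1L || max_size < 1) {
    gtm_error("max_size must be a single integer >= 1", "gtm_validation_error")
  }
  subsets <- g_centroid_decomposition(as_graph(t), as.integer(max_size))
  firsts <- vapply(subsets, `[`, character(1), 1L)
  subsets <- subsets[order(firsts, method = "radix")]
  structure(subsets, max_size = as.integer(max_size),
            class = "gtm_decomposition")
}

#' @export
print.gtm_decomposition <- function(x, ...) {
  cat("Centroid edge decomposition:", length(x), "subsets (max size",
      attr(x, "max_size"), ")\n")
  cat("  sizes:", paste(lengths(x), collapse = ", "), "\n")
  invisible(x)
}
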