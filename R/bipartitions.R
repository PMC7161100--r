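# Bipartition extraction and canonical split keys.
#
# A bipartition A|B of a leafset is orientation-free; it is canonicalized
# by keeping the side that contains the lexicographically smallest taxon
# of the reference leafset, and keyed as the comma-joined sorted taxa of
# that side. Two bipartitions over different leafsets therefore never
# share a key space in any comparison this package performs (all
# comparisons first validate equal leafsets).

.gtm_state <- new.env(parent = emptyenv())
.gtm_state$hash_ops <- 0

#' Bipartition-hashing work counters
#'
#' The package counts the elementary work spent building bipartition keys
#' and subtree hash signatures (one unit per taxon hashed). This is the
#' empirical proxy for the algorithm's bipartition-hashing cost, used to
#' check that the merge scales quadratically.
#'
#' @return \code{gtm_op_count()} returns the units accumulated since the
#'   last reset; \code{gtm_op_reset()} zeroes the counter invisibly.
#' @export
gtm_op_count <- function() .gtm_state$hash_ops

#' @rdname gtm_op_count
#' @export
gtm_op_reset <- function() {
  .gtm_state$hash_ops <- 0
  invisible(0)
}

count_hash_ops <- function(n) {
  .gtm_state$hash_ops <- .gtm_state$hash_ops + n
  invisible(NULL)
}

# Canonical key for side `side_ranks` (integer ranks into `taxa`, sorted
# taxa vector). `nall` = length(taxa).
key_from_ranks <- function(side_ranks, taxa) {
  nall <- length(taxa)
  count_hash_ops(length(side_ranks))
  side_ranks <- sort.int(side_ranks, method = "radix")
  if (side_ranks[1L] != 1L) {
    inside <- logical(nall)
    inside[side_ranks] <- TRUE
    side_ranks <- which(!inside)
  }
  paste(taxa[side_ranks], collapse = ",")
}

# Split keys of every edge of a graph; include_trivial adds pendant-type
# splits (one side a single taxon). Returns character vector; the edges
# attribute aligns each key with its (parent, child) node pair.
g_split_keys <- function(g, include_trivial = FALSE) {
  nl <- g_n_leaves(g)
  if (nl < 2L) {
    return(structure(character(0), edges = matrix(integer(0), 0L, 2L),
                     leafset = g_leafset(g)))
  }
  bs <- g_below_sets(g)
  rt <- bs$rt
  taxa <- bs$taxa
  keys <- character(0)
  from <- integer(0); to <- integer(0)
  for (v in rt$order) {
    if (v == rt$root) next
    side <- bs$below[[v]]
    sz <- length(side)
    if (!include_trivial && min(sz, nl - sz) <= 1L) next
    if (min(sz, nl - sz) < 1L) next      # root-adjacent full side
    keys <- c(keys, key_from_ranks(side, taxa))
    from <- c(from, rt$parent[v]); to <- c(to, v)
  }
  structure(keys, edges = cbind(from, to), leafset = taxa)
}

#' Bipartitions of a tree
#'
#' Each edge of an unrooted tree splits the leafset in two; the set of
#' these splits characterizes the topology. By default only nontrivial
#' splits (both sides with at least two taxa) are returned, matching the
#' convention under which a binary tree on n leaves has exactly n - 3
#' splits and trivial splits, common to all trees on a leafset, are
#' ignored by the distances.
#'
#' @param t a \code{phylo} object.
#' @param include_trivial also return the pendant (single-taxon) splits.
#' @return a character vector of canonical split keys, sorted; each key
#'   is the comma-joined side of the split containing the smallest taxon.
#'   The reference leafset is attached as attribute \code{"leafset"}.
#' @examples
#' cat8 <- parse_newick("(1,(2,(3,(4,(5,(6,(7,8)))))));")
#' bipartitions(cat8)   # the 5 nontrivial caterpillar splits
#' @export
bipartitions <- function(t, include_trivial = FALSE) {
  ks <- g_split_keys(as_graph(t), include_trivial = include_trivial)
  structure(sort.int(unique(ks), method = "radix"),
            leafset = attr(ks, "leafset"))
}

# Fast unsorted key set for internal use (duplicates impossible in a tree).
g_keyset <- function(g, include_trivial = FALSE) {
  as.character(g_split_keys(g, include_trivial = include_trivial))
}
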