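# Seeded generation of synthetic fixtures: uniform random binary trees,
# NNI perturbation for guide trees of controlled error, and complete
# merge problem instances emulating the divide-and-conquer pipeline
# (true tree -> centroid decomposition -> induced constraint trees ->
# perturbed guide).

g_random_binary <- function(taxa) {
  n <- length(taxa)
  g <- g_new()
  for (i in 1:3) g <- g_add_node(g, taxa[i])$g
  g <- g_add_node(g)$g                  # central node of the 3-leaf star
  for (i in 1:3) g <- g_add_edge(g, i, 4L)
  if (n == 3L) return(g)
  for (m in 4:n) {
    em <- g_edges(g)
    r <- sample.int(nrow(em), 1L)
    sd <- g_subdivide(g, em[r, 1L], em[r, 2L])
    g <- sd$g
    leafn <- g_add_node(g, taxa[m])
    g <- leafn$g
    g <- g_add_edge(g, sd$id, leafn$id)
  }
  g
}

#' Random unrooted binary tree
#'
#' Samples an unrooted binary topology uniformly at random by sequential
#' leaf attachment: starting from the 3-leaf star, each further taxon is
#' attached to an edge drawn uniformly from the current tree.
#'
#' @param taxa character vector of at least 3 unique taxon names.
#' @param seed integer seed; the same seed always yields the same tree
#'   and the caller's RNG state is left untouched.
#' @return a binary \code{phylo} on \code{taxa}.
#' @export
random_binary_tree <- function(taxa, seed) {
  if (anyDuplicated(taxa)) {
    gtm_error("duplicate taxon names", "gtm_validation_error")
  }
  if (length(taxa) < 3L) {
    gtm_error("need at least 3 taxa", "gtm_validation_error")
  }
  g <- with_preserved_seed(seed, g_random_binary(taxa))
  g_to_phylo(g)
}

g_perturb_nni <- function(g, moves) {
  for (m in seq_len(moves)) {
    em <- g_edges(g)
    internal <- em[is.na(g$lab[em[, 1L]]) & is.na(g$lab[em[, 2L]]), ,
                   drop = FALSE]
    if (nrow(internal) == 0L) break
    r <- internal[sample.int(nrow(internal), 1L), ]
    u <- r[1L]; v <- r[2L]
    nu <- g$adj[[u]][g$adj[[u]] != v]
    nv <- g$adj[[v]][g$adj[[v]] != u]
    a <- nu[sample.int(length(nu), 1L)]
    b <- nv[sample.int(length(nv), 1L)]
    la <- g_edge_len(g, u, a); lb <- g_edge_len(g, v, b)
    g <- g_del_edge(g, u, a)
    g <- g_del_edge(g, v, b)
    g <- g_add_edge(g, u, b, lb)
    g <- g_add_edge(g, v, a, la)
  }
  g
}

#' Perturb a tree by random NNI moves
#'
#' Applies \code{moves} nearest-neighbor-interchange rearrangements at
#' internal edges drawn uniformly at random. Each move changes at most
#' one bipartition, so the RF distance to the input is at most
#' \code{2 * moves}; this gives guide trees of controlled topological
#' error.
#'
#' @param t a binary \code{phylo}.
#' @param moves non-negative integer number of NNI moves (0 = identity).
#' @param seed integer seed; deterministic per seed.
#' @return a \code{phylo} on the same leafset.
#' @export
perturb_nni <- function(t, moves, seed) {
  if (moves < 0) gtm_error("moves must be >= 0", "gtm_validation_error")
  g <- as_graph(t)
  if (moves == 0) return(g_to_phylo(g))
  g <- with_preserved_seed(seed, g_perturb_nni(g, as.integer(moves)))
  g_to_phylo(g)
}

#' Generate a complete synthetic merge instance
#'
#' Emulates the shape of a divide-and-conquer pipeline input: a true
#' binary tree on \code{n} taxa, its centroid decomposition into subsets
#' of at most \code{max_size} taxa, constraint trees obtained as the
#' induced subtrees on those subsets, and a guide tree obtained by
#' perturbing the true tree with \code{guide_moves} random NNI moves
#' (0 gives a perfect guide).
#'
#' @param n number of taxa (>= 4); taxa are named \code{t1 ... tn}.
#' @param max_size subset size bound B for the decomposition.
#' @param guide_moves number of NNI moves applied to form the guide.
#' @param seed integer seed controlling all randomness.
#' @return a list with components \code{true_tree}, \code{guide},
#'   \code{constraints} (list of \code{phylo}), \code{decomposition}
#'   (a \code{gtm_decomposition}), and the generating parameters.
#' @examples
#' inst <- make_instance(n = 16, max_size = 8, guide_moves = 0, seed = 1)
#' gtm(inst$guide, inst$constraints)$fn_to_guide   # 0: perfect guide
#' @export
make_instance <- function(n, max_size, guide_moves = 0L, seed = 1L) {
  if (n < 4L) gtm_error("need n >= 4", "gtm_validation_error")
  if (max_size < 1L || max_size > n) {
    gtm_error("need 1 <= max_size <= n", "gtm_validation_error")
  }
  taxa <- paste0("t", seq_len(n))
  with_preserved_seed(seed, {
    gt <- g_random_binary(taxa)
    true_tree <- g_to_phylo(gt)
    decomp <- centroid_decomposition(true_tree, max_size)
    constraints <- lapply(decomp, function(s) restrict(true_tree, s))
    guide <- if (guide_moves > 0L) {
      g_to_phylo(g_perturb_nni(as_graph(true_tree), as.integer(guide_moves)))
    } else {
      true_tree
    }
    list(true_tree = true_tree, guide = guide, constraints = constraints,
         decomposition = decomp, n = n, max_size = max_size,
         guide_moves = guide_moves, seed = seed)
  })
}
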