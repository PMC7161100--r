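# Bipartition distances: false-negative (FN) distance, Robinson-Foulds
# (RF) distance, and the normalized RF error rate.

check_same_leafset <- function(a, b) {
  la <- leafset(a); lb <- leafset(b)
  if (length(la) != length(lb) || !all(la == lb)) {
    diffs <- c(setdiff(la, lb), setdiff(lb, la))
    diffs <- diffs[seq_len(min(3L, length(diffs)))]
    stop("trees are on different leafsets (",
         length(la), " vs ", length(lb), " taxa; e.g. ",
         paste(diffs, collapse = ", "), ")", call. = FALSE)
  }
  la
}

#' False-negative bipartition distance
#'
#' \code{fn_distance(a, b)} counts the nontrivial bipartitions of
#' \code{b} that are missing from \code{a}. It is asymmetric: it is zero
#' exactly when every split of \code{b} also appears in \code{a} (for
#' example when \code{b} is less resolved than \code{a}). The guide-tree
#' merge minimizes \code{fn_distance(supertree, guide)}.
#'
#' @param a,b \code{phylo} objects on the same leafset; either may be
#'   multifurcating.
#' @return a non-negative integer, at most \code{n - 3}.
#' @examples
#' star <- parse_newick("(1,2,3,4,5,6,7,8);")
#' cat8 <- parse_newick("(1,(2,(3,(4,(5,(6,(7,8)))))));")
#' fn_distance(star, cat8)  # 5: the star resolves nothing
#' fn_distance(cat8, star)  # 0: the star has no splits to miss
#' @export
fn_distance <- function(a, b) {
  check_same_leafset(a, b)
  ka <- g_keyset(as_graph(a))
  kb <- g_keyset(as_graph(b))
  sum(!(kb %in% ka))
}

#' Robinson-Foulds distance
#'
#' The number of nontrivial bipartitions present in exactly one of the
#' two trees (the symmetric difference of their split sets); equals
#' \code{fn_distance(a, b) + fn_distance(b, a)}.
#'
#' @inheritParams fn_distance
#' @return a non-negative integer, at most \code{2n - 6}.
#' @export
rf_distance <- function(a, b) {
  check_same_leafset(a, b)
  ka <- g_keyset(as_graph(a))
  kb <- g_keyset(as_graph(b))
  sum(!(kb %in% ka)) + sum(!(ka %in% kb))
}

#' Normalized Robinson-Foulds error rate
#'
#' The RF distance divided by \code{2N - 6}, the total number of
#' nontrivial bipartitions of two binary trees on \code{N} leaves. Ranges
#' from 0 (identical) to 1 (binary trees sharing no nontrivial split).
#'
#' @param estimated,true_tree \code{phylo} objects on the same leafset of
#'   at least 4 taxa.
#' @return a real number in [0, 1].
#' @export
normalized_rf_error <- function(estimated, true_tree) {
  la <- check_same_leafset(estimated, true_tree)
  n <- length(la)
  if (n < 4L) {
    stop("normalized RF error needs at least 4 taxa (denominator 2N - 6)",
         call. = FALSE)
  }
  rf_distance(estimated, true_tree) / (2L * n - 6L)
}
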