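# Shared fixtures and generators for the test suite. All fixtures are
# built in code; randomized cases run under fixed seeds.

caterpillar8 <- function() parse_newick("(1,(2,(3,(4,(5,(6,(7,8)))))));")
cat_t1 <- function() parse_newick("(1,(5,(6,7)));")
cat_t2 <- function() parse_newick("(2,(3,(4,8)));")
star8 <- function() parse_newick("(1,2,3,4,5,6,7,8);")

# A merge instance whose constraint sets are a random (not necessarily
# convex) partition of the taxa into k blocks with sizes in [minsz, maxsz];
# constraints are induced subtrees of the true tree, the guide a perturbed
# copy. Returns list(guide, constraints, true_tree).
random_partition_instance <- function(n, k, minsz, maxsz, moves, seed) {
  taxa <- paste0("t", seq_len(n))
  true <- random_binary_tree(taxa, seed)
  grp <- withr_seed(seed + 1L, {
    repeat {
      grp <- sample(rep(seq_len(k), length.out = n))
      szs <- tabulate(grp, k)
      if (all(szs >= minsz) && all(szs <= maxsz)) break
    }
    grp
  })
  cons <- lapply(seq_len(k), function(i) restrict(true, taxa[grp == i]))
  guide <- perturb_nni(true, moves, seed + 2L)
  list(guide = guide, constraints = cons, true_tree = true)
}

# run code under a seed without touching the session RNG state
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# independent split-set extraction via ape, for cross-checking:
# returns the canonical keys of the nontrivial splits of a phylo
ape_split_keys <- function(t) {
  taxa <- sort(t$tip.label, method = "radix")
  pp <- ape::prop.part(t)
  labs <- attr(pp, "labels")
  n <- length(taxa)
  keys <- character(0)
  for (p in pp) {
    side <- sort(labs[p], method = "radix")
    if (min(length(side), n - length(side)) <= 1L) next
    if (!(taxa[1L] %in% side)) side <- setdiff(taxa, side)
    keys <- c(keys, paste(side, collapse = ","))
  }
  sort(unique(keys), method = "radix")
}
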