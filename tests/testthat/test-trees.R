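test_that("newick parsing unroots and canonicalizes", {
  expect_equal(write_newick(parse_newick("(a,(b,c));")), "(a,b,c);")
  expect_equal(write_newick(parse_newick("((c,b),a);")), "(a,b,c);")
  # 8-taxon caterpillar: 5 nontrivial splits
  bp <- bipartitions(caterpillar8())
  expect_equal(as.character(bp),
               c("1,2", "1,2,3", "1,2,3,4", "1,2,3,4,5", "1,2,3,4,5,6"))
  # multifurcation survives writing
  expect_equal(write_newick(parse_newick("(a,b,c,(d,e,f));")),
               "(a,b,c,(d,e,f));")
  # quoted labels round-trip
  tq <- parse_newick("('sp one','sp; two',c);")
  expect_setequal(leafset(tq), c("sp one", "sp; two", "c"))
  expect_equal(leafset(parse_newick(write_newick(tq))), leafset(tq))
})

test_that("parse errors are raised for malformed input", {
  expect_error(parse_newick("((a,b);"), "malformed")
  expect_error(parse_newick("(a,(b,a));"), "duplicate")
  expect_error(parse_newick(""), "empty")
})

test_that("parse/write round-trip preserves the split set", {
  for (s in 1:25) {
    n <- withr_seed(s, sample(4:64, 1))
    t <- random_binary_tree(paste0("x", 1:n), 100 + s)
    # sometimes collapse a few edges to get multifurcations
    if (s %% 3 == 0 && n >= 6) {
      bp <- bipartitions(t)
      pick <- withr_seed(s, sample(seq_along(bp), min(3, length(bp))))
      t <- collapse_splits(t, lapply(bp[pick], function(k) strsplit(k, ",")[[1]]))
    }
    t2 <- parse_newick(write_newick(t))
    expect_identical(bipartitions(t2), bipartitions(t))
    expect_identical(write_newick(t2), write_newick(t))
  }
})

test_that("bipartition counts match tree resolution", {
  expect_length(bipartitions(star8()), 0)
  expect_length(bipartitions(parse_newick("((a,b),(c,d));")), 1)
  for (n in c(4, 9, 33)) {
    t <- random_binary_tree(paste0("x", 1:n), n)
    expect_length(bipartitions(t), n - 3)
    expect_length(bipartitions(t, include_trivial = TRUE), 2 * n - 3)
  }
})

test_that("bipartitions agree with an independent extraction", {
  for (s in 1:10) {
    t <- random_binary_tree(paste0("x", 1:20), 500 + s)
    expect_equal(as.character(bipartitions(t)), ape_split_keys(t))
  }
})

test_that("restriction reproduces the worked subtrees", {
  cat8 <- caterpillar8()
  r1 <- restrict(cat8, c("1", "5", "6", "7"))
  expect_identical(bipartitions(r1), bipartitions(cat_t1()))
  r2 <- restrict(cat8, c("2", "3", "4", "8"))
  expect_identical(bipartitions(r2), bipartitions(cat_t2()))
  # identity restriction
  expect_identical(bipartitions(restrict(cat8, leafset(cat8))),
                   bipartitions(cat8))
  expect_error(restrict(cat8, c("1", "99")), "not in tree")
})

test_that("restriction is idempotent and composes", {
  for (s in 1:8) {
    t <- random_binary_tree(paste0("x", 1:16), 700 + s)
    A <- withr_seed(s, sample(leafset(t), 10))
    B <- withr_seed(s + 50, sample(A, 5))
    expect_identical(write_newick(restrict(restrict(t, A), B)),
                     write_newick(restrict(t, B)))
    expect_identical(write_newick(restrict(restrict(t, A), A)),
                     write_newick(restrict(t, A)))
  }
})

test_that("every nontrivial split of a restriction restricts a full split", {
  t <- random_binary_tree(paste0("x", 1:12), 31)
  A <- sort(paste0("x", c(1, 3, 4, 6, 8, 9, 12)))
  r <- restrict(t, A)
  full <- bipartitions(t, include_trivial = TRUE)
  # restrict each full split to A and collect the nontrivial keys
  restricted <- character(0)
  for (k in full) {
    side <- intersect(strsplit(k, ",")[[1]], A)
    if (min(length(side), length(A) - length(side)) <= 1L) next
    if (!(A[1] %in% side)) side <- setdiff(A, side)
    restricted <- c(restricted, paste(sort(side, method = "radix"), collapse = ","))
  }
  expect_true(all(as.character(bipartitions(r)) %in% restricted))
})

test_that("collapsing splits removes exactly those splits", {
  cat8 <- caterpillar8()
  bp <- bipartitions(cat8)
  allgone <- collapse_splits(cat8, lapply(bp, function(k) strsplit(k, ",")[[1]]))
  expect_length(bipartitions(allgone), 0)
  expect_identical(leafset(allgone), leafset(cat8))
  expect_identical(write_newick(collapse_splits(cat8, list())),
                   write_newick(cat8))
  one <- collapse_splits(cat8, list(c("1", "2", "3")))
  expect_identical(as.character(bipartitions(one)),
                   setdiff(as.character(bp), "1,2,3"))
  expect_error(collapse_splits(cat8, list("1")), "trivial")
  expect_error(collapse_splits(cat8, list(c("1", "3"))), "no edge")
})

test_that("joining disjoint trees preserves both inputs", {
  q <- join_trees(parse_newick("(a,b);"), parse_newick("(c,d);"))
  expect_equal(as.character(bipartitions(q)), "a,b")
  t1 <- cat_t1(); t2 <- cat_t2()
  j <- join_trees(t1, t2, at1 = "1", at2 = "2")
  expect_identical(bipartitions(restrict(j, leafset(t1))), bipartitions(t1))
  expect_identical(bipartitions(restrict(j, leafset(t2))), bipartitions(t2))
  expect_error(join_trees(t1, t1), "overlap")
})

test_that("every attachment choice yields a compatibility supertree", {
  t1 <- random_binary_tree(paste0("a", 1:4), 1)
  t2 <- random_binary_tree(paste0("b", 1:4), 2)
  sides1 <- bipartitions(t1, include_trivial = TRUE)
  sides2 <- bipartitions(t2, include_trivial = TRUE)
  for (s1 in sides1) {
    for (s2 in sides2) {
      j <- join_trees(t1, t2,
                      at1 = strsplit(s1, ",")[[1]],
                      at2 = strsplit(s2, ",")[[1]])
      expect_true(is_compatibility_supertree(j, list(t1, t2)))
    }
  }
})

test_that("branch lengths pass through untouched edges only", {
  t <- parse_newick("((a:1,b:2):0.5,(c:3,d:4):0.25);")
  s <- write_newick(t)
  expect_match(s, "a:1")
  expect_match(s, "d:4")
  # joining adds length-free edges; subdivided edges lose their length,
  # untouched edges keep theirs
  j <- join_trees(t, parse_newick("(e:9,(f:8,g:7));"), at1 = c("a", "b"),
                  at2 = "e")
  js <- write_newick(j)
  expect_match(js, "f:8")
  expect_match(js, "g:7")
  expect_match(js, "a:1")
  expect_false(grepl("e:9", js))   # pendant edge of e was subdivided
})

test_that("single- and two-taxon trees round-trip", {
  expect_equal(write_newick(restrict(caterpillar8(), "3")), "(3);")
  expect_equal(leafset(parse_newick("(3);")), "3")
  two <- restrict(caterpillar8(), c("2", "7"))
  expect_equal(write_newick(two), "(2,7);")
})
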