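Package: gtmerge
Title: Guide-Tree Merging of Leaf-Disjoint Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges a collection of leaf-disjoint constraint trees into a
    single compatibility supertree by adding connecting edges, choosing the
    connections so that the number of guide-tree bipartitions missing from
    the merged tree (the false-negative distance) is provably minimal among
    all unblended mergers. Includes the supporting machinery of
    divide-and-conquer species-tree pipelines: centroid edge decomposition
    of a starting tree into bounded-size taxon subsets, Robinson-Foulds and
    false-negative bipartition distances, a brute-force enumeration oracle
    for small instances, and a seeded generator of synthetic problem
    instances. Trees are exchanged as 'ape' phylo objects read from and
    written to Newick.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
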