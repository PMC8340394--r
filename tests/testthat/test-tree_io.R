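test_that("newick parsing reads structure, labels and child order", {
  t <- parse_newick("((a,b)x,c)r;")
  expect_equal(t$labels[t$root], "r")
  expect_setequal(t$labels[t$leaves], c("a", "b", "c"))
  expect_equal(postorder_edges(t), c("a", "b", "x", "c", "r"))
  # branch lengths and support values are ignored
  t2 <- parse_newick("((a:1.5,b:2)x:0.1,c:3)r;")
  expect_equal(postorder_edges(t2), postorder_edges(t))
  # mirrored child order yields the mirrored postorder
  t3 <- parse_newick("(c,(b,a)x)r;")
  expect_equal(postorder_edges(t3), c("c", "b", "a", "x", "r"))
})

test_that("degenerate and malformed newick inputs are handled", {
  # a singleton root child is parseable (the binary solver rejects it later)
  t1 <- parse_newick("(a);")
  expect_equal(sum(t1$is_leaf), 1L)
  expect_error(
    dtlor_instance(fix_species3(), t1, phi = c(a = "a"), gamma = c(a = 1)),
    "at least two children")
  # a bare label is a single-vertex tree
  expect_equal(parse_newick("ga;")$n, 1L)
  expect_error(parse_newick("((a,b),(a,c));"), "duplicate leaf label")
  expect_error(parse_newick("((a,b)"), "parse error")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick(";"), "parse error")
})

test_that("parse/write round trip preserves topology and labels", {
  set.seed(101)
  for (i in 1:20) {
    t <- random_topology(sample(2:64, 1L), "t")
    s <- write_newick(t)
    t2 <- parse_newick(s)
    expect_equal(write_newick(t2), s)
    expect_equal(sort(t2$labels[t2$leaves]), sort(t$labels[t$leaves]))
  }
})

test_that("postorder covers every edge once, children first", {
  set.seed(102)
  for (i in 1:10) {
    t <- random_topology(sample(2:30, 1L))
    po <- postorder_edges(t)
    expect_equal(length(po), t$n)
    expect_setequal(po, t$labels)
    pos <- match(t$labels, po)
    for (v in seq_len(t$n)[-t$root])
      expect_lt(pos[v], pos[t$parent[v]])
    expect_equal(po[t$n], t$labels[t$root]) # handle last
  }
})

test_that("ancestry predicate agrees with a path-walk oracle", {
  set.seed(103)
  for (i in 1:8) {
    t <- random_topology(sample(2:64, 1L))
    pairs <- cbind(sample.int(t$n, 40, replace = TRUE),
                   sample.int(t$n, 40, replace = TRUE))
    for (j in seq_len(nrow(pairs))) {
      u <- pairs[j, 1L]; v <- pairs[j, 2L]
      expect_identical(is_ancestor(t, u, v),
                       u != v && walk_is_ancestor(t, u, v))
      expect_identical(are_comparable(t, u, v),
                       u == v || walk_is_ancestor(t, u, v) ||
                         walk_is_ancestor(t, v, u))
    }
  }
  t <- parse_newick("((a,b)x,c)r;")
  expect_true(is_ancestor(t, "r", "a"))
  expect_false(is_ancestor(t, "a", "a"))
  expect_false(are_comparable(t, "a", "c"))
  expect_error(is_ancestor(t, "zz", "a"), "not in tree")
})

test_that("association tables are read and validated", {
  S <- fix_species3()
  G <- parse_newick("(ga,gb)u;")
  mk <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
  }
  map <- mk(c("# gene\tspecies", "ga\ta", "gb\tb"))
  syn <- mk(c("ga\t1", "gb\t2"))
  a <- read_associations(map, syn, G, S)
  expect_equal(unname(a$phi[c("ga", "gb")]), c("a", "b"))
  expect_equal(a$labels, c(1L, 2L))
  syn1 <- mk(c("ga\t1", "gb\t1"))
  expect_equal(read_associations(map, syn1, G, S)$labels, 1L)
  expect_error(read_associations(mk(c("ga\ta")), syn, G, S),
               "gb")
  expect_error(read_associations(mk(c("ga\tzz", "gb\tb")), syn, G, S),
               "zz")
  expect_error(read_associations(map, mk(c("ga\t0", "gb\t1")), G, S),
               "positive integer")
  expect_error(read_associations(map, mk(c("ga\t1", "ga\t2", "gb\t1")), G, S),
               "duplicate")
})
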