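# Shared fixture builders. All fixtures are constructed in code; the worked
# toy instances are certified against the brute-force oracle inside the
# tests that use them.

fix_species3 <- function() parse_newick("((a,b)x,c)r;")

fix_iso3 <- function(costs = dtlor_costs()) {
  dtlor_instance(fix_species3(), parse_newick("((ga,gb)u,gc)v;"),
                 phi = c(ga = "a", gb = "b", gc = "c"),
                 gamma = c(ga = 1, gb = 1, gc = 1), costs = costs)
}

fix_mixed_synteny <- function(costs = dtlor_costs()) {
  dtlor_instance(fix_species3(), parse_newick("((ga,gb)u,gc)v;"),
                 phi = c(ga = "a", gb = "b", gc = "c"),
                 gamma = c(ga = 1, gb = 1, gc = 2), costs = costs)
}

fix_cherry_dup <- function(costs = dtlor_costs()) {
  dtlor_instance(fix_species3(), parse_newick("(ga,gb)u;"),
                 phi = c(ga = "a", gb = "a"),
                 gamma = c(ga = 1, gb = 1), costs = costs)
}

fix_trifurcation <- function(costs = dtlor_costs()) {
  dtlor_instance(fix_species3(), parse_newick("(g1,g2,g3)v;"),
                 phi = c(g1 = "a", g2 = "b", g3 = "c"),
                 gamma = c(g1 = 1, g2 = 1, g3 = 1), costs = costs)
}

# random small configuration drawn from the acceptance study conditions:
# species and gene trees up to 5 leaves, up to 3 syntenic regions, integer
# costs in 0..3
draw_small_config <- function(seed, max_leaves = 5L, max_labels = 3L,
                              max_arity = 2L, p_polytomy = 0) {
  gl <- sample(2:max_leaves, 1L)
  synth_config(
    seed = seed,
    species_leaves = sample(2:max_leaves, 1L),
    gene_leaves = gl,
    n_labels = min(sample.int(max_labels, 1L), gl),
    max_arity = max_arity, p_polytomy = p_polytomy,
    costs = dtlor_costs(sample(0:3, 1L), sample(0:3, 1L), sample(0:3, 1L),
                        sample(0:3, 1L), sample(0:3, 1L)))
}

# independent ancestor check by walking the parent chain
walk_is_ancestor <- function(tree, u, v) {
  w <- tree$parent[v]
  while (!is.na(w)) {
    if (w == u) return(TRUE)
    w <- tree$parent[w]
  }
  FALSE
}

# brute-force synteny oracle: minimum rearrangement cost over all full
# labelings of the subtree at g with the root labeled l
brute_synteny <- function(gene, gamma_idx, nL, R, g, l) {
  ints <- which(!gene$is_leaf)
  sub <- function(v) { # vertices of the subtree rooted at g
    out <- v
    for (c in gene$children[[v]]) out <- c(out, sub(c))
    out
  }
  verts <- sub(g)
  free <- setdiff(intersect(verts, ints), g)
  lab <- rep(NA_integer_, gene$n)
  lab[intersect(verts, which(gene$is_leaf))] <-
    gamma_idx[intersect(verts, which(gene$is_leaf))]
  lab[g] <- l
  if (gene$is_leaf[g]) lab[g] <- gamma_idx[g]
  if (gene$is_leaf[g] && gamma_idx[g] != l) return(Inf)
  grid <- if (length(free))
    as.matrix(expand.grid(rep(list(seq_len(nL)), length(free)),
                          KEEP.OUT.ATTRS = FALSE)) else
    matrix(integer(0), nrow = 1L, ncol = 0L)
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    lab2 <- lab
    lab2[free] <- grid[i, ]
    cost <- 0
    for (v in setdiff(verts, g))
      cost <- cost + R * (lab2[v] != lab2[gene$parent[v]])
    best <- min(best, cost)
  }
  best
}

double_factorial_resolutions <- function(k) prod(seq(2 * k - 3, 1, by = -2))

# canonical string form of a nested-pair resolution (subtrees ordered by
# their smallest leaf), used to check duplicate-freeness
canonical_form <- function(t) {
  if (!is.list(t)) return(list(min = t, repr = as.character(t)))
  a <- canonical_form(t[[1L]]); b <- canonical_form(t[[2L]])
  if (a$min > b$min) { tmp <- a; a <- b; b <- tmp }
  list(min = a$min, repr = paste0("(", a$repr, ",", b$repr, ")"))
}
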