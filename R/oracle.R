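# Brute-force reference implementations, used for verification only. The
# species mappings are enumerated as raw assignments and filtered by
# vectorized constraint checks; event costing here is an independent
# re-derivation from first principles (classification by where child images
# fall, losses by path lengths, origins by the unknown-region frontier) and
# shares no code with the dynamic programs. Deliberately simple over clever.

oracle_guard <- function(gene, species) {
  m <- sum(!gene$is_leaf)
  if (gene$n > 13L || species$n > 9L)
    stop("oracle size guard exceeded (|V(G)| <= 13, |V(S)| <= 9): ",
         gene$n, " gene and ", species$n, " species vertices")
  if ((species$n + 1)^m > 4e6)
    stop("oracle assignment space too large: (", species$n, "+1)^", m)
  invisible(m)
}

#' Enumerate all valid species mappings
#'
#' Every assignment of the internal gene vertices to species vertices or the
#' outside location, filtered by the mapping constraints (children inside
#' when the parent is inside, no child on a proper ancestor, at least one
#' child equal-or-below). Leaves are fixed by the leaf map.
#'
#' @param instance a [dtlor_instance()] with binary gene tree (small; hard
#'   size guards apply).
#' @return integer matrix, one row per valid mapping, one column per
#'   internal gene vertex (named), `0` encoding the outside location `N`.
#' @export
enumerate_species_maps <- function(instance) {
  G <- instance$gene; S <- instance$species
  oracle_guard(G, S)
  ints <- G$postorder[!G$is_leaf[G$postorder]]
  m <- length(ints)
  if (m == 0L)
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  A <- as.matrix(expand.grid(rep(list(0:S$n), m), KEEP.OUT.ATTRS = FALSE))
  colnames(A) <- G$labels[ints]
  anc <- ancestor_matrix(S)
  # padded lookups so that index 0 (= N) is always FALSE
  ancp <- rbind(FALSE, cbind(FALSE, anc))
  lookup_anc <- function(a, b) ancp[cbind(a + 1L, b + 1L)] # a proper anc of b
  img <- function(v) {
    if (G$is_leaf[v]) rep(instance$phi_idx[v], nrow(A)) else
      A[, match(v, ints)]
  }
  keep <- rep(TRUE, nrow(A))
  for (g in ints) {
    p <- img(g)
    ok_children <- rep(TRUE, nrow(A))
    any_deq <- rep(FALSE, nrow(A))
    for (c in G$children[[g]]) {
      ci <- img(c)
      ok_children <- ok_children & ci > 0L & !lookup_anc(ci, p)
      any_deq <- any_deq | ci == p | lookup_anc(p, ci)
    }
    keep <- keep & (p == 0L | (ok_children & any_deq))
  }
  A[keep, , drop = FALSE]
}

# vectorized event costing over all mapping rows: duplication/transfer
# classification, path-length losses, origin count. Returns cost excluding
# rearrangements plus per-row bookkeeping needed for the synteny part.
oracle_species_costs <- function(instance, A) {
  G <- instance$gene; S <- instance$species
  cst <- instance$costs
  anc <- ancestor_matrix(S)
  ancp <- rbind(FALSE, cbind(FALSE, anc))
  lanc <- function(a, b) ancp[cbind(a + 1L, b + 1L)]
  depth0 <- c(0L, S$depth) # padded: depth0[i+1]
  ints <- G$postorder[!G$is_leaf[G$postorder]]
  nr <- nrow(A)
  img <- function(v) {
    if (G$is_leaf[v]) rep(instance$phi_idx[v], nr) else A[, match(v, ints)]
  }
  sc1 <- child_index(S, 1L); sc2 <- child_index(S, 2L)
  cost <- numeric(nr)
  is_spec <- vector("list", G$n)
  for (g in ints) {
    p <- img(g)
    ch <- G$children[[g]]
    i1 <- img(ch[1L]); i2 <- img(ch[2L])
    deq <- function(a, b) a == b | lanc(b, a)
    pint <- p > 0L & !S$is_leaf[pmax(p, 1L)]
    x <- ifelse(pint, sc1[pmax(p, 1L)], 0L)
    y <- ifelse(pint, sc2[pmax(p, 1L)], 0L)
    spec <- pint & ((deq(i1, x) & deq(i2, y)) | (deq(i1, y) & deq(i2, x)))
    dup <- p > 0L & !spec & deq(i1, p) & deq(i2, p)
    trans <- p > 0L & !spec & !dup
    cost <- cost + dup * cst$duplication + trans * cst$transfer
    is_spec[[g]] <- spec
  }
  origins <- as.numeric(img(G$root) > 0L)
  for (v in seq_len(G$n)[-G$root]) {
    p <- img(G$parent[v]); cv <- img(v)
    proper <- p > 0L & cv > 0L & lanc(p, cv)
    top_counts <- if (is.null(is_spec[[G$parent[v]]])) rep(TRUE, nr) else
      !is_spec[[G$parent[v]]]
    nl <- ifelse(proper, depth0[cv + 1L] - depth0[p + 1L] - 1L +
                   as.numeric(top_counts), 0)
    cost <- cost + cst$loss * nl
    origins <- origins + (p == 0L & cv > 0L)
  }
  list(cost = cost + cst$origin * origins, origins = origins)
}

# minimum rearrangement cost and number of optimal labelings over all full
# actual labelings of the non-N internal vertices, for one N-pattern
oracle_synteny_part <- function(instance, n_pattern, ints) {
  G <- instance$gene
  nL <- length(instance$association$labels)
  R <- instance$costs$rearrangement
  free <- ints[!n_pattern] # internal vertices with actual regions
  m2 <- length(free)
  if (m2 == 0L) return(list(min = 0, count = 1))
  B <- as.matrix(expand.grid(rep(list(seq_len(nL)), m2),
                             KEEP.OUT.ATTRS = FALSE))
  lab <- function(v) {
    if (G$is_leaf[v]) rep(instance$gamma_idx[v], nrow(B))
    else if (v %in% free) B[, match(v, free)]
    else rep(NA_integer_, nrow(B)) # vertex at N
  }
  rcount <- numeric(nrow(B))
  for (v in seq_len(G$n)[-G$root]) {
    lv <- lab(v); lp <- lab(G$parent[v])
    if (all(is.na(lv)) || all(is.na(lp))) next
    rcount <- rcount + (!is.na(lv) & !is.na(lp) & lv != lp)
  }
  val <- R * rcount
  list(min = min(val), count = sum(val == min(val)))
}

#' Brute-force optimum by exhaustive enumeration
#'
#' Minimum total event cost over all valid mapping pairs, with the exact
#' number of optimal pairs; used as the reference the dynamic programs are
#' checked against. For a fixed species mapping the rearrangement part
#' depends only on which vertices are outside the species tree, so labelings
#' are enumerated once per outside-pattern.
#'
#' @param instance a small binary [dtlor_instance()].
#' @return list of class `dtlor_oracle` with `opt` (minimum cost), `count`
#'   (number of optimal mapping pairs) and `n_maps` (number of valid species
#'   mappings).
#' @export
brute_force_opt <- function(instance) {
  G <- instance$gene
  A <- enumerate_species_maps(instance)
  ints <- G$postorder[!G$is_leaf[G$postorder]]
  spc <- oracle_species_costs(instance, A)
  patterns <- if (ncol(A))
    apply(A == 0L, 1L, function(r) paste(as.integer(r), collapse = "")) else
    rep("", nrow(A))
  syn_min <- numeric(nrow(A))
  syn_cnt <- numeric(nrow(A))
  for (pt in unique(patterns)) {
    rows <- patterns == pt
    part <- oracle_synteny_part(instance, strsplit(pt, "")[[1L]] == "1",
                                ints)
    syn_min[rows] <- part$min
    syn_cnt[rows] <- part$count
  }
  total <- spc$cost + syn_min
  opt <- min(total)
  structure(list(opt = opt, count = sum(syn_cnt[total == opt]),
                 n_maps = nrow(A)),
            class = "dtlor_oracle")
}

# all complete binary resolutions of a multifurcating gene tree: one
# resolution choice per multifurcation, combined as a cartesian product
resolve_tree <- function(gene, choices) {
  # choices: named list, vertex label -> nested-pair resolution of children
  n_new <- sum(vapply(choices, function(h) {
    cnt <- function(t) if (is.list(t)) 1L + cnt(t[[1L]]) + cnt(t[[2L]]) else 0L
    cnt(h) - 1L
  }, integer(1)))
  labels <- character(0); parent <- integer(0)
  children <- list()
  add_vertex <- function(lab) {
    labels[length(labels) + 1L] <<- lab
    parent[length(labels)] <<- NA_integer_
    children[[length(labels)]] <<- integer(0)
    length(labels)
  }
  link <- function(p, c) {
    force(c) # child construction mutates the closure state
    parent[c] <<- p
    children[[p]] <<- c(children[[p]], c)
  }
  fresh <- 0L
  build <- function(v) { # returns new index for gene vertex v
    lab <- gene$labels[v]
    i <- add_vertex(lab)
    ch <- gene$children[[v]]
    if (length(ch) == 0L) return(i)
    if (is.null(choices[[lab]])) {
      for (c in ch) link(i, build(c))
    } else {
      expand <- function(t) {
        if (!is.list(t)) return(build(ch[t]))
        fresh <<- fresh + 1L
        j <- add_vertex(paste0(lab, "#", fresh))
        link(j, expand(t[[1L]]))
        link(j, expand(t[[2L]]))
        j
      }
      h <- choices[[lab]]
      link(i, expand(h[[1L]]))
      link(i, expand(h[[2L]]))
    }
    i
  }
  build(gene$root)
  new_rooted_tree(labels, parent, children)
}

#' Brute-force optimum over all complete binary resolutions
#'
#' Enumerates every complete binary resolution of the multifurcating gene
#' tree (cartesian product of per-vertex resolutions) and reconciles each
#' with the binary pipeline, returning the minimum; the reference for the
#' fixed-parameter solver. Binary input reduces to a single resolution.
#'
#' @param instance a small [dtlor_instance()] (resolution count guard 1e4).
#' @return list with `opt` and `n_resolutions`.
#' @export
brute_force_nonbinary <- function(instance) {
  G <- instance$gene
  multis <- which(!G$is_leaf & lengths(G$children) > 2L)
  per <- lapply(multis, function(v)
    enumerate_resolutions(length(G$children[[v]])))
  total <- prod(vapply(per, length, integer(1)))
  if (total > 1e4)
    stop("resolution space too large for the oracle: ", total)
  if (length(multis) == 0L)
    return(list(opt = dtlor_solve(instance, count = FALSE)$opt,
                n_resolutions = 1L))
  combo <- do.call(expand.grid,
                   c(lapply(per, seq_along), KEEP.OUT.ATTRS = FALSE))
  best <- Inf
  for (i in seq_len(nrow(combo))) {
    choices <- stats::setNames(
      lapply(seq_along(multis), function(j) per[[j]][[combo[i, j]]]),
      G$labels[multis])
    rt <- resolve_tree(G, choices)
    ri <- dtlor_instance(instance$species, rt,
                         association = instance$association,
                         costs = instance$costs)
    best <- min(best, dtlor_solve(ri, count = FALSE)$opt)
  }
  list(opt = best, n_resolutions = total)
}
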