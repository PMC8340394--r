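#' Rooted trees with a handle edge
#'
#' A `rooted_tree` stores a rooted phylogeny in flat index form. Every vertex
#' is identified with its incoming edge; the root's incoming edge is the
#' *handle*, an artificial edge from a virtual pre-root vertex. This makes
#' "gene edge placed on species edge" a vertex-pair-indexed notion, which is
#' the shape all reconciliation tables in this package use.
#'
#' Fields: `n` (vertex count), `labels` (unique vertex names), `parent`
#' (integer, `NA` at the root), `children` (list of integer vectors in input
#' order), `root`, `is_leaf`, `postorder` (children before parents, root
#' last), `depth` (root = 0), `leaves`.
#'
#' @param labels character vector of unique vertex names.
#' @param parent integer vector of parent indices (`NA` for the root).
#' @param children list of integer child vectors, one per vertex.
#' @return An object of class `rooted_tree`.
#' @export
new_rooted_tree <- function(labels, parent, children) {
  n <- length(labels)
  stopifnot(length(parent) == n, length(children) == n)
  if (anyDuplicated(labels))
    stop("duplicate vertex label: ", labels[duplicated(labels)][1L])
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root, found ", length(root))
  is_leaf <- lengths(children) == 0L
  # iterative postorder; also validates acyclicity/connectivity
  post <- integer(n)
  k <- 0L
  stack <- c(root)
  state <- integer(0) # expanded flags via two-phase stack: negative = emit
  stack <- root
  emit <- logical(length(stack))
  while (length(stack)) {
    v <- stack[length(stack)]
    e <- emit[length(emit)]
    stack <- stack[-length(stack)]
    emit <- emit[-length(emit)]
    if (e) {
      k <- k + 1L
      post[k] <- v
    } else {
      stack <- c(stack, v)
      emit <- c(emit, TRUE)
      ch <- children[[v]]
      if (length(ch)) {
        stack <- c(stack, rev(ch))
        emit <- c(emit, rep(FALSE, length(ch)))
      }
    }
  }
  if (k != n) stop("tree is not connected (", k, " of ", n, " vertices reachable)")
  depth <- integer(n)
  for (v in rev(post)) if (!is.na(parent[v])) depth[v] <- depth[parent[v]] + 1L
  structure(
    list(n = n, labels = labels, parent = parent, children = children,
         root = root, is_leaf = is_leaf, postorder = post, depth = depth,
         leaves = which(is_leaf)),
    class = "rooted_tree")
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("rooted_tree: ", sum(x$is_leaf), " leaves, ", x$n, " vertices, root '",
      x$labels[x$root], "'\n", sep = "")
  invisible(x)
}

#' Parse a rooted tree from a newick string
#'
#' Branch lengths and support values are accepted and ignored (the
#' reconciliation model is undated). Internal vertex labels are kept when
#' present and unique; otherwise stable names `n1, n2, ...` are generated in
#' vertex-index order. Child order follows the document order of the input.
#'
#' @param text a newick string, e.g. `"((a,b)x,c)r;"`.
#' @return a [new_rooted_tree()] object.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty newick input")
  # a bare label is a single-vertex tree (ape cannot represent it)
  if (grepl("^[^();,:\\s]+;?$", trimws(text), perl = TRUE)) {
    lab <- sub(";$", "", trimws(text))
    return(new_rooted_tree(lab, NA_integer_, list(integer(0))))
  }
  ph <- withCallingHandlers(
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("newick parse error: ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) stop("newick parse error: ", conditionMessage(w),
                               call. = FALSE))
  if (is.null(ph)) stop("newick parse error: unreadable tree in '", text, "'")
  phylo_to_rooted_tree(ph)
}

#' Read a rooted tree from a newick file
#' @param path path to a newick file (first tree is used).
#' @return a [new_rooted_tree()] object.
#' @export
read_tree <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

phylo_to_rooted_tree <- function(ph) {
  ntip <- length(ph$tip.label)
  n <- ntip + ph$Nnode
  if (anyDuplicated(ph$tip.label))
    stop("duplicate leaf label: ", ph$tip.label[duplicated(ph$tip.label)][1L])
  labels <- character(n)
  labels[seq_len(ntip)] <- ph$tip.label
  nl <- ph$node.label
  if (!is.null(nl)) labels[ntip + seq_along(nl)] <- nl
  blank <- !nzchar(labels) | is.na(labels)
  labels[blank] <- paste0("n", which(blank))
  if (anyDuplicated(labels)) { # internal labels clash: regenerate all internals
    labels[(ntip + 1L):n] <- paste0("n", (ntip + 1L):n)
    if (anyDuplicated(labels))
      stop("cannot assign unique vertex names (leaf labels use the n<k> form)")
  }
  parent <- rep(NA_integer_, n)
  children <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(ph$edge))) {
    a <- ph$edge[i, 1L]; b <- ph$edge[i, 2L]
    parent[b] <- a
    children[[a]] <- c(children[[a]], b)
  }
  new_rooted_tree(labels, parent, children)
}

#' Write a rooted tree as a newick string
#' @param tree a `rooted_tree`.
#' @return a newick string (topology and labels only).
#' @export
write_newick <- function(tree) {
  rec <- function(v) {
    if (tree$is_leaf[v]) return(tree$labels[v])
    paste0("(", paste(vapply(tree$children[[v]], rec, character(1)),
                      collapse = ","), ")", tree$labels[v])
  }
  paste0(rec(tree$root), ";")
}

#' Postorder sequence of edges
#'
#' Returns the vertex names in postorder under the vertex-equals-incoming-edge
#' identification: children edges precede parent edges and the handle (the
#' root's edge) comes last. Deterministic given the input child order.
#'
#' @param tree a `rooted_tree`.
#' @return character vector of length `tree$n`.
#' @export
postorder_edges <- function(tree) tree$labels[tree$postorder]

vertex_index <- function(tree, v) {
  i <- match(v, tree$labels)
  if (anyNA(i)) stop("vertex not in tree: ", v[is.na(i)][1L])
  i
}

#' Strict ancestry test
#'
#' `is_ancestor` is `TRUE` iff `u` is a *proper* ancestor of `v`.
#' `are_comparable` is `TRUE` iff one is an ancestor of the other or they are
#' equal.
#'
#' @param tree a `rooted_tree`.
#' @param u,v vertex names (or integer indices).
#' @return logical scalar.
#' @export
is_ancestor <- function(tree, u, v) {
  ui <- if (is.character(u)) vertex_index(tree, u) else u
  vi <- if (is.character(v)) vertex_index(tree, v) else v
  if (ui == vi) return(FALSE)
  w <- tree$parent[vi]
  while (!is.na(w)) {
    if (w == ui) return(TRUE)
    w <- tree$parent[w]
  }
  FALSE
}

#' @rdname is_ancestor
#' @export
are_comparable <- function(tree, u, v) {
  ui <- if (is.character(u)) vertex_index(tree, u) else u
  vi <- if (is.character(v)) vertex_index(tree, v) else v
  ui == vi || is_ancestor(tree, ui, vi) || is_ancestor(tree, vi, ui)
}

# n x n logical matrix: [u, v] TRUE iff u is a proper ancestor of v
ancestor_matrix <- function(tree) {
  n <- tree$n
  A <- matrix(FALSE, n, n)
  for (v in rev(tree$postorder)) { # preorder
    p <- tree$parent[v]
    if (!is.na(p)) A[, v] <- A[, p] | (seq_len(n) == p)
  }
  A
}

is_binary_tree <- function(tree) {
  all(lengths(tree$children)[!tree$is_leaf] == 2L)
}

# first/second child index vectors (NA at leaves), used by the DP fills
child_index <- function(tree, which) {
  vapply(seq_len(tree$n), function(v) {
    ch <- tree$children[[v]]
    if (length(ch) >= which) ch[which] else NA_integer_
  }, integer(1))
}

sibling_index <- function(tree) {
  sib <- rep(NA_integer_, tree$n)
  for (v in seq_len(tree$n)) {
    ch <- tree$children[[v]]
    if (length(ch) == 2L) { sib[ch[1L]] <- ch[2L]; sib[ch[2L]] <- ch[1L] }
  }
  sib
}

#' Leaf associations between a gene tree and a species tree
#'
#' Bundles the two leaf-level inputs of a reconciliation instance: the
#' species map `phi` (gene leaf -> species leaf) and the syntenic-region map
#' `gamma` (gene leaf -> positive integer). The label set `L` is taken to be
#' the image of `gamma`, so `gamma` is surjective by construction.
#'
#' @param phi named character vector: names are gene leaf labels, values
#'   species leaf labels.
#' @param gamma named integer-ish vector: names are gene leaf labels, values
#'   positive integers.
#' @param gene,species the two `rooted_tree`s the association refers to.
#' @return an object of class `leaf_association` with fields `phi`, `gamma`
#'   and `labels` (sorted unique syntenic regions).
#' @export
leaf_association <- function(phi, gamma, gene, species) {
  gl <- tree_leaf_labels(gene)
  sl <- tree_leaf_labels(species)
  if (is.null(names(phi)) || is.null(names(gamma)))
    stop("phi and gamma must be named by gene leaf label")
  miss <- setdiff(gl, names(phi))
  if (length(miss)) stop("gene leaf missing from species map: ", miss[1L])
  miss <- setdiff(gl, names(gamma))
  if (length(miss)) stop("gene leaf missing from synteny map: ", miss[1L])
  extra <- setdiff(names(phi), gl)
  if (length(extra)) stop("unknown gene leaf in species map: ", extra[1L])
  extra <- setdiff(names(gamma), gl)
  if (length(extra)) stop("unknown gene leaf in synteny map: ", extra[1L])
  bad <- setdiff(unname(phi), sl)
  if (length(bad)) stop("mapped species leaf not in species tree: ", bad[1L])
  gnum <- suppressWarnings(as.numeric(gamma))
  if (anyNA(gnum) || any(gnum != round(gnum)) || any(gnum < 1))
    stop("synteny values must be positive integers; offending gene leaf: ",
         names(gamma)[which(is.na(gnum) | gnum != round(gnum) | gnum < 1)[1L]])
  gamma <- stats::setNames(as.integer(gnum), names(gamma))
  structure(list(phi = phi[gl], gamma = gamma[gl],
                 labels = sort(unique(unname(gamma)))),
            class = "leaf_association")
}

tree_leaf_labels <- function(tree) tree$labels[tree$leaves]

read_two_column_tsv <- function(path, what) {
  d <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      colClasses = "character", quote = "",
                      stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("cannot read ", what, " table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(d) != 2L)
    stop(what, " table must have exactly two tab-separated columns: ", path)
  if (anyDuplicated(d[[1L]]))
    stop("duplicate gene-leaf row in ", what, " table: ",
         d[[1L]][duplicated(d[[1L]])][1L])
  d
}

#' Read leaf-association tables
#'
#' Both tables are two-column, tab-separated, UTF-8, without header;
#' `#`-prefixed lines are skipped. The first column is the gene leaf label;
#' the second is the associated species leaf (map table) or the positive
#' integer syntenic region (synteny table).
#'
#' @param map_path path of the gene-leaf to species-leaf table.
#' @param synteny_path path of the gene-leaf to syntenic-region table.
#' @param gene,species the corresponding `rooted_tree`s.
#' @return a [leaf_association()].
#' @export
read_associations <- function(map_path, synteny_path, gene, species) {
  m <- read_two_column_tsv(map_path, "leaf map")
  s <- read_two_column_tsv(synteny_path, "synteny")
  leaf_association(stats::setNames(m[[2L]], m[[1L]]),
                   stats::setNames(s[[2L]], s[[1L]]), gene, species)
}
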