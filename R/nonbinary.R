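# Fixed-parameter solver for multifurcating gene trees. Species and synteny
# mappings can no longer be decoupled (one resolution of a multifurcation can
# be best for the species map while another is best for the synteny map), so
# the program works on joint tables C(e_g, e_s, l): the optimal cost of
# reconciling the gene subtree with the gene edge placed on the species edge
# and the gene vertex in syntenic region l, rearrangements included. Every
# multifurcation is expanded into each of its (2k-3)!! binary resolutions,
# one vertex at a time (costs of resolved subtrees are reused through the
# tables, so the resolution count is additive over vertices, not
# multiplicative).

#' Enumerate binary resolutions of a multifurcation
#'
#' All topologically distinct rooted binary trees on `k` labeled leaves
#' (the children of the multifurcating vertex), generated by recursive leaf
#' insertion on every edge including the handle; there are `(2k-3)!!` of
#' them. Each resolution is a nested pair structure whose leaves are the
#' child indices `1..k`.
#'
#' @param k number of children (>= 2).
#' @param cap hard arity cap; beyond it the resolution count
#'   (1, 3, 15, 105, 945, ...) makes exhaustive resolution impractical.
#' @return list of nested-pair trees.
#' @export
enumerate_resolutions <- function(k, cap = 8L) {
  if (k < 2L) stop("binary resolutions are defined for k >= 2")
  if (k > cap)
    stop("multifurcation with ", k, " children exceeds the arity cap (",
         cap, "); raise max_arity to resolve it anyway")
  insert_everywhere <- function(t, i) {
    res <- list(list(t, i)) # on t's incoming edge (handle included)
    if (is.list(t)) {
      for (x in insert_everywhere(t[[1L]], i))
        res <- c(res, list(list(x, t[[2L]])))
      for (x in insert_everywhere(t[[2L]], i))
        res <- c(res, list(list(t[[1L]], x)))
    }
    res
  }
  trees <- list(1L)
  for (i in seq_len(k)[-1L]) {
    nxt <- list()
    for (t in trees) nxt <- c(nxt, insert_everywhere(t, i))
    trees <- nxt
  }
  trees
}

row_mins <- function(m)
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))

# loss continuation per label column (postorder over species edges)
loss_pass <- function(term_mat, lay, Lc) {
  for (l in seq_len(ncol(term_mat))) {
    col <- term_mat[, l]
    for (s in lay$post_int)
      col[s] <- min(col[s], Lc + col[lay$c1[s]], Lc + col[lay$c2[s]])
    term_mat[, l] <- col
  }
  term_mat
}

# best-transfer table derived from a placed-cost table: per label column,
# best entry bottom-up then transfer targets in preorder (infinite at the
# handle; sibling subtrees of ancestors are the only candidates).
bt_from_C <- function(Cmat, lay) {
  BT <- matrix(Inf, nrow(Cmat), ncol(Cmat))
  for (l in seq_len(ncol(Cmat))) {
    cc <- Cmat[, l]
    be <- cc
    for (s in lay$post_int)
      be[s] <- min(cc[s], be[lay$c1[s]], be[lay$c2[s]])
    btc <- rep(Inf, nrow(Cmat))
    for (s in lay$pre_int) {
      x <- lay$c1[s]; y <- lay$c2[s]
      btc[x] <- min(btc[s], be[y])
      btc[y] <- min(btc[s], be[x])
    }
    BT[, l] <- btc
  }
  BT
}

# joint recurrence for a binary vertex whose children have placed tables
# C1/C2 and transfer tables BT1/BT2: each child term independently keeps the
# parent's label or pays R to switch to its free minimum.
joint_C <- function(C1, BT1, C2, BT2, lay, costs, nL) {
  D <- costs$duplication; Tc <- costs$transfer; Lc <- costs$loss
  R <- costs$rearrangement
  nS <- nrow(C1)
  C1L <- row_mins(C1); C2L <- row_mins(C2)
  BT1L <- row_mins(BT1); BT2L <- row_mins(BT2)
  out <- matrix(Inf, nS, nL)
  for (l in seq_len(nL)) {
    ct1 <- pmin(C1[, l], R + C1L)
    ct2 <- pmin(C2[, l], R + C2L)
    bt1 <- pmin(BT1[, l], R + BT1L)
    bt2 <- pmin(BT2[, l], R + BT2L)
    dup <- D + ct1 + ct2
    tr <- Tc + pmin(ct1 + bt2, ct2 + bt1)
    spec <- rep(Inf, nS)
    spec[lay$ii] <- pmin(ct1[lay$i1] + ct2[lay$i2],
                         ct1[lay$i2] + ct2[lay$i1])
    col <- pmin(spec, dup, tr)
    for (s in lay$post_int)
      col[s] <- min(col[s], Lc + col[lay$c1[s]], Lc + col[lay$c2[s]])
    out[, l] <- col
  }
  out
}

# Evaluate one binary resolution H of a multifurcation: H leaves inherit the
# children's tables; H-internal vertices are filled bottom-up with the joint
# recurrence. Returns the nested node structure (kind "G" for inherited
# children, "H" for resolution-internal vertices) with per-node placed table
# C, transfer table BT, origin cost and unknown-region cost.
eval_resolution <- function(H, ch, Ctab, BTtab, origin, null, lay, costs, nL) {
  O <- costs$origin
  build <- function(node) {
    if (!is.list(node)) {
      v <- ch[node]
      return(list(kind = "G", v = v, C = Ctab[[v]], BT = BTtab[[v]],
                  orig = origin[v], nul = null[v]))
    }
    k1 <- build(node[[1L]])
    k2 <- build(node[[2L]])
    Cn <- joint_C(k1$C, k1$BT, k2$C, k2$BT, lay, costs, nL)
    list(kind = "H", C = Cn, BT = bt_from_C(Cn, lay),
         orig = O + min(Cn),
         nul = min(k1$nul, k1$orig) + min(k2$nul, k2$orig),
         kids = list(k1, k2))
  }
  build(H)
}

#' Solve the DTLOR MPR problem for a multifurcating gene tree
#'
#' Processes gene edges in postorder; at each internal vertex every binary
#' resolution of its children is evaluated on the joint tables and the
#' per-cell minima (and the best unknown-region cost) are kept, together
#' with the winning resolution per cell for traceback. The result is the
#' optimum over all complete binary resolutions of the gene tree, one
#' optimal fully resolved binary gene tree, and its reconciliation (which
#' validates and re-scores to the optimum on the resolved tree). An
#' already-binary gene tree reproduces the decoupled solver's optimum.
#'
#' @param instance a [dtlor_instance()]; the species tree must be binary,
#'   gene-tree internal vertices may have any number of children up to
#'   `max_arity`.
#' @param max_arity cap on multifurcation arity (resolution counts grow as
#'   `(2k-3)!!`).
#' @param traceback also reconstruct the resolved tree and reconciliation?
#' @return object of class `dtlor_nb_solution` with `opt`, per-vertex
#'   `origin` and `null`, the merged tables, and when traced `resolved`
#'   (a `rooted_tree`) plus `reconciliation`.
#' @export
solve_nonbinary <- function(instance, max_arity = 8L, traceback = TRUE) {
  G <- instance$gene; S <- instance$species
  costs <- instance$costs
  O <- costs$origin; Lc <- costs$loss
  nL <- length(instance$association$labels)
  lay <- species_layout(S)
  Ctab <- BTtab <- Hwin <- resolutions <- vector("list", G$n)
  origin <- null <- rep(Inf, G$n)
  nullHwin <- rep(NA_integer_, G$n)
  for (g in G$postorder) {
    if (G$is_leaf[g]) {
      tm <- matrix(Inf, S$n, nL)
      tm[instance$phi_idx[g], instance$gamma_idx[g]] <- 0
      Cg <- loss_pass(tm, lay, Lc)
      Ctab[[g]] <- Cg
      BTtab[[g]] <- bt_from_C(Cg, lay)
      origin[g] <- O + min(Cg)
      next
    }
    ch <- G$children[[g]]
    res <- enumerate_resolutions(length(ch), cap = max_arity)
    resolutions[[g]] <- res
    bestC <- matrix(Inf, S$n, nL)
    Hw <- matrix(0L, S$n, nL)
    bestNull <- Inf
    for (hi in seq_along(res)) {
      rt <- eval_resolution(res[[hi]], ch, Ctab, BTtab, origin, null,
                            lay, costs, nL)
      upd <- rt$C < bestC
      bestC[upd] <- rt$C[upd]
      Hw[upd] <- hi
      if (rt$nul < bestNull) { bestNull <- rt$nul; nullHwin[g] <- hi }
    }
    Ctab[[g]] <- bestC
    BTtab[[g]] <- bt_from_C(bestC, lay)
    Hwin[[g]] <- Hw
    origin[g] <- O + min(bestC)
    null[g] <- bestNull
  }
  opt <- min(null[G$root], origin[G$root])
  sol <- structure(
    list(opt = opt, origin = origin, null = null, C = Ctab, BT = BTtab,
         Hwin = Hwin, nullHwin = nullHwin, resolutions = resolutions,
         instance = instance),
    class = "dtlor_nb_solution")
  if (traceback) {
    tb <- traceback_nonbinary(sol)
    sol$resolved <- tb$resolved
    sol$reconciliation <- tb$reconciliation
  }
  sol
}

#' @export
print.dtlor_nb_solution <- function(x, ...) {
  cat("dtlor_nb_solution: optimal cost ", x$opt,
      " over all binary resolutions\n", sep = "")
  invisible(x)
}

#' Trace back a resolved tree and reconciliation (polytomy solver)
#'
#' Deterministic traceback mirroring the binary rules (unknown-region before
#' origin at ties; speciation < loss < duplication < transfer; postorder-
#' first species edge, smallest label). Winning resolutions are re-evaluated
#' on demand. Multifurcations entirely outside the species tree are resolved
#' by a canonical left comb (any resolution is cost-neutral there).
#'
#' @param sol a [solve_nonbinary()] result.
#' @return list with `resolved` (binary `rooted_tree`) and `reconciliation`.
#' @export
traceback_nonbinary <- function(sol) {
  inst <- sol$instance
  G <- inst$gene; S <- inst$species
  costs <- inst$costs
  D <- costs$duplication; Tc <- costs$transfer; Lc <- costs$loss
  R <- costs$rearrangement; O <- costs$origin
  nL <- length(inst$association$labels)
  lay <- species_layout(S)
  sc1 <- child_index(S, 1L); sc2 <- child_index(S, 2L)
  sib <- sibling_index(S)
  rank <- post_rank(S)

  phi <- character(0)
  gamma <- integer(0) # label indices; NA = unknown region
  kids <- list()
  counter <- integer(G$n)
  new_name <- function(g) {
    counter[g] <<- counter[g] + 1L
    paste0(G$labels[g], "#", counter[g])
  }
  set_vertex <- function(name, s, l, children = NULL) {
    force(children) # child traces mutate the closure state
    phi[name] <<- if (is.na(s)) "N" else S$labels[s]
    gamma[name] <<- l
    if (!is.null(children)) kids[[name]] <<- children
    invisible(name)
  }
  argmin_cell <- function(M) {
    idx <- which(M == min(M), arr.ind = TRUE)
    idx[order(rank[idx[, 1L]], idx[, 2L])[1L], ]
  }
  reeval <- function(g, hi)
    eval_resolution(sol$resolutions[[g]][[hi]], G$children[[g]],
                    sol$C, sol$BT, sol$origin, sol$null, lay, costs, nL)

  be_col <- function(cc) {
    be <- cc
    for (s in lay$post_int) be[s] <- min(cc[s], be[sc1[s]], be[sc2[s]])
    be
  }
  bt_walk <- function(kid, s, l) {
    v <- kid$BT[s, l]
    bev <- be_col(kid$C[, l])
    cur <- s
    repeat {
      if (is.na(S$parent[cur])) internal_error("transfer target not found")
      sb <- sib[cur]
      if (!is.na(sb) && bev[sb] == v) {
        t <- sb
        while (!S$is_leaf[t] && kid$C[t, l] != v)
          t <- if (bev[sc1[t]] == v) sc1[t] else sc2[t]
        if (kid$C[t, l] != v) internal_error("best-entry descent failed")
        return(t)
      }
      cur <- S$parent[cur]
    }
  }

  # child term: keep the parent's label or switch to the child's free best
  pick <- function(M, s, l) {
    m <- min(M[s, ])
    if (M[s, l] <= R + m) list(val = M[s, l], lab = l)
    else list(val = R + m, lab = which(M[s, ] == m)[1L])
  }

  tb_gene <- function(g, s, l) { # trace placed cell of an original vertex
    name <- G$labels[g]
    if (G$is_leaf[g]) {
      if (l != inst$gamma_idx[g] || !is.finite(sol$C[[g]][s, l]))
        internal_error("leaf cell mismatch at ", name)
      return(set_vertex(name, inst$phi_idx[g], l))
    }
    hi <- sol$Hwin[[g]][s, l]
    if (hi == 0L) internal_error("untraceable cell at ", name)
    tb_hnode(reeval(g, hi), g, name, s, l)
    name
  }

  descend <- function(kid, g, s, l) {
    if (kid$kind == "G") tb_gene(kid$v, s, l)
    else {
      nm <- new_name(g)
      tb_hnode(kid, g, nm, s, l)
      nm
    }
  }

  tb_hnode <- function(node, g, name, s, l) {
    v <- node$C[s, l]
    if (!is.finite(v)) internal_error("infinite cell traced at ", name)
    k1 <- node$kids[[1L]]; k2 <- node$kids[[2L]]
    if (!S$is_leaf[s]) {
      x <- sc1[s]; y <- sc2[s]
      a1 <- pick(k1$C, x, l); a2 <- pick(k2$C, y, l)
      if (a1$val + a2$val == v)
        return(set_vertex(name, s, l, c(descend(k1, g, x, a1$lab),
                                        descend(k2, g, y, a2$lab))))
      b1 <- pick(k1$C, y, l); b2 <- pick(k2$C, x, l)
      if (b1$val + b2$val == v)
        return(set_vertex(name, s, l, c(descend(k1, g, y, b1$lab),
                                        descend(k2, g, x, b2$lab))))
      if (Lc + node$C[x, l] == v) return(tb_hnode(node, g, name, x, l))
      if (Lc + node$C[y, l] == v) return(tb_hnode(node, g, name, y, l))
    }
    d1 <- pick(k1$C, s, l); d2 <- pick(k2$C, s, l)
    if (D + d1$val + d2$val == v)
      return(set_vertex(name, s, l, c(descend(k1, g, s, d1$lab),
                                      descend(k2, g, s, d2$lab))))
    t1 <- pick(k1$C, s, l); w2 <- pick(k2$BT, s, l)
    if (Tc + t1$val + w2$val == v)
      return(set_vertex(name, s, l,
                        c(descend(k1, g, s, t1$lab),
                          descend(k2, g, bt_walk(k2, s, w2$lab), w2$lab))))
    t2 <- pick(k2$C, s, l); w1 <- pick(k1$BT, s, l)
    if (Tc + t2$val + w1$val == v)
      return(set_vertex(name, s, l,
                        c(descend(k1, g, bt_walk(k1, s, w1$lab), w1$lab),
                          descend(k2, g, s, t2$lab))))
    internal_error("no joint case achieves the cell value at ", name)
  }

  tb_origin_gene <- function(g) {
    cell <- argmin_cell(sol$C[[g]])
    tb_gene(g, cell[[1L]], cell[[2L]])
  }

  # unknown-region frontier: inside the winning resolution, each vertex
  # either stays unknown or roots an origin subtree
  null_or_origin <- function(kid, g) {
    if (kid$kind == "G") {
      v <- kid$v
      if (sol$null[v] <= sol$origin[v]) tb_null_gene(v) else tb_origin_gene(v)
    } else if (kid$nul <= kid$orig) {
      nm <- new_name(g)
      set_vertex(nm, NA, NA_integer_,
                 c(null_or_origin(kid$kids[[1L]], g),
                   null_or_origin(kid$kids[[2L]], g)))
      nm
    } else {
      cell <- argmin_cell(kid$C)
      nm <- new_name(g)
      tb_hnode(kid, g, nm, cell[[1L]], cell[[2L]])
      nm
    }
  }
  tb_null_gene <- function(g) {
    name <- G$labels[g]
    rt <- reeval(g, sol$nullHwin[g])
    set_vertex(name, NA, NA_integer_,
               c(null_or_origin(rt$kids[[1L]], g),
                 null_or_origin(rt$kids[[2L]], g)))
    name
  }

  r <- G$root
  root_name <- if (sol$null[r] <= sol$origin[r]) tb_null_gene(r) else
    tb_origin_gene(r)

  # assemble the resolved binary tree in preorder document order
  nm_order <- character(0)
  walk <- function(nm) {
    nm_order <<- c(nm_order, nm)
    for (c in kids[[nm]]) walk(c)
  }
  walk(root_name)
  idx <- stats::setNames(seq_along(nm_order), nm_order)
  parent <- rep(NA_integer_, length(nm_order))
  children <- rep(list(integer(0)), length(nm_order))
  for (nm in nm_order) {
    for (c in kids[[nm]]) {
      parent[idx[[c]]] <- idx[[nm]]
      children[[idx[[nm]]]] <- c(children[[idx[[nm]]]], idx[[c]])
    }
  }
  resolved <- new_rooted_tree(nm_order, parent, children)
  res_inst <- dtlor_instance(S, resolved, association = inst$association,
                             costs = costs)
  lab_vals <- inst$association$labels
  rec <- reconciliation(
    res_inst,
    stats::setNames(phi[nm_order], nm_order),
    stats::setNames(ifelse(is.na(gamma[nm_order]), NA_integer_,
                           lab_vals[gamma[nm_order]]), nm_order))
  if (rec$cost != sol$opt)
    internal_error("resolved reconciliation scores ", rec$cost,
                   " but the optimum is ", sol$opt)
  list(resolved = resolved, reconciliation = rec)
}
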