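# Decoupled species-map dynamic program (binary gene trees).
#
# Tables are [gene edge x species edge] matrices under the vertex-equals-
# incoming-edge identification. Alongside the "placed" table C we keep an
# explicit "terminates" table Term with Term(e_g,e_s) = optimal cost given
# Phi(g) = s. They satisfy
#   C(e_g,e_s) = min(Term(e_g,e_s), L + min_child C(e_g,e_child))
# and share all row minima, so every published recurrence value is unchanged;
# Term is what makes solution *counting* exact: origin entries and transfer
# landings induce no loss events, so counting over C cells would double-count
# mappings through zero-cost loss chains when L = 0.

species_layout <- function(S) {
  post_int <- S$postorder[!S$is_leaf[S$postorder]]
  c1 <- child_index(S, 1L)
  c2 <- child_index(S, 2L)
  ii <- which(!S$is_leaf)
  list(post_int = post_int, pre_int = rev(post_int),
       c1 = c1, c2 = c2, ii = ii, i1 = c1[ii], i2 = c2[ii])
}

#' Species-map dynamic-programming tables
#'
#' Fills, for a binary gene tree, the cost tables over all gene-edge x
#' species-edge pairs: `term` (gene edge terminates on the species edge,
#' i.e. the gene vertex maps there), `C` (gene edge placed on the species
#' edge, possibly continuing through losses), `best_entry` (cheapest
#' termination within the species subtree), `best_transfer` (cheapest
#' termination on an edge incomparable to the given one; infinite at the
#' species handle, which is never a transfer target), and the per-gene-vertex
#' optimum `opt` with `opt[g] = min_s term[g, s]`. Gene edges are processed
#' in postorder (outer loop) and species edges in postorder within, with
#' `best_transfer` derived in a preorder pass. When `count = TRUE`, parallel
#' tables with the exact number of optimal species mappings per cell are
#' filled.
#'
#' @param instance a [dtlor_instance()] with binary gene tree.
#' @param count also fill solution-count tables?
#' @return a list of class `dtlor_species_tables` with matrices `term`, `C`,
#'   `best_entry`, `best_transfer`, vector `opt`, and (optionally) `counts`
#'   with the same shapes.
#' @export
species_tables <- function(instance, count = TRUE) {
  G <- instance$gene
  S <- instance$species
  if (!is_binary_tree(G)) {
    v <- which(!G$is_leaf & lengths(G$children) != 2L)[1L]
    stop("gene tree has a multifurcation at vertex '", G$labels[v],
         "'; use solve_nonbinary()")
  }
  cst <- instance$costs
  D <- cst$duplication; Tc <- cst$transfer; Lc <- cst$loss
  nG <- G$n; nS <- S$n
  lay <- species_layout(S)
  gc1 <- child_index(G, 1L); gc2 <- child_index(G, 2L)
  term <- Cm <- be <- bt <- matrix(Inf, nG, nS)
  if (count) nterm <- nC <- nbe <- nbt <- matrix(0, nG, nS)
  optg <- rep(Inf, nG); noptg <- numeric(nG)

  for (g in G$postorder) {
    if (G$is_leaf[g]) {
      trow <- rep(Inf, nS)
      trow[instance$phi_idx[g]] <- 0
      if (count) { ntrow <- numeric(nS); ntrow[instance$phi_idx[g]] <- 1 }
    } else {
      a <- gc1[g]; b <- gc2[g]
      dup <- D + Cm[a, ] + Cm[b, ]
      trA <- Cm[a, ] + bt[b, ]
      trB <- Cm[b, ] + bt[a, ]
      tr <- Tc + pmin(trA, trB)
      spec <- rep(Inf, nS)
      sA <- Cm[a, lay$i1] + Cm[b, lay$i2]
      sB <- Cm[a, lay$i2] + Cm[b, lay$i1]
      spec[lay$ii] <- pmin(sA, sB)
      trow <- pmin(spec, dup, tr)
      if (count) {
        nspec <- numeric(nS)
        nspec[lay$ii] <-
          (sA == spec[lay$ii]) * nC[a, lay$i1] * nC[b, lay$i2] +
          (sB == spec[lay$ii]) * nC[a, lay$i2] * nC[b, lay$i1]
        # the duplication route with both children continuing into opposite
        # child subtrees describes a mapping whose induced event is a
        # speciation (already counted by the speciation route): exclude
        # those cross-continuation pairs (they tie only when D = L = 0)
        via <- function(c, side) {
          v <- numeric(nS)
          sx <- if (side == 1L) lay$i1 else lay$i2
          v[lay$ii] <- (Lc + Cm[c, sx] == Cm[c, lay$ii]) * nC[c, sx]
          v
        }
        ndup <- nC[a, ] * nC[b, ] -
          via(a, 1L) * via(b, 2L) - via(a, 2L) * via(b, 1L)
        ntr <- (trA <= trB) * nC[a, ] * nbt[b, ] +
               (trB <= trA) * nC[b, ] * nbt[a, ]
        ntrow <- is.finite(trow) *
          ((spec == trow) * nspec + (dup == trow) * ndup + (tr == trow) * ntr)
      }
    }
    # placed table: termination or continue through a loss (postorder in S)
    crow <- trow
    if (count) ncrow <- ntrow
    for (s in lay$post_int) {
      x <- lay$c1[s]; y <- lay$c2[s]
      v <- min(trow[s], Lc + crow[x], Lc + crow[y])
      if (count) {
        n <- 0
        if (is.finite(v)) {
          if (trow[s] == v) n <- n + ntrow[s]
          if (Lc + crow[x] == v) n <- n + ncrow[x]
          if (Lc + crow[y] == v) n <- n + ncrow[y]
        }
        ncrow[s] <- n
      }
      crow[s] <- v
    }
    # best entry within each species subtree (from terminations)
    berow <- trow
    if (count) nberow <- ntrow
    for (s in lay$post_int) {
      x <- lay$c1[s]; y <- lay$c2[s]
      v <- min(trow[s], berow[x], berow[y])
      if (count) {
        n <- 0
        if (is.finite(v)) {
          if (trow[s] == v) n <- n + ntrow[s]
          if (berow[x] == v) n <- n + nberow[x]
          if (berow[y] == v) n <- n + nberow[y]
        }
        nberow[s] <- n
      }
      berow[s] <- v
    }
    # best transfer target: preorder, sibling subtrees of all ancestors
    btrow <- rep(Inf, nS)
    if (count) nbtrow <- numeric(nS)
    for (s in lay$pre_int) {
      x <- lay$c1[s]; y <- lay$c2[s]
      vx <- min(btrow[s], berow[y])
      vy <- min(btrow[s], berow[x])
      if (count) {
        nbtrow[x] <- if (is.finite(vx))
          (btrow[s] == vx) * nbtrow[s] + (berow[y] == vx) * nberow[y] else 0
        nbtrow[y] <- if (is.finite(vy))
          (btrow[s] == vy) * nbtrow[s] + (berow[x] == vy) * nberow[x] else 0
      }
      btrow[x] <- vx
      btrow[y] <- vy
    }
    term[g, ] <- trow; Cm[g, ] <- crow; be[g, ] <- berow; bt[g, ] <- btrow
    optg[g] <- min(trow)
    if (count) {
      nterm[g, ] <- ntrow; nC[g, ] <- ncrow
      nbe[g, ] <- nberow; nbt[g, ] <- nbtrow
      noptg[g] <- sum(ntrow[trow == optg[g] & is.finite(trow)])
    }
  }
  out <- list(term = term, C = Cm, best_entry = be, best_transfer = bt,
              opt = optg)
  if (count)
    out$counts <- list(term = nterm, C = nC, best_entry = nbe,
                       best_transfer = nbt, opt = noptg)
  structure(out, class = "dtlor_species_tables")
}

#' Optimal species-mapping cost for a gene subtree
#'
#' The minimum over all species edges (including the handle) of the cost of
#' mapping the gene subtree with its root edge terminating there.
#'
#' @param tables a [species_tables()] result.
#' @param instance the instance the tables were computed from.
#' @param g a gene vertex name.
#' @return numeric cost.
#' @export
species_opt <- function(tables, instance, g) {
  tables$opt[vertex_index(instance$gene, g)]
}
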