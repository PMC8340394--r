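# Combine step for binary gene trees: place origin events optimally given the
# decoupled species and synteny tables, then trace back one maximum-parsimony
# reconciliation deterministically and count all co-optimal ones.

#' Solve the DTLOR MPR problem (binary gene tree)
#'
#' Computes, for every gene vertex, `origin[g] = O + C(g) + syn(g)` (the cost
#' of an origin subtree rooted at `g`) and `null[g]` (the cost of
#' reconciling the subtree with `g` in the unknown syntenic region: infinite
#' at leaves, otherwise the sum over children of the cheaper of staying
#' unknown or starting an origin subtree). The optimum is
#' `min(null[root], origin[root])`.
#'
#' @param instance a [dtlor_instance()] with binary gene tree.
#' @param count also compute exact counts of co-optimal reconciliations?
#' @return object of class `dtlor_solution`: fields `opt`, `origin`, `null`,
#'   `species` ([species_tables()]), `synteny` ([synteny_tables()]),
#'   `n_opt`/`n_origin`/`n_null` when counted, and `instance`.
#' @export
dtlor_solve <- function(instance, count = TRUE) {
  G <- instance$gene
  O <- instance$costs$origin
  sp <- species_tables(instance, count = count)
  sy <- synteny_tables(instance, count = count)
  origin <- O + sp$opt + sy$opt
  null <- rep(Inf, G$n)
  if (count) {
    n_origin <- sp$counts$opt * sy$counts$opt
    n_null <- numeric(G$n)
  }
  for (g in G$postorder) {
    if (G$is_leaf[g]) next
    ch <- G$children[[g]]
    f <- pmin(null[ch], origin[ch])
    null[g] <- sum(f)
    if (count) {
      nf <- (null[ch] == f) * n_null[ch] + (origin[ch] == f) * n_origin[ch]
      n_null[g] <- prod(nf)
    }
  }
  r <- G$root
  opt <- min(null[r], origin[r])
  out <- list(opt = opt, origin = origin, null = null,
              species = sp, synteny = sy, instance = instance)
  if (count) {
    out$n_origin <- n_origin
    out$n_null <- n_null
    out$n_opt <- (null[r] == opt) * n_null[r] + (origin[r] == opt) * n_origin[r]
  }
  structure(out, class = "dtlor_solution")
}

#' @export
print.dtlor_solution <- function(x, ...) {
  cat("dtlor_solution: optimal cost ", x$opt,
      if (!is.null(x$n_opt)) paste0(" (", format(x$n_opt, big.mark = ","),
                                    " co-optimal reconciliation(s))"),
      "\n", sep = "")
  invisible(x)
}

#' Number of maximum-parsimony reconciliations
#'
#' Exact count of distinct optimal mapping pairs, computed by
#' sum-over-argmin / product-over-children recursions on the annotated
#' tables. Loss placements are determined by the species mapping (tree paths
#' are unique), so no reconciliation is counted twice. Counts are exact
#' doubles (integers up to 2^53).
#'
#' @param solution a [dtlor_solve()] result with `count = TRUE`.
#' @return numeric count (>= 1).
#' @export
count_mprs <- function(solution) {
  if (is.null(solution$n_opt))
    stop("solution was computed with count = FALSE")
  solution$n_opt
}

internal_error <- function(...) {
  stop(errorCondition(paste0("internal inconsistency: ", ...),
                      class = c("dtlor_internal_error", "error")))
}

# postorder-first deterministic choice among species edges
post_rank <- function(S) match(seq_len(S$n), S$postorder)

#' Trace back one maximum-parsimony reconciliation
#'
#' Deterministic traceback: unknown-region subtrees are preferred over
#' origins at ties; within a cell, speciation is preferred to loss, loss to
#' duplication, duplication to transfer; ties among species edges go to the
#' first edge in postorder and ties among syntenic regions to the smallest
#' label. The returned reconciliation always validates and re-scores
#' (through the event-inference path) exactly to the optimum.
#'
#' @param solution a [dtlor_solve()] result.
#' @return a `dtlor_reconciliation`.
#' @export
dtlor_traceback <- function(solution) {
  inst <- solution$instance
  G <- inst$gene; S <- inst$species
  cst <- inst$costs
  D <- cst$duplication; Tc <- cst$transfer; Lc <- cst$loss
  R <- cst$rearrangement
  sp <- solution$species; sy <- solution$synteny
  term <- sp$term; Cm <- sp$C; be <- sp$best_entry; bt <- sp$best_transfer
  gc1 <- child_index(G, 1L); gc2 <- child_index(G, 2L)
  sc1 <- child_index(S, 1L); sc2 <- child_index(S, 2L)
  sib <- sibling_index(S)
  rank <- post_rank(S)
  phi <- rep("N", G$n)
  gamma <- rep(NA_integer_, G$n)

  tb_syn <- function(g, l) {
    gamma[g] <<- l
    if (G$is_leaf[g]) {
      if (inst$gamma_idx[g] != l) internal_error("synteny leaf mismatch")
      return(invisible())
    }
    for (c in G$children[[g]]) {
      crow <- sy$syn[c, ]
      m <- min(crow)
      if (crow[l] <= R + m) tb_syn(c, l)
      else tb_syn(c, which(crow == m)[1L])
    }
  }

  be_descend <- function(g, s, v) {
    while (!S$is_leaf[s]) {
      if (term[g, s] == v) break
      s <- if (be[g, sc1[s]] == v) sc1[s] else sc2[s]
    }
    if (term[g, s] != v) internal_error("best-entry descent failed")
    s
  }

  bt_target <- function(g, s) {
    v <- bt[g, s]
    cur <- s
    repeat {
      if (is.na(S$parent[cur])) internal_error("transfer target not found")
      sb <- sib[cur]
      if (!is.na(sb) && be[g, sb] == v) return(be_descend(g, sb, v))
      cur <- S$parent[cur]
    }
  }

  # e_g terminates at s (tb_terminate) or is placed on e_s and may continue
  # through losses (tb_place); case preference: speciation < loss <
  # duplication < transfer.
  tb_case <- function(g, s, v, allow_loss) {
    g_int <- !G$is_leaf[g]; s_int <- !S$is_leaf[s]
    if (g_int) { a <- gc1[g]; b <- gc2[g] }
    if (g_int && s_int) {
      x <- sc1[s]; y <- sc2[s]
      if (Cm[a, x] + Cm[b, y] == v) {
        phi[g] <<- S$labels[s]
        tb_place(a, x); tb_place(b, y)
        return(invisible())
      }
      if (Cm[a, y] + Cm[b, x] == v) {
        phi[g] <<- S$labels[s]
        tb_place(a, y); tb_place(b, x)
        return(invisible())
      }
    }
    if (allow_loss && s_int) {
      if (Lc + Cm[g, sc1[s]] == v) return(tb_place(g, sc1[s]))
      if (Lc + Cm[g, sc2[s]] == v) return(tb_place(g, sc2[s]))
    }
    if (g_int) {
      if (D + Cm[a, s] + Cm[b, s] == v) {
        phi[g] <<- S$labels[s]
        tb_place(a, s); tb_place(b, s)
        return(invisible())
      }
      if (Tc + Cm[a, s] + bt[b, s] == v) {
        phi[g] <<- S$labels[s]
        tb_place(a, s)
        tb_terminate(b, bt_target(b, s))
        return(invisible())
      }
      if (Tc + Cm[b, s] + bt[a, s] == v) {
        phi[g] <<- S$labels[s]
        tb_place(b, s)
        tb_terminate(a, bt_target(a, s))
        return(invisible())
      }
    } else if (v == 0 && inst$phi_idx[g] == s) {
      phi[g] <<- S$labels[s]
      return(invisible())
    }
    internal_error("no case achieves table value at (",
                   G$labels[g], ", ", S$labels[s], ")")
  }
  tb_place <- function(g, s) tb_case(g, s, Cm[g, s], allow_loss = TRUE)
  tb_terminate <- function(g, s) tb_case(g, s, term[g, s], allow_loss = FALSE)

  tb_origin <- function(g) {
    trow <- term[g, ]
    candidates <- which(trow == sp$opt[g])
    s <- candidates[which.min(rank[candidates])]
    l <- which(sy$syn[g, ] == sy$opt[g])[1L]
    tb_syn(g, l)
    tb_terminate(g, s)
  }

  tb_null <- function(g) {
    for (c in G$children[[g]]) {
      if (solution$null[c] <= solution$origin[c]) tb_null(c)
      else tb_origin(c)
    }
  }

  r <- G$root
  if (solution$null[r] <= solution$origin[r]) tb_null(r) else tb_origin(r)

  rec <- reconciliation(inst, stats::setNames(phi, G$labels),
                        stats::setNames(gamma, G$labels))
  if (rec$cost != solution$opt)
    internal_error("traced reconciliation scores ", rec$cost,
                   " but the optimum is ", solution$opt)
  rec
}

#' One-call DTLOR reconciliation
#'
#' Convenience wrapper: dispatches to the binary solver or, when the gene
#' tree has multifurcations (and `allow_polytomies` is set), to the
#' fixed-parameter polytomy solver; returns the optimum, one traced
#' reconciliation and optionally the count of co-optimal reconciliations
#' (binary gene trees only).
#'
#' @param instance a [dtlor_instance()].
#' @param count report the number of maximum-parsimony reconciliations?
#' @param allow_polytomies permit multifurcating gene trees?
#' @param max_arity arity cap for the polytomy solver.
#' @return list with `opt`, `reconciliation`, and depending on the route
#'   `n_mprs` or `resolved` (the chosen binary resolution of the gene tree).
#' @export
dtlor_reconcile <- function(instance, count = FALSE, allow_polytomies = FALSE,
                            max_arity = 8L) {
  if (is_binary_instance(instance)) {
    sol <- dtlor_solve(instance, count = count)
    out <- list(opt = sol$opt, reconciliation = dtlor_traceback(sol))
    if (count) out$n_mprs <- count_mprs(sol)
    return(out)
  }
  if (!allow_polytomies) {
    v <- which(!instance$gene$is_leaf &
                 lengths(instance$gene$children) > 2L)[1L]
    stop("gene tree has a multifurcation at vertex '",
         instance$gene$labels[v],
         "'; set allow_polytomies = TRUE to resolve it")
  }
  if (count)
    stop("MPR counting is only defined for binary gene trees")
  nb <- solve_nonbinary(instance, max_arity = max_arity)
  list(opt = nb$opt, reconciliation = nb$reconciliation,
       resolved = nb$resolved)
}
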