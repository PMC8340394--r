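# Synteny-map dynamic program: optimal rearrangement cost of labeling a gene
# subtree with actual syntenic regions, given the root's label. Only actual
# labels appear here; the unknown region is handled by the combine step,
# because the decoupling of species and synteny maps holds only inside
# origin subtrees, where all labels are actual.

#' Synteny-map dynamic-programming tables
#'
#' Fills `syn[g, l]`, the optimal rearrangement cost of labeling the gene
#' subtree below `g` with actual syntenic regions so that `g` carries label
#' `l`, and the per-vertex free minimum `opt[g] = min_l syn[g, l]`. Leaf rows
#' are 0 at the observed label and infinite elsewhere; internal rows let each
#' child independently keep the parent's label or switch to its own best
#' label at rearrangement cost `R`. With `count = TRUE`, exact counts of
#' optimal labelings are filled alongside (a child switching to the parent's
#' own label is not a distinct labeling and is never double-counted).
#'
#' @param instance a [dtlor_instance()]. The gene tree may have any arity
#'   (each child contributes an independent factor).
#' @param count also fill labeling-count tables?
#' @return list of class `dtlor_synteny_tables` with matrix `syn`
#'   (`|G| x |L|`), vector `opt`, and optionally `counts`.
#' @export
synteny_tables <- function(instance, count = TRUE) {
  G <- instance$gene
  nL <- length(instance$association$labels)
  R <- instance$costs$rearrangement
  syn <- matrix(Inf, G$n, nL)
  if (count) nsyn <- matrix(0, G$n, nL)
  optg <- rep(Inf, G$n); noptg <- numeric(G$n)
  for (g in G$postorder) {
    if (G$is_leaf[g]) {
      row <- rep(Inf, nL)
      row[instance$gamma_idx[g]] <- 0
      if (count) { nrow_ <- numeric(nL); nrow_[instance$gamma_idx[g]] <- 1 }
    } else {
      row <- numeric(nL)
      if (count) nrow_ <- rep(1, nL)
      for (c in G$children[[g]]) {
        crow <- syn[c, ]
        m <- min(crow)
        f <- pmin(crow, R + m)
        row <- row + f
        if (count) {
          mcount <- sum(nsyn[c, crow == m])
          nf <- (crow == f) * nsyn[c, ] +
            (R + m == f) * (mcount - (crow == m) * nsyn[c, ])
          nrow_ <- nrow_ * nf
        }
      }
    }
    syn[g, ] <- row
    optg[g] <- min(row)
    if (count) {
      nsyn[g, ] <- nrow_
      noptg[g] <- sum(nrow_[row == optg[g] & is.finite(row)])
    }
  }
  out <- list(syn = syn, opt = optg)
  if (count) out$counts <- list(syn = nsyn, opt = noptg)
  structure(out, class = "dtlor_synteny_tables")
}
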