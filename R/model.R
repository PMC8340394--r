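#' Event costs for DTLOR reconciliation
#'
#' Nonnegative finite costs for the five chargeable event types. Speciation
#' always costs zero. The defaults (1, 1, 1, 2, 2) are the costs used for the
#' bacterial analyses that motivated the model. Zero costs are accepted as a
#' degenerate case (useful for reduction checks) but can make the number of
#' co-optimal reconciliations very large.
#'
#' @param duplication,transfer,loss,origin,rearrangement nonnegative numbers.
#' @return an object of class `dtlor_costs`.
#' @export
dtlor_costs <- function(duplication = 1, transfer = 1, loss = 1,
                        origin = 2, rearrangement = 2) {
  x <- c(duplication = duplication, transfer = transfer, loss = loss,
         origin = origin, rearrangement = rearrangement)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop("event costs must be nonnegative finite numbers")
  structure(as.list(x), class = "dtlor_costs")
}

#' A DTLOR reconciliation instance
#'
#' Bundles the full problem input: a binary rooted species tree, a rooted
#' gene tree (binary for the decoupled solver, arbitrary arity for the
#' polytomy solver), the leaf associations and the event costs.
#'
#' @param species,gene `rooted_tree`s. The species tree must be binary.
#' @param association a [leaf_association()]; alternatively pass `phi` and
#'   `gamma` as named vectors.
#' @param phi,gamma used when `association` is `NULL`; see
#'   [leaf_association()].
#' @param costs a [dtlor_costs()].
#' @return an object of class `dtlor_instance`.
#' @export
dtlor_instance <- function(species, gene, association = NULL,
                           phi = NULL, gamma = NULL, costs = dtlor_costs()) {
  stopifnot(inherits(species, "rooted_tree"), inherits(gene, "rooted_tree"),
            inherits(costs, "dtlor_costs"))
  if (!is_binary_tree(species))
    stop("species tree must be binary")
  if (any(lengths(gene$children)[!gene$is_leaf] < 2L))
    stop("gene tree internal vertices must have at least two children; ",
         "offending vertex: ",
         gene$labels[which(!gene$is_leaf &
                             lengths(gene$children) < 2L)[1L]])
  if (is.null(association))
    association <- leaf_association(phi, gamma, gene, species)
  stopifnot(inherits(association, "leaf_association"))
  inst <- structure(
    list(species = species, gene = gene, association = association,
         costs = costs),
    class = "dtlor_instance")
  # precomputed integer views used by the solvers
  inst$phi_idx <- {
    v <- rep(NA_integer_, gene$n)
    v[gene$leaves] <- vertex_index(species,
                                   unname(association$phi[gene$labels[gene$leaves]]))
    v
  }
  inst$gamma_idx <- {
    v <- rep(NA_integer_, gene$n)
    v[gene$leaves] <- match(unname(association$gamma[gene$labels[gene$leaves]]),
                            association$labels)
    v
  }
  inst
}

#' @export
print.dtlor_instance <- function(x, ...) {
  cat("dtlor_instance: gene tree with ", sum(x$gene$is_leaf), " leaves",
      if (!is_binary_tree(x$gene)) " (multifurcating)", ", species tree with ",
      sum(x$species$is_leaf), " leaves, ", length(x$association$labels),
      " syntenic region(s)\n", sep = "")
  invisible(x)
}

is_binary_instance <- function(inst) is_binary_tree(inst$gene)

#' Construct (and check) a reconciliation
#'
#' A reconciliation is a pair of mappings: `phi` sends every gene vertex to a
#' species vertex or to `"N"` (outside the sampled species tree), and `gamma`
#' sends every gene vertex to an actual syntenic region or to the unknown
#' region (`NA`, printed `*`). Construction validates the mapping constraints
#' and infers the induced event list and total cost.
#'
#' @param instance a [dtlor_instance()].
#' @param phi named character vector over all gene vertex names; values are
#'   species vertex names or `"N"`.
#' @param gamma named vector over all gene vertex names; values are syntenic
#'   regions, with `NA` (or `"*"`) for the unknown region.
#' @return an object of class `dtlor_reconciliation` with fields `phi`,
#'   `gamma`, `events` (data frame) and `cost`.
#' @export
reconciliation <- function(instance, phi, gamma) {
  v <- validate_reconciliation(instance, phi, gamma)
  if (!v$ok)
    stop("invalid reconciliation: constraint ", v$violations$constraint[1L],
         " violated at gene vertex '", v$violations$vertex[1L], "'")
  gamma <- normalize_gamma(gamma)
  ev <- infer_events(instance, phi, gamma)
  structure(list(phi = phi, gamma = gamma, events = ev,
                 cost = event_cost(ev, instance$costs)),
            class = "dtlor_reconciliation")
}

#' @export
print.dtlor_reconciliation <- function(x, ...) {
  tab <- table(factor(x$events$kind,
                      levels = c("speciation", "duplication", "transfer",
                                 "loss", "origin", "rearrangement")))
  cat("dtlor_reconciliation: cost ", x$cost, " (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

normalize_gamma <- function(gamma) {
  g <- gamma
  g[g %in% "*"] <- NA
  stats::setNames(suppressWarnings(as.integer(g)), names(gamma))
}

#' Check the mapping constraints of a reconciliation
#'
#' Checks each constraint independently and reports every violation with the
#' offending gene vertex. Constraints on `phi`: leaves follow the leaf map
#' (`phi-1`); for an internal vertex mapped inside the species tree, neither
#' child is outside (`phi-2a`), no child maps to a proper ancestor
#' (`phi-2b`), and at least one child maps to the vertex itself or a
#' descendant (`phi-2c`). Constraints on `gamma`: leaves follow the synteny
#' map (`gamma-1`), the unknown region coincides exactly with the outside
#' location (`gamma-2`), and an actual region is never followed by an unknown
#' one (`gamma-3`).
#'
#' @inheritParams reconciliation
#' @return list with `ok` (logical) and `violations`
#'   (data frame with columns `constraint`, `vertex`).
#' @export
validate_reconciliation <- function(instance, phi, gamma) {
  G <- instance$gene; S <- instance$species
  gl <- G$labels
  if (!all(gl %in% names(phi)) || !all(gl %in% names(gamma)))
    stop("phi and gamma must cover every gene vertex")
  phi <- phi[gl]
  gamma <- normalize_gamma(gamma[gl])
  bad <- !(unname(phi) %in% c(S$labels, "N"))
  if (any(bad))
    stop("phi value is not a species vertex or 'N': ", unname(phi)[bad][1L])
  pidx <- ifelse(phi == "N", 0L, match(phi, S$labels)) # 0 encodes N
  anc <- ancestor_matrix(S)
  viol <- list()
  add <- function(constraint, v)
    viol[[length(viol) + 1L]] <<- data.frame(constraint = constraint,
                                             vertex = gl[v])
  for (v in G$leaves) {
    if (phi[v] != instance$association$phi[[gl[v]]]) add("phi-1", v)
    if (is.na(gamma[v]) || gamma[v] != instance$association$gamma[[gl[v]]])
      add("gamma-1", v)
  }
  deq <- function(a, b) a == b || anc[b, a] # a equal to or descendant of b
  for (v in which(!G$is_leaf)) {
    ch <- G$children[[v]]
    if (pidx[v] > 0L) {
      if (any(pidx[ch] == 0L)) add("phi-2a", v)
      else {
        if (any(anc[cbind(pidx[ch], pidx[v])])) add("phi-2b", v)
        if (!any(vapply(pidx[ch], deq, logical(1), b = pidx[v])))
          add("phi-2c", v)
      }
    }
    if (!is.na(gamma[v]) && anyNA(gamma[ch])) add("gamma-3", v)
  }
  mism <- (pidx == 0L) != is.na(gamma)
  for (v in which(mism)) add("gamma-2", v)
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(constraint = character(0), vertex = character(0))
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Classify the event induced at an internal gene vertex
#'
#' For an internal gene vertex mapped inside the species tree, exactly one of
#' speciation, duplication or transfer is induced, determined by where the
#' two child images fall relative to the vertex image. Vertices mapped
#' outside (`"N"`) induce none of these and yield `NA`.
#'
#' @inheritParams reconciliation
#' @param g a gene vertex name (internal).
#' @return `"speciation"`, `"duplication"`, `"transfer"`, or `NA`.
#' @export
classify_vertex_event <- function(instance, phi, g) {
  G <- instance$gene; S <- instance$species
  gi <- vertex_index(G, g)
  if (G$is_leaf[gi]) stop("classification applies to internal vertices: ", g)
  if (phi[[g]] == "N") return(NA_character_)
  anc <- ancestor_matrix(S)
  classify_idx(instance, phi_to_index(instance, phi), gi, anc)
}

phi_to_index <- function(instance, phi) {
  S <- instance$species
  p <- phi[instance$gene$labels]
  ifelse(p == "N", 0L, match(p, S$labels))
}

# classification on integer-encoded phi (0 = N); assumes constraints hold
classify_idx <- function(instance, pidx, gi, anc) {
  G <- instance$gene; S <- instance$species
  s <- pidx[gi]
  if (s == 0L) return(NA_character_)
  ch <- G$children[[gi]]
  i1 <- pidx[ch[1L]]; i2 <- pidx[ch[2L]]
  deq <- function(a, b) a == b || anc[b, a]
  if (!S$is_leaf[s]) {
    sc <- S$children[[s]]
    if ((deq(i1, sc[1L]) && deq(i2, sc[2L])) ||
        (deq(i1, sc[2L]) && deq(i2, sc[1L]))) return("speciation")
  }
  if (deq(i1, s) && deq(i2, s)) return("duplication")
  "transfer"
}

#' Loss events induced below a gene vertex
#'
#' If the image of the parent of `g` is a proper ancestor of the image of
#' `g`, every species vertex on the connecting path induces a loss, excluding
#' the image of `g` itself and excluding the parent's image exactly when the
#' parent induces a speciation (for duplication and transfer parents the
#' continuing lineage does pass through, and lose at, the parent's image).
#' Entry from outside the species tree induces no losses.
#'
#' @inheritParams classify_vertex_event
#' @param g a non-root gene vertex name.
#' @return character vector of species vertex names the lineage passes
#'   through (possibly empty).
#' @export
infer_losses <- function(instance, phi, g) {
  G <- instance$gene; S <- instance$species
  gi <- vertex_index(G, g)
  if (gi == G$root) stop("losses are induced below non-root vertices: ", g)
  anc <- ancestor_matrix(S)
  pidx <- phi_to_index(instance, phi)
  S$labels[losses_idx(instance, pidx, gi, anc)]
}

losses_idx <- function(instance, pidx, gi, anc) {
  G <- instance$gene; S <- instance$species
  p <- G$parent[gi]
  sp <- pidx[p]; sg <- pidx[gi]
  if (sp == 0L || sg == 0L || !anc[sp, sg]) return(integer(0))
  path <- integer(0)
  w <- S$parent[sg]
  while (w != sp) { path <- c(path, w); w <- S$parent[w] }
  if (classify_idx(instance, pidx, p, anc) != "speciation")
    path <- c(path, sp)
  path
}

#' Origin and rearrangement events induced by a synteny labeling
#'
#' An origin is induced at every vertex whose own region is actual while the
#' parent's is unknown (and at the root if its region is actual); a
#' rearrangement is induced on every edge whose two endpoint regions are
#' actual and different.
#'
#' @inheritParams reconciliation
#' @return data frame with columns `kind`, `gene`, `from_label`, `to_label`.
#' @export
infer_or_events <- function(instance, gamma) {
  G <- instance$gene
  gamma <- normalize_gamma(gamma[G$labels])
  out <- list()
  for (v in seq_len(G$n)) {
    p <- G$parent[v]
    if (is.na(gamma[v])) next
    if (is.na(p) || is.na(gamma[p])) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "origin", gene = G$labels[v],
        from_label = NA_integer_, to_label = gamma[[v]])
    } else if (gamma[p] != gamma[v]) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "rearrangement", gene = G$labels[v],
        from_label = gamma[[p]], to_label = gamma[[v]])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(0), gene = character(0),
               from_label = integer(0), to_label = integer(0))
}

#' Infer the full event list of a reconciliation
#'
#' Pure function of the two mappings: recomputation is stable and
#' order-independent. Speciation events are included (at zero cost).
#'
#' @inheritParams reconciliation
#' @return data frame with columns `kind`, `gene`, `species`, `from_label`,
#'   `to_label`.
#' @export
infer_events <- function(instance, phi, gamma) {
  G <- instance$gene; S <- instance$species
  phi <- phi[G$labels]
  gamma <- normalize_gamma(gamma[G$labels])
  pidx <- phi_to_index(instance, phi)
  anc <- ancestor_matrix(S)
  rows <- list()
  emit <- function(kind, v, s = NA_integer_, from = NA_integer_,
                   to = NA_integer_)
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, gene = G$labels[v],
      species = if (is.na(s)) NA_character_ else S$labels[s],
      from_label = from, to_label = to)
  for (v in which(!G$is_leaf)) {
    k <- classify_idx(instance, pidx, v, anc)
    if (!is.na(k)) emit(k, v, pidx[v])
  }
  for (v in seq_len(G$n)[-G$root])
    for (s in losses_idx(instance, pidx, v, anc)) emit("loss", v, s)
  orr <- infer_or_events(instance, gamma)
  for (i in seq_len(nrow(orr))) {
    v <- vertex_index(G, orr$gene[i])
    emit(orr$kind[i], v, if (pidx[v] > 0L) pidx[v] else NA_integer_,
         orr$from_label[i], orr$to_label[i])
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), gene = character(0),
               species = character(0), from_label = integer(0),
               to_label = integer(0))
}

event_cost <- function(events, costs) {
  k <- events$kind
  costs$duplication * sum(k == "duplication") +
    costs$transfer * sum(k == "transfer") +
    costs$loss * sum(k == "loss") +
    costs$origin * sum(k == "origin") +
    costs$rearrangement * sum(k == "rearrangement")
}

#' Score a reconciliation
#'
#' Total cost: number of duplication, transfer, loss, origin and
#' rearrangement events scaled by the respective costs; speciations
#' contribute zero. Either pass a `dtlor_reconciliation` or the raw `phi` and
#' `gamma` mappings (which are validated first).
#'
#' @inheritParams reconciliation
#' @param rec optionally, a ready `dtlor_reconciliation`.
#' @param costs a [dtlor_costs()]; defaults to the instance's costs.
#' @return numeric total cost.
#' @export
score_reconciliation <- function(instance, rec = NULL, phi = NULL,
                                 gamma = NULL, costs = instance$costs) {
  if (is.null(rec)) rec <- reconciliation(instance, phi, gamma)
  event_cost(rec$events, costs)
}

#' Serialize a reconciliation to JSON
#'
#' Schema `dtlor-reconciliation/1`: a per-gene-vertex record
#' `{vertex, species, synteny, event}` (species `"N"` and synteny `"*"` for
#' lineages outside the sampled tree), a flat event list and the total cost.
#'
#' @param instance a [dtlor_instance()].
#' @param rec a `dtlor_reconciliation`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
reconciliation_json <- function(instance, rec, path = NULL) {
  G <- instance$gene
  vertex_event <- function(v) {
    hit <- rec$events$kind[rec$events$gene == v &
                             rec$events$kind %in%
                               c("speciation", "duplication", "transfer")]
    if (length(hit)) hit[1L] else NA_character_
  }
  verts <- lapply(G$labels, function(v) list(
    vertex = v,
    species = unname(rec$phi[[v]]),
    synteny = if (is.na(rec$gamma[[v]])) "*" else
      as.character(rec$gamma[[v]]),
    event = vertex_event(v)))
  obj <- list(schema = "dtlor-reconciliation/1", cost = rec$cost,
              vertices = verts, events = rec$events)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}
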