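# Seeded generators of test instances and forward-simulated gene histories.
# The simulator is a testing aid, not a calibrated evolutionary model:
# events are per-branch Bernoulli draws, not continuous-time rates.

#' Configuration for the synthetic-instance generators
#'
#' @param seed integer seed; identical configurations give identical output.
#' @param species_leaves,gene_leaves leaf counts of the generated trees.
#' @param n_labels number of syntenic regions (must not exceed
#'   `gene_leaves`; the leaf labeling is surjective).
#' @param max_arity maximum gene-vertex arity (2 = binary).
#' @param p_polytomy per-edge probability of contracting an internal gene
#'   edge into a multifurcation (only when `max_arity > 2`).
#' @param p_dup,p_transfer,p_loss per-arrival event probabilities of the
#'   forward simulator.
#' @param p_rearr per-gene-edge probability of a syntenic rearrangement.
#' @param origin origin placement for the simulator: `"root"` places the
#'   entering lineage on the species handle, `"random"` on a random edge.
#' @param costs a [dtlor_costs()].
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = NULL, species_leaves = 6L, gene_leaves = 6L,
                         n_labels = 2L, max_arity = 2L, p_polytomy = 0.3,
                         p_dup = 0.05, p_transfer = 0.05, p_loss = 0.05,
                         p_rearr = 0.05, origin = c("root", "random"),
                         costs = dtlor_costs()) {
  p <- c(p_polytomy, p_dup, p_transfer, p_loss, p_rearr)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(species_leaves >= 1L, gene_leaves >= 1L, n_labels >= 1L,
            max_arity >= 2L)
  structure(list(seed = seed, species_leaves = species_leaves,
                 gene_leaves = gene_leaves, n_labels = n_labels,
                 max_arity = max_arity, p_polytomy = p_polytomy,
                 p_dup = p_dup, p_transfer = p_transfer, p_loss = p_loss,
                 p_rearr = p_rearr, origin = match.arg(origin),
                 costs = costs),
            class = "synth_config")
}

#' Uniformly random rooted binary topology
#'
#' Sequential leaf insertion on a uniformly chosen edge (the handle
#' included), which yields the uniform distribution over labeled rooted
#' binary topologies.
#'
#' @param n_leaves number of leaves (>= 1).
#' @param prefix leaf labels are `prefix1..prefixN`.
#' @return a `rooted_tree`.
#' @export
random_topology <- function(n_leaves, prefix = "t") {
  labels <- paste0(prefix, 1L)
  parent <- NA_integer_
  children <- list(integer(0))
  n_int <- 0L
  for (i in seq_len(n_leaves)[-1L]) {
    v <- sample.int(length(labels), 1L) # insert above v (handle included)
    n_int <- n_int + 1L
    labels <- c(labels, paste0(prefix, "_i", n_int), paste0(prefix, i))
    mid <- length(labels) - 1L
    leaf <- length(labels)
    p <- parent[v]
    parent <- c(parent, p, mid)
    children <- c(children, list(c(v, leaf)), list(integer(0)))
    parent[v] <- mid
    if (!is.na(p)) children[[p]][children[[p]] == v] <- mid
  }
  new_rooted_tree(labels, parent, children)
}

# randomly contract internal gene edges into multifurcations (preorder, so
# each contraction sees up-to-date arities)
contract_polytomies <- function(tree, p_polytomy, max_arity) {
  parent <- tree$parent
  children <- tree$children
  keep <- rep(TRUE, tree$n)
  for (v in rev(tree$postorder)) {
    if (tree$is_leaf[v] || v == tree$root) next
    p <- parent[v]
    if (length(children[[p]]) - 1L + length(children[[v]]) > max_arity) next
    if (stats::runif(1) >= p_polytomy) next
    pos <- match(v, children[[p]])
    children[[p]] <- append(children[[p]][-pos], children[[v]],
                            after = pos - 1L)
    for (c in children[[v]]) parent[c] <- p
    children[[v]] <- integer(0)
    keep[v] <- FALSE
  }
  idx <- cumsum(keep)
  new_rooted_tree(tree$labels[keep],
                  ifelse(is.na(parent[keep]), NA_integer_,
                         idx[parent[keep]]),
                  lapply(children[keep], function(ch) idx[ch]))
}

#' Random reconciliation instance
#'
#' Uniformly random tree topologies, a uniformly random leaf map, and a
#' random surjective synteny labeling; reproducible under the
#' configuration's seed.
#'
#' @param config a [synth_config()].
#' @return a [dtlor_instance()].
#' @export
random_instance <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  S <- random_topology(config$species_leaves, "s")
  G <- random_topology(config$gene_leaves, "g")
  if (config$max_arity > 2L && config$p_polytomy > 0)
    G <- contract_polytomies(G, config$p_polytomy, config$max_arity)
  gl <- tree_leaf_labels(G)
  K <- config$n_labels
  if (K > length(gl))
    stop("cannot draw a surjective labeling: ", K, " syntenic regions but ",
         length(gl), " gene leaves")
  phi <- stats::setNames(sample(tree_leaf_labels(S), length(gl),
                                replace = TRUE), gl)
  gam <- sample.int(K, length(gl), replace = TRUE)
  gam[sample.int(length(gl), K)] <- seq_len(K) # force surjectivity
  dtlor_instance(S, G, phi = phi, gamma = stats::setNames(gam, gl),
                 costs = config$costs)
}

#' Forward-simulate a gene history through a species tree
#'
#' A single gene lineage enters the species tree at the configured origin
#' and evolves towards the leaves; on each arrival at a species vertex it
#' may be lost, duplicate, or transfer to an incomparable edge (per-branch
#' Bernoulli draws), otherwise it follows the speciation; each new gene edge
#' may switch to a fresh syntenic region. Unary gene vertices left by
#' one-sided losses are contracted away. The returned "true" reconciliation
#' is the history's mapping restricted to the observed (contracted) gene
#' tree; the true cost is the cost of that reconciliation plus the cost of
#' all events on pruned (extinct) lineages, so it always upper-bounds the
#' parsimony optimum. Histories whose lineages all die out (or whose
#' contraction is not expressible as a valid reconciliation, which is rare)
#' are redrawn a bounded number of times.
#'
#' @param config a [synth_config()].
#' @param max_retries redraw budget for degenerate histories.
#' @return list of class `simulated_history`: `instance`, `phi` and `gamma`
#'   (the true mappings over observed gene vertices), `reconciliation`,
#'   `true_cost`, `pruned_cost`, and `tally` (event counts including pruned
#'   lineages).
#' @export
simulate_history <- function(config, max_retries = 50L) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  for (i in seq_len(max_retries)) {
    h <- tryCatch(sim_once(config), error = function(e) {
      if (inherits(e, "dtlor_sim_retry")) NULL else stop(e)
    })
    if (!is.null(h)) {
      if (i > 1L)
        message("simulate_history: redrew ", i - 1L, " degenerate histories")
      return(h)
    }
  }
  stop("all ", max_retries, " simulated histories were degenerate; ",
       "lower p_loss")
}

sim_retry <- function(msg)
  stop(errorCondition(msg, class = c("dtlor_sim_retry", "error")))

sim_once <- function(config) {
  S <- random_topology(config$species_leaves, "s")
  anc <- ancestor_matrix(S)
  incomp <- lapply(seq_len(S$n), function(s)
    which(!anc[s, ] & !anc[, s] & seq_len(S$n) != s))
  env <- new.env()
  env$tally <- c(duplication = 0, transfer = 0, loss = 0, origin = 1,
                 rearrangement = 0)
  env$nleaf <- 0L
  env$nint <- 0L
  env$nlab <- 1L
  env$steps <- 0L
  mutate <- function(lab) {
    if (stats::runif(1) < config$p_rearr) {
      env$nlab <- env$nlab + 1L
      env$tally["rearrangement"] <- env$tally["rearrangement"] + 1
      env$nlab
    } else lab
  }
  combine <- function(s, lab, c1, c2) {
    if (is.null(c1) && is.null(c2)) return(NULL)
    if (is.null(c1)) return(c2)
    if (is.null(c2)) return(c1)
    env$nint <- env$nint + 1L
    list(name = paste0("g_i", env$nint), phi = s, gamma = lab,
         kids = list(c1, c2))
  }
  evolve <- function(s, lab) {
    env$steps <- env$steps + 1L
    if (env$steps > 5000L) sim_retry("runaway history")
    if (stats::runif(1) < config$p_loss) {
      env$tally["loss"] <- env$tally["loss"] + 1
      return(NULL)
    }
    if (stats::runif(1) < config$p_dup) {
      env$tally["duplication"] <- env$tally["duplication"] + 1
      return(combine(s, lab, evolve(s, mutate(lab)), evolve(s, mutate(lab))))
    }
    if (stats::runif(1) < config$p_transfer && length(incomp[[s]])) {
      env$tally["transfer"] <- env$tally["transfer"] + 1
      tgt <- incomp[[s]][sample.int(length(incomp[[s]]), 1L)]
      return(combine(s, lab, evolve(s, mutate(lab)),
                     evolve(tgt, mutate(lab))))
    }
    if (S$is_leaf[s]) {
      env$nleaf <- env$nleaf + 1L
      return(list(name = paste0("g", env$nleaf), phi = s, gamma = lab,
                  kids = NULL))
    }
    ch <- S$children[[s]]
    combine(s, lab, evolve(ch[1L], mutate(lab)), evolve(ch[2L], mutate(lab)))
  }
  origin_v <- if (config$origin == "root") S$root else
    sample.int(S$n, 1L)
  root <- evolve(origin_v, 1L)
  if (is.null(root)) sim_retry("all lineages lost")

  # flatten the surviving history into a rooted_tree + true mappings
  labels <- character(0); parent <- integer(0); children <- list()
  phi <- character(0); gamma <- integer(0)
  flatten <- function(node, p) {
    labels[length(labels) + 1L] <<- node$name
    i <- length(labels)
    parent[i] <<- p
    children[[i]] <<- integer(0)
    if (!is.na(p)) children[[p]] <<- c(children[[p]], i)
    phi[node$name] <<- S$labels[node$phi]
    gamma[node$name] <<- node$gamma
    for (k in node$kids) flatten(k, i)
  }
  flatten(root, NA_integer_)
  G <- new_rooted_tree(labels, parent, children)
  # compact syntenic regions to 1..K in order of first appearance on leaves
  leaf_names <- G$labels[G$leaves]
  seen <- unique(unname(gamma[leaf_names]))
  gamma <- stats::setNames(match(gamma, seen), names(gamma))
  if (anyNA(gamma[leaf_names])) sim_retry("unlabeled leaf") # cannot happen
  inst <- dtlor_instance(S, G,
                         phi = phi[leaf_names], gamma = gamma[leaf_names],
                         costs = config$costs)
  # internal vertices whose region never reaches a leaf keep a fresh label;
  # map them to the nearest surviving label to stay within L
  gap <- is.na(gamma)
  if (any(gap)) {
    for (v in G$postorder) {
      nm <- G$labels[v]
      if (is.na(gamma[nm]))
        gamma[nm] <- gamma[G$labels[G$children[[v]][1L]]]
    }
  }
  val <- validate_reconciliation(inst, phi[G$labels], gamma[G$labels])
  if (!val$ok) sim_retry("contracted history not expressible as a valid
reconciliation")
  rec <- reconciliation(inst, phi[G$labels], gamma[G$labels])
  tally <- env$tally
  # events on pruned lineages = simulated totals minus those expressed in rec
  expressed <- table(factor(rec$events$kind, levels = names(tally)))
  pruned <- pmax(tally - as.numeric(expressed), 0)
  pruned_cost <- sum(pruned * unlist(inst$costs)[c("duplication", "transfer",
                                                   "loss", "origin",
                                                   "rearrangement")])
  structure(list(instance = inst, phi = phi[G$labels],
                 gamma = gamma[G$labels], reconciliation = rec,
                 true_cost = rec$cost + pruned_cost,
                 pruned_cost = pruned_cost, tally = tally),
            class = "simulated_history")
}
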