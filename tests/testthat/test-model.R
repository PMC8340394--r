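test_that("internal vertices classify as speciation, duplication or transfer", {
  inst <- fix_iso3()
  G <- inst$gene
  mk_phi <- function(v, u) c(ga = "a", gb = "b", gc = "c", v = v, u = u)
  # children images in the two subtrees of the vertex image: speciation
  expect_equal(classify_vertex_event(inst, mk_phi("r", "x"), "u"), "speciation")
  # both child images equal the vertex image: duplication
  inst2 <- fix_cherry_dup()
  expect_equal(classify_vertex_event(inst2, c(ga = "a", gb = "a", u = "a"),
                                     "u"), "duplication")
  # one descendant, one incomparable: transfer
  inst3 <- dtlor_instance(fix_species3(), parse_newick("(ga,gc)u;"),
                          phi = c(ga = "a", gc = "c"),
                          gamma = c(ga = 1, gc = 1))
  expect_equal(classify_vertex_event(inst3, c(ga = "a", gc = "c", u = "x"),
                                     "u"), "transfer")
  # vertices outside the species tree induce none of these
  expect_true(is.na(classify_vertex_event(
    inst, c(ga = "a", gb = "b", gc = "c", u = "x", v = "N"), "v")))
})

test_that("loss rule: speciation parents skip the top endpoint, others lose it", {
  S <- fix_species3()
  G <- parse_newick("(g1,g2)p;")
  inst <- dtlor_instance(S, G, phi = c(g1 = "a", g2 = "c"),
                         gamma = c(g1 = 1, g2 = 1))
  # p speciates at r: g1 descends to a, passing (and losing) only x
  phi_spec <- c(g1 = "a", g2 = "c", p = "r")
  expect_equal(infer_losses(inst, phi_spec, "g1"), "x")
  expect_equal(infer_losses(inst, phi_spec, "g2"), character(0))
  # duplication parent at r: the path to a loses at both r and x
  instd <- dtlor_instance(S, G, phi = c(g1 = "a", g2 = "a"),
                          gamma = c(g1 = 1, g2 = 1))
  phi_dup <- c(g1 = "a", g2 = "a", p = "r")
  expect_setequal(infer_losses(instd, phi_dup, "g1"), c("r", "x"))
  # entry from outside the species tree incurs no losses
  G2 <- parse_newick("((g1,g2)p,g3)q;")
  inst2 <- dtlor_instance(S, G2, phi = c(g1 = "a", g2 = "b", g3 = "c"),
                          gamma = c(g1 = 1, g2 = 1, g3 = 1))
  phiN <- c(g1 = "a", g2 = "b", g3 = "c", p = "x", q = "N")
  expect_equal(infer_losses(inst2, phiN, "p"), character(0))
})

test_that("origin and rearrangement events follow the synteny labeling", {
  inst <- fix_iso3()
  ev <- infer_or_events(inst, c(ga = 1, gb = 1, gc = 1, u = 1, v = 1))
  expect_equal(ev$kind, "origin")
  expect_equal(ev$gene, "v")
  ev2 <- infer_or_events(inst, c(ga = 1, gb = 1, gc = 2, u = 1, v = NA))
  expect_setequal(ev2$gene[ev2$kind == "origin"], c("u", "gc"))
  expect_equal(sum(ev2$kind == "rearrangement"), 0L)
  ev3 <- infer_or_events(inst, c(ga = 1, gb = 1, gc = 2, u = 1, v = 1))
  expect_equal(sum(ev3$kind == "origin"), 1L)
  expect_equal(ev3$gene[ev3$kind == "rearrangement"], "gc")
})

test_that("validation reports each violated constraint with its vertex", {
  inst <- fix_iso3()
  ok <- validate_reconciliation(
    inst, c(ga = "a", gb = "b", gc = "c", u = "x", v = "r"),
    c(ga = 1, gb = 1, gc = 1, u = 1, v = 1))
  expect_true(ok$ok)
  # child mapped to a proper ancestor of its parent's image
  bad <- validate_reconciliation(
    inst, c(ga = "a", gb = "b", gc = "c", u = "r", v = "x"),
    c(ga = 1, gb = 1, gc = 1, u = 1, v = 1))
  expect_false(bad$ok)
  expect_true("phi-2b" %in% bad$violations$constraint)
  # actual region followed by an unknown one
  bad2 <- validate_reconciliation(
    inst, c(ga = "a", gb = "b", gc = "c", u = "N", v = "r"),
    c(ga = 1, gb = 1, gc = 1, u = NA, v = 1))
  expect_true(all(c("gamma-3", "phi-2a") %in% bad2$violations$constraint))
  # an all-outside mapping is invalid whenever the gene tree has leaves
  bad3 <- validate_reconciliation(
    inst, c(ga = "N", gb = "N", gc = "N", u = "N", v = "N"),
    c(ga = NA, gb = NA, gc = NA, u = NA, v = NA))
  expect_false(bad3$ok)
  expect_error(reconciliation(inst, c(ga = "N", gb = "N", gc = "N", u = "N",
                                      v = "N"),
                              c(ga = NA, gb = NA, gc = NA, u = NA, v = NA)),
               "invalid reconciliation")
})

test_that("scoring is linear in event counts and matches the cost vector", {
  inst <- fix_mixed_synteny()
  phi <- c(ga = "a", gb = "b", gc = "c", u = "x", v = "r")
  gamma <- c(ga = 1, gb = 1, gc = 2, u = 1, v = 1)
  rec <- reconciliation(inst, phi, gamma)
  # one origin (2) + one rearrangement (2) + two speciations (0)
  expect_equal(rec$cost, 4)
  # doubling the rearrangement cost adds one rearrangement's worth
  costs2 <- dtlor_costs(rearrangement = 4)
  expect_equal(score_reconciliation(inst, rec, costs = costs2), 6)
  # event inference is a pure function: recomputation is identical
  expect_identical(infer_events(inst, phi, gamma),
                   infer_events(inst, phi, gamma))
})

test_that("every valid mapping classifies exactly one event per inside vertex", {
  set.seed(104)
  for (i in 1:10) {
    cfg <- draw_small_config(seed = 300 + i, max_leaves = 4L)
    inst <- random_instance(cfg)
    A <- enumerate_species_maps(inst)
    G <- inst$gene; S <- inst$species
    ints <- G$postorder[!G$is_leaf[G$postorder]]
    rows <- sample.int(nrow(A), min(20L, nrow(A)))
    for (r in rows) {
      phi <- stats::setNames(rep("N", G$n), G$labels)
      phi[G$labels[G$leaves]] <- unname(inst$association$phi)
      phi[colnames(A)] <- ifelse(A[r, ] == 0L, "N", S$labels[A[r, ]])
      for (g in ints) {
        cls <- classify_vertex_event(inst, phi, G$labels[g])
        if (phi[[G$labels[g]]] == "N") expect_true(is.na(cls))
        else expect_true(cls %in% c("speciation", "duplication", "transfer"))
      }
    }
  }
})
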