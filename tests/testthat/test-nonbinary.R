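test_that("resolution enumeration is complete and duplicate-free", {
  for (k in 2:6) {
    res <- enumerate_resolutions(k)
    expect_equal(length(res), double_factorial_resolutions(k))
    reprs <- vapply(res, function(t) canonical_form(t)$repr, character(1))
    expect_equal(anyDuplicated(reprs), 0L)
  }
  expect_error(enumerate_resolutions(9), "arity cap")
  expect_error(enumerate_resolutions(7, cap = 6L), "arity cap")
  expect_equal(length(enumerate_resolutions(7)), 10395) # within default cap
})

test_that("trifurcation fixture resolves to the isomorphic topology", {
  inst <- fix_trifurcation()
  expect_equal(brute_force_nonbinary(inst)$opt, 2)
  nb <- solve_nonbinary(inst)
  expect_equal(nb$opt, 2)
  # the chosen resolution groups the two sister-species genes
  rs <- nb$resolved
  expect_true(is_binary_tree <- all(lengths(rs$children)[!rs$is_leaf] == 2L))
  rec <- nb$reconciliation
  expect_equal(rec$cost, 2)
  expect_setequal(rec$events$kind, c("speciation", "origin"))
})

test_that("binary gene trees give identical optima through both solvers", {
  set.seed(112)
  for (i in 1:25) {
    inst <- random_instance(draw_small_config(seed = 1300 + i))
    expect_equal(solve_nonbinary(inst, traceback = FALSE)$opt,
                 dtlor_solve(inst, count = FALSE)$opt)
  }
})

test_that("polytomy optimum equals the exhaustive-resolution minimum", {
  set.seed(113)
  for (i in 1:40) {
    cfg <- draw_small_config(seed = 1400 + i, max_leaves = 6L,
                             max_arity = 4L, p_polytomy = 0.8)
    cfg$species_leaves <- min(cfg$species_leaves, 4L)
    inst <- random_instance(cfg)
    nb <- solve_nonbinary(inst)
    expect_equal(nb$opt, brute_force_nonbinary(inst)$opt)
    # traced reconciliation validates and scores to the optimum on the
    # resolved tree
    ri <- dtlor_instance(inst$species, nb$resolved,
                         association = inst$association, costs = inst$costs)
    rec <- nb$reconciliation
    expect_true(validate_reconciliation(ri, rec$phi, rec$gamma)$ok)
    expect_equal(score_reconciliation(ri, phi = rec$phi, gamma = rec$gamma),
                 nb$opt)
  }
})

test_that("species-best and synteny-best resolutions can differ, joint wins", {
  # four gene cherries with interleaved region blocks (1,1 / 2,2 / 1,1 /
  # 2,2) under a multifurcating root: the resolution that is isomorphic to
  # the species tree minimizes the species-map cost but forces two
  # rearrangements, while pairing same-region cherries needs only one
  # rearrangement at a species-map price; with R = 3 no resolution is
  # optimal for both criteria, and committing to the species criterion
  # alone costs more than the joint optimum
  S <- parse_newick("(((s1,s2)a,(s3,s4)b)e,((s5,s6)c,(s7,s8)d)f)r;")
  G <- parse_newick("((g1,g2)p,(g3,g4)q,(g5,g6)w,(g7,g8)x)v;")
  cst <- dtlor_costs(rearrangement = 3)
  inst <- dtlor_instance(
    S, G, phi = stats::setNames(paste0("s", 1:8), paste0("g", 1:8)),
    gamma = stats::setNames(c(1, 1, 2, 2, 1, 1, 2, 2), paste0("g", 1:8)),
    costs = cst)
  per <- enumerate_resolutions(4L)
  full <- species_part <- synteny_part <- numeric(length(per))
  for (j in seq_along(per)) {
    rt <- dtlor:::resolve_tree(G, stats::setNames(per[j], "v"))
    ri <- dtlor_instance(S, rt, association = inst$association, costs = cst)
    full[j] <- dtlor_solve(ri, count = FALSE)$opt
    species_part[j] <- species_tables(ri, count = FALSE)$opt[rt$root]
    synteny_part[j] <- synteny_tables(ri, count = FALSE)$opt[rt$root]
  }
  opt <- min(full)
  sp_best <- which(species_part == min(species_part))
  sy_best <- which(synteny_part == min(synteny_part))
  expect_length(intersect(sp_best, sy_best), 0)
  expect_gt(min(full[sp_best]), opt)
  expect_equal(solve_nonbinary(inst, traceback = FALSE)$opt, opt)
})
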