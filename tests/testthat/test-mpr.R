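test_that("worked fixtures reproduce after oracle certification", {
  # isomorphic three-leaf case: one origin, two speciations
  i1 <- fix_iso3()
  o1 <- brute_force_opt(i1)
  expect_equal(o1$opt, 2); expect_equal(o1$count, 1)
  s1 <- dtlor_solve(i1)
  expect_equal(s1$opt, 2)
  expect_equal(count_mprs(s1), 1)
  r1 <- dtlor_traceback(s1)
  expect_equal(unname(r1$phi[c("v", "u", "ga", "gb", "gc")]),
               c("r", "x", "a", "b", "c"))
  expect_true(all(r1$gamma == 1))
  expect_setequal(r1$events$kind, c("speciation", "origin"))

  # mixed synteny: one origin + one rearrangement, or two origins
  i2 <- fix_mixed_synteny()
  o2 <- brute_force_opt(i2)
  expect_equal(o2$opt, 4); expect_equal(o2$count, 3)
  s2 <- dtlor_solve(i2)
  expect_equal(s2$opt, 4)
  expect_equal(count_mprs(s2), 3)

  # cherry mapped twice to one species leaf: origin + duplication
  i3 <- fix_cherry_dup()
  expect_equal(brute_force_opt(i3)$opt, 3)
  s3 <- dtlor_solve(i3)
  expect_equal(s3$opt, 3)
  r3 <- dtlor_traceback(s3)
  expect_equal(unname(r3$phi[["u"]]), "a")
  expect_setequal(r3$events$kind, c("duplication", "origin"))

  # a single-leaf gene family costs exactly one origin
  i4 <- dtlor_instance(fix_species3(), parse_newick("ga;"),
                       phi = c(ga = "a"), gamma = c(ga = 1))
  s4 <- dtlor_solve(i4)
  expect_equal(s4$opt, i4$costs$origin)
  expect_equal(count_mprs(s4), 1)
  expect_equal(brute_force_opt(i4)$opt, i4$costs$origin)
})

test_that("traceback always validates and re-scores to the optimum", {
  set.seed(109)
  for (i in 1:40) {
    inst <- random_instance(draw_small_config(seed = 800 + i))
    sol <- dtlor_solve(inst)
    rec <- dtlor_traceback(sol)
    expect_true(validate_reconciliation(inst, rec$phi, rec$gamma)$ok)
    expect_equal(score_reconciliation(inst, phi = rec$phi,
                                      gamma = rec$gamma), sol$opt)
    expect_gte(count_mprs(sol), 1)
  }
})

test_that("optimum is monotone in costs and bounded by origin counts", {
  set.seed(110)
  for (i in 1:10) {
    inst <- random_instance(draw_small_config(seed = 900 + i))
    opt <- dtlor_solve(inst, count = FALSE)$opt
    nl <- sum(inst$gene$is_leaf)
    expect_gte(opt, inst$costs$origin) # at least one origin exists
    expect_lte(opt, inst$costs$origin * nl) # each leaf its own origin
    for (nm in c("duplication", "transfer", "loss", "origin",
                 "rearrangement")) {
      cst <- inst$costs
      cst[[nm]] <- cst[[nm]] + 2
      i2 <- dtlor_instance(inst$species, inst$gene,
                           association = inst$association, costs = cst)
      expect_gte(dtlor_solve(i2, count = FALSE)$opt, opt)
    }
  }
})

test_that("single-region instances with large O reduce to one origin + DTL", {
  set.seed(111)
  for (i in 1:15) {
    cfg <- draw_small_config(seed = 1100 + i)
    cfg$n_labels <- 1L
    inst <- random_instance(cfg)
    big <- (inst$costs$duplication + inst$costs$transfer + inst$costs$loss) *
      (inst$gene$n + inst$species$n) + 1
    cst <- inst$costs; cst$origin <- big
    i2 <- dtlor_instance(inst$species, inst$gene,
                         association = inst$association, costs = cst)
    sol <- dtlor_solve(i2, count = FALSE)
    expect_equal(sol$opt, big + species_tables(i2)$opt[i2$gene$root])
  }
})

test_that("deterministic traceback: identical solutions on identical input", {
  inst <- random_instance(draw_small_config(seed = 1200))
  r1 <- dtlor_traceback(dtlor_solve(inst))
  r2 <- dtlor_traceback(dtlor_solve(inst))
  expect_identical(r1$phi, r2$phi)
  expect_identical(r1$gamma, r2$gamma)
  js1 <- reconciliation_json(inst, r1)
  js2 <- reconciliation_json(inst, r2)
  expect_identical(js1, js2)
})
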