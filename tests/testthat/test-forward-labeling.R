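test_that("glycolysis-only [1,6-13C]glucose labels pyruvate fully at C3", {
  s <- simulate_labeling(default_net, trc_glc16(), pathway_params())
  expect_pid_pure(s$distributions$pyruvate, 3)
  expect_pid_pure(s$distributions$alanine, 3)
  # first turn: citrate from [2-13C]acetyl + unlabeled OAA is singly labeled
  t1 <- simulate_turns(default_net, trc_glc16(), pathway_params(), 1)[[1]]
  cit_mid <- positional_to_mid(t1$citrate)
  expect_equal(unname(cit_mid[["M+1"]]), 1)
})

test_that("PC is required for the [2,3-13C]glutamate pattern on the two-turn horizon", {
  # beyond turn 2, succinate scrambling of acetyl-derived label can reach
  # the [2,3] pattern without PC; the diagnostic contrast lives in the
  # first two turns, where only PC produces it
  p23 <- pattern_index(c(2, 3))
  t0 <- simulate_turns(default_net, trc_glc12(), pathway_params(f_pc = 0), 2)
  expect_equal(t0[[1]]$glutamate$probs[p23], 0)
  expect_equal(t0[[2]]$glutamate$probs[p23], 0)
  # PC inflow enters the OAA pool at the end of turn 1, so the pattern
  # surfaces in glutamate from turn 2
  t1 <- simulate_turns(default_net, trc_glc12(), pathway_params(f_pc = 0.2), 2)
  expect_gt(t1[[2]]$glutamate$probs[p23], 0)
  # steady state: the pattern is monotone in f_pc
  lvl <- vapply(c(0, 0.1, 0.3), function(f) {
    simulate_labeling(default_net, trc_glc12(),
                      pathway_params(f_pc = f))$distributions$glutamate$probs[p23]
  }, 0)
  expect_true(all(diff(lvl) > 0))
})

test_that("[1-13C]lactate label is lost at PDH unless PC is active", {
  s0 <- simulate_labeling(default_net, trc_lac1(), pathway_params(f_pc = 0))
  for (m in c("citrate", "glutamate", "malate", "aspartate")) {
    expect_equal(labeled_fraction(s0$distributions[[m]]), 0, label = m)
  }
  s1 <- simulate_labeling(default_net, trc_lac1(), pathway_params(f_pc = 0.15))
  expect_gt(labeled_fraction(s1$distributions$citrate), 0)
  expect_gt(positional_to_mid(s1$distributions$citrate)[["M+1"]], 0)
})

test_that("turn-resolved patterns match the first/second-turn schemes", {
  # [1,2-13C]glucose, turn 1: citrate is a mix of [1,2-13C] and unlabeled
  t1 <- simulate_turns(default_net, trc_glc12(), pathway_params(), 1)[[1]]
  cit <- t1$citrate
  expect_equal(cit$probs[pattern_index(c(1, 2))] + cit$probs[1], 1,
               tolerance = 1e-12)
  expect_equal(cit$probs[pattern_index(c(1, 2))], 0.5)
  # acetate and glucose tracers yield the identical [1,2-13C]acetyl CoA
  # (identical distributions once the acetate pool share matches the 50%
  # pyruvate labeling from [1,2-13C]glucose)
  ta <- simulate_turns(default_net, trc_ace12(0.5),
                       pathway_params(f_acetyl_from_acetate = 1), 1)[[1]]
  expect_equal(ta$acetyl_coa$probs, t1$acetyl_coa$probs)
  # second turn produces M+1 compounds from labeled OAA + unlabeled acetyl
  pp <- pathway_params(f_acetyl_unlabeled = 0.5)
  t2 <- simulate_turns(default_net, trc_glc16(), pp, 2)[[2]]
  expect_gt(positional_to_mid(t2$citrate)[["M+2"]], 0)
  # fully unlabeled inputs stay unlabeled through any number of turns
  t0 <- simulate_turns(default_net, list(tracer_spec("glucose", integer(0))),
                       pathway_params(f_pc = 0.3, f_recycle = 0.2), 3)
  for (turn in t0) {
    for (m in names(turn)) expect_equal(labeled_fraction(turn[[m]]), 0)
  }
})

test_that("all steady-state distributions are normalized", {
  pp <- pathway_params(f_ppp = 0.2, f_pc = 0.15, f_recycle = 0.1,
                       f_pyr_unlabeled = 0.2, f_acetyl_unlabeled = 0.1,
                       f_gln_dilution = 0.4)
  s <- simulate_labeling(default_net, trc_glc12(), pp)
  for (m in names(s$distributions)) {
    expect_equal(sum(s$distributions[[m]]$probs), 1, tolerance = 1e-9)
    expect_true(all(s$distributions[[m]]$probs >= 0))
  }
})

test_that("the fixed point does not depend on the OAA initialization", {
  pp <- pathway_params(f_ppp = 0.1, f_pc = 0.2, f_recycle = 0.05,
                       f_pyr_unlabeled = 0.1)
  s_unl <- simulate_labeling(default_net, trc_glc12(), pp)
  uniform <- pid("oaa", 4, rep(1 / 16, 16))
  s_uni <- simulate_labeling(default_net, trc_glc12(), pp, oaa_init = uniform)
  for (m in names(s_unl$distributions)) {
    expect_lt(isopath:::pid_l1(s_unl$distributions[[m]],
                               s_uni$distributions[[m]]),
              10 * pp$convergence_tol)
  }
})

test_that("unlabeled pyruvate dilution never increases downstream labeling", {
  base <- pathway_params(f_ppp = 0.1, f_pc = 0.2, f_recycle = 0.1)
  prev <- NULL
  for (f in c(0, 0.25, 0.5, 0.75)) {
    s <- simulate_labeling(default_net, trc_glc12(),
                           update_params(base, f_pyr_unlabeled = f))
    lf <- vapply(s$distributions, labeled_fraction, 0)
    if (!is.null(prev)) expect_true(all(lf <= prev + 1e-12))
    prev <- lf
  }
})

test_that("pyruvate labeling from [1,2-13C]glucose is half that from [1,6]", {
  s12 <- simulate_labeling(default_net, trc_glc12(), pathway_params())
  s16 <- simulate_labeling(default_net, trc_glc16(), pathway_params())
  expect_equal(labeled_fraction(s12$distributions$pyruvate),
               labeled_fraction(s16$distributions$pyruvate) / 2)
})

test_that("invalid parameters and non-convergence are reported", {
  expect_error(pathway_params(f_ppp = 1.5), "f_ppp")
  expect_error(pathway_params(f_acetyl_from_acetate = 0.7,
                              f_acetyl_unlabeled = 0.5), "<= 1")
  expect_error(pathway_params(max_turns = 0), "max_turns")
  expect_error(simulate_labeling(default_net, trc_glc16(),
                                 pathway_params(max_turns = 2)),
               "did not converge")
})

test_that("PPP re-entry passes shift triose labeling as configured", {
  p0 <- pathway_params(f_ppp = 0.3)
  p1 <- pathway_params(f_ppp = 0.3, ppp_reentry_passes = 2)
  s0 <- simulate_labeling(default_net, trc_glc12(), p0)
  s1 <- simulate_labeling(default_net, trc_glc12(), p1)
  m0 <- positional_to_mid(s0$distributions$triose)
  m1 <- positional_to_mid(s1$distributions$triose)
  # more oxidative passes remove more C1 label: M+2 falls
  expect_lt(m1[["M+2"]], m0[["M+2"]])
})
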