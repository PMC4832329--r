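test_that("PPP fraction from a triose MID follows the M+1/M+2 reading", {
  mid <- c(0.868, 0.012, 0.120, 0)
  rep <- ppp_fraction_from_mid(mid)
  expect_equal(rep$value[rep$method == "M1/M2"], 10.0)
  expect_equal(rep$value[rep$method == "M1/(M1+M2)"], 100 * 0.012 / 0.132)
  expect_match(rep$note[1], "underestimate")
  zero <- ppp_fraction_from_mid(c(0.9, 0, 0.1, 0))
  expect_equal(zero$value[1], 0)
  expect_error(ppp_fraction_from_mid(c(0.9, 0.1, 0, 0)), "undefined")
  # scale invariance of the ratio readings
  expect_equal(ppp_fraction_from_mid(mid)$value,
               ppp_fraction_from_mid(mid / sum(mid[1:3]))$value)
})

test_that("PPP fraction from glutamate C4 divides singlet by doublet", {
  ps <- nmr_peak_set("glutamate", 4, c(singlet = 0.9, d5 = 9.0),
                     internal_standard_area = 1,
                     internal_standard_13c_amount = 1, pool_total = 0)
  rep <- ppp_fraction_from_glutamate_c4(ps)
  expect_equal(rep$value[rep$method == "s/d"], 10.0)
  expect_equal(rep$value[rep$method == "s/(s+d)"], 100 * 0.9 / 9.9)
  ps0 <- nmr_peak_set("glutamate", 4, c(singlet = 0, d5 = 9.0))
  expect_equal(ppp_fraction_from_glutamate_c4(ps0)$value[1], 0)
  psz <- nmr_peak_set("glutamate", 4, c(singlet = 1, d5 = 0))
  expect_error(ppp_fraction_from_glutamate_c4(psz), "doublet")
  # area scale invariance
  ps10 <- nmr_peak_set("glutamate", 4, c(singlet = 9, d5 = 90))
  expect_equal(ppp_fraction_from_glutamate_c4(ps10)$value,
               ppp_fraction_from_glutamate_c4(
                 nmr_peak_set("glutamate", 4, c(singlet = 0.9, d5 = 9)))$value)
})

test_that("both PPP estimators increase with the generating f_ppp", {
  prev_mid <- -1; prev_nmr <- -1
  for (f in c(0.05, 0.15, 0.3)) {
    s <- simulate_labeling(default_net, trc_glc12(), pathway_params(f_ppp = f))
    est_mid <- ppp_fraction_from_mid(positional_to_mid(s$distributions$triose))
    mp <- predict_multiplets(s$distributions$glutamate, 4)
    ps <- nmr_peak_set("glutamate", 4,
                       c(singlet = mp$fractions[["singlet"]],
                         d5 = mp$fractions[["d5"]]))
    est_nmr <- ppp_fraction_from_glutamate_c4(ps)
    expect_gt(est_mid$value[1], prev_mid)
    expect_gt(est_nmr$value[1], prev_nmr)
    prev_mid <- est_mid$value[1]; prev_nmr <- est_nmr$value[1]
  }
})

test_that("PC evidence from citrate under labeled lactate", {
  s0 <- simulate_labeling(default_net, trc_lac1(), pathway_params(f_pc = 0))
  r0 <- pc_evidence_from_lactate_tracer(
    positional_to_mid(s0$distributions$citrate))
  expect_equal(r0$value, 0)
  expect_equal(r0$flag, "PC-negative")
  s1 <- simulate_labeling(default_net, trc_lac1(), pathway_params(f_pc = 0.15))
  r1 <- pc_evidence_from_lactate_tracer(
    positional_to_mid(s1$distributions$citrate))
  expect_gt(r1$value, 0)
  expect_equal(r1$flag, "PC-positive")
  expect_equal(pc_evidence_from_lactate_tracer(c(0.9, 0.10, 0, 0, 0, 0, 0))$value,
               10)
})

test_that("PC evidence from the glutamate C2 doublets", {
  expect_equal(pc_evidence_from_glutamate_c2(
    nmr_peak_set("glutamate", 2, c(d1 = 1, d3 = 0)))$value, 0)
  expect_equal(pc_evidence_from_glutamate_c2(
    nmr_peak_set("glutamate", 2, c(d1 = 2, d3 = 2)))$value, 0.5)
  expect_error(pc_evidence_from_glutamate_c2(
    nmr_peak_set("glutamate", 2, c(d1 = 0, d3 = 0))), "undefined")
  # monotone in f_pc on forward simulations
  prev <- -1
  for (f in c(0, 0.1, 0.2, 0.35)) {
    s <- simulate_labeling(default_net, trc_glc12(), pathway_params(f_pc = f))
    mp <- predict_multiplets(s$distributions$glutamate, 2)
    ps <- nmr_peak_set("glutamate", 2, c(d1 = mp$fractions[["d1"]],
                                         d3 = mp$fractions[["d3"]]))
    v <- pc_evidence_from_glutamate_c2(ps)$value
    expect_gt(v, prev)
    prev <- v
  }
})

test_that("recycling index uses the tracer-diagnostic channels", {
  s0 <- simulate_labeling(default_net, trc_glc12(), pathway_params(f_recycle = 0))
  r0 <- recycling_index(positional_to_mid(s0$distributions$alanine),
                        trc_glc12()[[1]])
  expect_equal(r0$value, 0)
  prev <- -1
  for (f in c(0.05, 0.1, 0.2)) {
    s <- simulate_labeling(default_net, trc_glc12(),
                           pathway_params(f_recycle = f))
    v <- recycling_index(positional_to_mid(s$distributions$alanine),
                         trc_glc12()[[1]])$value
    expect_gt(v, prev); prev <- v
  }
  sa <- simulate_labeling(default_net, trc_ace12(),
                          pathway_params(f_acetyl_from_acetate = 0.5,
                                         f_recycle = 0.1))
  ra <- recycling_index(positional_to_mid(sa$distributions$alanine),
                        trc_ace12()[[1]])
  expect_gt(ra$value, 0)
  expect_error(recycling_index(c(1, 0, 0, 0), trc_glc16()[[1]]),
               "no recycling-diagnostic")
})

test_that("medium rates follow the printed normalization", {
  mm <- medium_measurement("glucose", 2.0, 1.2, volume = 2,
                           cell_count = 1e6, duration = 24)
  expect_equal(medium_rate(mm)$value[1], -1.6)
  expect_equal(medium_rate(medium_measurement("lactate", 1, 1))$value[1], 0)
  half <- medium_measurement("glucose", 2.0, 1.2, volume = 2,
                             cell_count = 1e6, duration = 12)
  expect_equal(medium_rate(half)$value[1], -3.2)
  expect_error(medium_measurement("glucose", 2, 1, cell_count = 0), "positive")
  # labeled/unlabeled split
  mm2 <- medium_measurement("lactate", 5, 6.8, volume = 2, cell_count = 1e6,
                            duration = 24, labeled_conc_t0 = 5,
                            labeled_conc_t_end = 4.5)
  rates <- medium_rate(mm2)
  expect_equal(rates$value[rates$quantity == "lactate_rate_labeled"], -1.0)
  expect_equal(rates$value[rates$quantity == "lactate_rate_unlabeled"], 4.6)
})

test_that("lactate:oxidation partition rounds to the display ratio", {
  astro <- lactate_oxidation_partition(3.2, 5.3)
  expect_equal(astro$display_ratio, "80:20")
  expect_equal(astro$lactate_pct, 100 * 5.3 / 6.4)
  expect_equal(lactate_oxidation_partition(2, 4)$display_ratio, "100:0")
  expect_equal(lactate_oxidation_partition(2, 0)$display_ratio, "0:100")
  over <- lactate_oxidation_partition(1, 3)
  expect_match(over$warnings, "exceeds")
  expect_error(lactate_oxidation_partition(0, 1), "> 0")
})

test_that("fitting recovers a single free parameter from noiseless data", {
  truth <- pathway_params(f_ppp = 0.18, f_pyr_unlabeled = 0.1)
  s <- simulate_labeling(default_net, trc_glc12(), truth)
  cond <- list(list(tracers = trc_glc12(),
                    mids = list(triose = positional_to_mid(s$distributions$triose),
                                alanine = positional_to_mid(s$distributions$alanine))))
  fit <- fit_params(default_net, cond, free = "f_ppp",
                    base_params = pathway_params(f_pyr_unlabeled = 0.1),
                    n_starts = 3, seed = 42)
  expect_lt(abs(fit$estimate[["f_ppp"]] - 0.18), 1e-3)
  expect_lt(fit$residual, 1e-10)
  expect_error(fit_params(default_net, cond, free = character(0), seed = 1),
               "no free parameters")
  expect_error(fit_params(default_net, cond, free = "f_ppp"), "seed")
})
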