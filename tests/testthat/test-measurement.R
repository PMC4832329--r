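test_that("positional to mass isotopologue collapse counts labels", {
  expect_equal(unname(positional_to_mid(pid_pure("pyruvate", 3, c(2, 3)))),
               c(0, 0, 1, 0))
  half <- pid_mix(list(pid_pure("pyruvate", 3, c(2, 3)),
                       pid_unlabeled("pyruvate", 3)), c(1, 1))
  expect_equal(unname(positional_to_mid(half)), c(0.5, 0, 0.5, 0))
  uniform <- pid("triose", 3, rep(1 / 8, 8))
  expect_equal(unname(positional_to_mid(uniform)), c(1, 3, 3, 1) / 8)
  # linear, probability-preserving map
  withr::with_seed(5, {
    p <- stats::runif(32); p <- p / sum(p)
    q <- stats::runif(32); q <- q / sum(q)
    mix <- positional_to_mid(pid("glutamate", 5, 0.3 * p + 0.7 * q))
    expect_equal(unname(mix),
                 unname(0.3 * positional_to_mid(pid("glutamate", 5, p)) +
                          0.7 * positional_to_mid(pid("glutamate", 5, q))))
    expect_equal(sum(mix), 1)
  })
})

test_that("multiplet prediction resolves coupling partners", {
  d45 <- predict_multiplets(pid_pure("glutamate", 5, c(4, 5)), 4)
  expect_equal(unname(d45$fractions[["d5"]]), 1)
  d23 <- predict_multiplets(pid_pure("glutamate", 5, c(2, 3)), 2)
  expect_equal(unname(d23$fractions[["d3"]]), 1)
  d12 <- predict_multiplets(pid_pure("glutamate", 5, c(1, 2)), 2)
  expect_equal(unname(d12$fractions[["d1"]]), 1)
  s4 <- predict_multiplets(pid_pure("glutamate", 5, 4), 4)
  expect_equal(unname(s4$fractions[["singlet"]]), 1)
  dd <- predict_multiplets(pid_pure("glutamate", 5, c(3, 4, 5)), 4)
  expect_equal(unname(dd$fractions[["dd"]]), 1)
  # fractions sum to 1 whenever the observed carbon can be labeled
  withr::with_seed(6, {
    p <- stats::runif(32); p <- p / sum(p)
    mp <- predict_multiplets(pid("glutamate", 5, p), 3)
    expect_equal(sum(mp$fractions), 1)
  })
  # never-labeled observed carbon yields a flagged empty result
  empty <- predict_multiplets(pid_pure("glutamate", 5, 2), 4)
  expect_true(empty$empty)
  expect_length(empty$fractions, 0)
})

test_that("natural-abundance convolution matches binomial expectations", {
  f6 <- fragment_formula(C = 6, backbone = 6)
  obs <- natural_abundance_convolve(c(1, rep(0, 6)), f6)
  expect_equal(unname(obs[["M+1"]]),
               6 * 0.0107 * (1 - 0.0107)^5 / sum(stats::dbinom(0:6, 6, 0.0107)),
               tolerance = 1e-12)
  # zero-abundance table: identity
  zero <- lapply(natural_abundance_table(), function(x) c(1, rep(0, length(x) - 1)))
  mid <- c(0.5, 0, 0.5, 0)
  f3 <- fragment_formula(C = 15, H = 30, O = 3, Si = 2, backbone = 3)
  expect_equal(unname(natural_abundance_convolve(mid, f3, abundance = zero)),
               mid)
  expect_error(natural_abundance_convolve(mid, f6), "backbone")
})

test_that("convolve then correct is the identity", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      n <- sample(2:6, 1)
      frm <- fragment_formula(C = n + sample(5:14, 1), H = sample(10:40, 1),
                              N = sample(0:1, 1), O = sample(1:4, 1),
                              Si = sample(0:2, 1), backbone = n)
      x <- random_mid(n)
      obs <- natural_abundance_convolve(x, frm)
      back <- natural_abundance_correct(obs, frm)
      expect_equal(unname(back), unname(x), tolerance = 1e-8)
    }
  })
})

test_that("empirical and theoretical corrections agree on the same standard", {
  frm <- fragment_formula(C = 12, H = 26, O = 3, Si = 2, backbone = 4)
  standard <- natural_abundance_convolve(c(1, rep(0, 4)), frm)
  # correcting the standard itself yields pure M+0
  expect_equal(unname(natural_abundance_correct(standard, frm)),
               c(1, 0, 0, 0, 0), tolerance = 1e-10)
  x <- c(0.3, 0.1, 0.4, 0.15, 0.05)
  obs <- natural_abundance_convolve(x, frm)
  theo <- natural_abundance_correct(obs, frm)
  emp <- natural_abundance_correct(obs, standard_mid = standard, n_backbone = 4)
  expect_equal(unname(emp), unname(theo), tolerance = 1e-8)
})

test_that("large negative corrected mass is a data-quality error", {
  # an observed spectrum with no M+1 is impossible for a heavy-atom fragment;
  # the solver's negative component must be reported, not silently clipped
  expect_error(natural_abundance_correct(c(0.5, 0, 0, 0.5),
                                         fragment_formula(C = 20, backbone = 3)),
               "negative mass")
  frm <- fragment_formula(C = 3, backbone = 3)
  expect_silent(natural_abundance_correct(
    natural_abundance_convolve(c(0.5, 0, 0.5, 0), frm), frm))
})

test_that("percent excess reports M+1.. as percentages", {
  expect_equal(unname(percent_excess(c(0.8, 0.05, 0.15))), c(5, 15))
  expect_equal(unname(percent_excess(c(1, 0, 0))), c(0, 0))
})

test_that("NMR quantification follows the internal-standard rule", {
  ps <- nmr_peak_set("glutamate", 4, c(singlet = 2, d5 = 8),
                     internal_standard_area = 2,
                     internal_standard_13c_amount = 1)
  expect_equal(quantify_nmr_peak(2, ps), 1)
  expect_equal(quantify_nmr_peak(0, ps), 0)
  expect_equal(quantify_nmr_peak(2, ps, correction_factor = 2), 2)
  bad <- nmr_peak_set("glutamate", 4, c(singlet = 1), internal_standard_area = 1)
  bad$internal_standard_area <- 0
  expect_error(quantify_nmr_peak(1, bad), "standard area")
})

test_that("singlet natural-abundance correction uses the 1H pool", {
  expect_equal(correct_singlet_for_natural_abundance(1.07, 100), 0)
  expect_equal(correct_singlet_for_natural_abundance(5, 0), 5)
  expect_equal(correct_singlet_for_natural_abundance(2.07, 100), 1.0)
  expect_warning(out <- correct_singlet_for_natural_abundance(0.5, 100),
                 "floored")
  expect_equal(out, 0)
})

test_that("C4 singlet:doublet equals the acetyl [2]:[1,2] ratio", {
  # first-turn, undiluted: glutamate C4/C5 come directly from acetyl C2/C1
  for (f in c(0.05, 0.1, 0.3)) {
    t1 <- simulate_turns(default_net, trc_glc12(), pathway_params(f_ppp = f),
                         1)[[1]]
    ac <- t1$acetyl_coa$probs
    ratio_acetyl <- ac[pattern_index(2)] / ac[pattern_index(c(1, 2))]
    mp <- predict_multiplets(t1$glutamate, 4)
    ratio_nmr <- mp$fractions[["singlet"]] / mp$fractions[["d5"]]
    expect_equal(ratio_nmr, ratio_acetyl, tolerance = 1e-9)
  }
})
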