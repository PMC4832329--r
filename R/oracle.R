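# Stochastic single-molecule atom tracker: an independent brute-force check
# of the deterministic fixed-point simulator.  Each molecule's labeling
# pattern is an integer bit mask; pathway branches are chosen per molecule
# with probabilities equal to the mixing parameters.

# vectorized carbon-map application: pattern vectors per substrate slot in,
# product pattern vector out
mc_map <- function(network, rx_name, product_index, pattern_vectors) {
  rx <- network$reactions[[rx_name]]
  cm <- rx$carbon_map[[product_index]]
  out <- integer(length(pattern_vectors[[1]]))
  for (c in seq_along(cm)) {
    srcv <- cm[[c]]
    if (identical(srcv, CO2_FIXED)) next
    bit <- bitwAnd(bitwShiftR(pattern_vectors[[srcv[1]]], srcv[2] - 1L), 1L)
    out <- out + bitwShiftL(bit, c - 1L)
  }
  out
}

# sample n labeling patterns from a tracer specification
mc_sample_tracer <- function(tracer, n) {
  pat <- integer(n)
  lab <- stats::runif(n) < tracer$pool_fraction_labeled
  for (pos in tracer$labeled_positions) {
    hit <- lab & (stats::runif(n) < tracer$isotopic_purity)
    pat <- pat + bitwShiftL(as.integer(hit), pos - 1L)
  }
  pat
}

#' Monte-Carlo single-molecule labeling oracle
#'
#' Tracks `n_molecules` individual molecules through stochastically chosen
#' pathway branches (branch probabilities equal to the mixing parameters)
#' for `n_turns` TCA turns, and returns empirical positional isotopomer
#' distributions.  Deterministic under a fixed seed.  Supports the default
#' single-pass PPP and one-compartment acetyl CoA model only.
#'
#' @inheritParams simulate_labeling
#' @param n_molecules number of molecules per pool (>= 1).
#' @param seed integer seed (mandatory; the only source of randomness).
#' @param n_turns TCA turns simulated (default 60, ample for the pool
#'   memory to decay below sampling noise).
#' @return list with `distributions` (named list of `pid`, same metabolites
#'   as [simulate_labeling()]) and `n_molecules`.
#' @export
monte_carlo_oracle <- function(network, tracers, params, n_molecules, seed,
                               n_turns = 60L) {
  stopifnot(n_molecules >= 1)
  validate_params(params)
  if (params$ppp_reentry_passes > 0) {
    stop("the Monte-Carlo oracle supports the single-pass PPP model only")
  }
  if (params$two_compartment) {
    stop("the Monte-Carlo oracle supports the one-compartment model only")
  }
  tracers <- as_tracer_list(tracers)
  n <- as.integer(n_molecules)
  mets <- network$metabolites
  p <- params

  hx_tr <- find_tracer(tracers, "hexose")
  lac_tr <- find_tracer(tracers, "lactate")
  ace_tr <- find_tracer(tracers, "acetate")

  sample_hexose <- function(m) {
    if (is.null(hx_tr)) integer(m) else mc_sample_tracer(hx_tr, m)
  }
  glyc_triose <- function(hex) {
    a <- mc_map(network, "glycolysis_cleavage", 1L, list(hex))
    b <- mc_map(network, "glycolysis_cleavage", 2L, list(hex))
    ifelse(stats::runif(length(hex)) < 0.5, a, b)
  }
  ppp_triose <- function(m) {
    # three pentoses (one per hexose entering the branch) -> 2 F6P + 1 GA3P;
    # five product trioses per trio, one picked uniformly per molecule
    p1 <- mc_map(network, "ppp_oxidative", 1L, list(sample_hexose(m)))
    p2 <- mc_map(network, "ppp_oxidative", 1L, list(sample_hexose(m)))
    p3 <- mc_map(network, "ppp_oxidative", 1L, list(sample_hexose(m)))
    s7p   <- mc_map(network, "ppp_tk1", 1L, list(p1, p2))
    ga3p1 <- mc_map(network, "ppp_tk1", 2L, list(p1, p2))
    f6p1  <- mc_map(network, "ppp_ta", 1L, list(s7p, ga3p1))
    e4p   <- mc_map(network, "ppp_ta", 2L, list(s7p, ga3p1))
    f6p2  <- mc_map(network, "ppp_tk2", 1L, list(p3, e4p))
    ga3p2 <- mc_map(network, "ppp_tk2", 2L, list(p3, e4p))
    pick <- sample.int(5L, m, replace = TRUE)
    out <- integer(m)
    out[pick <= 2L] <- glyc_triose(f6p1[pick <= 2L])
    out[pick %in% c(3L, 4L)] <- glyc_triose(f6p2[pick %in% c(3L, 4L)])
    out[pick == 5L] <- ga3p2[pick == 5L]
    out
  }
  # a triose molecule's route probability is yield-weighted: 2 trioses per
  # hexose via glycolysis, 5/3 via the single-pass PPP
  p_triose_ppp <- if (p$f_ppp > 0) {
    p$f_ppp * (5 / 3) / ((1 - p$f_ppp) * 2 + p$f_ppp * (5 / 3))
  } else 0
  sample_triose <- function(m) {
    via_ppp <- stats::runif(m) < p_triose_ppp
    out <- integer(m)
    if (any(via_ppp)) out[via_ppp] <- ppp_triose(sum(via_ppp))
    if (any(!via_ppp)) out[!via_ppp] <- glyc_triose(sample_hexose(sum(!via_ppp)))
    out
  }
  sample_base_pyr <- function(m) {
    out <- sample_triose(m)  # triose pool is pyruvate-numbered
    if (!is.null(lac_tr)) {
      from_lac <- stats::runif(m) < lac_tr$pool_fraction_labeled
      lab <- tracer_spec("lactate", lac_tr$labeled_positions,
                         lac_tr$isotopic_purity, 1)
      out[from_lac] <- mc_sample_tracer(lab, sum(from_lac))
    }
    out
  }
  sample_pyr <- function(m, malate_pool) {
    u <- stats::runif(m)
    out <- integer(m)
    rec <- u < p$f_recycle
    unl <- !rec & (u < p$f_recycle + (1 - p$f_recycle) * p$f_pyr_unlabeled)
    base <- !rec & !unl
    if (any(rec)) {
      parents <- malate_pool[sample.int(length(malate_pool), sum(rec), replace = TRUE)]
      out[rec] <- mc_map(network, "malic_enzyme", 1L, list(parents))
    }
    if (any(base)) out[base] <- sample_base_pyr(sum(base))
    out
  }
  sample_acetate_acetyl <- function(m) {
    ace <- if (is.null(ace_tr)) integer(m) else mc_sample_tracer(ace_tr, m)
    mc_map(network, "acetate_to_acetyl", 1L, list(ace))
  }

  rev4 <- reverse_perm(4L)

  withr::with_seed(as.integer(seed), {
    oaa <- integer(n); malate <- integer(n)
    pools <- NULL
    for (turn in seq_len(n_turns)) {
      pyr <- sample_pyr(n, malate)
      u <- stats::runif(n)
      acetyl <- integer(n)
      from_ace <- u < p$f_acetyl_from_acetate
      from_unl <- !from_ace &
        (u < p$f_acetyl_from_acetate + p$f_acetyl_unlabeled)
      from_pdh <- !from_ace & !from_unl
      if (any(from_ace)) acetyl[from_ace] <- sample_acetate_acetyl(sum(from_ace))
      if (any(from_pdh)) {
        parents <- pyr[sample.int(n, sum(from_pdh), replace = TRUE)]
        acetyl[from_pdh] <- mc_map(network, "pdh", 1L, list(parents))
      }
      oaa_partner <- oaa[sample.int(n)]
      citrate <- mc_map(network, "citrate_synthase", 1L, list(acetyl, oaa_partner))
      akg <- mc_map(network, "citrate_to_akg", 1L, list(citrate))
      succ <- mc_map(network, "akg_to_succinate", 1L, list(akg))
      flip <- stats::runif(n) < 0.5
      succ[flip] <- rev4[succ[flip] + 1L] - 1L
      malate_new <- mc_map(network, "succinate_to_malate", 1L, list(succ))
      via_pc <- stats::runif(n) < p$f_pc
      oaa_new <- mc_map(network, "malate_to_oaa", 1L, list(malate_new))
      if (any(via_pc)) {
        parents <- pyr[sample.int(n, sum(via_pc), replace = TRUE)]
        oaa_new[via_pc] <- mc_map(network, "pc", 1L, list(parents))
      }
      oaa <- oaa_new; malate <- malate_new
      pools <- list(pyruvate = pyr, acetyl_coa = acetyl, citrate = citrate,
                    akg = akg, succinate = succ, malate = malate, oaa = oaa)
    }
    gln_unl <- stats::runif(n) < p$f_gln_dilution
    gln <- pools$akg
    gln[gln_unl] <- 0L
    hexose <- sample_hexose(n)
    triose <- sample_triose(n)
    emp <- function(metab, pat) {
      m <- mets[[metab]]
      counts <- tabulate(pat + 1L, nbins = 2L^m)
      pid(metab, m, counts / n)
    }
    dists <- list(
      hexose = emp("hexose", hexose),
      triose = emp("triose", triose),
      pyruvate = emp("pyruvate", pools$pyruvate),
      lactate = emp("lactate", pools$pyruvate),
      alanine = emp("alanine", pools$pyruvate),
      acetyl_coa = emp("acetyl_coa", pools$acetyl_coa),
      citrate = emp("citrate", pools$citrate),
      akg = emp("akg", pools$akg),
      glutamate = emp("glutamate", pools$akg),
      glutamine = emp("glutamine", gln),
      succinate = emp("succinate", pools$succinate),
      malate = emp("malate", pools$malate),
      oaa = emp("oaa", pools$oaa),
      aspartate = emp("aspartate", pools$oaa))
    list(distributions = dists, n_molecules = n, n_turns = n_turns)
  })
}
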