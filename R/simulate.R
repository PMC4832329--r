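# Steady-state propagation of tracer label through the network under
# pathway mixing parameters.  The only state carried across TCA turns is the
# OAA distribution (and the malate pool feeding pyruvate recycling); all
# cytosolic pools are recomputed from the tracers each turn.

#' Pathway mixing parameters
#'
#' The dimensionless pool-mixing fractions the estimators aim to recover.
#' All fractions are pool shares per turn: `f_pc` is the PC-derived share of
#' the OAA pool, `f_recycle` the malate-derived share of the pyruvate pool
#' (via malic enzyme).
#'
#' @param f_ppp fraction of hexose-P entering the oxidative PPP (vs direct
#'   glycolysis).
#' @param f_pc PC-derived share of the OAA pool (vs carbon cycled through
#'   citrate -> alpha-KG -> succinate -> malate).
#' @param f_recycle malate-derived share of the pyruvate pool (pyruvate
#'   recycling via malic enzyme).
#' @param f_pyr_unlabeled fraction of pyruvate from unlabeled sources.
#' @param f_acetyl_from_acetate fraction of acetyl CoA derived from the
#'   acetate pool (vs pyruvate via PDH).
#' @param f_acetyl_unlabeled fraction of acetyl CoA from unlabeled sources.
#' @param f_gln_dilution fraction of the glutamine pool from unlabeled
#'   sources (glutamine labels slower than glutamate).
#' @param ppp_reentry_passes number of additional oxidative-branch re-entry
#'   passes for PPP-regenerated hexose-P (default 0: one full TK/TA pass,
#'   regenerated hexose-P exits via glycolysis).
#' @param two_compartment if TRUE, acetate-derived acetyl CoA feeds a
#'   separate TCA pool (with unlabeled pyruvate inflow) and measured TCA
#'   metabolites are mixed across compartments by `f_acetyl_from_acetate`.
#' @param convergence_tol L1 threshold on the OAA distribution change per
#'   turn (default 1e-10).
#' @param max_turns iteration cap (default 500).
#' @return object of class `pathway_params`.
#' @export
pathway_params <- function(f_ppp = 0, f_pc = 0, f_recycle = 0,
                           f_pyr_unlabeled = 0, f_acetyl_from_acetate = 0,
                           f_acetyl_unlabeled = 0, f_gln_dilution = 0,
                           ppp_reentry_passes = 0L, two_compartment = FALSE,
                           convergence_tol = 1e-10, max_turns = 500L) {
  p <- list(f_ppp = f_ppp, f_pc = f_pc, f_recycle = f_recycle,
            f_pyr_unlabeled = f_pyr_unlabeled,
            f_acetyl_from_acetate = f_acetyl_from_acetate,
            f_acetyl_unlabeled = f_acetyl_unlabeled,
            f_gln_dilution = f_gln_dilution,
            ppp_reentry_passes = as.integer(ppp_reentry_passes),
            two_compartment = isTRUE(two_compartment),
            convergence_tol = convergence_tol,
            max_turns = as.integer(max_turns))
  validate_params(p)
  structure(p, class = "pathway_params")
}

validate_params <- function(p) {
  fr <- c("f_ppp", "f_pc", "f_recycle", "f_pyr_unlabeled",
          "f_acetyl_from_acetate", "f_acetyl_unlabeled", "f_gln_dilution")
  for (f in fr) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("parameter ", f, " must be a fraction in [0,1]")
    }
  }
  if (p$f_acetyl_from_acetate + p$f_acetyl_unlabeled > 1 + 1e-12) {
    stop("f_acetyl_from_acetate + f_acetyl_unlabeled must be <= 1")
  }
  if (p$convergence_tol <= 0) stop("convergence_tol must be > 0")
  if (p$max_turns < 1) stop("max_turns must be >= 1")
  invisible(TRUE)
}

#' Update a parameter set
#' @param params a `pathway_params`.
#' @param ... fields to replace.
#' @export
update_params <- function(params, ...) {
  upd <- list(...)
  for (nm in names(upd)) {
    if (!nm %in% names(params)) stop("unknown parameter ", nm)
    params[[nm]] <- upd[[nm]]
  }
  validate_params(params)
  params
}

# find a tracer by substrate name in a tracer list
find_tracer <- function(tracers, substrate) {
  for (tr in tracers) if (tr$substrate == substrate) return(tr)
  NULL
}

as_tracer_list <- function(tracers) {
  if (inherits(tracers, "tracer_spec")) list(tracers) else tracers
}

# Cytosolic triose (3PG/PEP) pool from the hexose pool: mixture of direct
# glycolysis output and the PPP route (oxidative loss of C1, one or more
# TK/TA passes).  Returns the triose pid plus the hexose pid used.
triose_pool <- function(network, hexose, f_ppp, reentry_passes = 0L) {
  glyc <- function(hx) {
    pr <- apply_reaction(network, "glycolysis_cleavage", hx)$products
    pid_mix(pr, c(1, 1))
  }
  if (f_ppp <= 0) {
    return(list(triose = glyc(hexose), hexose = hexose))
  }
  # PPP route, tracked in triose molecules per hexose entering the branch
  triose_parts <- list(); triose_wts <- numeric(0)
  hex_in <- hexose; amount <- 1  # hexose molecules entering oxidative branch
  for (pass in 0:reentry_passes) {
    pentose <- apply_reaction(network, "ppp_oxidative", hex_in)$products[[1]]
    tk1 <- apply_reaction(network, "ppp_tk1", list(pentose, pentose))
    s7p <- tk1$products[[1]]; ga3p1 <- tk1$products[[2]]
    ta <- apply_reaction(network, "ppp_ta", list(s7p, ga3p1))
    f6p1 <- ta$products[[1]]; e4p <- ta$products[[2]]
    tk2 <- apply_reaction(network, "ppp_tk2", list(pentose, e4p))
    f6p2 <- tk2$products[[1]]; ga3p2 <- tk2$products[[2]]
    # per 3 pentoses: 1 F6P (TA), 1 F6P (TK2), 1 triose (TK2)
    triose_parts <- c(triose_parts, list(ga3p2))
    triose_wts <- c(triose_wts, amount / 3)
    f6p <- pid_mix(list(f6p1, f6p2), c(1, 1))
    f6p_amount <- amount * 2 / 3
    if (pass < reentry_passes) {
      hex_in <- f6p; amount <- f6p_amount
    } else {
      triose_parts <- c(triose_parts, list(glyc(f6p)))
      triose_wts <- c(triose_wts, f6p_amount * 2)
    }
  }
  t_ppp <- pid_mix(triose_parts, triose_wts)
  w_ppp <- f_ppp * sum(triose_wts)       # trioses per hexose via PPP
  w_gly <- (1 - f_ppp) * 2               # trioses per hexose via glycolysis
  triose <- pid_mix(list(glyc(hexose), t_ppp), c(w_gly, w_ppp))
  list(triose = triose, hexose = hexose)
}

# one-compartment core: iterate TCA turns, return full metabolite map
simulate_core <- function(network, pyr_base, acetate_acetyl, params,
                          n_turns = NULL, oaa_init = NULL, keep_turns = FALSE) {
  mets <- network$metabolites
  U <- function(m) pid_unlabeled(m, mets[[m]])
  oaa <- if (is.null(oaa_init)) U("oaa") else oaa_init
  malate <- U("malate")
  p <- params
  turn_list <- if (keep_turns) vector("list", 0) else NULL
  residual <- NA_real_; converged <- FALSE
  cap <- if (is.null(n_turns)) p$max_turns else n_turns
  state <- NULL
  for (turn in seq_len(cap)) {
    recycled <- apply_reaction(network, "malic_enzyme", malate)$products[[1]]
    pyr <- pid_mix(list(pyr_base, U("pyruvate"), recycled),
                   c((1 - p$f_recycle) * (1 - p$f_pyr_unlabeled),
                     (1 - p$f_recycle) * p$f_pyr_unlabeled,
                     p$f_recycle))
    acetyl_pdh <- apply_reaction(network, "pdh", pyr)$products[[1]]
    w_pdh <- 1 - p$f_acetyl_from_acetate - p$f_acetyl_unlabeled
    acetyl <- pid_mix(list(acetyl_pdh, acetate_acetyl, U("acetyl_coa")),
                      c(w_pdh, p$f_acetyl_from_acetate, p$f_acetyl_unlabeled))
    citrate <- apply_reaction(network, "citrate_synthase",
                              list(acetyl, oaa))$products[[1]]
    akg <- apply_reaction(network, "citrate_to_akg", citrate)$products[[1]]
    succ <- apply_reaction(network, "akg_to_succinate", akg)$products[[1]]
    malate_new <- apply_reaction(network, "succinate_to_malate", succ)$products[[1]]
    oaa_cycle <- apply_reaction(network, "malate_to_oaa", malate_new)$products[[1]]
    oaa_pc <- apply_reaction(network, "pc", pyr)$products[[1]]
    oaa_new <- pid_mix(list(oaa_cycle, oaa_pc), c(1 - p$f_pc, p$f_pc))
    residual <- pid_l1(oaa_new, oaa)
    state <- list(pyruvate = pyr, acetyl_coa = acetyl, citrate = citrate,
                  akg = akg, succinate = succ, malate = malate_new,
                  oaa = oaa_new)
    oaa <- oaa_new; malate <- malate_new
    if (keep_turns) turn_list[[turn]] <- state
    if (is.null(n_turns) && residual < p$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (is.null(n_turns) && !converged) {
    stop(sprintf(
      "fixed-point iteration did not converge within %d turns (final L1 residual %.3g)",
      p$max_turns, residual))
  }
  list(state = state, turns = turn_list, n_turns = turn,
       residual = residual, converged = converged || !is.null(n_turns))
}

# assemble the reported metabolite map from a core state + cytosolic pools
assemble_map <- function(network, state, hexose, triose, params) {
  mets <- network$metabolites
  glu <- apply_reaction(network, "akg_to_glutamate", state$akg)$products[[1]]
  gln <- pid_mix(list(pid("glutamine", 5, glu$probs),
                      pid_unlabeled("glutamine", 5)),
                 c(1 - params$f_gln_dilution, params$f_gln_dilution))
  asp <- apply_reaction(network, "oaa_to_aspartate", state$oaa)$products[[1]]
  lac <- apply_reaction(network, "pyruvate_to_lactate", state$pyruvate)$products[[1]]
  ala <- apply_reaction(network, "pyruvate_to_alanine", state$pyruvate)$products[[1]]
  list(hexose = hexose, triose = triose, pyruvate = state$pyruvate,
       lactate = lac, alanine = ala, acetyl_coa = state$acetyl_coa,
       citrate = state$citrate, akg = state$akg, glutamate = glu,
       glutamine = gln, succinate = state$succinate, malate = state$malate,
       oaa = state$oaa, aspartate = asp)
}

# mix two metabolite maps elementwise (two-compartment reporting)
mix_maps <- function(map_a, map_b, w_a, w_b) {
  out <- map_a
  for (nm in names(map_a)) {
    out[[nm]] <- pid_mix(list(map_a[[nm]], map_b[[nm]]), c(w_a, w_b))
  }
  out
}

# resolve tracer inputs into the base (pre-dilution, pre-recycling) pyruvate
# pool and the acetate-derived acetyl pool
resolve_sources <- function(network, tracers, params) {
  mets <- network$metabolites
  tracers <- as_tracer_list(tracers)
  for (tr in tracers) {
    if (!tr$substrate %in% names(mets)) {
      stop("tracer substrate ", tr$substrate, " not in network")
    }
  }
  hx_tr <- find_tracer(tracers, "hexose")
  hexose <- if (is.null(hx_tr)) pid_unlabeled("hexose", 6) else
    tracer_pid(hx_tr, "hexose", 6)
  tp <- triose_pool(network, hexose, params$f_ppp, params$ppp_reentry_passes)
  lac_tr <- find_tracer(tracers, "lactate")
  pyr_glc <- apply_reaction(network, "glycolysis_lower", tp$triose)$products[[1]]
  if (is.null(lac_tr)) {
    pyr_base <- pyr_glc
  } else {
    # exogenous lactate competes with glucose-derived pyruvate for the pool:
    # pool_fraction_labeled is the lactate share of the pyruvate-source mix
    lab <- tracer_spec("lactate", lac_tr$labeled_positions,
                       lac_tr$isotopic_purity, 1)
    lac_full <- tracer_pid(lab, "pyruvate", 3)
    pyr_base <- pid_mix(list(lac_full, pyr_glc),
                        c(lac_tr$pool_fraction_labeled,
                          1 - lac_tr$pool_fraction_labeled))
  }
  ace_tr <- find_tracer(tracers, "acetate")
  acetate <- if (is.null(ace_tr)) pid_unlabeled("acetate", 2) else
    tracer_pid(ace_tr, "acetate", 2)
  acetyl_ace <- apply_reaction(network, "acetate_to_acetyl", acetate)$products[[1]]
  list(hexose = tp$hexose, triose = tp$triose, pyr_base = pyr_base,
       acetyl_acetate = acetyl_ace)
}

#' Simulate steady-state label propagation
#'
#' Fixed-point iteration over TCA turns: the pyruvate pool is a mixture of
#' glycolytic/PPP triose output, recycled malate-derived pyruvate and
#' unlabeled dilution; acetyl CoA mixes PDH output, acetate-derived acetyl
#' and unlabeled dilution; the OAA pool is updated each turn through
#' citrate -> alpha-KG -> succinate (symmetric) -> malate plus PC inflow.
#' Iteration stops when the L1 change of the OAA distribution drops below
#' `params$convergence_tol`.
#'
#' @param network an `iso_network` (see [build_default_network()]).
#' @param tracers a `tracer_spec` or list of them.
#' @param params a `pathway_params`.
#' @param oaa_init optional initial OAA `pid` (default unlabeled).
#' @return list with `distributions` (named list of `pid` for hexose,
#'   triose (3PG/PEP), pyruvate, lactate, alanine, acetyl CoA, citrate,
#'   alpha-KG, glutamate, glutamine, succinate, malate, OAA, aspartate),
#'   `n_turns`, `residual`, and the echoed `params`/`tracers`.
#' @export
simulate_labeling <- function(network, tracers, params, oaa_init = NULL) {
  validate_params(params)
  tracers <- as_tracer_list(tracers)
  src <- resolve_sources(network, tracers, params)
  if (!params$two_compartment) {
    core <- simulate_core(network, src$pyr_base, src$acetyl_acetate, params,
                          oaa_init = oaa_init)
    dmap <- assemble_map(network, core$state, src$hexose, src$triose, params)
  } else {
    faa <- params$f_acetyl_from_acetate
    # compartment A: pyruvate-derived acetyl only
    pa <- update_params(params, f_acetyl_from_acetate = 0)
    core_a <- simulate_core(network, src$pyr_base, src$acetyl_acetate, pa,
                            oaa_init = oaa_init)
    map_a <- assemble_map(network, core_a$state, src$hexose, src$triose, pa)
    # compartment B: acetate-derived acetyl, unlabeled pyruvate inflow
    pb <- update_params(params, f_acetyl_from_acetate = 1 - params$f_acetyl_unlabeled)
    core_b <- simulate_core(network, pid_unlabeled("pyruvate", 3),
                            src$acetyl_acetate, pb, oaa_init = oaa_init)
    map_b <- assemble_map(network, core_b$state, src$hexose, src$triose, pb)
    dmap <- mix_maps(map_a, map_b, 1 - faa, faa)
    # cytosolic pools are shared
    for (nm in c("hexose", "triose")) dmap[[nm]] <- map_a[[nm]]
    core <- list(n_turns = max(core_a$n_turns, core_b$n_turns),
                 residual = max(core_a$residual, core_b$residual))
  }
  list(distributions = dmap, n_turns = core$n_turns,
       residual = core$residual, params = params, tracers = tracers)
}

#' Turn-resolved label propagation
#'
#' Runs exactly `n_turns` TCA turns starting from unlabeled OAA and returns
#' the metabolite map after each turn (turn 1 corresponds to condensation of
#' acetyl CoA with unlabeled OAA).
#'
#' @inheritParams simulate_labeling
#' @param n_turns number of turns (>= 1).
#' @return list of per-turn metabolite maps (each as in
#'   [simulate_labeling()]'s `distributions`).
#' @export
simulate_turns <- function(network, tracers, params, n_turns) {
  stopifnot(n_turns >= 1)
  validate_params(params)
  if (params$two_compartment) {
    stop("turn-resolved output is defined for the one-compartment model")
  }
  tracers <- as_tracer_list(tracers)
  src <- resolve_sources(network, tracers, params)
  core <- simulate_core(network, src$pyr_base, src$acetyl_acetate, params,
                        n_turns = n_turns, keep_turns = TRUE)
  lapply(core$turns, function(state) {
    assemble_map(network, state, src$hexose, src$triose, params)
  })
}
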