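# Inference procedures: PPP fraction (GC-MS triose route and NMR glutamate
# C4 route), pyruvate carboxylation evidence (citrate M+1 from labeled
# lactate; glutamate C2 doublet decomposition), pyruvate recycling index,
# medium consumption/release rates with the lactate:oxidation partition,
# and global least-squares parameter fitting against the forward model.

estimate_report <- function(quantity, value, method, note = "",
                            flag = NA_character_, extra = NULL) {
  tb <- tibble::tibble(quantity = quantity, value = unname(value),
                       method = method,
                       flag = flag, note = note)
  if (!is.null(extra)) attr(tb, "extra") <- extra
  tb
}

#' PPP fraction from a corrected triose (PEP/3PG) MID
#'
#' PPP-derived trioses appear as M+1, glycolysis-derived ones as M+2 in a
#' \[1,2-13C\]glucose experiment.  The primary statistic is 100 x M+1/M+2;
#' the alternative normalization 100 x M+1/(M+1+M+2) is co-reported.  The
#' value is known to underestimate the PPP contribution.
#'
#' @param corrected_mid natural-abundance-corrected MID of PEP or 3PG
#'   (vector M+0..M+n, n >= 2).
#' @return tibble of `EstimateReport` rows (method tags `M1/M2` and
#'   `M1/(M1+M2)`).
#' @export
ppp_fraction_from_mid <- function(corrected_mid) {
  m1 <- corrected_mid[2]; m2 <- corrected_mid[3]
  if (is.na(m2) || m2 <= 0) stop("M+2 is zero; the M+1/M+2 ratio is undefined")
  note <- "likely to underestimate the contribution of the PPP"
  rbind(
    estimate_report("ppp_fraction_pct", 100 * m1 / m2, "M1/M2", note),
    estimate_report("ppp_fraction_pct", 100 * m1 / (m1 + m2), "M1/(M1+M2)", note))
}

#' PPP fraction from the glutamate C4 multiplet
#'
#' The C4 singlet (\[4-13C\]glutamate, PPP route) divided by the C4-C5
#' doublet (\[4,5-13C\]glutamate, glycolysis route), after correcting the
#' singlet for natural abundance via the 1H-quantified pool.
#'
#' @param peak_set an [nmr_peak_set()] for glutamate C4 with areas
#'   `singlet` and `d5`.
#' @param c13 natural 13C abundance used in the singlet correction.
#' @return tibble of `EstimateReport` rows (method tags `s/d`, `s/(s+d)`).
#' @export
ppp_fraction_from_glutamate_c4 <- function(peak_set, c13 = 0.0107) {
  areas <- peak_set$areas
  if (!all(c("singlet", "d5") %in% names(areas))) {
    stop("peak set must contain `singlet` and `d5` areas for glutamate C4")
  }
  cf <- peak_set$correction_factors
  s_amt <- quantify_nmr_peak(areas[["singlet"]], peak_set,
                             if ("singlet" %in% names(cf)) cf[["singlet"]] else 1)
  d_amt <- quantify_nmr_peak(areas[["d5"]], peak_set,
                             if ("d5" %in% names(cf)) cf[["d5"]] else 1)
  if (d_amt <= 0) stop("doublet area is zero; the singlet/doublet ratio is undefined")
  s_corr <- correct_singlet_for_natural_abundance(s_amt, peak_set$pool_total, c13)
  rbind(
    estimate_report("ppp_fraction_glu_c4_pct", 100 * s_corr / d_amt, "s/d"),
    estimate_report("ppp_fraction_glu_c4_pct", 100 * s_corr / (s_corr + d_amt),
                    "s/(s+d)"))
}

#' Pyruvate carboxylation evidence from citrate under a \[1-13C\]lactate tracer
#'
#' PDH removes pyruvate C1, so citrate can only be labeled from
#' \[1-13C\]lactate if PC is active; citrate M+1 percent is the readout.
#'
#' @param citrate_mid_corrected corrected citrate MID.
#' @param noise_sigma stated measurement noise on MID fractions; the
#'   PC-positive flag fires above `3 * noise_sigma` (as percent).
#' @return tibble of `EstimateReport` rows.
#' @export
pc_evidence_from_lactate_tracer <- function(citrate_mid_corrected,
                                            noise_sigma = 0.005) {
  m1_pct <- 100 * citrate_mid_corrected[2]
  flag <- if (m1_pct > 3 * 100 * noise_sigma) "PC-positive" else "PC-negative"
  estimate_report("citrate_m1_pct", unname(m1_pct), "citrate M+1",
                  "under PDH-only routing the forward model predicts 0",
                  flag = flag)
}

#' Pyruvate carboxylation evidence from the glutamate C2 doublets
#'
#' In a \[1,2-13C\]glucose experiment the C2-C3 doublet (\[2,3-13C\]
#' glutamate) arises via PC and the C1-C2 doublet (\[1,2-13C\]glutamate)
#' via PDH; the PC share of C2-labeled glutamate is d23 / (d23 + d12).
#'
#' @param peak_set an [nmr_peak_set()] for glutamate C2 with areas `d1`
#'   (C1 coupling partner) and `d3` (C3 partner).
#' @param threshold PC-positive flag threshold on the C3 doublet share.
#' @return tibble of `EstimateReport` rows.
#' @export
pc_evidence_from_glutamate_c2 <- function(peak_set, threshold = 0.015) {
  areas <- peak_set$areas
  if (!all(c("d1", "d3") %in% names(areas))) {
    stop("peak set must contain `d1` and `d3` doublet areas for glutamate C2")
  }
  d12 <- areas[["d1"]]; d23 <- areas[["d3"]]
  if (d12 + d23 <= 0) stop("both C2 doublets are zero; the PC share is undefined")
  share <- d23 / (d23 + d12)
  flag <- if (share > threshold) "PC-positive" else "PC-negative"
  estimate_report("pc_share_glu_c2", unname(share), "d23/(d23+d12)", flag = flag)
}

#' Pyruvate recycling index from a corrected alanine MID
#'
#' Alanine isotopologues that cannot arise from the direct glycolytic route
#' of the given tracer are diagnostic of pyruvate recycling (TCA-cycle
#' carbon returned to pyruvate via malic enzyme): M+1 alanine for
#' \[1,2-13C\]glucose; any labeled alanine for \[1,2-13C\]acetate.
#'
#' @param alanine_mid_corrected corrected alanine MID.
#' @param tracer a `tracer_spec` identifying the labeled substrate.
#' @param threshold positive flag threshold in percent.
#' @return tibble of `EstimateReport` rows.
#' @export
recycling_index <- function(alanine_mid_corrected, tracer, threshold = 1.5) {
  if (tracer$substrate == "hexose" &&
      identical(tracer$labeled_positions, c(1L, 2L))) {
    value <- 100 * alanine_mid_corrected[2]
    method <- "alanine M+1 ([1,2-13C]glucose)"
  } else if (tracer$substrate == "acetate") {
    value <- 100 * sum(alanine_mid_corrected[-1])
    method <- "labeled alanine ([1,2-13C]acetate)"
  } else {
    stop("tracer has no recycling-diagnostic alanine channel: ",
         tracer$substrate, " [", paste(tracer$labeled_positions, collapse = ","),
         "]")
  }
  flag <- if (value > threshold) "recycling-positive" else "recycling-negative"
  estimate_report("recycling_index_pct", unname(value), method, flag = flag)
}

#' Medium measurement
#'
#' @param analyte analyte name.
#' @param conc_t0,conc_t_end concentration (mM) at the start and end of the
#'   incubation.
#' @param volume medium volume (mL).
#' @param cell_count cells per well.
#' @param duration incubation length (hours).
#' @param labeled_conc_t0,labeled_conc_t_end optional mM of the 13C-labeled
#'   species, to split net change into tracer uptake and endogenous release.
#' @export
medium_measurement <- function(analyte, conc_t0, conc_t_end, volume = 2,
                               cell_count = 4e5, duration = 24,
                               labeled_conc_t0 = NA, labeled_conc_t_end = NA) {
  if (volume <= 0 || cell_count <= 0 || duration <= 0) {
    stop("volume, cell_count and duration must be positive")
  }
  if (any(c(conc_t0, conc_t_end) < 0)) stop("concentrations must be >= 0")
  structure(list(analyte = analyte, conc_t0 = conc_t0,
                 conc_t_end = conc_t_end, volume = volume,
                 cell_count = cell_count, duration = duration,
                 labeled_conc_t0 = labeled_conc_t0,
                 labeled_conc_t_end = labeled_conc_t_end),
            class = "medium_measurement")
}

#' Net medium rate in micromol per 10^6 cells per 24 h
#'
#' rate = (end - start concentration) \[mM\] x volume \[mL\] / (cells/10^6)
#' x (24 / duration).  Negative = consumption, positive = release.  When
#' labeled concentrations are supplied the labeled/unlabeled split is
#' reported too (distinguishing tracer uptake from endogenous release).
#'
#' @param measurement a [medium_measurement()].
#' @return tibble of `EstimateReport` rows (`<analyte>_rate`, plus
#'   `<analyte>_rate_labeled` / `_unlabeled` when available).
#' @export
medium_rate <- function(measurement) {
  m <- measurement
  per_rate <- function(c0, c1) {
    (c1 - c0) * m$volume / (m$cell_count / 1e6) * (24 / m$duration)
  }
  out <- estimate_report(paste0(m$analyte, "_rate"),
                         per_rate(m$conc_t0, m$conc_t_end),
                         "umol/1e6 cells/24 h",
                         "negative = consumption, positive = release")
  if (!is.na(m$labeled_conc_t0) && !is.na(m$labeled_conc_t_end)) {
    lab <- per_rate(m$labeled_conc_t0, m$labeled_conc_t_end)
    unl <- per_rate(m$conc_t0 - m$labeled_conc_t0,
                    m$conc_t_end - m$labeled_conc_t_end)
    out <- rbind(out,
      estimate_report(paste0(m$analyte, "_rate_labeled"), lab,
                      "umol/1e6 cells/24 h"),
      estimate_report(paste0(m$analyte, "_rate_unlabeled"), unl,
                      "umol/1e6 cells/24 h"))
  }
  out
}

#' Glucose-to-lactate vs oxidation partition
#'
#' Each glucose yields two pyruvates, so the fraction of glycolytic carbon
#' released as lactate is `lactate_release / (2 x glucose_consumption)`;
#' the remainder is attributed to mitochondrial oxidation.  A display ratio
#' rounded to the nearest ten is reported alongside the raw percentages.
#'
#' @param glucose_consumption_rate positive consumption rate
#'   (umol/10^6 cells/24 h).
#' @param lactate_release_rate non-negative release rate (same units).
#' @return list with `lactate_pct`, `oxidation_pct`, `display_ratio`
#'   (e.g. "80:20") and `warnings`.
#' @export
lactate_oxidation_partition <- function(glucose_consumption_rate,
                                        lactate_release_rate) {
  if (glucose_consumption_rate <= 0) stop("glucose consumption rate must be > 0")
  if (lactate_release_rate < 0) stop("lactate release rate must be >= 0")
  lac_pct <- 100 * lactate_release_rate / (2 * glucose_consumption_rate)
  warnings <- character(0)
  if (lac_pct > 100) {
    warnings <- "net lactate release exceeds glycolytic pyruvate production"
  }
  disp_lac <- round(lac_pct / 10) * 10
  list(lactate_pct = lac_pct, oxidation_pct = 100 - lac_pct,
       display_ratio = sprintf("%d:%d", disp_lac, 100 - disp_lac),
       warnings = warnings)
}

# forward-model observables for fitting: corrected-scale MIDs (and glutamate
# multiplet shares) for one condition
predict_observables <- function(network, tracers, params,
                                metabolites, multiplets = character(0)) {
  sim <- simulate_labeling(network, tracers, params)
  mids <- lapply(sim$distributions[metabolites], positional_to_mid)
  mult <- list()
  for (key in multiplets) {
    parts <- strsplit(key, "_c")[[1]]
    mp <- predict_multiplets(sim$distributions[[parts[1]]],
                             as.integer(parts[2]))
    mult[[key]] <- if (mp$empty) numeric(0) else mp$fractions
  }
  list(mids = mids, multiplets = mult)
}

#' Fit pathway parameters to measured observables
#'
#' Minimizes the sum of squared differences between forward-model
#' observables (corrected MIDs, optionally glutamate multiplet fractions)
#' and measurements across one or more tracer conditions, over a chosen
#' subset of free parameters, using multi-start Nelder-Mead on a logit
#' scale (a bounded derivative-free search).  Equal-residual optima are
#' tie-broken by the smallest parameter-vector norm.
#'
#' @param network an `iso_network`.
#' @param conditions list of conditions; each a list with `tracers`
#'   (tracer list), `mids` (named list: metabolite -> corrected MID vector)
#'   and optionally `multiplets` (named list, e.g.
#'   `glutamate_c2 = c(singlet=..., d1=..., d3=...)`, fractions).
#' @param free character vector of free parameter names (non-empty).
#' @param base_params `pathway_params` supplying the fixed parameters and
#'   starting structure.
#' @param n_starts number of Nelder-Mead starts (Latin-hypercube spread;
#'   default 16).
#' @param seed integer seed for the start design (required).
#' @param lower,upper bounds on every free parameter (defaults 0 and 1).
#' @return list with `params` (fitted `pathway_params`), `estimate` (named
#'   vector of free-parameter values), `residual` (best SSE), and `starts`
#'   (tibble of per-start results).
#' @export
fit_params <- function(network, conditions, free, base_params = pathway_params(),
                       n_starts = 16L, seed, lower = 0, upper = 1) {
  if (length(free) == 0) stop("no free parameters to fit")
  if (missing(seed)) stop("a seed is required for the multi-start design")
  k <- length(free)
  eps <- 1e-6
  lo <- rep_len(lower, k); hi <- rep_len(upper, k)
  to_unit <- function(theta) 1 / (1 + exp(-theta))      # logit^-1
  to_theta <- function(x) log(x / (1 - x))
  make_params <- function(x) {
    upd <- as.list(lo + x * (hi - lo))
    names(upd) <- free
    do.call(update_params, c(list(base_params), upd))
  }
  objective <- function(theta) {
    par <- try(make_params(to_unit(theta)), silent = TRUE)
    if (inherits(par, "try-error")) return(1e6)
    sse <- 0
    for (cond in conditions) {
      mets <- names(cond$mids)
      mkeys <- names(cond$multiplets)
      pred <- try(predict_observables(network, cond$tracers, par, mets,
                                      mkeys %||% character(0)),
                  silent = TRUE)
      if (inherits(pred, "try-error")) return(1e6)
      for (m in mets) {
        obs <- cond$mids[[m]]
        sse <- sse + sum((pred$mids[[m]][seq_along(obs)] - obs)^2)
      }
      for (key in mkeys) {
        obs <- cond$multiplets[[key]]
        prd <- pred$multiplets[[key]]
        shared <- intersect(names(obs), names(prd))
        sse <- sse + sum((prd[shared] - obs[shared])^2)
      }
    }
    sse
  }
  design <- withr::with_seed(as.integer(seed), lhs::randomLHS(n_starts, k))
  starts <- lapply(seq_len(n_starts), function(i) {
    x0 <- pmin(pmax(design[i, ], eps), 1 - eps)
    fit <- if (k == 1) {
      stats::optim(to_theta(x0), objective, method = "Brent",
                   lower = -16, upper = 16,
                   control = list(maxit = 400, reltol = 1e-10))
    } else {
      stats::optim(to_theta(x0), objective, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-10))
    }
    x <- to_unit(fit$par)
    row <- tibble::tibble(start = i, residual = fit$value,
                          converged = fit$convergence == 0)
    vals <- lo + x * (hi - lo)
    for (j in seq_len(k)) row[[free[j]]] <- vals[j]
    row
  })
  starts <- do.call(rbind, starts)
  if (!any(starts$converged | is.finite(starts$residual))) {
    stop("all optimization starts failed")
  }
  est_mat <- as.matrix(starts[, free, drop = FALSE])
  ord <- order(starts$residual, sqrt(rowSums(est_mat^2)))
  best <- starts[ord[1], ]
  estimate <- stats::setNames(as.numeric(best[1, free]), free)
  list(params = make_params((estimate - lo) / (hi - lo)),
       estimate = estimate, residual = best$residual[1], starts = starts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
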