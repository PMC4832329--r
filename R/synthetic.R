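# Synthetic experiments: forward-simulated truth plus natural-abundance-
# contaminated, noisy GC-MS / NMR / medium observables for the four tracer
# incubation designs, with a ground-truth manifest that fully determines
# regeneration.

#' Measurement noise model
#'
#' @param mid_sigma additive Gaussian sigma on observed MID fractions
#'   (renormalized, clipped at 0).
#' @param area_cv lognormal coefficient of variation on NMR peak and pool
#'   areas.
#' @param conc_sigma Gaussian sigma (mM) on medium concentrations.
#' @param seed mandatory integer seed.
#' @export
noise_model <- function(mid_sigma = 0.005, area_cv = 0.05,
                        conc_sigma = 0.05, seed) {
  if (missing(seed)) stop("noise_model requires a seed")
  if (any(c(mid_sigma, area_cv, conc_sigma) < 0)) stop("noise sigmas must be >= 0")
  structure(list(mid_sigma = mid_sigma, area_cv = area_cv,
                 conc_sigma = conc_sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthetic fragment formulas for the measured metabolites
#'
#' Stand-in elemental compositions for the derivatized GC-MS fragments
#' (TBDMS-style: backbone carbons plus a derivatization moiety).  These are
#' synthetic defaults, not literature fragment compositions; supply your own
#' table for real instrument data.
#'
#' @param metabolites named integer vector of backbone carbon counts;
#'   defaults to the measured set.
#' @return named list of [fragment_formula()] objects.
#' @export
default_fragment_formulas <- function(metabolites = NULL) {
  if (is.null(metabolites)) {
    metabolites <- c(triose = 3L, pep = 3L, pg3 = 3L, lactate = 3L,
                     alanine = 3L, citrate = 6L, malate = 4L,
                     aspartate = 4L, glutamate = 5L, glutamine = 5L)
  }
  amino <- c("alanine", "aspartate", "glutamate", "glutamine")
  out <- lapply(names(metabolites), function(m) {
    n <- metabolites[[m]]
    fragment_formula(C = n + 12L, H = 2L * n + 24L,
                     N = if (m %in% amino) 1L else 0L,
                     O = 3L, Si = 2L, backbone = n)
  })
  names(out) <- names(metabolites)
  out
}

# metabolites reported in the GC-MS table; triose is reported under both of
# its measurable proxies (PEP and 3PG share the triose distribution)
mid_report_set <- function() {
  c(pep = "triose", pg3 = "triose", lactate = "lactate", alanine = "alanine",
    citrate = "citrate", malate = "malate", aspartate = "aspartate",
    glutamate = "glutamate", glutamine = "glutamine")
}

perturb_mid <- function(mid, sigma) {
  if (sigma <= 0) return(mid)
  out <- pmax(mid + stats::rnorm(length(mid), 0, sigma), 0)
  out / sum(out)
}

perturb_area <- function(area, cv) {
  if (cv <= 0 || area <= 0) return(area)
  sdlog <- sqrt(log(1 + cv^2))
  area * stats::rlnorm(length(area), -sdlog^2 / 2, sdlog)
}

#' Generate one synthetic tracer condition
#'
#' Runs the forward simulator, converts to GC-MS and NMR observables
#' (natural-abundance convolution on the MIDs; glutamate C4/C2 multiplet
#' areas scaled to the 1H pool with the natural-abundance singlet
#' contribution added), perturbs each replicate per the noise model, and
#' synthesizes medium concentration measurements from configured
#' consumption/release rates.
#'
#' @inheritParams simulate_labeling
#' @param noise a [noise_model()].
#' @param n_replicates replicate wells per condition.
#' @param condition condition label written into every table row.
#' @param medium_rates named list of net rates in umol/10^6 cells/24 h
#'   (negative = consumption), e.g. `list(glucose = -3.0, lactate = 3.6)`;
#'   optionally `lactate_labeled` for the tracer-lactate split.
#' @param medium_t0 named list of starting concentrations (mM).
#' @param formulas named list of fragment formulas (defaults to
#'   [default_fragment_formulas()]).
#' @param pool_umol glutamate pool size for NMR area scaling (umol).
#' @param volume_ml,cell_count,duration_h incubation geometry defaults
#'   (2 mL, 4e5 cells/well, 24 h).
#' @return list with tibbles `mid`, `nmr`, `medium` and the `manifest` list.
#' @export
generate_condition <- function(network, tracers, params, noise,
                               n_replicates = 3L, condition = "condition",
                               medium_rates = list(glucose = -3.0, lactate = 3.6),
                               medium_t0 = list(glucose = 2.0, lactate = 0),
                               formulas = default_fragment_formulas(),
                               pool_umol = 0.05, volume_ml = 2,
                               cell_count = 4e5, duration_h = 24) {
  tracers <- as_tracer_list(tracers)
  sim <- simulate_labeling(network, tracers, params)
  report <- mid_report_set()

  withr::with_seed(noise$seed, {
    mid_rows <- list()
    for (label in names(report)) {
      dist <- sim$distributions[[report[[label]]]]
      true_mid <- positional_to_mid(dist)
      frm <- formulas[[label]]
      observed <- natural_abundance_convolve(true_mid, frm)
      for (r in seq_len(n_replicates)) {
        obs <- perturb_mid(observed, noise$mid_sigma)
        row <- tibble::tibble(condition = condition, metabolite = label,
                              fragment = sprintf("C%dH%dN%dO%dSi%d",
                                                 frm$C, frm$H, frm$N, frm$O,
                                                 frm$Si),
                              replicate = r, n_backbone = frm$backbone)
        for (k in 0:6) {
          row[[paste0("M+", k)]] <- if (k <= frm$backbone) obs[k + 1] else NA_real_
        }
        mid_rows[[length(mid_rows) + 1L]] <- row
      }
    }
    mid_tab <- do.call(rbind, mid_rows)

    # NMR: glutamate C4 and C2 multiplet areas.  Area scale: 1 area unit per
    # umol of 13C (internal standard defines the scale).  The enriched-peak
    # areas are pool x P(pattern class); the natural-abundance contribution
    # (1.07% of the pool) is added to the singlet, matching the 1H-based
    # subtraction applied downstream.
    nmr_rows <- list()
    glu <- sim$distributions$glutamate
    for (r in seq_len(n_replicates)) {
      for (pos in c(2L, 4L)) {
        mp <- predict_multiplets(glu, pos)
        fr <- if (mp$empty) c(singlet = 0) else mp$fractions
        for (peak in names(fr)) {
          area <- pool_umol * mp$observed_probability * fr[[peak]]
          if (peak == "singlet") area <- area + 0.0107 * pool_umol
          nmr_rows[[length(nmr_rows) + 1L]] <- tibble::tibble(
            condition = condition, metabolite = "glutamate", carbon = pos,
            multiplet = peak, replicate = r,
            area = perturb_area(area, noise$area_cv))
        }
      }
      nmr_rows[[length(nmr_rows) + 1L]] <- tibble::tibble(
        condition = condition, metabolite = "glutamate", carbon = 0L,
        multiplet = "pool_1h", replicate = r,
        area = perturb_area(pool_umol, noise$area_cv))
      nmr_rows[[length(nmr_rows) + 1L]] <- tibble::tibble(
        condition = condition, metabolite = "ethylene_glycol", carbon = 1L,
        multiplet = "standard", replicate = r, area = 1)
    }
    nmr_tab <- do.call(rbind, nmr_rows)

    # medium: linear change over the incubation from the configured rates
    med_rows <- list()
    for (analyte in setdiff(names(medium_rates), "lactate_labeled")) {
      rate <- medium_rates[[analyte]]
      c0 <- medium_t0[[analyte]] %||% 0
      c_end <- c0 + rate * (cell_count / 1e6) / volume_ml * (duration_h / 24)
      lab0 <- lab_end <- NA_real_
      if (analyte == "lactate" && !is.null(medium_rates$lactate_labeled)) {
        lab0 <- medium_t0$lactate_labeled %||% 0
        lab_end <- lab0 + medium_rates$lactate_labeled *
          (cell_count / 1e6) / volume_ml * (duration_h / 24)
      }
      for (r in seq_len(n_replicates)) {
        jitter <- function(x) {
          if (is.na(x) || noise$conc_sigma <= 0) x else
            max(x + stats::rnorm(1, 0, noise$conc_sigma), 0)
        }
        med_rows[[length(med_rows) + 1L]] <- tibble::tibble(
          condition = condition, analyte = analyte, replicate = r,
          conc_t0 = jitter(c0), conc_t_end = jitter(c_end),
          labeled_conc_t0 = jitter(lab0), labeled_conc_t_end = jitter(lab_end),
          volume_ml = volume_ml, cell_count = cell_count,
          duration_h = duration_h)
      }
    }
    medium_tab <- do.call(rbind, med_rows)

    manifest <- list(
      schema_version = "1",
      condition = condition,
      seed = noise$seed,
      n_replicates = n_replicates,
      params = unclass(params),
      tracers = lapply(tracers, unclass),
      noise = unclass(noise),
      medium_rates = medium_rates,
      medium_t0 = medium_t0,
      pool_umol = pool_umol,
      volume_ml = volume_ml, cell_count = cell_count, duration_h = duration_h)
    list(mid = mid_tab, nmr = nmr_tab, medium = medium_tab,
         manifest = manifest)
  })
}

#' The four reference incubation conditions
#'
#' Tracer and parameter setup emulating the study design: 2 mM
#' \[1,6-13C\]glucose; 2 mM \[1,2-13C\]glucose (+ 1 mM glutamine); 2 mM
#' \[1,2-13C\]acetate (+ 1 mM glutamine); 5 mM \[1-13C\]lactate + 2 mM
#' unlabeled glucose.
#'
#' @param params base `pathway_params` shared across conditions.
#' @return named list of condition specs (tracers, params, medium setup).
#' @export
reference_conditions <- function(params = default_oligo_params()) {
  list(
    glc16 = list(
      tracers = list(tracer_spec("glucose", c(1, 6))),
      params = params,
      medium_rates = list(glucose = -3.0, lactate = 3.6),
      medium_t0 = list(glucose = 2.0, lactate = 0)),
    glc12 = list(
      tracers = list(tracer_spec("glucose", c(1, 2))),
      params = params,
      medium_rates = list(glucose = -3.0, lactate = 3.6),
      medium_t0 = list(glucose = 2.0, lactate = 0)),
    ace12 = list(
      tracers = list(tracer_spec("acetate", c(1, 2), pool_fraction_labeled = 0.9)),
      params = update_params(params, f_acetyl_from_acetate = 0.5),
      medium_rates = list(glucose = 0, lactate = 0.5),
      medium_t0 = list(glucose = 0, lactate = 0)),
    lac1 = list(
      tracers = list(tracer_spec("lactate", 1, pool_fraction_labeled = 0.55),
                     tracer_spec("glucose", integer(0))),
      params = params,
      # lactate-supplemented design: glucose consumption doubles, total
      # lactate release is unchanged (30:70 partition), endogenous release
      # exceeds tracer-lactate uptake several-fold
      medium_rates = list(glucose = -6.0, lactate = 3.6,
                          lactate_labeled = -1.0),
      medium_t0 = list(glucose = 2.0, lactate = 0, lactate_labeled = 5.0)))
}

#' Default oligodendrocyte-style pathway parameters
#'
#' The generating truth used for the synthetic study conditions: PPP share
#' 0.10 of hexose-P, PC share 0.10 of the OAA pool, pyruvate recycling 0.05,
#' 10% unlabeled pyruvate dilution, 5% unlabeled acetyl dilution, glutamine
#' 50% diluted (glutamine labels slowest).
#'
#' @export
default_oligo_params <- function() {
  pathway_params(f_ppp = 0.10, f_pc = 0.10, f_recycle = 0.05,
                 f_pyr_unlabeled = 0.10, f_acetyl_from_acetate = 0,
                 f_acetyl_unlabeled = 0.05, f_gln_dilution = 0.5)
}

#' Generate the full fixture suite
#'
#' Writes one subdirectory per reference condition (mid.tsv, nmr.tsv,
#' medium.tsv, manifest.yml) plus an astrocyte-style medium-only dataset
#' built from the printed astrocyte rates (glucose consumption 3.2, lactate
#' release 5.3 umol/10^6 cells/24 h).
#'
#' @param network an `iso_network`.
#' @param params base `pathway_params`.
#' @param noise a [noise_model()]; per-condition seeds are derived from its
#'   seed.
#' @param out_dir output directory (created if needed).
#' @param n_replicates replicates per condition.
#' @return invisibly, the named list of generated condition objects.
#' @export
generate_fixture_suite <- function(network, params = default_oligo_params(),
                                   noise = noise_model(seed = 1),
                                   out_dir, n_replicates = 3L) {
  conds <- reference_conditions(params)
  out <- list()
  i <- 0L
  for (nm in names(conds)) {
    i <- i + 1L
    spec <- conds[[nm]]
    nz <- noise_model(noise$mid_sigma, noise$area_cv, noise$conc_sigma,
                      seed = noise$seed + 1000L * i)
    out[[nm]] <- generate_condition(network, spec$tracers, spec$params, nz,
                                    n_replicates = n_replicates,
                                    condition = nm,
                                    medium_rates = spec$medium_rates,
                                    medium_t0 = spec$medium_t0)
  }
  # astrocyte-style medium dataset from the printed astrocyte rates
  nz <- noise_model(noise$mid_sigma, noise$area_cv, noise$conc_sigma,
                    seed = noise$seed + 1000L * (i + 1L))
  astro_tracers <- list(tracer_spec("glucose", integer(0)))
  out$astro <- generate_condition(network, astro_tracers, params, nz,
                                  n_replicates = n_replicates,
                                  condition = "astro",
                                  medium_rates = list(glucose = -3.2,
                                                      lactate = 5.3),
                                  medium_t0 = list(glucose = 2.0, lactate = 0))
  if (!missing(out_dir) && !is.null(out_dir)) {
    for (nm in names(out)) {
      d <- file.path(out_dir, nm)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      readr::write_tsv(out[[nm]]$mid, file.path(d, "mid.tsv"))
      readr::write_tsv(out[[nm]]$nmr, file.path(d, "nmr.tsv"))
      readr::write_tsv(out[[nm]]$medium, file.path(d, "medium.tsv"))
      yaml::write_yaml(out[[nm]]$manifest, file.path(d, "manifest.yml"))
    }
  }
  invisible(out)
}
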