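# Config-driven pipeline over the simulator, measurement models and
# estimators: reproducible runs with schema validation, a structured text
# log and a config digest in every output.  Outputs are a pure function of
# config + seed (no timestamps), so identical runs are bit-identical.

mid_schema <- c("condition", "metabolite", "fragment", "replicate",
                "n_backbone", paste0("M+", 0:6))
nmr_schema <- c("condition", "metabolite", "carbon", "multiplet",
                "replicate", "area")
medium_schema <- c("condition", "analyte", "replicate", "conc_t0",
                   "conc_t_end", "labeled_conc_t0", "labeled_conc_t_end",
                   "volume_ml", "cell_count", "duration_h")

check_schema <- function(tab, schema, what) {
  missing <- setdiff(schema, names(tab))
  unknown <- setdiff(names(tab), schema)
  if (length(missing)) {
    stop(what, " table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (length(unknown)) {
    stop(what, " table has unknown column(s): ", paste(unknown, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(tab[, setdiff(schema, c(
    "labeled_conc_t0", "labeled_conc_t_end", paste0("M+", 0:6)))]))
  if (length(bad)) {
    stop(what, " table has incomplete row(s): ", paste(utils::head(bad, 5),
                                                       collapse = ", "))
  }
  invisible(tab)
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    digest <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else {
    tf <- tempfile(fileext = ".yml")
    on.exit(unlink(tf))
    yaml::write_yaml(config, tf)
    digest <- unname(tools::md5sum(tf))
  }
  if (is.null(config$seed)) stop("config field `seed` is required")
  config$digest <- digest
  config
}

config_tracers <- function(config) {
  lapply(config$tracers, function(tr) {
    tracer_spec(tr$substrate, unlist(tr$positions) %||% integer(0),
                tr$purity %||% 1, tr$pool_fraction %||% 1)
  })
}

config_params <- function(config) {
  do.call(pathway_params, config$params %||% list())
}

write_run_log <- function(out_dir, config, lines = character(0)) {
  log <- c(sprintf("config_digest: %s", config$digest),
           sprintf("seed: %d", as.integer(config$seed)),
           lines)
  writeLines(log, file.path(out_dir, "run_log.txt"))
}

#' Run a forward simulation from a config
#'
#' Config fields: `seed`, `out_dir`, `condition`, `params` (pathway
#' parameter fields), `tracers` (list of substrate/positions/purity/
#' pool_fraction blocks), `n_replicates`, `noise` (mid_sigma/area_cv/
#' conc_sigma), optional `medium_rates`/`medium_t0`.  Writes the positional
#' distribution table (metabolite, pattern bitstring, probability), the
#' observable tables and a run log echoing the parameters.
#'
#' @param config list or path to a YAML file.
#' @return invisibly, the generated condition object plus distributions.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  network <- build_default_network()
  params <- config_params(config)
  tracers <- config_tracers(config)
  if (!length(tracers)) stop("config field `tracers` is required")
  nz <- noise_model(config$noise$mid_sigma %||% 0,
                    config$noise$area_cv %||% 0,
                    config$noise$conc_sigma %||% 0,
                    seed = config$seed)
  out_dir <- config$out_dir %||% stop("config field `out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen_args <- list(network = network, tracers = tracers, params = params,
                   noise = nz, n_replicates = config$n_replicates %||% 3L,
                   condition = config$condition %||% "condition")
  if (!is.null(config$medium_rates)) gen_args$medium_rates <- config$medium_rates
  if (!is.null(config$medium_t0)) gen_args$medium_t0 <- config$medium_t0
  cond <- do.call(generate_condition, gen_args)
  sim <- simulate_labeling(network, tracers, params)
  dist_rows <- lapply(names(sim$distributions), function(m) {
    d <- sim$distributions[[m]]
    nz_idx <- which(d$probs > 0)
    tibble::tibble(metabolite = m,
                   pattern = vapply(nz_idx, pattern_bitstring,
                                    "", n_carbons = d$n_carbons),
                   probability = d$probs[nz_idx])
  })
  readr::write_tsv(do.call(rbind, dist_rows),
                   file.path(out_dir, "distributions.tsv"))
  readr::write_tsv(cond$mid, file.path(out_dir, "mid.tsv"))
  readr::write_tsv(cond$nmr, file.path(out_dir, "nmr.tsv"))
  readr::write_tsv(cond$medium, file.path(out_dir, "medium.tsv"))
  yaml::write_yaml(cond$manifest, file.path(out_dir, "manifest.yml"))
  write_run_log(out_dir, config,
                c(sprintf("n_turns: %d", sim$n_turns),
                  sprintf("residual: %.3g", sim$residual),
                  paste0("param ", names(unclass(params)), ": ",
                         vapply(unclass(params), format, ""))))
  invisible(c(cond, list(distributions = sim$distributions)))
}

# replicate-averaged corrected MID per metabolite from a mid table
corrected_mids_from_table <- function(mid_tab,
                                      formulas = default_fragment_formulas(),
                                      neg_tol = 1e-6) {
  out <- list()
  for (label in unique(mid_tab$metabolite)) {
    sub <- mid_tab[mid_tab$metabolite == label, ]
    nb <- sub$n_backbone[1]
    cols <- paste0("M+", 0:nb)
    observed <- colMeans(as.matrix(sub[, cols]))
    out[[label]] <- natural_abundance_correct(observed, formulas[[label]],
                                              neg_tol = neg_tol)
  }
  out
}

# assemble an nmr_peak_set for one carbon from a (replicate-averaged) table
peak_set_from_table <- function(nmr_tab, metabolite, carbon) {
  sub <- nmr_tab[nmr_tab$metabolite == metabolite & nmr_tab$carbon == carbon, ]
  if (!nrow(sub)) return(NULL)
  areas <- tapply(sub$area, sub$multiplet, mean)
  pool <- nmr_tab[nmr_tab$multiplet == "pool_1h" &
                    nmr_tab$metabolite == metabolite, ]
  std <- nmr_tab[nmr_tab$multiplet == "standard", ]
  nmr_peak_set(metabolite, carbon,
               stats::setNames(as.numeric(areas), names(areas)),
               internal_standard_area = if (nrow(std)) mean(std$area) else 1,
               internal_standard_13c_amount = 1,
               pool_total = if (nrow(pool)) mean(pool$area) else 0)
}

manifest_tracers <- function(manifest) {
  lapply(manifest$tracers, function(tr) {
    tracer_spec(tr$substrate, unlist(tr$labeled_positions) %||% integer(0),
                tr$isotopic_purity %||% 1, tr$pool_fraction_labeled %||% 1)
  })
}

#' Run the estimation pipeline on fixture tables
#'
#' Config fields: `seed`, `out_dir`, `fixture_dir` (directory with
#' condition subdirectories as written by [generate_fixture_suite()]),
#' `estimators` (non-empty subset of `ppp_mid`, `ppp_glu_c4`, `pc_citrate`,
#' `pc_glu_c2`, `recycling`, `medium_rates`, `partition`), optional
#' `noise_sigma` for evidence thresholds.  Writes an estimate table and a
#' human-readable summary.
#'
#' @param config list or path to a YAML file.
#' @return invisibly, the tibble of estimate reports.
#' @export
run_estimate <- function(config) {
  config <- read_run_config(config)
  if (!length(config$estimators)) stop("config field `estimators` must be non-empty")
  fixture_dir <- config$fixture_dir %||% stop("config field `fixture_dir` is required")
  out_dir <- config$out_dir %||% stop("config field `out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sigma <- config$noise_sigma %||% 0.005
  conds <- list.dirs(fixture_dir, recursive = FALSE)
  reports <- list(); summary_lines <- character(0); warn_lines <- character(0)
  for (d in conds) {
    nm <- basename(d)
    mid_tab <- if (file.exists(file.path(d, "mid.tsv"))) {
      check_schema(readr::read_tsv(file.path(d, "mid.tsv"),
                                   show_col_types = FALSE), mid_schema, "MID")
    } else NULL
    nmr_tab <- if (file.exists(file.path(d, "nmr.tsv"))) {
      check_schema(readr::read_tsv(file.path(d, "nmr.tsv"),
                                   show_col_types = FALSE), nmr_schema, "NMR")
    } else NULL
    med_tab <- if (file.exists(file.path(d, "medium.tsv"))) {
      check_schema(readr::read_tsv(file.path(d, "medium.tsv"),
                                   show_col_types = FALSE), medium_schema,
                   "medium")
    } else NULL
    manifest <- if (file.exists(file.path(d, "manifest.yml"))) {
      yaml::read_yaml(file.path(d, "manifest.yml"))
    } else NULL
    tracers <- if (!is.null(manifest)) manifest_tracers(manifest) else NULL
    mids <- if (!is.null(mid_tab)) {
      # noisy zero channels can correct slightly negative; scale the
      # data-quality threshold to the stated replicate-mean noise
      corrected_mids_from_table(mid_tab, neg_tol = 1e-6 + 3 * sigma)
    } else list()
    add <- function(tb) {
      tb$condition <- nm
      reports[[length(reports) + 1L]] <<- tb
      for (i in seq_len(nrow(tb))) {
        summary_lines <<- c(summary_lines, sprintf(
          "%s  %-28s %10.4f  [%s]%s", nm, tb$quantity[i], tb$value[i],
          tb$method[i], ifelse(is.na(tb$flag[i]), "",
                               paste0(" ", tb$flag[i]))))
        if (tb$value[i] < 0 || (grepl("pct", tb$quantity[i]) &&
                                tb$value[i] > 100)) {
          warn_lines <<- c(warn_lines, sprintf(
            "warning: %s %s out of range (%.4f)", nm, tb$quantity[i],
            tb$value[i]))
        }
      }
    }
    # estimators tied to a tracer design only run on matching conditions
    is_glc12 <- !is.null(tracers) && {
      tr <- find_tracer(tracers, "hexose")
      !is.null(tr) && identical(tr$labeled_positions, c(1L, 2L))
    }
    has_lactate_tracer <- !is.null(tracers) && !is.null(find_tracer(tracers, "lactate"))
    for (est in config$estimators) {
      switch(est,
        ppp_mid = if (is_glc12 && !is.null(mids$pep))
          add(ppp_fraction_from_mid(mids$pep)),
        ppp_glu_c4 = if (is_glc12) {
          ps <- if (!is.null(nmr_tab)) peak_set_from_table(nmr_tab, "glutamate", 4L)
          if (!is.null(ps) && "d5" %in% names(ps$areas) && ps$areas[["d5"]] > 0)
            add(ppp_fraction_from_glutamate_c4(ps))
        },
        pc_citrate = if (has_lactate_tracer && !is.null(mids$citrate))
          add(pc_evidence_from_lactate_tracer(mids$citrate, sigma)),
        pc_glu_c2 = if (is_glc12) {
          ps <- if (!is.null(nmr_tab)) peak_set_from_table(nmr_tab, "glutamate", 2L)
          if (!is.null(ps) && all(c("d1", "d3") %in% names(ps$areas)) &&
              sum(ps$areas[c("d1", "d3")]) > 0)
            add(pc_evidence_from_glutamate_c2(ps))
        },
        recycling = {
          tr <- if (!is.null(tracers)) {
            find_tracer(tracers, "acetate") %||% find_tracer(tracers, "hexose")
          }
          if (!is.null(mids$alanine) && !is.null(tr) &&
              (tr$substrate == "acetate" ||
                 identical(tr$labeled_positions, c(1L, 2L))))
            add(recycling_index(mids$alanine, tr))
        },
        medium_rates = if (!is.null(med_tab)) {
          for (an in unique(med_tab$analyte)) {
            sub <- med_tab[med_tab$analyte == an, ]
            mm <- medium_measurement(an, mean(sub$conc_t0), mean(sub$conc_t_end),
                                     sub$volume_ml[1], sub$cell_count[1],
                                     sub$duration_h[1],
                                     mean(sub$labeled_conc_t0),
                                     mean(sub$labeled_conc_t_end))
            add(medium_rate(mm))
          }
        },
        partition = if (!is.null(med_tab) &&
                        all(c("glucose", "lactate") %in% med_tab$analyte)) {
          rate_of <- function(an) {
            sub <- med_tab[med_tab$analyte == an, ]
            (mean(sub$conc_t_end) - mean(sub$conc_t0)) * sub$volume_ml[1] /
              (sub$cell_count[1] / 1e6) * (24 / sub$duration_h[1])
          }
          glc <- -rate_of("glucose"); lac <- rate_of("lactate")
          if (glc > 0 && lac >= 0) {
            part <- lactate_oxidation_partition(glc, lac)
            add(estimate_report("lactate_pct", part$lactate_pct,
                                "lac/(2*glc)",
                                paste0("display ratio ", part$display_ratio)))
            warn_lines <- c(warn_lines, part$warnings)
          }
        },
        stop("unknown estimator: ", est))
    }
  }
  if (!length(reports)) stop("no estimates produced; check estimator/fixture match")
  report_tab <- do.call(rbind, reports)
  readr::write_tsv(report_tab, file.path(out_dir, "estimates.tsv"))
  writeLines(c("estimate summary", summary_lines,
               if (length(warn_lines)) c("", warn_lines)),
             file.path(out_dir, "summary.txt"))
  write_run_log(out_dir, config,
                c(sprintf("estimators: %s",
                          paste(config$estimators, collapse = ",")),
                  warn_lines))
  invisible(report_tab)
}

#' Fit pathway parameters from fixture tables
#'
#' Config fields: `seed` (required), `out_dir`, `fixture_dir`, `free`
#' (parameter names), optional `conditions` (subset of condition directory
#' names), `n_starts`, `params` (fixed-parameter overrides), `multiplets`
#' (logical: include glutamate C2/C4 multiplet fractions; default TRUE).
#'
#' @param config list or path to a YAML file.
#' @return invisibly, the [fit_params()] result.
#' @export
run_fit <- function(config) {
  config <- read_run_config(config)
  fixture_dir <- config$fixture_dir %||% stop("config field `fixture_dir` is required")
  out_dir <- config$out_dir %||% stop("config field `out_dir` is required")
  free <- unlist(config$free) %||% stop("config field `free` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  network <- build_default_network()
  base <- config_params(config)
  use_mult <- config$multiplets %||% TRUE
  dirs <- list.dirs(fixture_dir, recursive = FALSE)
  if (!is.null(config$conditions)) {
    dirs <- dirs[basename(dirs) %in% config$conditions]
  }
  conditions <- list()
  for (d in dirs) {
    if (!file.exists(file.path(d, "manifest.yml"))) next
    manifest <- yaml::read_yaml(file.path(d, "manifest.yml"))
    mid_tab <- check_schema(readr::read_tsv(file.path(d, "mid.tsv"),
                                            show_col_types = FALSE),
                            mid_schema, "MID")
    mids <- corrected_mids_from_table(
      mid_tab, neg_tol = 1e-6 + 3 * (config$noise_sigma %||% 0.005))
    names(mids)[names(mids) == "pep"] <- "triose"
    mids <- mids[names(mids) %in% c("triose", "lactate", "alanine", "citrate",
                                    "malate", "aspartate", "glutamate")]
    cond <- list(tracers = manifest_tracers(manifest), mids = mids)
    if (use_mult && file.exists(file.path(d, "nmr.tsv"))) {
      nmr_tab <- readr::read_tsv(file.path(d, "nmr.tsv"), show_col_types = FALSE)
      mult <- list()
      for (pos in c(2L, 4L)) {
        ps <- peak_set_from_table(nmr_tab, "glutamate", pos)
        if (is.null(ps)) next
        areas <- ps$areas[setdiff(names(ps$areas), "pool_1h")]
        if ("singlet" %in% names(areas)) {
          areas[["singlet"]] <- max(areas[["singlet"]] -
                                      0.0107 * ps$pool_total, 0)
        }
        if (sum(areas) > 0) {
          mult[[paste0("glutamate_c", pos)]] <- areas / sum(areas)
        }
      }
      if (length(mult)) cond$multiplets <- mult
    }
    conditions[[basename(d)]] <- cond
  }
  if (!length(conditions)) stop("no usable conditions under ", fixture_dir)
  fit <- fit_params(network, conditions, free = free, base_params = base,
                    n_starts = config$n_starts %||% 16L, seed = config$seed)
  readr::write_tsv(fit$starts, file.path(out_dir, "fit_starts.tsv"))
  est_tab <- tibble::tibble(parameter = names(fit$estimate),
                            estimate = as.numeric(fit$estimate))
  readr::write_tsv(est_tab, file.path(out_dir, "fit_estimates.tsv"))
  write_run_log(out_dir, config,
                c(sprintf("residual: %.6g", fit$residual),
                  sprintf("fitted %s: %.4f", names(fit$estimate),
                          fit$estimate)))
  invisible(fit)
}
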