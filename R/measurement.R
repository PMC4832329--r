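# Measurement models: GC-MS mass isotopologue distributions with
# natural-abundance effects (Biemann-style correction matrix) and 13C-NMR
# multiplet fractions with internal-standard quantification.

#' Collapse a positional distribution to a mass isotopologue distribution
#'
#' `fractions[k+1]` is the total probability of patterns with exactly k
#' labeled carbons (M+0 .. M+n).
#'
#' @param dist a `pid`.
#' @return numeric vector of length `n_carbons + 1`, names `M+0` ...
#' @export
positional_to_mid <- function(dist) {
  stopifnot(inherits(dist, "pid"))
  w <- pattern_weights(dist$n_carbons)
  mid <- vapply(0:dist$n_carbons, function(k) sum(dist$probs[w == k]), 0)
  names(mid) <- paste0("M+", 0:dist$n_carbons)
  mid
}

#' Predict 13C-NMR multiplet fractions at one carbon position
#'
#' Conditional on the observed carbon being 13C, returns the fractions of
#' molecules with neither adjacent carbon labeled (singlet), exactly one
#' labeled neighbor (one doublet per coupling partner) or both labeled
#' (doublet of doublets).  Only adjacent one-bond couplings are considered.
#'
#' @param dist a `pid`.
#' @param carbon_position 1-based observed carbon.
#' @return list with `observed_probability` (labeling probability of the
#'   observed carbon) and `fractions` (named numeric: `singlet`,
#'   `d<neighbor>` entries, `dd`); `fractions` is empty with `empty = TRUE`
#'   when the observed carbon is never labeled.
#' @export
predict_multiplets <- function(dist, carbon_position) {
  stopifnot(inherits(dist, "pid"))
  n <- dist$n_carbons
  if (carbon_position < 1 || carbon_position > n) stop("carbon position out of range")
  neighbors <- intersect(c(carbon_position - 1L, carbon_position + 1L), seq_len(n))
  idx <- 0:(2L^n - 1L)
  obs_bit <- bitwAnd(bitwShiftR(idx, carbon_position - 1L), 1L) == 1L
  p_obs <- sum(dist$probs[obs_bit])
  if (p_obs <= 0) {
    return(list(observed_probability = 0, fractions = numeric(0), empty = TRUE))
  }
  nb_lab <- vapply(neighbors, function(nb) {
    bitwAnd(bitwShiftR(idx, nb - 1L), 1L) == 1L
  }, logical(length(idx)))
  nb_lab <- matrix(nb_lab, ncol = length(neighbors))
  n_nb <- rowSums(nb_lab)
  fr <- c(singlet = sum(dist$probs[obs_bit & n_nb == 0]) / p_obs)
  for (j in seq_along(neighbors)) {
    only_j <- obs_bit & nb_lab[, j] & n_nb == 1
    fr[paste0("d", neighbors[j])] <- sum(dist$probs[only_j]) / p_obs
  }
  if (length(neighbors) == 2) {
    fr["dd"] <- sum(dist$probs[obs_bit & n_nb == 2]) / p_obs
  }
  list(observed_probability = p_obs, fractions = fr, empty = FALSE)
}

#' Elemental fragment formula of a derivatized GC-MS fragment
#'
#' @param C,H,N,O,Si element counts of the detected fragment.
#' @param backbone number of metabolite backbone carbons within the fragment
#'   (must not exceed `C`).
#' @export
fragment_formula <- function(C, H = 0, N = 0, O = 0, Si = 0, backbone = C) {
  if (backbone > C) stop("backbone carbons cannot exceed total carbon count")
  structure(list(C = as.integer(C), H = as.integer(H), N = as.integer(N),
                 O = as.integer(O), Si = as.integer(Si),
                 backbone = as.integer(backbone)),
            class = "fragment_formula")
}

#' Default heavy-isotope abundance table
#'
#' Per-element probabilities of +1 and +2 mass shifts per atom.  13C is
#' 1.07% by default (configurable).
#'
#' @param c13 13C natural abundance.
#' @export
natural_abundance_table <- function(c13 = 0.0107) {
  list(C = c(1 - c13, c13),
       H = c(1 - 0.000115, 0.000115),
       N = c(1 - 0.00364, 0.00364),
       O = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
       Si = c(1 - 0.04685 - 0.03092, 0.04685, 0.03092))
}

# mass-shift pmf of n atoms of one element (polynomial power by convolution)
element_shift_pmf <- function(pmf, n) {
  out <- 1
  for (i in seq_len(n)) {
    res <- numeric(length(out) + length(pmf) - 1L)
    for (k in seq_along(pmf)) {
      res[k:(k + length(out) - 1L)] <- res[k:(k + length(out) - 1L)] + pmf[k] * out
    }
    out <- res
  }
  out
}

# natural-isotope mass-shift spectrum of a whole fragment formula
formula_shift_pmf <- function(formula, abundance = natural_abundance_table()) {
  for (el in names(abundance)) {
    if (any(abundance[[el]] < 0)) stop("negative abundance for ", el)
  }
  pmf <- 1
  counts <- c(C = formula$C, H = formula$H, N = formula$N, O = formula$O,
              Si = formula$Si)
  for (el in names(counts)) {
    if (counts[[el]] > 0) {
      e <- element_shift_pmf(abundance[[el]], counts[[el]])
      res <- numeric(length(pmf) + length(e) - 1L)
      for (k in seq_along(e)) {
        res[k:(k + length(pmf) - 1L)] <- res[k:(k + length(pmf) - 1L)] + e[k] * pmf
      }
      pmf <- res
    }
  }
  pmf
}

# Biemann-style correction matrix: column k (enrichment M+k) is the
# natural-isotope spectrum of the fragment shifted by k mass units,
# truncated to the observation window.
correction_matrix <- function(n_backbone, formula = NULL,
                              standard_mid = NULL,
                              abundance = natural_abundance_table(),
                              extra_channels = 0L) {
  nch <- n_backbone + 1L + extra_channels
  if (!is.null(standard_mid)) {
    base <- standard_mid
  } else {
    if (is.null(formula)) stop("supply a fragment formula or an unenriched-standard MID")
    base <- formula_shift_pmf(formula, abundance)
  }
  A <- matrix(0, nch, n_backbone + 1L)
  for (k in 0:n_backbone) {
    seg <- base[seq_len(min(length(base), nch - k))]
    A[(k + 1L):(k + length(seg)), k + 1L] <- seg
  }
  A
}

#' Forward natural-abundance convolution of a backbone MID
#'
#' Convolves the enrichment-only (backbone) MID with the natural
#' heavy-isotope spectrum of the derivatized fragment, then renormalizes
#' over the observation window M+0 .. M+n_backbone (+ `extra_channels`).
#'
#' @param mid numeric backbone MID (M+0 .. M+n_backbone).
#' @param formula a [fragment_formula()].
#' @param abundance abundance table (see [natural_abundance_table()]).
#' @param extra_channels additional mass channels retained beyond
#'   M+n_backbone (default 0).
#' @return observed MID over the retained channels (sums to 1).
#' @export
natural_abundance_convolve <- function(mid, formula,
                                       abundance = natural_abundance_table(),
                                       extra_channels = 0L) {
  n <- length(mid) - 1L
  if (n != formula$backbone) {
    stop("MID length does not match fragment backbone carbon count")
  }
  A <- correction_matrix(n, formula, abundance = abundance,
                         extra_channels = extra_channels)
  obs <- as.vector(A %*% mid)
  obs <- obs / sum(obs)
  names(obs) <- paste0("M+", 0:(length(obs) - 1L))
  obs
}

#' Correct an observed MID for natural isotope abundance
#'
#' Solves the lower-triangular convolution system for the enrichment-only
#' MID, using either a theoretical correction matrix built from the fragment
#' formula or an empirical matrix built from a measured unenriched-standard
#' spectrum.  Small negative components (> -1e-6 after normalization) are
#' clipped to zero; larger negative mass raises an error.
#'
#' @param observed_mid observed fractions over M+0 .. (at least M+n_backbone).
#' @param formula a [fragment_formula()] (theoretical route), or NULL.
#' @param standard_mid measured MID of an unenriched standard (empirical
#'   route), or NULL.  Exactly one of `formula`/`standard_mid` is required.
#' @param n_backbone number of backbone carbons; defaults to
#'   `formula$backbone` or `length(observed_mid) - 1`.
#' @param abundance abundance table for the theoretical route.
#' @param neg_tol negativity tolerance: components above `-neg_tol` are
#'   clipped to zero, anything below is a data-quality error.  The default
#'   1e-6 suits noise-free data; scale it to the measurement noise
#'   (e.g. `3 * sigma`) for replicate-averaged noisy spectra, where
#'   zero-abundance channels legitimately come out slightly negative.
#' @return corrected MID (M+0 .. M+n_backbone, sums to 1).
#' @export
natural_abundance_correct <- function(observed_mid, formula = NULL,
                                      standard_mid = NULL, n_backbone = NULL,
                                      abundance = natural_abundance_table(),
                                      neg_tol = 1e-6) {
  if (is.null(formula) && is.null(standard_mid)) {
    stop("supply a fragment formula or an unenriched-standard MID")
  }
  if (is.null(n_backbone)) {
    n_backbone <- if (!is.null(formula)) formula$backbone else
      length(observed_mid) - 1L
  }
  nch <- length(observed_mid)
  A <- correction_matrix(n_backbone, formula, standard_mid, abundance,
                         extra_channels = nch - n_backbone - 1L)
  fit <- stats::lsfit(A, observed_mid, intercept = FALSE)
  x <- unname(fit$coefficients)
  x <- x / sum(x)
  if (any(x < -neg_tol)) {
    stop(sprintf(
      "natural-abundance correction produced negative mass (min %.3g); check inputs",
      min(x)))
  }
  x <- pmax(x, 0)
  x <- x / sum(x)
  names(x) <- paste0("M+", 0:n_backbone)
  x
}

#' Percent enrichment per isotopologue
#'
#' @param corrected_mid natural-abundance-corrected MID.
#' @return named vector, 100 x fractions for M+1 .. M+n.
#' @export
percent_excess <- function(corrected_mid) {
  out <- 100 * corrected_mid[-1]
  names(out) <- paste0("M+", seq_along(out))
  out
}

#' NMR peak set
#'
#' Singlet/doublet areas for one carbon position plus the internal-standard
#' and 1H-derived pool quantities needed for quantification and
#' natural-abundance correction.
#'
#' @param metabolite metabolite name.
#' @param carbon_position observed carbon.
#' @param areas named numeric: `singlet`, `d<k>` per coupling partner k,
#'   optionally `dd` (arbitrary units, >= 0).
#' @param internal_standard_area integral of the internal standard peak.
#' @param internal_standard_13c_amount micromol of 13C in the internal
#'   standard (ethylene glycol in the reference protocol).
#' @param pool_total micromol of the total metabolite pool from 1H NMR.
#' @param correction_factors per-peak multiplicative factors for NOE and
#'   relaxation effects (default 1 for all peaks).
#' @export
nmr_peak_set <- function(metabolite, carbon_position, areas,
                         internal_standard_area = 1,
                         internal_standard_13c_amount = 1,
                         pool_total = 0, correction_factors = NULL) {
  if (any(areas < 0)) stop("peak areas must be non-negative")
  if (is.null(correction_factors)) {
    correction_factors <- stats::setNames(rep(1, length(areas)), names(areas))
  }
  structure(list(metabolite = metabolite,
                 carbon_position = as.integer(carbon_position),
                 areas = areas,
                 internal_standard_area = internal_standard_area,
                 internal_standard_13c_amount = internal_standard_13c_amount,
                 pool_total = pool_total,
                 correction_factors = correction_factors),
            class = "nmr_peak_set")
}

#' Quantify one NMR peak against the internal standard
#'
#' amount = area / standard area x standard 13C amount x correction factor.
#'
#' @param peak_area integral of the peak.
#' @param peak_set an [nmr_peak_set()].
#' @param correction_factor per-peak NOE/relaxation factor (default 1).
#' @return micromol of 13C-labeled carbon in the peak.
#' @export
quantify_nmr_peak <- function(peak_area, peak_set, correction_factor = 1) {
  if (peak_set$internal_standard_area <= 0) {
    stop("internal standard area must be > 0")
  }
  peak_area / peak_set$internal_standard_area *
    peak_set$internal_standard_13c_amount * correction_factor
}

#' Correct a singlet amount for natural 13C abundance via the 1H pool
#'
#' Subtracts the natural-abundance contribution (1.07% of the total pool,
#' quantified by 1H NMR) from the singlet amount; floors at zero with a
#' warning if the subtraction goes negative.
#'
#' @param singlet_amount quantified singlet amount (micromol).
#' @param pool_total total metabolite pool from 1H NMR (micromol).
#' @param c13 natural 13C abundance (default 0.0107).
#' @export
correct_singlet_for_natural_abundance <- function(singlet_amount, pool_total,
                                                  c13 = 0.0107) {
  if (pool_total < 0) stop("pool_total must be >= 0")
  out <- singlet_amount - c13 * pool_total
  if (out < 0) {
    warning("natural-abundance correction exceeds singlet amount; floored at 0")
    out <- 0
  }
  out
}
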