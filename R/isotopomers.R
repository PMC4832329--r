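#' @keywords internal
"_PACKAGE"

# A positional isotopomer distribution ("pid") is a probability vector over
# all 2^n labeling patterns of an n-carbon metabolite.  Pattern index i
# (1-based) encodes the bit pattern i-1, where bit (c-1) set means carbon c
# carries 13C.  Index 1 is therefore the fully unlabeled species.

#' Create a positional isotopomer distribution
#'
#' @param metabolite metabolite name.
#' @param n_carbons number of backbone carbons (1-7).
#' @param probs numeric vector of length `2^n_carbons`; non-negative, summing
#'   to 1 within `1e-9`.  Defaults to the fully unlabeled distribution.
#' @return an object of class `pid`: a list with fields `metabolite`,
#'   `n_carbons` and `probs`.
#' @examples
#' pid_pure("pyruvate", 3, c(2, 3))  # [2,3-13C]pyruvate
#' @export
pid <- function(metabolite, n_carbons, probs = NULL) {
  stopifnot(is.character(metabolite), length(metabolite) == 1L)
  if (n_carbons < 1 || n_carbons > 7) {
    stop("n_carbons must be between 1 and 7, got ", n_carbons)
  }
  m <- 2L^n_carbons
  if (is.null(probs)) {
    probs <- c(1, rep(0, m - 1L))
  }
  if (length(probs) != m) {
    stop("probs must have length 2^n_carbons = ", m, " for ", metabolite,
         ", got ", length(probs))
  }
  if (any(probs < -1e-12)) stop("probs must be non-negative")
  s <- sum(probs)
  if (abs(s - 1) > 1e-9) stop("probs must sum to 1 (got ", format(s), ")")
  structure(list(metabolite = metabolite, n_carbons = as.integer(n_carbons),
                 probs = pmax(probs, 0)),
            class = "pid")
}

#' Pure positional isotopomer
#'
#' Distribution placing all mass on one labeling pattern, e.g.
#' `pid_pure("glutamate", 5, c(4, 5))` is \[4,5-13C\]glutamate.
#'
#' @inheritParams pid
#' @param positions 1-based carbon indices carrying 13C (may be empty).
#' @export
pid_pure <- function(metabolite, n_carbons, positions = integer(0)) {
  if (length(positions) && (any(positions < 1) || any(positions > n_carbons))) {
    stop("labeled positions out of range for ", metabolite)
  }
  probs <- rep(0, 2L^n_carbons)
  probs[pattern_index(positions)] <- 1
  pid(metabolite, n_carbons, probs)
}

#' Fully unlabeled distribution
#' @inheritParams pid
#' @export
pid_unlabeled <- function(metabolite, n_carbons) {
  pid_pure(metabolite, n_carbons)
}

# 1-based vector index of the pattern labeling exactly `positions`
pattern_index <- function(positions) {
  as.integer(sum(2^(as.integer(positions) - 1L)) + 1L)
}

# carbon positions labeled in 1-based pattern index i
pattern_positions <- function(i, n_carbons) {
  bits <- bitwAnd(bitwShiftR(i - 1L, 0:(n_carbons - 1L)), 1L)
  which(bits == 1L)
}

# number of 13C atoms for each pattern index 1..2^n
pattern_weights <- function(n_carbons) {
  idx <- 0:(2L^n_carbons - 1L)
  w <- integer(length(idx))
  for (b in 0:(n_carbons - 1L)) {
    w <- w + bitwAnd(bitwShiftR(idx, b), 1L)
  }
  w
}

#' Mix positional distributions
#'
#' Convex combination of distributions over the same metabolite.
#'
#' @param dists list of `pid` objects with identical metabolite/carbon count.
#' @param weights non-negative weights; normalized internally.
#' @export
pid_mix <- function(dists, weights) {
  stopifnot(length(dists) == length(weights), length(dists) >= 1)
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("mixture weights sum to zero")
  n <- dists[[1]]$n_carbons
  for (d in dists) {
    if (d$n_carbons != n) stop("cannot mix distributions of different sizes")
  }
  probs <- rep(0, 2L^n)
  for (k in seq_along(dists)) {
    probs <- probs + weights[k] / tot * dists[[k]]$probs
  }
  pid(dists[[1]]$metabolite, n, probs / sum(probs))
}

#' Fraction of molecules carrying at least one 13C
#' @param dist a `pid`.
#' @export
labeled_fraction <- function(dist) {
  stopifnot(inherits(dist, "pid"))
  1 - dist$probs[1]
}

#' Expected number of 13C atoms per molecule
#' @param dist a `pid`.
#' @export
expected_label_count <- function(dist) {
  stopifnot(inherits(dist, "pid"))
  sum(dist$probs * pattern_weights(dist$n_carbons))
}

# L1 distance between two probability vectors / pids
pid_l1 <- function(a, b) {
  pa <- if (inherits(a, "pid")) a$probs else a
  pb <- if (inherits(b, "pid")) b$probs else b
  sum(abs(pa - pb))
}

#' @export
print.pid <- function(x, digits = 4, ...) {
  cat(sprintf("<pid> %s (%d carbons)\n", x$metabolite, x$n_carbons))
  nz <- which(x$probs > 1e-12)
  for (i in nz) {
    pos <- pattern_positions(i, x$n_carbons)
    lab <- if (length(pos)) paste0("[", paste(pos, collapse = ","), "-13C]") else "unlabeled"
    cat(sprintf("  %-14s %.*f\n", lab, digits, x$probs[i]))
  }
  invisible(x)
}

#' Format a labeling pattern as a bitstring (carbon 1 first)
#' @param i 1-based pattern index.
#' @param n_carbons number of carbons.
#' @export
pattern_bitstring <- function(i, n_carbons) {
  bits <- bitwAnd(bitwShiftR(i - 1L, 0:(n_carbons - 1L)), 1L)
  paste(bits, collapse = "")
}

#' Tracer specification
#'
#' Describes one 13C-labeled substrate in the incubation medium, e.g.
#' 2 mM \[1,2-13C\]glucose: `tracer_spec("hexose", c(1, 2))`.
#'
#' @param substrate metabolite name in the network ("glucose" is accepted as
#'   an alias for the hexose phosphate pool).
#' @param labeled_positions 1-based carbon indices labeled in the tracer.
#' @param isotopic_purity probability that a nominally labeled position
#'   actually carries 13C (default 1).
#' @param pool_fraction_labeled fraction of that substrate pool supplied by
#'   the tracer (default 1); the remainder is unlabeled.
#' @return object of class `tracer_spec`.
#' @export
tracer_spec <- function(substrate, labeled_positions,
                        isotopic_purity = 1, pool_fraction_labeled = 1) {
  substrate <- switch(substrate, glucose = "hexose", lactate = "lactate",
                      acetate = "acetate", substrate)
  if (isotopic_purity < 0 || isotopic_purity > 1) {
    stop("isotopic_purity must be in [0,1]")
  }
  if (pool_fraction_labeled < 0 || pool_fraction_labeled > 1) {
    stop("pool_fraction_labeled must be in [0,1]")
  }
  structure(list(substrate = substrate,
                 labeled_positions = sort(as.integer(labeled_positions)),
                 isotopic_purity = isotopic_purity,
                 pool_fraction_labeled = pool_fraction_labeled),
            class = "tracer_spec")
}

# Positional distribution of a tracer-fed pool: the tracer molecules carry
# 13C at each nominal position independently with prob = purity, and make up
# pool_fraction_labeled of the pool.
tracer_pid <- function(tracer, metabolite, n_carbons) {
  if (any(tracer$labeled_positions > n_carbons)) {
    stop("tracer positions exceed carbon count of ", metabolite)
  }
  probs <- rep(0, 2L^n_carbons)
  pos <- tracer$labeled_positions
  pur <- tracer$isotopic_purity
  if (!length(pos)) {
    probs[1] <- 1
  } else {
    # enumerate subsets of the nominal positions actually labeled
    for (s in 0:(2L^length(pos) - 1L)) {
      inset <- bitwAnd(bitwShiftR(s, 0:(length(pos) - 1L)), 1L) == 1L
      p <- prod(ifelse(inset, pur, 1 - pur))
      probs[pattern_index(pos[inset])] <- probs[pattern_index(pos[inset])] + p
    }
  }
  f <- tracer$pool_fraction_labeled
  probs <- f * probs
  probs[1] <- probs[1] + (1 - f)
  pid(metabolite, n_carbons, probs)
}
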