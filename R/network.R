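# Atom-mapped reaction network of central carbon metabolism.
#
# Carbon numbering conventions (chosen so that the named isotopomers of the
# classic tracer literature come out verbatim):
#   - pyruvate/lactate/alanine: C1 = carboxyl.  Hexose C1,C2,C3 map to one
#     triose's carbons 3,2,1 and C4,C5,C6 to the other's 1,2,3.
#   - acetyl CoA: C1 = carboxyl (-> citrate C1), C2 = methyl (-> citrate C2).
#   - citrate: C1,C2 from acetyl CoA C1,C2; C3,C4,C5 from OAA C2,C3,C4;
#     C6 from OAA C1 (lost as CO2 at the alpha-ketoglutarate step, so
#     [1-13C]OAA yields [6-13C]citrate and then unlabeled alpha-KG).
#   - alpha-KG/glutamate: C4,C5 from acetyl CoA C2,C1 on the first turn;
#     C1,C2,C3 from OAA C4,C3,C2.
#   - succinate/fumarate: one symmetric 4-carbon species (2-fold rotational
#     symmetry applied on formation).
#   - OAA via pyruvate carboxylase: pyruvate C1-C3 preserved, C4 fixed CO2.

CO2_FIXED <- c(0L, 0L)

#' Construct an atom-mapped reaction
#'
#' @param name reaction identifier.
#' @param substrates character vector of substrate metabolite names (slots).
#' @param products character vector of product metabolite names (slots).
#' @param carbon_map list, one element per product slot: a list with one
#'   entry per product carbon, each either `c(substrate_slot, substrate_carbon)`
#'   or the token `"CO2_FIXED"` (carbon fixed from the unlabeled CO2 pool).
#' @param co2_losses matrix with columns `slot`, `carbon`: substrate carbons
#'   emitted as CO2 (may be NULL).
#' @param symmetric_product integer indices of product slots with two-fold
#'   rotational symmetry (a 50/50 mix of the two orientations is applied).
#' @return object of class `iso_reaction`.
#' @export
reaction <- function(name, substrates, products, carbon_map,
                     co2_losses = NULL, symmetric_product = integer(0)) {
  stopifnot(length(carbon_map) == length(products))
  cm <- lapply(carbon_map, function(prod) {
    lapply(prod, function(src) {
      if (identical(src, "CO2_FIXED")) CO2_FIXED else as.integer(src)
    })
  })
  if (!is.null(co2_losses)) {
    co2_losses <- matrix(as.integer(co2_losses), ncol = 2,
                         dimnames = list(NULL, c("slot", "carbon")))
  }
  structure(list(name = name, substrates = substrates, products = products,
                 carbon_map = cm, co2_losses = co2_losses,
                 symmetric_product = as.integer(symmetric_product)),
            class = "iso_reaction")
}

# permutation of pattern indices under 2-fold rotation (carbon i <-> n+1-i)
reverse_perm <- function(n) {
  idx <- 0:(2L^n - 1L)
  out <- integer(length(idx))
  for (b in 0:(n - 1L)) {
    out <- out + bitwShiftL(bitwAnd(bitwShiftR(idx, b), 1L), n - 1L - b)
  }
  out + 1L
}

#' Build the default central-carbon network
#'
#' Glycolysis (hexose -> 2 trioses -> pyruvate), the oxidative PPP
#' (hexose -> pentose-P + CO2 from C1), one full transketolase/transaldolase
#' pass of the non-oxidative PPP (3 pentose-P -> 2 hexose-P + 1 triose-P),
#' PDH, pyruvate carboxylase, citrate synthase, the oxidative TCA span
#' citrate -> alpha-KG -> succinate (symmetric) -> malate -> OAA, malic
#' enzyme, and the transamination/exchange identities (glutamate, glutamine,
#' aspartate, lactate, alanine, acetate -> acetyl CoA).
#'
#' @return object of class `iso_network` with fields `metabolites` (named
#'   integer vector of carbon counts) and `reactions` (named list).
#' @export
build_default_network <- function() {
  metabolites <- c(hexose = 6L, pentose = 5L, s7p = 7L, e4p = 4L,
                   triose = 3L, pyruvate = 3L, lactate = 3L, alanine = 3L,
                   acetyl_coa = 2L, acetate = 2L, citrate = 6L, akg = 5L,
                   glutamate = 5L, glutamine = 5L, succinate = 4L,
                   malate = 4L, oaa = 4L, aspartate = 4L)
  src <- function(slot, carbons) lapply(carbons, function(k) c(slot, k))
  identity_map <- function(n, slot = 1L) src(slot, seq_len(n))

  rxns <- list(
    # hexose C1,C2,C3 -> triose(A) carbons 3,2,1; C4,C5,C6 -> triose(B) 1,2,3
    reaction("glycolysis_cleavage", "hexose", c("triose", "triose"),
             list(src(1L, c(3L, 2L, 1L)), src(1L, c(4L, 5L, 6L)))),
    # oxidative PPP: C1 lost as CO2; pentose 1..5 <- hexose 2..6
    reaction("ppp_oxidative", "hexose", "pentose",
             list(src(1L, 2:6)), co2_losses = cbind(1L, 1L)),
    # transketolase 1: X5P + R5P -> S7P + GA3P
    reaction("ppp_tk1", c("pentose", "pentose"), c("s7p", "triose"),
             list(c(src(1L, 1:2), src(2L, 1:5)), src(1L, 3:5))),
    # transaldolase: S7P + GA3P -> F6P + E4P
    reaction("ppp_ta", c("s7p", "triose"), c("hexose", "e4p"),
             list(c(src(1L, 1:3), src(2L, 1:3)), src(1L, 4:7))),
    # transketolase 2: X5P + E4P -> F6P + GA3P
    reaction("ppp_tk2", c("pentose", "e4p"), c("hexose", "triose"),
             list(c(src(1L, 1:2), src(2L, 1:4)), src(1L, 3:5))),
    # lower glycolysis: the triose pool is pyruvate-numbered already
    reaction("glycolysis_lower", "triose", "pyruvate",
             list(identity_map(3L))),
    # PDH: pyruvate C1 lost; acetyl C1 <- pyr C2, acetyl C2 <- pyr C3
    reaction("pdh", "pyruvate", "acetyl_coa",
             list(src(1L, c(2L, 3L))), co2_losses = cbind(1L, 1L)),
    # pyruvate carboxylase: C1-C3 preserved, C4 fixed from CO2
    reaction("pc", "pyruvate", "oaa",
             list(c(src(1L, 1:3), list("CO2_FIXED")))),
    # citrate synthase (stereospecific; see numbering note above)
    reaction("citrate_synthase", c("acetyl_coa", "oaa"), "citrate",
             list(c(src(1L, 1:2), src(2L, c(2L, 3L, 4L, 1L))))),
    # citrate -> alpha-KG + CO2 (citrate C6 = OAA C1 lost)
    reaction("citrate_to_akg", "citrate", "akg",
             list(src(1L, c(5L, 4L, 3L, 2L, 1L))),
             co2_losses = cbind(1L, 6L)),
    reaction("akg_to_glutamate", "akg", "glutamate", list(identity_map(5L))),
    reaction("glutamate_to_glutamine", "glutamate", "glutamine",
             list(identity_map(5L))),
    # alpha-KG C1 lost; succinate is symmetric
    reaction("akg_to_succinate", "akg", "succinate",
             list(src(1L, 2:5)), co2_losses = cbind(1L, 1L),
             symmetric_product = 1L),
    reaction("succinate_to_malate", "succinate", "malate",
             list(identity_map(4L))),
    reaction("malate_to_oaa", "malate", "oaa", list(identity_map(4L))),
    # malic enzyme: malate C4 lost as CO2
    reaction("malic_enzyme", "malate", "pyruvate",
             list(src(1L, 1:3)), co2_losses = cbind(1L, 4L)),
    reaction("oaa_to_aspartate", "oaa", "aspartate", list(identity_map(4L))),
    reaction("pyruvate_to_lactate", "pyruvate", "lactate",
             list(identity_map(3L))),
    reaction("pyruvate_to_alanine", "pyruvate", "alanine",
             list(identity_map(3L))),
    reaction("acetate_to_acetyl", "acetate", "acetyl_coa",
             list(identity_map(2L)))
  )
  names(rxns) <- vapply(rxns, `[[`, "", "name")
  net <- structure(list(metabolites = metabolites, reactions = rxns,
                        maps = new.env(parent = emptyenv())),
                  class = "iso_network")
  net
}

#' @export
print.iso_network <- function(x, ...) {
  cat(sprintf("<iso_network> %d metabolites, %d reactions\n",
              length(x$metabolites), length(x$reactions)))
  invisible(x)
}

#' Validate carbon conservation and single sourcing of a network
#'
#' Checks, for every reaction, that each substrate carbon appears exactly
#' once across the carbon map and CO2 losses, and that each product carbon
#' has exactly one source.
#'
#' @param network an `iso_network`.
#' @return list with `pass` (logical) and `violations` (character vector
#'   naming offending reactions with the reason).
#' @export
validate_network <- function(network) {
  violations <- character(0)
  mets <- network$metabolites
  for (rx in network$reactions) {
    used <- character(0)
    for (p in seq_along(rx$products)) {
      pm <- rx$products[p]
      if (!pm %in% names(mets)) {
        violations <- c(violations, sprintf("%s: unknown product %s", rx$name, pm))
        next
      }
      np <- mets[[pm]]
      if (length(rx$carbon_map[[p]]) != np) {
        violations <- c(violations, sprintf(
          "%s: product %s has %d mapped carbons, expected %d",
          rx$name, pm, length(rx$carbon_map[[p]]), np))
      }
      for (srcv in rx$carbon_map[[p]]) {
        if (identical(srcv, CO2_FIXED)) next
        used <- c(used, paste(srcv[1], srcv[2], sep = ":"))
      }
    }
    if (!is.null(rx$co2_losses)) {
      used <- c(used, paste(rx$co2_losses[, 1], rx$co2_losses[, 2], sep = ":"))
    }
    expected <- unlist(lapply(seq_along(rx$substrates), function(s) {
      sm <- rx$substrates[s]
      if (!sm %in% names(mets)) {
        violations <<- c(violations, sprintf("%s: unknown substrate %s", rx$name, sm))
        return(character(0))
      }
      paste(s, seq_len(mets[[sm]]), sep = ":")
    }))
    dup <- unique(used[duplicated(used)])
    if (length(dup)) {
      violations <- c(violations, sprintf(
        "%s: substrate carbon(s) %s used more than once", rx$name,
        paste(dup, collapse = ", ")))
    }
    missing <- setdiff(expected, used)
    if (length(missing)) {
      violations <- c(violations, sprintf(
        "%s: substrate carbon(s) %s unaccounted for", rx$name,
        paste(missing, collapse = ", ")))
    }
  }
  list(pass = length(violations) == 0L, violations = violations)
}

# Precomputed joint-state -> product-pattern index maps, cached per reaction.
# Joint states are ordered with substrate slot 1 varying fastest, matching
# as.vector(outer(p1, outer(p2, ...))) ordering.
reaction_maps <- function(network, rx) {
  cached <- network$maps[[rx$name]]
  if (!is.null(cached)) return(cached)
  mets <- network$metabolites
  ns <- vapply(rx$substrates, function(m) mets[[m]], integer(1))
  sizes <- 2L^ns
  total <- prod(sizes)
  joint <- 0:(total - 1L)
  stride <- cumprod(c(1L, sizes[-length(sizes)]))
  sub_pat <- lapply(seq_along(sizes), function(s) {
    (joint %/% stride[s]) %% sizes[s]
  })
  prod_idx <- lapply(seq_along(rx$products), function(p) {
    np <- mets[[rx$products[p]]]
    out <- integer(total)
    for (c in seq_len(np)) {
      srcv <- rx$carbon_map[[p]][[c]]
      if (identical(srcv, CO2_FIXED)) next
      bit <- bitwAnd(bitwShiftR(sub_pat[[srcv[1]]], srcv[2] - 1L), 1L)
      out <- out + bitwShiftL(bit, c - 1L)
    }
    out + 1L
  })
  maps <- list(sizes = sizes, total = total, prod_idx = prod_idx,
               prod_n = vapply(rx$products, function(m) mets[[m]], integer(1)))
  assign(rx$name, maps, envir = network$maps)
  maps
}

#' Apply a reaction to substrate distributions
#'
#' Pushes the joint labeling distribution of the substrate pools (assumed
#' independent) through the reaction's carbon map.  Products flagged as
#' symmetric receive a 50/50 mixture of the two rotational orientations.
#'
#' @param network an `iso_network`.
#' @param rx an `iso_reaction` or reaction name in the network.
#' @param dists a `pid` or list of `pid`s, one per substrate slot.
#' @return list with `products` (list of `pid`, one per product slot) and
#'   `co2_labeled` (expected number of 13C atoms released as CO2 per event).
#' @export
apply_reaction <- function(network, rx, dists) {
  if (is.character(rx)) rx <- network$reactions[[rx]]
  if (is.null(rx)) stop("unknown reaction")
  if (inherits(dists, "pid")) dists <- list(dists)
  if (length(dists) != length(rx$substrates)) {
    stop(rx$name, ": expected ", length(rx$substrates),
         " substrate distribution(s), got ", length(dists))
  }
  mets <- network$metabolites
  for (s in seq_along(dists)) {
    need <- mets[[rx$substrates[s]]]
    if (dists[[s]]$n_carbons != need) {
      stop(rx$name, ": substrate slot ", s, " (", rx$substrates[s],
           ") expects ", need, " carbons, distribution has ",
           dists[[s]]$n_carbons)
    }
  }
  maps <- reaction_maps(network, rx)
  jointp <- dists[[1]]$probs
  if (length(dists) > 1) {
    for (s in 2:length(dists)) jointp <- as.vector(outer(jointp, dists[[s]]$probs))
  }
  products <- vector("list", length(rx$products))
  for (p in seq_along(rx$products)) {
    np <- maps$prod_n[p]
    out <- numeric(2L^np)
    g <- rowsum(jointp, maps$prod_idx[[p]])
    out[as.integer(rownames(g))] <- g[, 1]
    if (p %in% rx$symmetric_product) {
      out <- 0.5 * out + 0.5 * out[reverse_perm(np)]
    }
    out <- out / sum(out)
    products[[p]] <- pid(rx$products[p], np, out)
  }
  co2 <- 0
  if (!is.null(rx$co2_losses)) {
    for (r in seq_len(nrow(rx$co2_losses))) {
      slot <- rx$co2_losses[r, 1]; carbon <- rx$co2_losses[r, 2]
      d <- dists[[slot]]
      idx <- 0:(2L^d$n_carbons - 1L)
      lab <- bitwAnd(bitwShiftR(idx, carbon - 1L), 1L)
      co2 <- co2 + sum(d$probs * lab)
    }
  }
  list(products = products, co2_labeled = co2)
}

#' Write a network's reaction table to TSV
#'
#' Plain-text serialization: one row per reaction with comma-separated slot
#' lists, carbon-map entries as `prod:carbon<-slot:carbon` (or
#' `prod:carbon<-CO2_FIXED`), CO2 losses as `slot:carbon`, and symmetric
#' product slot indices.
#'
#' @param network an `iso_network`.
#' @param path output file.
#' @export
write_network_tsv <- function(network, path) {
  rows <- lapply(network$reactions, function(rx) {
    cmap <- character(0)
    for (p in seq_along(rx$products)) {
      for (c in seq_along(rx$carbon_map[[p]])) {
        srcv <- rx$carbon_map[[p]][[c]]
        rhs <- if (identical(srcv, CO2_FIXED)) "CO2_FIXED" else
          paste(srcv[1], srcv[2], sep = ":")
        cmap <- c(cmap, sprintf("%d:%d<-%s", p, c, rhs))
      }
    }
    co2 <- if (is.null(rx$co2_losses)) "" else
      paste(paste(rx$co2_losses[, 1], rx$co2_losses[, 2], sep = ":"), collapse = ",")
    tibble::tibble(
      reaction = rx$name,
      substrates = paste(rx$substrates, collapse = ","),
      products = paste(rx$products, collapse = ","),
      carbon_map = paste(cmap, collapse = ";"),
      co2_losses = co2,
      symmetric_products = paste(rx$symmetric_product, collapse = ","))
  })
  readr::write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a network reaction table written by [write_network_tsv()]
#'
#' @param path TSV file.
#' @param metabolites named integer vector of carbon counts; defaults to the
#'   default network's metabolite set.
#' @export
read_network_tsv <- function(path, metabolites = NULL) {
  if (is.null(metabolites)) metabolites <- build_default_network()$metabolites
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  rxns <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    products <- strsplit(row$products, ",")[[1]]
    cmap_entries <- strsplit(row$carbon_map, ";")[[1]]
    carbon_map <- lapply(products, function(p) list())
    for (e in cmap_entries) {
      m <- regmatches(e, regexec("^(\\d+):(\\d+)<-(.+)$", e))[[1]]
      p <- as.integer(m[2]); c <- as.integer(m[3])
      srcv <- if (m[4] == "CO2_FIXED") "CO2_FIXED" else
        as.integer(strsplit(m[4], ":")[[1]])
      carbon_map[[p]][[c]] <- srcv
    }
    co2 <- NULL
    if (!is.na(row$co2_losses) && nzchar(row$co2_losses)) {
      parts <- strsplit(strsplit(row$co2_losses, ",")[[1]], ":")
      co2 <- do.call(rbind, lapply(parts, as.integer))
    }
    sym <- integer(0)
    if (!is.na(row$symmetric_products) && nzchar(row$symmetric_products)) {
      sym <- as.integer(strsplit(row$symmetric_products, ",")[[1]])
    }
    reaction(row$reaction, strsplit(row$substrates, ",")[[1]], products,
             carbon_map, co2, sym)
  })
  names(rxns) <- tab$reaction
  structure(list(metabolites = metabolites, reactions = rxns,
                 maps = new.env(parent = emptyenv())),
            class = "iso_network")
}
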