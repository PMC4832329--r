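#!/usr/bin/env Rscript
# Forward-simulate steady-state label propagation for the four tracer
# incubation designs under the study-default pathway parameters, and write
# the positional distributions and MIDs.  Key finding: the four designs
# produce the four diagnostic signatures the estimators rely on —
# [3-13C]pyruvate (glc16), half-labeled [2,3-13C]pyruvate plus M+1 trioses
# (glc12), [1,2-13C]acetyl-only labeling (ace12), and PC-gated citrate M+1
# (lac1).

suppressMessages(library(isopath))
dir.create("results", showWarnings = FALSE)

net <- build_default_network()
conds <- reference_conditions(default_oligo_params())

rows <- list(); mid_rows <- list()
for (nm in names(conds)[1:4]) {
  d <- conds[[nm]]
  s <- simulate_labeling(net, d$tracers, d$params)
  cat(sprintf("%s: converged in %d turns (residual %.1e)\n",
              nm, s$n_turns, s$residual))
  for (m in names(s$distributions)) {
    dist <- s$distributions[[m]]
    nz <- which(dist$probs > 1e-9)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      condition = nm, metabolite = m,
      pattern = vapply(nz, pattern_bitstring, "", n_carbons = dist$n_carbons),
      probability = dist$probs[nz])
    mid <- positional_to_mid(dist)
    mid_rows[[length(mid_rows) + 1L]] <- tibble::tibble(
      condition = nm, metabolite = m, isotopologue = names(mid),
      fraction = unname(mid))
  }
}
readr::write_tsv(do.call(rbind, rows), "results/positional_distributions.tsv")
readr::write_tsv(do.call(rbind, mid_rows), "results/simulated_mids.tsv")

# headline signatures
s12 <- simulate_labeling(net, conds$glc12$tracers, conds$glc12$params)
s16 <- simulate_labeling(net, conds$glc16$tracers, conds$glc16$params)
cat(sprintf("\nlabeled pyruvate: glc12 %.3f vs glc16 %.3f (ratio %.3f)\n",
            labeled_fraction(s12$distributions$pyruvate),
            labeled_fraction(s16$distributions$pyruvate),
            labeled_fraction(s12$distributions$pyruvate) /
              labeled_fraction(s16$distributions$pyruvate)))
slac0 <- simulate_labeling(net, conds$lac1$tracers,
                           update_params(conds$lac1$params, f_pc = 0))
cat(sprintf("lac1 citrate labeled fraction with f_pc = 0: %.4f (PC-gated)\n",
            labeled_fraction(slac0$distributions$citrate)))
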