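# shared fixtures: the default network (cheap to build, reused per file)
# and tracer shorthands for the four incubation designs

default_net <- build_default_network()

trc_glc16 <- function() list(tracer_spec("glucose", c(1, 6)))
trc_glc12 <- function() list(tracer_spec("glucose", c(1, 2)))
trc_ace12 <- function(pool = 1) {
  list(tracer_spec("acetate", c(1, 2), pool_fraction_labeled = pool))
}
trc_lac1 <- function(pool = 1) {
  list(tracer_spec("lactate", 1, pool_fraction_labeled = pool),
       tracer_spec("glucose", integer(0)))
}

expect_pid_pure <- function(dist, positions, tol = 1e-9) {
  expect_equal(dist$probs[pattern_index(positions)], 1, tolerance = tol)
}

# random valid MID of length n+1 under a fixed-seed generator
random_mid <- function(n) {
  x <- stats::runif(n + 1)
  x / sum(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
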