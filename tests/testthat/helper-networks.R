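# Small fixture builders shared across test files.

# single node producing sigma from x1 (weight w1) and antisigma from x2 (w2)
single_perceptron <- function(w1 = 1, w2 = 1, gamma1 = 1000, gamma2 = 10,
                              delta = 1, c_tot = 0.2, ...) {
  validate_network(network_spec(
    list(node_spec("node1", 1L,
                   weights = list(x1 = signed_weight(w1, "+"),
                                  x2 = signed_weight(w2, "-")))),
    c_tot = c_tot, kinetics = kinetic_params(gamma1, gamma2, delta), ...))
}

# a node of an existing network, isolated with the same pool and kinetics
isolated_node <- function(network, id) {
  nd <- Filter(function(n) n$id == id, network$nodes)[[1L]]
  validate_network(network_spec(list(nd), c_tot = network$c_tot,
                                kinetics = network$kinetics))
}

# max-normalized slice of a response map
norm_slice <- function(map, node = NULL) {
  m <- map_slice_of(map, node)
  mx <- max(m)
  if (mx > 0) m / mx else m
}

expect_state_close <- function(a, b, tol = 1e-6) {
  scale <- max(1, max(abs(a)), max(abs(b)))
  expect_lt(max(abs(a - b)) / scale, tol)
}

random_state <- function(network, seed) {
  set.seed(seed)
  st <- state_template(network)
  st[] <- runif(length(st), 0, 2)
  st
}
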