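# Closed-form oracle for the isolated sequestration pair: positive root of
# gamma1*s^2 + (delta - gamma1*(u-v)/delta)*s - u = 0 by the quadratic formula.
quad_oracle <- function(u, v, gamma1, delta = 1) {
  b <- delta - gamma1 * (u - v) / delta
  (-b + sqrt(b^2 + 4 * gamma1 * u)) / (2 * gamma1)
}

test_that("sequestration-pair solver matches the quadratic-formula oracle", {
  k10 <- kinetic_params(10, 10, 1)
  expect_equal(solve_sequestration_pair(1, 0.5, k10)$s, (4 + sqrt(56)) / 20,
               tolerance = 1e-12)
  # fast-sequestration limit approaches the rectified difference 0.5
  s_fast <- solve_sequestration_pair(1, 0.5, kinetic_params(1000, 10, 1))$s
  expect_equal(s_fast, quad_oracle(1, 0.5, 1000), tolerance = 1e-12)
  expect_equal(s_fast, 0.501, tolerance = 1e-3)
  # random fluxes against the oracle, including the antisigma balance
  set.seed(42)
  for (i in 1:50) {
    u <- runif(1, 0, 4); v <- runif(1, 0, 4)
    g1 <- 10^runif(1, -1, 3); d <- 10^runif(1, -1, 1)
    sol <- solve_sequestration_pair(u, v, kinetic_params(g1, 10, d))
    expect_equal(sol$s, quad_oracle(u, v, g1, d), tolerance = 1e-9)
    expect_gte(sol$a, 0)
    # steady-state balances of both species
    expect_equal(u, d * sol$s + g1 * sol$s * sol$a, tolerance = 1e-8)
    expect_equal(v, d * sol$a + g1 * sol$s * sol$a, tolerance = 1e-8)
  }
})

test_that("symmetric production gives equal sigma and antisigma", {
  for (g1 in c(1, 100, 1e4)) {
    sol <- solve_sequestration_pair(0.8, 0.8, kinetic_params(g1, 10, 1))
    expect_equal(sol$s, sol$a, tolerance = 1e-12)
  }
  sol0 <- solve_sequestration_pair(0, 0, kinetic_params(10, 10, 1))
  expect_identical(sol0$s, 0)
})

test_that("arelu is the rectified flux difference", {
  expect_identical(arelu(1, 0, 1), 1)
  expect_identical(arelu(0.3, 0.5, 1), 0)
  expect_identical(arelu(0.7, 0.7, 1), 0)
  expect_equal(arelu(c(1, 2), c(0.5, 3), 2), c(0.25, 0))
})

test_that("the exact pair converges to AReLU in the fast-sequestration regime", {
  g <- seq(0, 1, length.out = 21)
  k <- kinetic_params(1e4, 10, 1)
  worst <- 0
  for (x1 in g) for (x2 in g) {
    worst <- max(worst, abs(solve_sequestration_pair(x1, x2, k)$s - arelu(x1, x2, 1)))
  }
  expect_lte(worst, 1e-2)
})

test_that("slow sequestration loses thresholding: s -> u/delta", {
  k <- kinetic_params(1e-6, 10, 1)
  expect_equal(solve_sequestration_pair(1, 0.9, k)$s, 1, tolerance = 1e-5)
  expect_equal(solve_sequestration_pair(0.4, 2, k)$s, 0.4, tolerance = 1e-4)
})

test_that("single-node resource steady state matches its closed form", {
  # no antisigma: s_bar = u/delta; c_bar closes the pool:
  # c = gamma2*s*(c_tot - c)/delta  =>  c = c_tot*gamma2*s/(delta + gamma2*s)
  net <- validate_network(network_spec(
    list(node_spec("n1", 1L, weights = list(x1 = signed_weight(1, "+")))),
    c_tot = 0.2, kinetics = kinetic_params(1000, 10, 1)))
  ss <- solve_resource_fixed_point(net, c(1, 0))
  expect_true(ss$converged)
  expect_equal(unname(ss$state["s.n1"]), 1, tolerance = 1e-10)
  expect_equal(unname(ss$state["c.n1"]), 0.2 * 10 / 11, tolerance = 1e-9)
  expect_equal(unname(ss$state["c.n1"] + ss$state["c_free"]), 0.2, tolerance = 1e-12)
})

test_that("below-threshold input gives essentially no complex", {
  net <- single_perceptron(gamma1 = 1000)
  ss <- solve_resource_fixed_point(net, c(0.3, 0.9)) # w1*x1 < w2*x2
  expect_lt(ss$state["c.node1"] / net$c_tot, 0.05)
})

test_that("identical competing nodes split the pool symmetrically", {
  nodes <- list(
    node_spec("a", 1L, weights = list(x1 = signed_weight(1, "+"),
                                      x2 = signed_weight(1, "-"))),
    node_spec("b", 1L, weights = list(x1 = signed_weight(1, "+"),
                                      x2 = signed_weight(1, "-"))))
  net <- validate_network(network_spec(nodes, c_tot = 0.4,
                                       kinetics = kinetic_params(100, 10, 1)))
  ss <- solve_resource_fixed_point(net, c(1, 0.25))
  expect_equal(unname(ss$state["c.a"]), unname(ss$state["c.b"]), tolerance = 1e-12)
})

test_that("integration and algebraic solvers agree on presets", {
  for (nm in c("fig3_node", "fig3_competition", "fig4a_two_node",
               "fig4e_bandstop", "s2_coupled")) {
    net <- load_preset(nm)
    for (x in list(c(1, 0.2), c(0.4, 0.8))) {
      a <- solve_resource_fixed_point(net, x)
      b <- integrate_to_steady_state(net, x)
      expect_true(b$converged)
      expect_state_close(a$state, b$state, 1e-6)
    }
  }
})

test_that("zero input and bias yields the all-zero steady state", {
  net <- single_perceptron()
  for (m in c("algebraic", "integration")) {
    ss <- steady_state(net, c(0, 0), method = m)
    expect_equal(max(abs(ss$state[c("s.node1", "a.node1", "c.node1")])), 0,
                 tolerance = 1e-12)
    expect_equal(unname(ss$state["c_free"]), net$c_tot, tolerance = 1e-12)
  }
})

test_that("normalized single-node output saturates at 1 with growing input", {
  cn <- vapply(c(1, 5, 20, 50), function(w1) {
    net <- validate_network(network_spec(
      list(node_spec("n1", 1L, weights = list(x1 = signed_weight(w1, "+")))),
      c_tot = 0.2, kinetics = kinetic_params(1000, 10, 1)))
    evaluate_network(net, c(1, 0))$output_norm
  }, numeric(1))
  expect_true(all(diff(cn) > 0))
  expect_lt(max(cn), 1)
  expect_equal(cn[length(cn)], 1, tolerance = 0.01)
})

test_that("competitor bounds the saturation level at c_tot - c2", {
  g <- seq(0, 1, length.out = 11)
  net <- load_preset("fig2_competition", gamma1 = 100, alpha = 1, beta = 0)
  for (x1 in g) {
    ss <- solve_resource_fixed_point(net, c(x1, 0))
    expect_lte(ss$state["c.node1"],
               net$c_tot - ss$state["c.node2"] + 1e-9)
  }
})

test_that("transient trajectory rises monotonically to the steady state", {
  net <- single_perceptron(gamma1 = 100, c_tot = 0.5)
  tr <- transient_trajectory(net, c(1, 0.2), seq(0, 40, by = 0.25))
  expect_equal(tr$c.node1[1L], 0) # complexes start empty
  expect_true(all(diff(tr$c.node1) > -1e-10))
  ss <- integrate_to_steady_state(net, c(1, 0.2))
  expect_equal(tr$c.node1[nrow(tr)], unname(ss$state["c.node1"]), tolerance = 1e-6)
  expect_error(transient_trajectory(net, c(1, 0.2), numeric(0)), "nonempty")
  expect_error(transient_trajectory(net, c(1, 0.2), c(1, 2)), "start at 0")
})

test_that("transient response map peaks where the steady-state map peaks", {
  net <- load_preset("fig3_node")
  g <- seq(0, 1, length.out = 9)
  early <- matrix(0, 9, 9); late <- matrix(0, 9, 9)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    tr <- transient_trajectory(net, c(g[i], g[j]), c(0, 0.5, 30))
    early[i, j] <- tr$c.node1[2L]
    late[i, j] <- tr$c.node1[3L]
  }
  expect_identical(which.max(early), which.max(late))
  # maximum response at (x1 -> 1, x2 -> 0): grid cell (9, 1)
  expect_identical(unname(which(late == max(late), arr.ind = TRUE)[1, ]), c(9L, 1L))
  # transient response magnitude below the steady-state magnitude
  expect_lt(max(early), max(late))
})
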