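#' Evaluate a multilayer network at one input point
#'
#' Computes the full-network steady state (all nodes, all layers, one shared
#' polymerase pool) and reports per-node sigma--polymerase complex
#' concentrations \eqn{\bar c_i} together with their pool-normalized values
#' \eqn{\bar c_i^n = \bar c_i / c_{tot}}. The network output is the complex of
#' the designated output node (the single node in the final layer unless named
#' in the spec).
#'
#' @inheritParams solve_resource_fixed_point
#' @param method Steady-state solver, `"algebraic"` or `"integration"`.
#' @param ... Passed to the solver.
#' @return List with `c_bar` and `c_bar_norm` (named per node), `s_bar`,
#'   `output`, `output_norm`, `output_node`, `converged`, `residual_norm`, and
#'   the full `state`.
#' @examples
#' evaluate_network(load_preset("fig4e_bandstop"), c(0.5, 0.5))$output_norm
#' @export
evaluate_network <- function(network, x, method = c("algebraic", "integration"),
                             ...) {
  network <- assert_validated(network)
  ss <- steady_state(network, x, method = match.arg(method), ...)
  ids <- vapply(network$nodes, `[[`, character(1), "id")
  c_bar <- stats::setNames(ss$state[paste0("c.", ids)], ids)
  s_bar <- stats::setNames(ss$state[paste0("s.", ids)], ids)
  norm <- if (network$c_tot > 0) c_bar / network$c_tot else c_bar * NA_real_
  out_id <- network$output_node
  list(c_bar = c_bar, c_bar_norm = norm, s_bar = s_bar,
       output = unname(c_bar[out_id]), output_norm = unname(norm[out_id]),
       output_node = out_id, converged = ss$converged,
       residual_norm = ss$residual_norm, state = ss$state)
}

#' Ideal resource-free ReLU reference network
#'
#' Evaluates the network as an ideal feed-forward ReLU net with the same
#' signed weights and biases but no kinetics and no resource pool:
#' \eqn{\mathrm{out}_j = \max(0, \sum_k \pm w_{jk}\,\mathrm{src}_k \pm b_j)},
#' with external inputs feeding layer 1 and ideal outputs feeding higher
#' layers. This is the design target against which the mechanistic steady
#' state is compared.
#'
#' @inheritParams solve_resource_fixed_point
#' @return Named numeric vector of ideal outputs, one per node.
#' @examples
#' ideal_relu_network(load_preset("fig4e_bandstop"), c(1, 1))
#' @export
ideal_relu_network <- function(network, x) {
  network <- assert_validated(network)
  x <- check_input(network, x)
  ids <- vapply(network$nodes, `[[`, character(1), "id")
  out <- stats::setNames(numeric(length(ids)), ids)
  sources <- c(x, out)
  for (nd in network$nodes) { # canonical order is layer order
    pr <- production_rates_from_layer(sources, nd)
    out[nd$id] <- max(0, pr[["sigma"]] - pr[["antisigma"]])
    sources[nd$id] <- out[nd$id]
  }
  out
}

#' Signed-weight accumulation of production fluxes for one node
#'
#' Splits a node's production into its sigma flux (positive-signed weights
#' plus positive biases) and antisigma flux (negative-signed weights plus
#' negative biases), given the concentrations of every source it references.
#'
#' @param sources Named numeric vector covering all of the node's sources
#'   (external inputs `"x1"`, ... and/or upstream node ids mapped to their
#'   steady-state complex concentrations).
#' @param node A [node_spec()].
#' @return Numeric vector `c(sigma = , antisigma = )` in uM/h.
#' @examples
#' nd <- node_spec("n3", 2, bias = signed_weight(0.15, "-"),
#'                 weights = list(n1 = signed_weight(4), n2 = signed_weight(4)))
#' production_rates_from_layer(c(n1 = 0.1, n2 = 0.05), nd)
#' @export
production_rates_from_layer <- function(sources, node) {
  u <- 0; v <- 0
  for (b in node$bias) {
    if (b$sign == "+") u <- u + b$w else v <- v + b$w
  }
  for (src in names(node$weights)) {
    if (!src %in% names(sources))
      stop("missing source value for '", src, "'", call. = FALSE)
    sw <- node$weights[[src]]
    flux <- sw$w * sources[[src]]
    if (sw$sign == "+") u <- u + flux else v <- v + flux
  }
  c(sigma = u, antisigma = v)
}
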