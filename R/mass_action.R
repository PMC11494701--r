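#' State-vector layout of a network
#'
#' Per node `i` the state holds the free sigma `s.<id>`, free antisigma
#' `a.<id>`, and sigma--polymerase complex `c.<id>` concentrations (uM),
#' followed by the free polymerase `c_free`; coupled mode appends the two
#' housekeeping complexes `c_S` and `c_A`. The closed polymerase pool obeys
#' `c_free + sum(complexes) = c_tot` at all times.
#'
#' @param network A validated `bnn_network`.
#' @return Named numeric zero vector with the layout above.
#' @export
state_template <- function(network) {
  network <- assert_validated(network)
  ids <- vapply(network$nodes, `[[`, character(1), "id")
  nm <- c(t(outer(c("s", "a", "c"), ids, paste, sep = ".")), "c_free")
  if (network$coupling_mode == "coupled") nm <- c(nm, "c_S", "c_A")
  stats::setNames(numeric(length(nm)), nm)
}

# Flattened, index-based view of the network used by the RHS and the
# algebraic solver: precomputes per-node rates and signed weight vectors so
# the hot loops never touch the list structures.
compile_network <- function(network) {
  network <- assert_validated(network)
  ids <- vapply(network$nodes, `[[`, character(1), "id")
  n <- length(ids)
  ext <- input_names(network$n_inputs)
  kin <- lapply(network$nodes, node_kinetics, network = network)
  tpl <- state_template(network)
  idx <- function(p) match(paste(p, ids, sep = "."), names(tpl))

  terms <- lapply(seq_len(n), function(i) {
    nd <- network$nodes[[i]]
    src <- names(nd$weights)
    w <- vapply(nd$weights, `[[`, numeric(1), "w")
    pos <- vapply(nd$weights, `[[`, character(1), "sign") == "+"
    is_ext <- src %in% ext
    b <- vapply(nd$bias, `[[`, numeric(1), "w")
    bpos <- vapply(nd$bias, `[[`, character(1), "sign") == "+"
    list(
      # constitutive production on the virtual 1-uM input
      bias_u = sum(b[bpos]), bias_v = sum(b[!bpos]),
      ext_i = match(src[is_ext], ext), ext_w = w[is_ext], ext_pos = pos[is_ext],
      up_ci = match(paste("c", src[!is_ext], sep = "."), names(tpl)),
      up_w = w[!is_ext], up_pos = pos[!is_ext])
  })

  list(network = network, n = n, ids = ids,
       layers = vapply(network$nodes, `[[`, integer(1), "layer"),
       gamma1 = vapply(kin, `[[`, numeric(1), "gamma1"),
       gamma2 = vapply(kin, `[[`, numeric(1), "gamma2"),
       delta = vapply(kin, `[[`, numeric(1), "delta"),
       s_i = idx("s"), a_i = idx("a"), c_i = idx("c"),
       cf_i = match("c_free", names(tpl)),
       cS_i = match("c_S", names(tpl)), cA_i = match("c_A", names(tpl)),
       coupled = network$coupling_mode == "coupled",
       s_c = network$s_c, c_tot = network$c_tot,
       hk_gamma2 = network$kinetics$gamma2, hk_delta = network$kinetics$delta,
       terms = terms, template = tpl)
}

# Sigma and antisigma production fluxes (uM/h) for every node, given the
# external input x and the complex concentrations in `state` (upstream terms
# pre-scaled to occupancy fractions in compile_network). In coupled mode
# external-input and bias terms are driven by the housekeeping complexes
# (per uM of c_S / c_A), upstream-complex terms are not.
production_fluxes <- function(cmp, state, x) {
  u <- numeric(cmp$n); v <- numeric(cmp$n)
  scale_u <- 1; scale_v <- 1
  if (cmp$coupled) {
    scale_u <- state[[cmp$cS_i]]
    scale_v <- state[[cmp$cA_i]]
  }
  for (i in seq_len(cmp$n)) {
    tm <- cmp$terms[[i]]
    eu <- tm$bias_u; ev <- tm$bias_v
    if (length(tm$ext_i)) {
      fx <- tm$ext_w * x[tm$ext_i]
      eu <- eu + sum(fx[tm$ext_pos])
      ev <- ev + sum(fx[!tm$ext_pos])
    }
    u[i] <- eu * scale_u
    v[i] <- ev * scale_v
    if (length(tm$up_ci)) {
      fc <- tm$up_w * state[tm$up_ci]
      u[i] <- u[i] + sum(fc[tm$up_pos])
      v[i] <- v[i] + sum(fc[!tm$up_pos])
    }
  }
  list(u = u, v = v)
}

#' Build the mass-action right-hand side of a network
#'
#' Assembles the ODE system for the reactions of every node `i`: production of
#' the sigma \eqn{S_i} and antisigma \eqn{A_i} at the signed weighted source
#' fluxes, irreversible sequestration \eqn{S_i + A_i \to \emptyset} at
#' `gamma1`, irreversible polymerase binding \eqn{S_i + C \to C_i} at
#' `gamma2`, first-order decay of \eqn{S_i} and \eqn{A_i} at `delta`, and
#' complex turnover \eqn{C_i \to S_i + C} at `delta`, which recycles both the
#' polymerase and the sigma so the finite pool `c_tot` is conserved exactly
#' and the free-sigma balance at steady state is unaffected by the pool.
#' Downstream production (layers above 1) is linear in the upstream node's
#' sigma--polymerase complex concentration (transcription rate proportional
#' to the active complex, unit gain). In coupled mode the housekeeping
#' complexes `c_S`, `c_A` form at `gamma2 * s_c * c_free`, turn over at
#' `delta`, and gate all external-input and bias production.
#'
#' @param network A validated `bnn_network`.
#' @return A function `(t, state, x)` returning the derivative vector aligned
#'   with [state_template()].
#' @seealso [check_conservation()], [integrate_to_steady_state()]
#' @export
build_rhs <- function(network) {
  cmp <- compile_network(network)
  nst <- length(cmp$template)
  function(t, state, x) {
    if (length(state) != nst)
      stop("state vector has length ", length(state), ", expected ", nst,
           call. = FALSE)
    x <- check_input(cmp$network, x)
    s <- state[cmp$s_i]; a <- state[cmp$a_i]; cc <- state[cmp$c_i]
    cf <- state[[cmp$cf_i]]
    pr <- production_fluxes(cmp, state, x)
    seq_flux <- cmp$gamma1 * s * a
    bind_flux <- cmp$gamma2 * s * cf
    turn_flux <- cmp$delta * cc
    d <- numeric(nst)
    d[cmp$s_i] <- pr$u - cmp$delta * s - seq_flux - bind_flux + turn_flux
    d[cmp$a_i] <- pr$v - cmp$delta * a - seq_flux
    d[cmp$c_i] <- bind_flux - turn_flux
    d[cmp$cf_i] <- sum(turn_flux - bind_flux)
    if (cmp$coupled) {
      hk_bind <- cmp$hk_gamma2 * cmp$s_c * cf
      d[cmp$cS_i] <- hk_bind - cmp$hk_delta * state[[cmp$cS_i]]
      d[cmp$cA_i] <- hk_bind - cmp$hk_delta * state[[cmp$cA_i]]
      d[cmp$cf_i] <- d[cmp$cf_i] - 2 * hk_bind +
        cmp$hk_delta * (state[[cmp$cS_i]] + state[[cmp$cA_i]])
    }
    names(d) <- names(cmp$template)
    d
  }
}

#' Conservation residual of the polymerase pool
#'
#' Evaluates the right-hand side at `state` and returns the absolute time
#' derivative of the closed pool `c_free + sum(complexes)`, which is
#' identically zero for a correctly assembled network. Useful as a structural
#' test of the reaction bookkeeping.
#'
#' @param network A validated `bnn_network` (or a RHS built by [build_rhs()],
#'   in which case `state` must match its layout and `network` is that RHS).
#' @param state Named state vector in the [state_template()] layout.
#' @param x External input vector.
#' @return Absolute residual (uM/h).
#' @export
check_conservation <- function(network, state, x) {
  rhs <- if (is.function(network)) network else build_rhs(network)
  d <- rhs(0, state, x)
  pool <- grepl("^c\\.", names(d)) | names(d) %in% c("c_free", "c_S", "c_A")
  abs(sum(d[pool]))
}
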