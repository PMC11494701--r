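#' Exact steady state of an isolated sequestration pair
#'
#' For a sigma produced at constant flux `u` and its antisigma at flux `v`
#' (uM/h), with first-order decay `delta` and irreversible sequestration
#' `gamma1`, the steady-state free sigma solves the quadratic
#' \deqn{\gamma_1 s^2 + (\delta - \gamma_1 (u - v)/\delta)\, s - u = 0,}
#' and the antisigma follows from \eqn{\bar a = \bar s - (u - v)/\delta}.
#' The unique nonnegative root is returned in a cancellation-free form.
#' This is the building block of every activation function in the package:
#' as \eqn{\gamma_1 \to \infty} it converges to the AReLU limit
#' \eqn{\max(0, (u-v)/\delta)} (see [arelu()]), and as \eqn{\gamma_1 \to 0}
#' thresholding is lost and \eqn{\bar s \to u/\delta}.
#'
#' @param u Sigma production flux (uM/h), `>= 0`.
#' @param v Antisigma production flux (uM/h), `>= 0`.
#' @param kinetics A [kinetic_params()] object (only `gamma1` and `delta`
#'   are used).
#' @return List with elements `s` and `a` (steady-state free concentrations).
#' @examples
#' solve_sequestration_pair(1, 0.5, kinetic_params(10, 10, 1))$s # (4+sqrt(56))/20
#' @export
solve_sequestration_pair <- function(u, v, kinetics) {
  stopifnot(length(u) == 1L, length(v) == 1L)
  if (!is.finite(u) || !is.finite(v) || u < 0 || v < 0)
    stop("production fluxes must be finite and nonnegative", call. = FALSE)
  g1 <- kinetics$gamma1; d <- kinetics$delta
  m <- (u - v) / d
  b <- d - g1 * m
  disc <- b * b + 4 * g1 * u
  # s = (-b + sqrt(disc)) / (2 g1), rationalized so u = 0 gives exactly 0 and
  # large positive b does not cancel
  s <- 2 * u / (sqrt(disc) + b)
  a <- max(0, s - m)
  list(s = s, a = a)
}

#' Asymptotic ReLU activation (fast-sequestration limit)
#'
#' The limit of the sequestration steady state as sequestration becomes
#' instantaneous: the free sigma equals the rectified difference of the two
#' production fluxes, \eqn{\max(0, (u - v)/\delta)}. This is the idealized
#' activation function the biochemical perceptron approximates.
#'
#' @param u,v Sigma and antisigma production fluxes (uM/h); vectorized.
#' @param delta Degradation rate (1/h).
#' @return Rectified steady-state sigma concentration (uM).
#' @export
arelu <- function(u, v, delta = 1) {
  pmax(0, (u - v) / delta)
}

# Given free polymerase cf, solve every node in layer order (upstream
# complexes are functions of cf only) and return the per-node steady states.
solve_nodes_given_cfree <- function(cmp, x, cf) {
  state <- cmp$template
  state[cmp$cf_i] <- cf
  if (cmp$coupled) {
    hk <- cmp$hk_gamma2 * cmp$s_c * cf / cmp$hk_delta
    state[cmp$cS_i] <- hk
    state[cmp$cA_i] <- hk
  }
  u <- numeric(cmp$n); v <- numeric(cmp$n)
  for (i in order(cmp$layers)) {
    pr <- production_fluxes(cmp, state, x)
    u[i] <- pr$u[i]; v[i] <- pr$v[i]
    # At steady state complex turnover returns the sigma, so the free-sigma
    # balance reduces to the isolated sequestration pair.
    sol <- solve_sequestration_pair(u[i], v[i],
                                    kinetic_params(cmp$gamma1[i], cmp$gamma2[i],
                                                   cmp$delta[i]))
    state[cmp$s_i[i]] <- sol$s
    state[cmp$a_i[i]] <- sol$a
    state[cmp$c_i[i]] <- cmp$gamma2[i] * sol$s * cf / cmp$delta[i]
  }
  list(state = state, u = u, v = v)
}

#' Algebraic steady state with a shared polymerase pool
#'
#' Solves the steady-state algebraic system directly instead of integrating
#' in time. Given the free polymerase concentration, every node reduces to the
#' sequestration-pair quadratic (solved in layer order, since upstream
#' complexes are known functions of the free pool), and the pool closes
#' through the conservation law `c_free + sum(complexes) = c_tot`, a
#' one-dimensional root problem on `[0, c_tot]` solved with a bracketed root
#' finder. The endpoints always bracket the root, so convergence is
#' guaranteed; [integrate_to_steady_state()] provides the independent
#' cross-check.
#'
#' @param network A validated `bnn_network`.
#' @param x External input concentrations (uM), length `n_inputs`.
#' @param tol Residual tolerance (uM/h) used for the `converged` flag.
#' @return An object of class `bnn_steady_state`: list with `state` (named
#'   vector), `converged`, `residual_norm` (max-norm of the RHS), and
#'   `method = "algebraic"`.
#' @examples
#' net <- load_preset("fig3_node")
#' solve_resource_fixed_point(net, c(1, 0.2))$state
#' @export
solve_resource_fixed_point <- function(network, x, tol = 1e-9) {
  cmp <- compile_network(network)
  x <- check_input(cmp$network, x)
  if (cmp$c_tot == 0) {
    st <- solve_nodes_given_cfree(cmp, x, 0)$state
  } else {
    excess <- function(cf) {
      st <- solve_nodes_given_cfree(cmp, x, cf)$state
      pool <- sum(st[cmp$c_i]) + cf +
        (if (cmp$coupled) st[cmp$cS_i] + st[cmp$cA_i] else 0)
      pool - cmp$c_tot
    }
    hi <- excess(cmp$c_tot)
    if (hi <= 0) {
      cf <- cmp$c_tot # nothing binds (e.g. all sigma production zero)
    } else {
      cf <- stats::uniroot(excess, c(0, cmp$c_tot),
                           f.lower = -cmp$c_tot, f.upper = hi,
                           tol = .Machine$double.eps^0.75 * max(1, cmp$c_tot),
                           maxiter = 1000L)$root
      # Newton polish: with fast binding the residual is steep in c_free, so
      # the bracketing tolerance alone can leave an O(gamma2 * s) RHS error
      for (it in 1:4) {
        e0 <- excess(cf)
        if (abs(e0) < .Machine$double.eps * 16 * max(1, cmp$c_tot)) break
        h <- max(abs(cf), cmp$c_tot) * 1e-7
        de <- (excess(min(cf + h, cmp$c_tot)) - excess(max(cf - h, 0))) /
          (min(cf + h, cmp$c_tot) - max(cf - h, 0))
        if (!is.finite(de) || de <= 0) break
        cf <- min(max(cf - e0 / de, 0), cmp$c_tot)
      }
    }
    st <- solve_nodes_given_cfree(cmp, x, cf)$state
    # polish the pool balance exactly: assign the conservation slack to c_free
    st[cmp$cf_i] <- cmp$c_tot - sum(st[cmp$c_i]) -
      (if (cmp$coupled) st[cmp$cS_i] + st[cmp$cA_i] else 0)
    if (st[cmp$cf_i] < 0) st[cmp$cf_i] <- 0
  }
  res <- max(abs(build_rhs(cmp$network)(0, st, x)))
  structure(list(state = st, converged = res < tol, residual_norm = res,
                 method = "algebraic"),
            class = "bnn_steady_state")
}

#' @export
print.bnn_steady_state <- function(x, ...) {
  cat("<bnn_steady_state> method:", x$method,
      if (x$converged) "(converged)" else "(NOT converged)",
      sprintf("residual %.3g uM/h\n", x$residual_norm))
  print(x$state)
  invisible(x)
}

steady_times <- function(t_max, n = 80L) {
  unique(c(0, 10^seq(-3, log10(t_max), length.out = n)))
}

#' Steady state by long-time ODE integration
#'
#' Integrates the mass-action system from the all-zero initial condition with
#' `deSolve::ode` (lsoda) over a logarithmic time mesh and stops at the first
#' output time where the max-norm of the right-hand side drops below `tol`.
#' Non-convergence by `t_max` is flagged, not raised.
#'
#' @inheritParams solve_resource_fixed_point
#' @param tol Steady-state criterion on the RHS max-norm (uM/h).
#' @param t_max Maximum integration time (h).
#' @param rtol,atol Integrator tolerances passed to `deSolve::ode`.
#' @return An object of class `bnn_steady_state` with `method = "integration"`.
#' @export
integrate_to_steady_state <- function(network, x, tol = 1e-9, t_max = 1e4,
                                      rtol = 1e-10, atol = 1e-12) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  network <- assert_validated(network)
  x <- check_input(network, x)
  rhs <- build_rhs(network)
  y0 <- state_template(network)
  y0["c_free"] <- network$c_tot
  times <- steady_times(t_max)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, p) list(unname(rhs(t, y, x))),
                      parms = NULL, rtol = rtol, atol = atol)
  st <- y0; res <- Inf; converged <- FALSE
  for (k in 2:nrow(sol)) {
    yk <- sol[k, -1L]
    names(yk) <- names(y0)
    rk <- max(abs(rhs(sol[k, 1L], yk, x)))
    if (rk < res) { st <- yk; res <- rk }
    if (rk < tol) { converged <- TRUE; break }
  }
  structure(list(state = st, converged = converged, residual_norm = res,
                 method = "integration"),
            class = "bnn_steady_state")
}

#' Steady state of a network (solver dispatcher)
#'
#' @inheritParams solve_resource_fixed_point
#' @param method `"algebraic"` (default; exact fixed point of the shared
#'   pool) or `"integration"` (long-time ODE solution).
#' @param ... Passed on to the chosen solver.
#' @return A `bnn_steady_state`.
#' @export
steady_state <- function(network, x, method = c("algebraic", "integration"), ...) {
  method <- match.arg(method)
  switch(method,
         algebraic = solve_resource_fixed_point(network, x, ...),
         integration = integrate_to_steady_state(network, x, ...))
}

#' Transient trajectory of a network
#'
#' Full time course from the all-zero initial condition (free polymerase
#' starts at `c_tot`) over a user-supplied time grid.
#'
#' @inheritParams solve_resource_fixed_point
#' @param times Increasing time grid starting at 0 (h).
#' @param rtol,atol Integrator tolerances.
#' @return A data.frame with a `time` column and one column per state
#'   variable.
#' @export
transient_trajectory <- function(network, x, times, rtol = 1e-10, atol = 1e-12) {
  if (!length(times)) stop("t_grid must be nonempty", call. = FALSE)
  if (times[1L] != 0 || is.unsorted(times, strictly = TRUE))
    stop("t_grid must start at 0 and be strictly increasing", call. = FALSE)
  network <- assert_validated(network)
  x <- check_input(network, x)
  rhs <- build_rhs(network)
  y0 <- state_template(network)
  y0["c_free"] <- network$c_tot
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, p) list(unname(rhs(t, y, x))),
                      parms = NULL, rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out) <- c("time", names(y0))
  out
}

#' Dimensionless regime indicators
#'
#' Computes the competitive binding ratio \eqn{r = \gamma_2/\gamma_1} (ratio
#' of polymerase binding to sequestration rate; `r << 1` is the fast
#' competitive binding regime in which linear decision boundaries are
#' preserved) and the sequestration-speed indicator
#' \eqn{\xi = \delta^2 / (\gamma_1 \max_k \mathrm{flux}_k)}, the reciprocal of
#' the sequestration-strength group obtained by nondimensionalizing
#' concentration by (max production flux)/\eqn{\delta} and time by
#' \eqn{1/\delta}; `xi << 1` is the fast-sequestration regime in which
#' thresholding emerges. The maximum runs over all sigma and antisigma
#' production fluxes at input `x`, evaluated with all complexes at zero.
#' Indicators use the first node's kinetics (all published designs share one
#' rate set); each is classified `"fast"` below 1 and `"slow"` otherwise.
#'
#' @inheritParams solve_resource_fixed_point
#' @return List with `r`, `xi`, `r_class`, `xi_class`.
#' @examples
#' regime_indicators(load_preset("fig3_node"), c(1, 0.5))
#' @export
regime_indicators <- function(network, x) {
  cmp <- compile_network(network)
  x <- check_input(cmp$network, x)
  st <- cmp$template
  if (cmp$coupled) {
    st[cmp$cS_i] <- cmp$s_c
    st[cmp$cA_i] <- cmp$s_c
  }
  pr <- production_fluxes(cmp, st, x)
  flux <- max(pr$u, pr$v)
  r <- cmp$gamma2[1L] / cmp$gamma1[1L]
  xi <- if (flux > 0) cmp$delta[1L]^2 / (cmp$gamma1[1L] * flux) else Inf
  list(r = r, xi = xi,
       r_class = if (r < 1) "fast" else "slow",
       xi_class = if (xi < 1) "fast" else "slow")
}
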