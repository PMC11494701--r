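#' Names of the built-in network presets
#'
#' @return Character vector of preset names accepted by [load_preset()].
#' @export
preset_names <- function() {
  c("fig2_single", "fig2_resources", "fig2_competition",
    "fig3_node", "fig3_competition",
    "fig4a_two_node", "fig4e_bandstop", "fig4h_bandpass",
    "s2_coupled")
}

perceptron_node <- function(id = "node1", w1 = 1, w2 = 1, bias = NULL) {
  node_spec(id, 1L, bias = bias,
            weights = list(x1 = signed_weight(w1, "+"),
                           x2 = signed_weight(w2, "-")))
}

competitor_node <- function(id, alpha, beta) {
  node_spec(id, 1L,
            bias = c(if (alpha > 0) list(signed_weight(alpha, "+")),
                     if (beta > 0) list(signed_weight(beta, "-"))))
}

#' Load a published network design as a validated preset
#'
#' Transcribes the parameter sets of the published computational designs.
#' Shared rates are `delta` = 1/h and `gamma2` = 10/(uM h) throughout;
#' inputs range over 0--1 uM. The sequestration rate `gamma1` is the regime
#' dial: the single-pair and resource presets (`fig2_*`) take it as a
#' required argument (the published sweeps use values around 1--1000), the
#' single-perceptron presets default to `gamma1 = 100` (competitive binding
#' ratio r = 0.1), and the multilayer classifier presets default to
#' `gamma1 = 1000` (r = 0.01, the regime in which the published classifiers
#' track their ideal design).
#'
#' Available presets:
#' \describe{
#'   \item{fig2_single}{One sigma/antisigma pair, no polymerase pool
#'     (`c_tot = 0`); the AReLU motif. `gamma1` required.}
#'   \item{fig2_resources}{Same pair plus a finite pool (default
#'     `c_tot = 0.2` uM); the ASReLU motif. `gamma1` required.}
#'   \item{fig2_competition}{ASReLU plus a competing sigma/antisigma pair
#'     produced constitutively at rates `alpha` (sigma) and `beta`
#'     (antisigma), each from \{0, 0.5, 1\}. `gamma1` required.}
#'   \item{fig3_node}{Single perceptron, weights `[w1, -w2] = [1, -1]`,
#'     default `c_tot = 0.5` uM (the published panels state only the 0--1
#'     range).}
#'   \item{fig3_competition}{fig3_node plus a competitor with constitutive
#'     rates `alpha2`, `beta2` (published values 0 and 0.5).}
#'   \item{fig4a_two_node}{Two perceptrons sharing the pool: node1
#'     `[+1 bias, +x1, -x2]`, node2 `[-0.5 bias, +x1, +x2]`, so their
#'     isolated responses peak at (1,0) and (1,1) respectively and interfere
#'     where the other peaks.}
#'   \item{fig4e_bandstop}{Two-layer dual-region (band-stop) classifier:
#'     node1 `[-1.2, +1, +1]`, node2 `[+0.7, -1, -1]`, output node3
#'     `[-0.15, +4, +4]` on the layer-1 complexes.}
#'   \item{fig4h_bandpass}{Two-layer band-pass classifier: node1
#'     `[+bias1, -0.5, -0.5]` (default `bias1 = 0.4`; 0.2 and 0.3 are the
#'     published variants), node2 `[-0.8, +1.5, -0.5]`, node3
#'     `[-0.8, -0.5, +1.5]`, output node4 `[+0.3, -1, -1, -1]`.}
#'   \item{s2_coupled}{Single perceptron in coupled input--output mode: the
#'     housekeeping sigma (fixed at `s_c` uM) occupies the same pool to drive
#'     layer-1 production.}
#' }
#'
#' @param name Preset name; see [preset_names()].
#' @param gamma1 Sequestration rate (1/(uM h)); required for the `fig2_*`
#'   presets, preset-specific default otherwise.
#' @param c_tot Total polymerase (uM); preset-specific default.
#' @param alpha,beta Competitor production rates (uM/h) for
#'   `fig2_competition`.
#' @param alpha2,beta2 Competitor production rates for `fig3_competition`.
#' @param bias1 Node-1 bias (uM/h) for `fig4h_bandpass`.
#' @param s_c Housekeeping sigma concentration (uM) for `s2_coupled`.
#' @return A validated `bnn_network`.
#' @examples
#' load_preset("fig4e_bandstop")
#' load_preset("fig2_single", gamma1 = 1000)
#' @export
load_preset <- function(name, gamma1 = NULL, c_tot = NULL,
                        alpha = 0.5, beta = 0.5, alpha2 = 0.5, beta2 = 0.5,
                        bias1 = 0.4, s_c = 1) {
  name <- match.arg(name, preset_names())
  need_gamma1 <- startsWith(name, "fig2")
  if (need_gamma1 && is.null(gamma1))
    stop("preset '", name, "' requires an explicit gamma1 ",
         "(the published sweeps vary it; typical values 1, 10, 100, 1000)",
         call. = FALSE)
  g1 <- if (!is.null(gamma1)) gamma1 else
    switch(name,
           fig3_node = 100, fig3_competition = 100, fig4a_two_node = 100,
           fig4e_bandstop = 1000, fig4h_bandpass = 1000, s2_coupled = 1000)
  ct <- if (!is.null(c_tot)) c_tot else
    switch(name,
           fig2_single = 0,
           fig3_node = 0.5, fig3_competition = 0.5,
           0.2)
  kin <- kinetic_params(g1, 10, 1)

  nodes <- switch(
    name,
    fig2_single = ,
    fig2_resources = list(perceptron_node()),
    fig2_competition = list(perceptron_node(),
                            competitor_node("node2", alpha, beta)),
    fig3_node = list(perceptron_node()),
    fig3_competition = list(perceptron_node(),
                            competitor_node("node2", alpha2, beta2)),
    fig4a_two_node = list(
      node_spec("node1", 1L, bias = signed_weight(1, "+"),
                weights = list(x1 = signed_weight(1, "+"),
                               x2 = signed_weight(1, "-"))),
      node_spec("node2", 1L, bias = signed_weight(0.5, "-"),
                weights = list(x1 = signed_weight(1, "+"),
                               x2 = signed_weight(1, "+")))),
    fig4e_bandstop = list(
      node_spec("node1", 1L, bias = signed_weight(1.2, "-"),
                weights = list(x1 = signed_weight(1, "+"),
                               x2 = signed_weight(1, "+"))),
      node_spec("node2", 1L, bias = signed_weight(0.7, "+"),
                weights = list(x1 = signed_weight(1, "-"),
                               x2 = signed_weight(1, "-"))),
      node_spec("node3", 2L, bias = signed_weight(0.15, "-"),
                weights = list(node1 = signed_weight(4, "+"),
                               node2 = signed_weight(4, "+")))),
    fig4h_bandpass = list(
      node_spec("node1", 1L, bias = signed_weight(bias1, "+"),
                weights = list(x1 = signed_weight(0.5, "-"),
                               x2 = signed_weight(0.5, "-"))),
      node_spec("node2", 1L, bias = signed_weight(0.8, "-"),
                weights = list(x1 = signed_weight(1.5, "+"),
                               x2 = signed_weight(0.5, "-"))),
      node_spec("node3", 1L, bias = signed_weight(0.8, "-"),
                weights = list(x1 = signed_weight(0.5, "-"),
                               x2 = signed_weight(1.5, "+"))),
      node_spec("node4", 2L, bias = signed_weight(0.3, "+"),
                weights = list(node1 = signed_weight(1, "-"),
                               node2 = signed_weight(1, "-"),
                               node3 = signed_weight(1, "-")))),
    s2_coupled = list(perceptron_node()))

  validate_network(network_spec(
    nodes, c_tot = ct, kinetics = kin,
    coupling_mode = if (name == "s2_coupled") "coupled" else "uncoupled",
    s_c = s_c))
}

#' Generate a random valid feed-forward network (test fixture)
#'
#' Deterministic, seeded generator of small networks used for property and
#' solver cross-check tests: per-network rates log-uniform (`gamma1`,
#' `gamma2` in 0.1--1000 /(uM h); `delta` in 0.1--10 /h), weight magnitudes
#' uniform in 0--2 /h with random signs, biases uniform in 0--1 /h, and
#' `c_tot` uniform in 0.1--1 uM. Layer-2 nodes (when present) weight a random
#' nonempty subset of layer-1 complexes. The global RNG state is left
#' untouched.
#'
#' @param seed Integer seed; same seed, same network.
#' @param n_nodes Number of nodes, 1--4.
#' @param n_layers 1 or 2.
#' @return A validated `bnn_network`.
#' @export
generate_random_network <- function(seed, n_nodes = 2L, n_layers = 1L) {
  stopifnot(n_nodes >= 1L, n_nodes <= 4L, n_layers %in% c(1L, 2L))
  if (n_layers == 2L && n_nodes < 2L)
    stop("a 2-layer network needs at least 2 nodes", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  logunif <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  rsign <- function() sample(c("+", "-"), 1L)
  kin <- kinetic_params(logunif(0.1, 1000), logunif(0.1, 1000), logunif(0.1, 10))
  n_top <- if (n_layers == 2L) 1L else 0L
  n_bottom <- n_nodes - n_top
  ids <- paste0("node", seq_len(n_nodes))

  nodes <- lapply(seq_len(n_bottom), function(i) {
    node_spec(ids[i], 1L,
              bias = signed_weight(stats::runif(1), rsign()),
              weights = list(x1 = signed_weight(stats::runif(1, 0, 2), rsign()),
                             x2 = signed_weight(stats::runif(1, 0, 2), rsign())))
  })
  if (n_top == 1L) {
    k <- sample(n_bottom, 1L)
    src <- sort(sample(ids[seq_len(n_bottom)], k))
    w <- lapply(src, function(s) signed_weight(stats::runif(1, 0, 2), rsign()))
    names(w) <- src
    nodes <- c(nodes, list(
      node_spec(ids[n_nodes], 2L,
                bias = signed_weight(stats::runif(1), rsign()), weights = w)))
  }
  validate_network(network_spec(nodes, c_tot = stats::runif(1, 0.1, 1),
                                kinetics = kin))
}
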