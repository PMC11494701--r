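#' Kinetic rate constants for a sequestration node
#'
#' Bundles the three rate constants that govern a sigma/antisigma node:
#' the sigma--antisigma sequestration rate `gamma1`, the sigma--RNA-polymerase
#' complex-formation rate `gamma2` (both second order, in 1/(uM h)), and the
#' first-order degradation rate `delta` (1/h). All species are produced and
#' degraded in micromolar-and-hours units throughout the package.
#'
#' @param gamma1 Sequestration rate constant (1/(uM h)), strictly positive.
#' @param gamma2 Sigma--polymerase binding rate constant (1/(uM h)), strictly
#'   positive.
#' @param delta First-order degradation rate (1/h), strictly positive.
#' @return An object of class `bnn_kinetics`.
#' @examples
#' kinetic_params(gamma1 = 1000, gamma2 = 10, delta = 1)
#' @export
kinetic_params <- function(gamma1, gamma2 = 10, delta = 1) {
  for (nm in c("gamma1", "gamma2", "delta")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("kinetic parameter '", nm, "' must be a single finite positive number",
           call. = FALSE)
  }
  structure(list(gamma1 = gamma1, gamma2 = gamma2, delta = delta),
            class = "bnn_kinetics")
}

#' Signed production weight
#'
#' A weight attaches a production rate to a source species. The sign states
#' which partner the source drives: `"+"` produces the node's sigma factor,
#' `"-"` produces its antisigma. Magnitudes are production-rate constants in
#' 1/h (applied to a source concentration in uM they yield a flux in uM/h).
#'
#' @param w Nonnegative weight magnitude (1/h).
#' @param sign `"+"` (drives sigma production) or `"-"` (drives antisigma).
#' @return An object of class `bnn_weight`.
#' @examples
#' signed_weight(1.2, "-")
#' @export
signed_weight <- function(w, sign = "+") {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0)
    stop("weight magnitude must be a single finite nonnegative number", call. = FALSE)
  sign <- as.character(sign)
  if (!sign %in% c("+", "-"))
    stop("weight sign must be \"+\" or \"-\"", call. = FALSE)
  structure(list(w = w, sign = sign), class = "bnn_weight")
}

as_weight_list <- function(x, what = "bias") {
  if (is.null(x)) return(list())
  if (inherits(x, "bnn_weight")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "bnn_weight"))) return(x)
  stop(what, " must be a signed_weight or a list of signed_weights", call. = FALSE)
}

#' Specification of a single perceptron node
#'
#' A node is one sigma/antisigma pair. Its constitutive production (`bias`)
#' and per-source weights (`weights`) together define the production fluxes of
#' the sigma and the antisigma. Sources are either external inputs (`"x1"`,
#' `"x2"`, ...) or the ids of nodes in strictly lower layers, whose
#' sigma--polymerase complex concentration drives production downstream.
#' Constitutive terms act on a virtual input held at 1 uM, so a node can carry
#' several biases of either sign (e.g. a competitor producing both a sigma at
#' rate alpha and its antisigma at rate beta).
#'
#' @param id Unique node identifier (character).
#' @param layer Positive integer layer index (external inputs sit at layer 0).
#' @param bias A [signed_weight()] or list of them; constitutive production.
#' @param weights Named list of [signed_weight()]s; names are source ids.
#' @param kinetics Optional per-node [kinetic_params()] override.
#' @return An object of class `bnn_node`.
#' @export
node_spec <- function(id, layer, bias = NULL, weights = list(), kinetics = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("node id must be a nonempty character scalar", call. = FALSE)
  if (!is.numeric(layer) || length(layer) != 1L || layer < 1 || layer != round(layer))
    stop("node layer must be a positive integer", call. = FALSE)
  if (length(weights) && (is.null(names(weights)) || any(!nzchar(names(weights)))))
    stop("weights must be a named list keyed by source id", call. = FALSE)
  weights <- lapply(weights, function(sw) {
    if (!inherits(sw, "bnn_weight")) stop("each weight must be a signed_weight", call. = FALSE)
    sw
  })
  if (!is.null(kinetics) && !inherits(kinetics, "bnn_kinetics"))
    stop("kinetics must be created with kinetic_params()", call. = FALSE)
  structure(list(id = id, layer = as.integer(layer),
                 bias = as_weight_list(bias),
                 weights = weights, kinetics = kinetics),
            class = "bnn_node")
}

#' Specification of a feed-forward biomolecular network
#'
#' Collects the nodes, the total core RNA polymerase concentration `c_tot`
#' shared by every node, the number of external inputs, and the input--output
#' coupling mode. In `"coupled"` mode the production of layer-1 species is
#' driven by complexes of a housekeeping sigma factor (held at the fixed
#' concentration `s_c`) with the same polymerase pool, so the inputs themselves
#' consume shared resources.
#'
#' `c_tot = 0` is allowed and encodes the pure sequestration motif with no
#' polymerase pool (the free sigma is then the output of interest).
#'
#' @param nodes List of [node_spec()] objects.
#' @param c_tot Total core RNA polymerase concentration (uM), `>= 0`.
#' @param kinetics Default [kinetic_params()] applied to nodes without an
#'   override.
#' @param coupling_mode `"uncoupled"` (orthogonal-polymerase inputs, the
#'   default) or `"coupled"` (housekeeping-driven inputs).
#' @param n_inputs Number of external inputs (2 throughout the published
#'   designs).
#' @param s_c Housekeeping sigma concentration (uM), used in coupled mode.
#' @param output_node Optional id of the designated output node; defaults to
#'   the single node in the highest layer.
#' @return An unvalidated network description; pass to [validate_network()].
#' @seealso [validate_network()], [load_preset()]
#' @export
network_spec <- function(nodes, c_tot, kinetics = kinetic_params(1000, 10, 1),
                         coupling_mode = c("uncoupled", "coupled"),
                         n_inputs = 2L, s_c = 1, output_node = NULL) {
  coupling_mode <- match.arg(coupling_mode)
  structure(list(nodes = nodes, c_tot = c_tot, kinetics = kinetics,
                 coupling_mode = coupling_mode, n_inputs = as.integer(n_inputs),
                 s_c = s_c, output_node = output_node),
            class = "bnn_network")
}

input_names <- function(n_inputs) paste0("x", seq_len(n_inputs))

#' Validate and canonicalize a network specification
#'
#' Checks positivity of rates and `c_tot`, uniqueness of node ids, and the
#' feed-forward constraint that every weight source is an external input or a
#' node in a strictly lower layer (self-loops and same-layer or backward edges
#' are rejected). Nodes are returned sorted by `(layer, id)` so that two
#' specifications of the same network canonicalize identically.
#'
#' @param spec A network built with [network_spec()] or parsed from JSON.
#' @return The canonicalized network (class `bnn_network`), with attribute
#'   `validated = TRUE`.
#' @examples
#' net <- validate_network(load_preset("fig4e_bandstop"))
#' vapply(net$nodes, `[[`, integer(1), "layer")
#' @export
validate_network <- function(spec) {
  if (!inherits(spec, "bnn_network")) stop("not a bnn_network", call. = FALSE)
  if (!is.numeric(spec$c_tot) || length(spec$c_tot) != 1L ||
      !is.finite(spec$c_tot) || spec$c_tot < 0)
    stop("c_tot must be a single finite nonnegative number", call. = FALSE)
  if (!inherits(spec$kinetics, "bnn_kinetics"))
    stop("network default kinetics must be created with kinetic_params()", call. = FALSE)
  if (spec$n_inputs < 1L) stop("n_inputs must be at least 1", call. = FALSE)
  if (spec$coupling_mode == "coupled" &&
      (!is.numeric(spec$s_c) || length(spec$s_c) != 1L || spec$s_c < 0))
    stop("coupled mode requires a nonnegative housekeeping concentration s_c",
         call. = FALSE)
  if (!length(spec$nodes)) stop("network must contain at least one node", call. = FALSE)
  if (!all(vapply(spec$nodes, inherits, logical(1), "bnn_node")))
    stop("all nodes must be node_spec() objects", call. = FALSE)

  ids <- vapply(spec$nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate node id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  layers <- vapply(spec$nodes, `[[`, integer(1), "layer")
  ext <- input_names(spec$n_inputs)
  for (nd in spec$nodes) {
    for (src in names(nd$weights)) {
      if (src %in% ext) next
      j <- match(src, ids)
      if (is.na(j))
        stop("node '", nd$id, "' references unknown source '", src, "'", call. = FALSE)
      if (layers[j] >= nd$layer)
        stop("node '", nd$id, "' weights source '", src,
             "' in the same or a higher layer (network must be feed-forward)",
             call. = FALSE)
    }
  }

  ord <- order(layers, ids)
  spec$nodes <- spec$nodes[ord]
  top <- spec$nodes[layers[ord] == max(layers)]
  if (is.null(spec$output_node)) {
    spec$output_node <- top[[1L]]$id
  } else if (!spec$output_node %in% ids) {
    stop("output_node '", spec$output_node, "' is not a node id", call. = FALSE)
  }
  attr(spec, "validated") <- TRUE
  spec
}

node_kinetics <- function(network, node) {
  if (is.null(node$kinetics)) network$kinetics else node$kinetics
}

assert_validated <- function(network) {
  if (!isTRUE(attr(network, "validated"))) validate_network(network) else network
}

check_input <- function(network, x) {
  x <- as.numeric(x)
  if (length(x) != network$n_inputs)
    stop("input vector must have length n_inputs = ", network$n_inputs, call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("input concentrations must be finite and nonnegative", call. = FALSE)
  names(x) <- input_names(network$n_inputs)
  x
}

#' @export
print.bnn_network <- function(x, ...) {
  ids <- vapply(x$nodes, `[[`, character(1), "id")
  layers <- vapply(x$nodes, `[[`, integer(1), "layer")
  cat("<bnn_network> ", length(ids), " node(s), ", max(layers), " layer(s), ",
      x$n_inputs, " input(s)\n", sep = "")
  cat("  c_tot = ", x$c_tot, " uM, coupling: ", x$coupling_mode,
      ", output node: ", if (is.null(x$output_node)) ids[which.max(layers)] else x$output_node,
      "\n", sep = "")
  for (nd in x$nodes) {
    kin <- node_kinetics(x, nd)
    terms <- character(0)
    for (b in nd$bias) terms <- c(terms, sprintf("%s%.3g (bias)", b$sign, b$w))
    for (src in names(nd$weights))
      terms <- c(terms, sprintf("%s%.3g*%s", nd$weights[[src]]$sign,
                                nd$weights[[src]]$w, src))
    cat(sprintf("  [%d] %s: %s  (g1=%.3g, g2=%.3g, d=%.3g)\n", nd$layer, nd$id,
                if (length(terms)) paste(terms, collapse = ", ") else "(silent)",
                kin$gamma1, kin$gamma2, kin$delta))
  }
  invisible(x)
}

weight_to_json <- function(sw) list(w = sw$w, sign = sw$sign)

#' Serialize a network specification to JSON
#'
#' Writes the schema `{"c_tot", "coupling_mode", "n_inputs", "s_c",
#' "kinetics", "output_node", "nodes": [{"id", "layer", "bias", "weights",
#' "kinetics"}]}` with each weight as `{"w": number, "sign": "+"|"-"}`.
#' `bias` may be a single weight object or an array of them.
#'
#' @param network A (preferably validated) `bnn_network`.
#' @param path File path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @seealso [read_network_json()]
#' @export
write_network_json <- function(network, path = NULL) {
  network <- assert_validated(network)
  nodes <- lapply(network$nodes, function(nd) {
    out <- list(id = nd$id, layer = nd$layer,
                bias = lapply(nd$bias, weight_to_json),
                weights = lapply(nd$weights, weight_to_json))
    if (!is.null(nd$kinetics)) out$kinetics <- unclass(nd$kinetics)
    out
  })
  obj <- list(c_tot = network$c_tot,
              coupling_mode = network$coupling_mode,
              n_inputs = network$n_inputs,
              s_c = network$s_c,
              output_node = network$output_node,
              kinetics = unclass(network$kinetics),
              nodes = nodes)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Stable short hash of the canonical serialized network (rolling polynomial
# hash), recorded in map metadata so artifacts identify their network.
network_hash <- function(network) {
  bytes <- utf8ToInt(paste(write_network_json(network), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

json_to_weight <- function(obj, what = "weight") {
  if (is.null(obj$w) || is.null(obj$sign))
    stop("malformed ", what, " object in network JSON (need fields w, sign)",
         call. = FALSE)
  signed_weight(obj$w, obj$sign)
}

json_to_bias <- function(obj) {
  if (is.null(obj) || length(obj) == 0L) return(NULL)
  if (!is.null(obj$w)) return(json_to_weight(obj, "bias"))
  lapply(obj, json_to_weight, what = "bias")
}

#' Parse a network specification from JSON
#'
#' Inverse of [write_network_json()]; the result is validated before return.
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A validated `bnn_network`.
#' @export
read_network_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse network JSON: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(obj$c_tot) || is.null(obj$nodes))
    stop("network JSON must contain at least 'c_tot' and 'nodes'", call. = FALSE)
  kin <- if (is.null(obj$kinetics)) kinetic_params(1000, 10, 1)
         else kinetic_params(obj$kinetics$gamma1, obj$kinetics$gamma2, obj$kinetics$delta)
  nodes <- lapply(obj$nodes, function(nd) {
    if (is.null(nd$id) || is.null(nd$layer))
      stop("each node needs 'id' and 'layer' fields", call. = FALSE)
    node_spec(id = nd$id, layer = nd$layer,
              bias = json_to_bias(nd$bias),
              weights = lapply(nd$weights, json_to_weight),
              kinetics = if (is.null(nd$kinetics)) NULL
                         else kinetic_params(nd$kinetics$gamma1, nd$kinetics$gamma2,
                                             nd$kinetics$delta))
  })
  validate_network(network_spec(
    nodes = nodes, c_tot = obj$c_tot, kinetics = kin,
    coupling_mode = if (is.null(obj$coupling_mode)) "uncoupled" else obj$coupling_mode,
    n_inputs = if (is.null(obj$n_inputs)) 2L else obj$n_inputs,
    s_c = if (is.null(obj$s_c)) 1 else obj$s_c,
    output_node = obj$output_node))
}
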