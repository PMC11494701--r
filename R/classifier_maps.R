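#' Steady-state response map over an input grid
#'
#' Sweeps a square lattice of input concentrations `[0, x_max]^2` and records
#' every node's steady-state complex concentration. The default 51 x 51 grid
#' resolves the published decision boundaries; the algebraic solver makes the
#' sweep essentially instantaneous, and the integration solver is available as
#' a cross-check.
#'
#' @param network A validated `bnn_network` (2 external inputs).
#' @param resolution Grid points per axis, `>= 2`.
#' @param x_max Upper input concentration (uM).
#' @param solver `"algebraic"` or `"integration"`.
#' @return An object of class `bnn_response_map`: list with grid vectors
#'   `x1`, `x2`, arrays `c_bar` and `c_bar_norm` of dimension
#'   `resolution x resolution x n_nodes` (dimnames carry node ids; entry
#'   `[i, j, ]` is the response at `(x1[i], x2[j])`), a logical `flagged`
#'   matrix of non-converged points, and metadata (`r`, `c_tot`, solver).
#' @seealso [ideal_response_map()], [extract_decision_boundary()]
#' @export
response_map <- function(network, resolution = 51L, x_max = 1,
                         solver = c("algebraic", "integration")) {
  solver <- match.arg(solver)
  network <- assert_validated(network)
  if (network$n_inputs != 2L)
    stop("response maps are defined for networks with 2 external inputs",
         call. = FALSE)
  if (resolution < 2L) stop("resolution must be at least 2", call. = FALSE)
  grid <- seq(0, x_max, length.out = resolution)
  ids <- vapply(network$nodes, `[[`, character(1), "id")
  vals <- array(NA_real_, dim = c(resolution, resolution, length(ids)),
                dimnames = list(NULL, NULL, ids))
  flagged <- matrix(FALSE, resolution, resolution)
  for (j in seq_len(resolution)) {
    for (i in seq_len(resolution)) {
      ev <- evaluate_network(network, c(grid[i], grid[j]), method = solver)
      vals[i, j, ] <- ev$c_bar
      flagged[i, j] <- !ev$converged
    }
  }
  norm <- if (network$c_tot > 0) vals / network$c_tot else vals * NA_real_
  structure(list(x1 = grid, x2 = grid, c_bar = vals, c_bar_norm = norm,
                 nodes = ids, output_node = network$output_node,
                 flagged = flagged, ideal = FALSE,
                 meta = list(solver = solver, resolution = resolution,
                             x_max = x_max, c_tot = network$c_tot,
                             r = network$kinetics$gamma2 / network$kinetics$gamma1)),
            class = "bnn_response_map")
}

#' Ideal ReLU response map
#'
#' Same grid layout as [response_map()] but evaluated with
#' [ideal_relu_network()]: the resource-free design target. `c_bar_norm`
#' holds each node's map normalized by its own maximum (the ideal net has no
#' pool to normalize by).
#'
#' @inheritParams response_map
#' @return A `bnn_response_map` with `ideal = TRUE`.
#' @export
ideal_response_map <- function(network, resolution = 51L, x_max = 1) {
  network <- assert_validated(network)
  if (network$n_inputs != 2L)
    stop("response maps are defined for networks with 2 external inputs",
         call. = FALSE)
  grid <- seq(0, x_max, length.out = resolution)
  ids <- vapply(network$nodes, `[[`, character(1), "id")
  vals <- array(NA_real_, dim = c(resolution, resolution, length(ids)),
                dimnames = list(NULL, NULL, ids))
  for (j in seq_len(resolution)) {
    for (i in seq_len(resolution)) {
      vals[i, j, ] <- ideal_relu_network(network, c(grid[i], grid[j]))
    }
  }
  norm <- vals
  for (k in seq_along(ids)) {
    mx <- max(vals[, , k])
    norm[, , k] <- if (mx > 0) vals[, , k] / mx else 0
  }
  structure(list(x1 = grid, x2 = grid, c_bar = vals, c_bar_norm = norm,
                 nodes = ids, output_node = network$output_node,
                 flagged = matrix(FALSE, resolution, resolution), ideal = TRUE,
                 meta = list(solver = "ideal", resolution = resolution,
                             x_max = x_max, c_tot = NA_real_, r = 0)),
            class = "bnn_response_map")
}

#' @export
print.bnn_response_map <- function(x, ...) {
  cat("<bnn_response_map>", if (x$ideal) "(ideal)" else "",
      length(x$x1), "x", length(x$x2), "grid on [0,", max(x$x1), "]^2,",
      length(x$nodes), "node(s); solver:", x$meta$solver, "\n")
  for (k in x$nodes)
    cat(sprintf("  %s: max %.4g, argmax (%.3g, %.3g)\n", k,
                max(x$c_bar[, , k]),
                x$x1[which(x$c_bar[, , k] == max(x$c_bar[, , k]),
                           arr.ind = TRUE)[1, 1]],
                x$x2[which(x$c_bar[, , k] == max(x$c_bar[, , k]),
                           arr.ind = TRUE)[1, 2]]))
  if (any(x$flagged)) cat("  WARNING:", sum(x$flagged), "non-converged point(s)\n")
  invisible(x)
}

map_slice <- function(map, node = NULL) {
  if (is.null(node)) node <- map$output_node
  if (!node %in% map$nodes) stop("unknown node '", node, "'", call. = FALSE)
  map$c_bar[, , node]
}

# 4-connected component labelling of a logical matrix (iterative BFS).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    nr <- nrow(mask)
    while (length(queue)) {
      cell <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1L] >= 1L && nb[1L] <= nr && nb[2L] >= 1L && nb[2L] <= ncol(mask)) {
          k <- nb[1L] + (nb[2L] - 1L) * nr
          if (mask[k] && lab[k] == 0L) {
            lab[k] <- nxt
            queue <- c(queue, k)
          }
        }
      }
    }
  }
  lab
}

#' Extract a thresholded decision boundary from a response map
#'
#' The decision region is the set of grid cells whose response is at least
#' `theta` times the map maximum (ties included); the contour is the region's
#' 4-connected edge (region cells with at least one neighbour outside the
#' region or on the grid border). A map that is identically zero yields an
#' empty region with `empty = TRUE`.
#'
#' @param map A `bnn_response_map`.
#' @param theta Threshold fraction of the map maximum, in (0, 1).
#' @param node Node id; defaults to the map's output node.
#' @return An object of class `bnn_decision_boundary`: `region` (logical
#'   matrix), `n_components` (4-connected), `contour` (two-column matrix of
#'   cell indices), `threshold_value`, `empty`.
#' @export
extract_decision_boundary <- function(map, theta = 0.5, node = NULL) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)", call. = FALSE)
  vals <- map_slice(map, node)
  mx <- max(vals)
  if (mx <= 0) {
    return(structure(list(region = vals > 0, n_components = 0L,
                          contour = matrix(integer(0), 0, 2),
                          threshold = theta, threshold_value = 0, empty = TRUE),
                     class = "bnn_decision_boundary"))
  }
  region <- vals >= theta * mx
  lab <- label_components(region)
  pad <- matrix(FALSE, nrow(region) + 2L, ncol(region) + 2L)
  pad[2:(nrow(region) + 1L), 2:(ncol(region) + 1L)] <- region
  interior <- pad[1:nrow(region), 2:(ncol(region) + 1L)] &
    pad[3:(nrow(region) + 2L), 2:(ncol(region) + 1L)] &
    pad[2:(nrow(region) + 1L), 1:ncol(region)] &
    pad[2:(nrow(region) + 1L), 3:(ncol(region) + 2L)]
  contour <- which(region & !interior, arr.ind = TRUE)
  structure(list(region = region, n_components = max(lab),
                 contour = contour, threshold = theta,
                 threshold_value = theta * mx, empty = FALSE),
            class = "bnn_decision_boundary")
}

#' @export
print.bnn_decision_boundary <- function(x, ...) {
  cat("<bnn_decision_boundary> theta =", x$threshold,
      if (x$empty) "(empty: zero map)\n"
      else sprintf("; %d component(s), %d/%d cells in region\n",
                   x$n_components, sum(x$region), length(x$region)))
  invisible(x)
}

#' Overlap between two node response maps
#'
#' Each map is normalized by its own maximum and its support taken as the
#' cells exceeding `eps`; the metric is the Jaccard index of the two supports
#' (intersection over union), so identical maps score 1 and maps with
#' disjoint supports score 0. Used to check the design principle that nodes
#' in the same layer should not compete for resources in the same input
#' region.
#'
#' @param map_i,map_j Numeric matrices on the same grid (node slices of a
#'   `bnn_response_map`, see [map_slice_of()]).
#' @param eps Support threshold as a fraction of each map's own maximum.
#' @return Overlap in `[0, 1]` (0 when both supports are empty).
#' @export
overlap_metric <- function(map_i, map_j, eps = 0.1) {
  if (!all(dim(map_i) == dim(map_j)))
    stop("maps must share the same grid", call. = FALSE)
  supp <- function(m) {
    mx <- max(m)
    if (mx <= 0) m > 0 else m / mx > eps
  }
  si <- supp(map_i); sj <- supp(map_j)
  un <- sum(si | sj)
  if (un == 0L) return(0)
  sum(si & sj) / un
}

#' Extract one node's matrix from a response map
#'
#' @param map A `bnn_response_map`.
#' @param node Node id (default: output node).
#' @return Numeric matrix of steady-state complex concentrations.
#' @export
map_slice_of <- function(map, node = NULL) map_slice(map, node)

#' Deviation of a mechanistic map from its ideal design
#'
#' Both maps are normalized by their own maxima; reported are the maximum
#' absolute difference of the normalized maps and the fraction of grid cells
#' on which the two decision regions disagree. The mechanistic region is the
#' cells at or above `theta` of the map maximum. For an ideal
#' (resource-free) reference the region is the ideal map's support: a ReLU
#' unit is "on" wherever its output is positive, and its support contour is
#' the decision boundary drawn for the ideal design, whereas the saturating
#' mechanistic unit switches on over a narrow band so its `theta`-level set
#' tracks that same onset line. When both maps are mechanistic (e.g.
#' comparing two pool sizes) both regions use the `theta` threshold. A zero
#' ideal map facing a nonzero mechanistic map is a degenerate comparison and
#' is flagged rather than scored.
#'
#' @param map,ideal `bnn_response_map`s on the same grid (`ideal` typically
#'   from [ideal_response_map()]).
#' @param theta Threshold fraction for the region comparison.
#' @param node,ideal_node Node ids compared (default: each map's output node).
#' @return List with `max_abs_norm_diff`, `region_mismatch_fraction`,
#'   `degenerate`.
#' @export
deviation_from_ideal <- function(map, ideal, theta = 0.5, node = NULL,
                                 ideal_node = NULL) {
  a <- map_slice(map, node)
  b <- map_slice(ideal, ideal_node)
  if (!all(dim(a) == dim(b))) stop("maps must share the same grid", call. = FALSE)
  ma <- max(a); mb <- max(b)
  if (mb <= 0 && ma > 0)
    return(list(max_abs_norm_diff = NA_real_,
                region_mismatch_fraction = NA_real_, degenerate = TRUE))
  an <- if (ma > 0) a / ma else a
  bn <- if (mb > 0) b / mb else b
  ra <- if (ma > 0) an >= theta else an > 0
  rb <- if (isTRUE(ideal$ideal)) bn > 0 else if (mb > 0) bn >= theta else bn > 0
  list(max_abs_norm_diff = max(abs(an - bn)),
       region_mismatch_fraction = mean(ra != rb),
       degenerate = FALSE)
}

#' Write a response map to CSV with a JSON metadata sidecar
#'
#' The CSV is in long format with columns `x1, x2, node_id, c_bar,
#' c_bar_norm`; the sidecar records the network hash, solver, resolution and
#' grid range so a map is reproducible from its artifacts.
#'
#' @param map A `bnn_response_map`.
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path (default: `csv_path` with `.json`).
#' @param network Optional network whose serialized form is hashed into the
#'   metadata.
#' @return Invisibly, the long-format data.frame.
#' @export
write_response_map <- function(map, csv_path, json_path = NULL, network = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  res <- length(map$x1)
  rows <- do.call(rbind, lapply(map$nodes, function(k) {
    data.frame(x1 = rep(map$x1, times = res),
               x2 = rep(map$x2, each = res),
               node_id = k,
               c_bar = as.vector(map$c_bar[, , k]),
               c_bar_norm = as.vector(map$c_bar_norm[, , k]))
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
  meta <- map$meta
  meta$nodes <- map$nodes
  meta$output_node <- map$output_node
  meta$n_flagged <- sum(map$flagged)
  meta$ideal <- map$ideal
  if (!is.null(network)) meta$network_hash <- network_hash(network)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             json_path)
  invisible(rows)
}
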