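test_that("single-perceptron map peaks at (x1 -> 1, x2 -> 0)", {
  map <- response_map(load_preset("fig3_node"), 15)
  m <- map_slice_of(map, "node1")
  expect_identical(unname(which(m == max(m), arr.ind = TRUE)[1, ]), c(15L, 1L))
  expect_false(any(map$flagged))
  expect_true(all(m >= 0))
  expect_true(all(map$c_bar_norm <= 1 + 1e-9))
})

test_that("all-zero weights produce an identically zero map and empty boundary", {
  net <- validate_network(network_spec(list(node_spec("n", 1L)), c_tot = 0.2))
  map <- response_map(net, 7)
  expect_identical(max(map$c_bar), 0)
  db <- extract_decision_boundary(map)
  expect_true(db$empty)
  expect_identical(db$n_components, 0L)
  expect_identical(sum(db$region), 0L)
})

test_that("algebraic and integration maps agree pointwise", {
  net <- load_preset("fig3_competition")
  a <- response_map(net, 5)
  b <- response_map(net, 5, solver = "integration")
  expect_lt(max(abs(a$c_bar - b$c_bar)) / max(1, max(a$c_bar)), 1e-6)
})

test_that("decision regions: band-stop splits in two, band-pass stays whole", {
  ide <- ideal_response_map(load_preset("fig4e_bandstop"), 25)
  expect_identical(extract_decision_boundary(ide)$n_components, 2L)
  idh <- ideal_response_map(load_preset("fig4h_bandpass"), 25)
  expect_identical(extract_decision_boundary(idh)$n_components, 1L)
  # constant positive map: region is the whole grid, contour only the border
  const_map <- ide
  const_map$c_bar[, , "node3"] <- 1
  db <- extract_decision_boundary(const_map, node = "node3")
  expect_identical(sum(db$region), 25L * 25L)
  expect_identical(db$n_components, 1L)
  expect_identical(nrow(db$contour), 4L * 25L - 4L)
  expect_error(extract_decision_boundary(ide, theta = 1.2), "theta")
})

test_that("component labelling counts 4-connected regions, not diagonal ones", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE # diagonal touch: two components
  m[4, 4] <- TRUE; m[4, 5] <- TRUE; m[5, 4] <- TRUE # L-shape: one
  map <- list(x1 = 1:5, x2 = 1:5, c_bar = array(m * 1, c(5, 5, 1), list(NULL, NULL, "n")),
              nodes = "n", output_node = "n", ideal = FALSE)
  class(map) <- "bnn_response_map"
  expect_identical(extract_decision_boundary(map, theta = 0.5)$n_components, 3L)
})

test_that("overlap metric: identical maps 1, disjoint supports 0", {
  a <- matrix(runif(64), 8, 8)
  expect_identical(overlap_metric(a, a), 1)
  b <- matrix(0, 8, 8); b[1:4, ] <- 1
  d <- matrix(0, 8, 8); d[5:8, ] <- 1
  expect_identical(overlap_metric(b, d), 0)
  expect_identical(overlap_metric(matrix(0, 8, 8), matrix(0, 8, 8)), 0)
  expect_error(overlap_metric(a, matrix(0, 4, 4)), "same grid")
})

test_that("deviation from ideal is zero for self and flags degenerate pairs", {
  map <- response_map(load_preset("fig3_node"), 9)
  self <- deviation_from_ideal(map, map)
  expect_identical(self$max_abs_norm_diff, 0)
  expect_identical(self$region_mismatch_fraction, 0)
  expect_false(self$degenerate)
  zero_net <- validate_network(network_spec(list(node_spec("n", 1L)), c_tot = 0.2))
  zmap <- ideal_response_map(zero_net, 9)
  expect_true(deviation_from_ideal(map, zmap, node = "node1",
                                   ideal_node = "n")$degenerate)
})

test_that("interference raises the mechanistic deviation above the clean design", {
  dev_of <- function(net, res = 21) {
    deviation_from_ideal(response_map(net, res), ideal_response_map(net, res))
  }
  clean <- dev_of(load_preset("fig4e_bandstop"))
  noisy <- dev_of(load_preset("fig4a_two_node", gamma1 = 100))
  expect_gt(noisy$region_mismatch_fraction, clean$region_mismatch_fraction)
})

test_that("map CSV export is long-format and byte-stable", {
  map <- response_map(load_preset("fig3_node"), 5)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  rows <- write_response_map(map, f1, network = load_preset("fig3_node"))
  write_response_map(map, f2, network = load_preset("fig3_node"))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(nrow(rows), 25L)
  expect_named(rows, c("x1", "x2", "node_id", "c_bar", "c_bar_norm"))
  meta <- jsonlite::fromJSON(sub("\\.csv$", ".json", f1))
  expect_identical(meta$resolution, 5L)
  expect_match(meta$network_hash, "^[0-9a-f]+$")
})
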