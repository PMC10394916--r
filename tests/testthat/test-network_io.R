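test_that("read_network parses edge lists with comments and both separators", {
  f <- write_tmp(c("# interaction confidences", "A B 0.8", "B\tC\t0.9", ""))
  net <- read_network(f)
  expect_setequal(network_nodes(net), c("A", "B", "C"))
  expect_equal(network_edge_count(net), 2L)
  expect_equal(edge_weight(net, "A", "B"), 0.8)
  expect_equal(edge_weight(net, "C", "B"), 0.9)
  expect_equal(edge_weight(net, "A", "C"), 0)
})

test_that("self-loops are dropped with a warning", {
  f <- write_tmp(c("A A 0.5"))
  expect_warning(net <- read_network(f), "self-loop")
  expect_equal(network_nodes(net), "A")
  expect_equal(network_edge_count(net), 0L)
})

test_that("duplicate edges keep the maximum weight regardless of order", {
  f <- write_tmp(c("A B 0.3", "B A 0.7"))
  net <- read_network(f)
  expect_equal(network_edge_count(net), 1L)
  expect_equal(edge_weight(net, "A", "B"), 0.7)
})

test_that("malformed lines and bad weights are parse errors naming the line", {
  expect_error(read_network(write_tmp(c("A B 0.5", "A B"))), "line 2")
  expect_error(read_network(write_tmp(c("A B zero"))), "positive number")
  expect_error(read_network(write_tmp(c("A B -0.1"))), "positive number")
  expect_error(read_network(write_tmp(c("A B 0"))), "positive number")
})

test_that("write_network / read_network round-trip is identity", {
  net <- fixture_clique3()
  f <- withr::local_tempfile()
  write_network(net, f)
  back <- read_network(f)
  expect_equal(network_edges(back), network_edges(net))
  # isolated node Z is not representable in an edge list; everything else is
  expect_setequal(network_nodes(back), setdiff(network_nodes(net), "Z"))
})

test_that("read_complexes preserves order, dedupes members, skips blanks", {
  col <- read_complexes(write_tmp(c("A B C", "D E F G")))
  expect_length(col$members, 2)
  expect_equal(lengths(col$members), c(3L, 4L))
  expect_warning(col2 <- read_complexes(write_tmp(c("A A B", "", "C D"))),
                 "blank")
  expect_equal(col2$members[[1]], c("A", "B"))
  col7 <- read_complexes(write_tmp(sprintf("x%d y%d z%d", 1:7, 1:7, 1:7)))
  expect_length(col7$members, 7)
  expect_equal(col7$names, paste0("Cx", 1:7))
  expect_error(read_complexes(write_tmp(character(0))), "no complexes")
})

test_that("preprocess_complexes applies size, connectivity and merge rules", {
  net <- ppi_network(
    from = c("A", "B", "n1", "n1", "n2", "n3"),
    to   = c("B", "C", "n2", "n3", "n3", "n4"),
    weight = rep(0.9, 6), nodes = "X")
  col <- complex_collection(list(
    c("A", "B"),              # too small
    c("A", "B", "X"),         # X has no edge to A or B: disconnected
    c("n1", "n2", "n3"),      # jaccard 3/4 with next -> merged
    c("n1", "n2", "n3", "n4"),
    c("A", "B", "C", "ghost") # ghost removed, then {A,B,C} connected
  ))
  out <- preprocess_complexes(col, net)
  expect_length(out$members, 2)
  expect_true(list(c("n1", "n2", "n3", "n4")) %in% out$members ||
                any(vapply(out$members, identical,
                           TRUE, y = c("n1", "n2", "n3", "n4"))))
  expect_true(any(vapply(out$members, identical, TRUE,
                         y = c("A", "B", "C"))))
})

test_that("preprocess_complexes is idempotent and bounds pairwise Jaccard", {
  cfg <- planted_config(n_complexes = 6L, rng_seed = 11L,
                        disconnected = FALSE, inter_edge_prob = 0.05)
  sim <- generate_planted(cfg)
  # overlapping gold sets: duplicate some complexes with one node swapped
  mem <- sim$complexes$members
  extra <- lapply(mem[1:3], function(m) c(m[-1], mem[[4]][1]))
  col <- complex_collection(c(mem, extra))
  once <- preprocess_complexes(col, sim$network)
  twice <- preprocess_complexes(once, sim$network)
  expect_equal(twice$members, once$members)
  n <- length(once$members)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        expect_lte(jaccard(once$members[[i]], once$members[[j]]), 0.6)
      }
    }
  }
})

test_that("preprocessing merges a hand Jaccard pair (3/4 > 0.6)", {
  net <- ppi_network(c("1", "2", "3", "1"), c("2", "3", "4", "4"),
                     rep(1, 4))
  col <- complex_collection(list(c("1", "2", "3"), c("1", "2", "3", "4")))
  out <- preprocess_complexes(col, net)
  expect_length(out$members, 1)
  expect_equal(out$members[[1]], c("1", "2", "3", "4"))
})

test_that("value-table save/load round-trips exactly", {
  tab <- value_table()
  tab$values[c(3, 17)] <- c(0.125, -0.0625)
  tab$trained_on <- "unit test"
  f <- withr::local_tempfile(fileext = ".json")
  save_value_table(tab, f)
  back <- load_value_table(f)
  expect_identical(back$values, tab$values)
  expect_identical(back$gamma, tab$gamma)
  expect_identical(back$reward_correct, tab$reward_correct)
  expect_identical(back$reward_wrong, tab$reward_wrong)
  expect_identical(back$n_bins, tab$n_bins)

  # freshly initialized table round-trips as all zeros
  f2 <- withr::local_tempfile(fileext = ".json")
  save_value_table(value_table(), f2)
  expect_identical(load_value_table(f2)$values, numeric(20))

  # bin-count mismatch and field mismatch are errors
  expect_error(load_value_table(f, n_bins = 19), "19")
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$values <- obj$values[-1]
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f3, auto_unbox = TRUE, digits = NA)
  expect_error(load_value_table(f3), "19 values")
  expect_error(load_value_table(write_tmp("{}")), "not a value-table")
})

test_that("prediction files round-trip with their score column", {
  col <- complex_collection(list(c("A", "B", "C"), c("D", "E", "F")),
                            scores = c(0.35, 0.2))
  f <- withr::local_tempfile()
  write_complexes(col, f)
  back <- read_predictions(f)
  expect_equal(back$members, col$members)
  expect_equal(back$scores, col$scores)
})
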