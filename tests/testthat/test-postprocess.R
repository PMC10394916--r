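make_cand <- function(members, score) {
  structure(list(members = sort(members), score = score,
                 seed = sort(members)[1:2], trajectory = NULL,
                 density = NA_real_),
            class = "candidate_complex")
}

test_that("qi_overlap requires both ratios strictly above t", {
  expect_true(qi_overlap(c("A", "B", "C"), c("A", "B", "C", "E"), 0.5))
  expect_true(qi_overlap(c("A", "B"), c("A", "B"), 0.9))
  expect_false(qi_overlap(c("A", "B"), c("C", "D"), 0.2))
  # ratios 1.0 and 0.75: strict comparison fails at exactly t = 0.75
  expect_false(qi_overlap(c("A", "B", "C"), c("A", "B", "C", "E"), 0.75))
  expect_error(qi_overlap(character(0), "A", 0.5), "nonempty")
})

test_that("merge keeps one of two identical candidates and the retain-max rule", {
  net <- ppi_network(c("A", "A", "B", "C", "C", "E"),
                     c("B", "C", "C", "E", "D", "D"),
                     c(0.9, 0.9, 0.9, 0.8, 0.3, 0.2))
  tab <- value_table()
  dup <- list(make_cand(c("A", "B", "C"), 0.2),
              make_cand(c("A", "B", "C"), 0.2))
  expect_length(merge_candidates(dup, 0.5, tab, net), 1)

  # a={A,B,C} 0.2, b={A,B,C,E} 0.3; union == b scores highest -> survivor b
  ub <- density_state(c("A", "B", "C", "E"), net)
  tab$values[bin_index(ub$d) + 1] <- 0.3
  pair <- list(make_cand(c("A", "B", "C"), 0.2),
               make_cand(c("A", "B", "C", "E"), 0.3))
  out <- merge_candidates(pair, 0.5, tab, net)
  expect_length(out, 1)
  expect_equal(out[[1]]$members, c("A", "B", "C", "E"))
  expect_equal(out[[1]]$score, 0.3)

  # no qualifying pair: output == input (sorted)
  far <- list(make_cand(c("A", "B", "C"), 0.4),
              make_cand(c("C", "D", "E"), 0.1))
  expect_length(merge_candidates(far, 0.8, tab, net), 2)
})

test_that("merged output has no qualifying pair left and no duplicate sets", {
  set.seed(31)
  ids <- sprintf("p%02d", 1:15)
  pairs <- utils::combn(ids, 2)
  net <- ppi_network(pairs[1, ], pairs[2, ], runif(ncol(pairs), 0.3, 1))
  tab <- value_table()
  tab$values <- runif(20, 0, 0.4)
  for (t in c(0.25, 0.5)) {
    cands <- lapply(1:12, function(i) {
      make_cand(sample(ids, sample(3:6, 1)), runif(1, 0, 0.4))
    })
    out <- merge_candidates(cands, t, tab, net)
    keys <- vapply(out, function(cc) paste(cc$members, collapse = ","), "")
    expect_false(anyDuplicated(keys) > 0)
    n <- length(out)
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          expect_false(qi_overlap(out[[i]]$members, out[[j]]$members, t))
        }
      }
    }
  }
})

test_that("sweep returns the FMMF curve and its argmax", {
  net <- fixture_two_cliques()
  tab <- value_table()
  known <- complex_collection(list(c("A", "B", "C"), c("P", "Q", "R")))
  cands <- list(make_cand(c("A", "B", "C"), 0.3),
                make_cand(c("P", "Q", "R"), 0.3))
  # single threshold: best is that threshold
  one <- sweep_thresholds(cands, known, tab, net, thresholds = 0.4)
  expect_equal(one$best_threshold, 0.4)
  expect_equal(one$fmmf_per_threshold, 1)
  # disjoint candidates: merging never triggers, curve is flat
  sw <- sweep_thresholds(cands, known, tab, net,
                         thresholds = c(0.2, 0.5, 0.8))
  expect_equal(sw$fmmf_per_threshold, rep(1, 3))
  expect_equal(sw$best_threshold, 0.2)  # lowest on ties
  expect_error(sweep_thresholds(cands, known, tab, net,
                                thresholds = numeric(0)), "nonempty")
})

test_that("sweeping rescues duplicated noisy candidates on a planted fixture", {
  net <- fixture_two_cliques()
  known <- complex_collection(list(c("A", "B", "C"), c("P", "Q", "R")))
  tab <- value_table()
  d <- density_state(c("A", "B", "C"), net)$d
  tab$values[bin_index(d) + 1] <- 0.4
  # noisy duplicates: full cliques plus their 2/3 fragments
  cands <- list(make_cand(c("A", "B", "C"), 0.4),
                make_cand(c("A", "B"), 0.1),
                make_cand(c("B", "C"), 0.1),
                make_cand(c("P", "Q", "R"), 0.4),
                make_cand(c("P", "Q"), 0.1))
  sw <- sweep_thresholds(cands, known, tab, net,
                         thresholds = c(0.2, 0.5, 0.9))
  best <- max(sw$fmmf_per_threshold)
  expect_gte(best, sw$fmmf_per_threshold[sw$thresholds == 0.2][1])
  expect_gte(best, sw$fmmf_per_threshold[sw$thresholds == 0.9][1])
  # at a low threshold the fragments fold into the full cliques
  merged <- merge_candidates(cands, 0.5, tab, net)
  expect_setequal(lapply(merged, `[[`, "members"),
                  list(c("A", "B", "C"), c("P", "Q", "R")))
})
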