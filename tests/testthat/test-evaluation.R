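test_that("filter_to_known_nodes intersects with the gold universe", {
  known <- complex_collection(list(c("A", "B", "C"), c("D", "E", "F")))
  out <- filter_to_known_nodes(list(c("A", "B", "Z")), known)
  expect_length(out, 0)  # {A,B} after filtering, below min_size 3
  out2 <- filter_to_known_nodes(list(c("A", "B", "C", "Z"),
                                     c("D", "E", "F")), known)
  expect_equal(out2, list(c("A", "B", "C"), c("D", "E", "F")))
})

test_that("f_similarity matches the hand harmonic mean", {
  expect_equal(f_similarity(c("A", "B"), c("A", "B")), 1)
  expect_equal(f_similarity(c("A", "B", "C"), c("A", "B", "C", "E")), 6 / 7)
  expect_equal(f_similarity(c("A", "B"), c("C", "D")), 0)
  expect_error(f_similarity(character(0), "A"), "nonempty")
})

test_that("fmmf matches hand cases and the harmonic-mean identity", {
  known <- complex_collection(list(c("A", "B", "C", "E")))
  expect_equal(unname(fmmf(list(c("A", "B", "C", "E")), known)),
               c(1, 1, 1))
  fm <- fmmf(list(c("A", "B", "C")), known)
  expect_equal(unname(fm), rep(6 / 7, 3))
  # second prediction matches nothing: precision halves via the matching
  fm2 <- fmmf(list(c("A", "B", "C"), c("X", "Y", "Z")), known)
  expect_equal(fm2[["precision"]], 3 / 7)
  expect_equal(fm2[["recall"]], 6 / 7)
  expect_equal(fm2[["fscore"]], 4 / 7)
  expect_error(fmmf(list(), known), "nonempty")
})

test_that("fmmf matching equals brute-force enumeration up to 4x4", {
  set.seed(17)
  universe <- sprintf("u%02d", 1:12)
  for (rep in 1:25) {
    np <- sample(1:4, 1); nk <- sample(1:4, 1)
    pred <- random_member_sets(np, universe)
    known <- complex_collection(random_member_sets(nk, universe))
    W <- outer(seq_len(np), seq_len(nk), Vectorize(function(i, j) {
      brute_fsim(pred[[i]], known$members[[j]])
    }))
    expected_w <- brute_matching_weight(W)
    fm <- fmmf(pred, known)
    expect_equal(fm[["precision"]] * np, expected_w, tolerance = 1e-9)
    expect_equal(fm[["recall"]] * nk, expected_w, tolerance = 1e-9)
  }
})

test_that("cmmf matches hand case and a brute-force oracle", {
  known <- complex_collection(list(c("A", "B", "C", "E")))
  expect_equal(cmmf(list(c("A", "B", "C", "E")), known), 1)
  expect_equal(cmmf(list(c("A", "B", "C")), known), 6 / 7)
  # one perfect + one zero-similarity prediction: precision side halves
  known2 <- complex_collection(list(c("A", "B", "C")))
  val <- cmmf(list(c("A", "B", "C"), c("X", "Y", "Z")), known2)
  p <- mean(c(1, 0)); r <- 1
  expect_equal(val, 2 * p * r / (p + r))
  # random instances against first-principles recomputation
  set.seed(23)
  universe <- sprintf("u%02d", 1:10)
  for (rep in 1:10) {
    pred <- random_member_sets(3, universe)
    kn <- complex_collection(random_member_sets(2, universe))
    S <- outer(1:3, 1:2, Vectorize(function(i, j) {
      brute_fsim(pred[[i]], kn$members[[j]])
    }))
    p <- mean(apply(S, 1, max)); r <- mean(apply(S, 2, max))
    expect_equal(cmmf(pred, kn),
                 if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
})

test_that("spa/unspa match hand arithmetic and handle shared coverage", {
  known <- complex_collection(list(c("A", "B", "C")))
  out <- spa_unspa(list(c("A", "B")), known)
  expect_equal(out[["spa"]], sqrt(2 / 3))
  expect_equal(out[["unspa"]], sqrt(2 / 3))
  ident <- complex_collection(list(c("A", "B", "C"), c("D", "E", "F")))
  expect_equal(unname(spa_unspa(ident, ident)), c(1, 1))
  # one prediction spanning two known complexes: PPV < 1 despite coverage
  known2 <- complex_collection(list(c("A", "B", "C"), c("D", "E", "F")))
  pred <- list(c("A", "B", "C", "D", "E", "F"))
  out2 <- spa_unspa(pred, known2)
  # T = [3; 3]; Sn = 6/6 = 1; PPV = 3/6; by hand: SPA = sqrt(1 * 0.5)
  expect_equal(out2[["spa"]], sqrt(0.5))
  expect_equal(out2[["unspa"]], sqrt(1 * (3 / 6)))
})

test_that("qi_fscore applies the strict tau match rule", {
  known <- complex_collection(list(c("A", "B", "C", "E")))
  expect_equal(qi_fscore(list(c("A", "B", "C", "E")), known), 1)
  expect_equal(qi_fscore(list(c("A", "B", "C")), known, tau = 0.25), 1)
  expect_equal(qi_fscore(list(c("X", "Y", "Z")), known), 0)
  # ratio exactly tau does not match
  kn <- complex_collection(list(c("A", "B", "C", "D")))
  expect_equal(qi_fscore(list(c("A", "W", "X", "Y")), kn, tau = 0.25), 0)
})

test_that("kclique_fscores match hand subset counts", {
  known <- complex_collection(list(c("A", "B", "C", "E")))
  expect_equal(unname(kclique_fscores(list(c("A", "B", "C", "E")), known)),
               c(1, 1))
  out <- kclique_fscores(list(c("A", "B", "C")), known)
  # F2 = harmonic(3/3, 3/6) = 2/3; F3 = harmonic(1/1, 1/4) = 0.4;
  # k=4: known has 1 set, predicted none -> F4 = 0; k >= 5 skipped
  f2 <- 2 / 3; f3 <- 0.4
  expect_equal(out[["f_grand"]], mean(c(f2, f3, 0)))
  expect_equal(out[["f_weighted"]], (f2 * 6 + f3 * 4 + 0 * 1) / 11)
  expect_equal(unname(kclique_fscores(list(c("X", "Y", "Z")), known)),
               c(0, 0))
  big <- complex_collection(list(sprintf("g%02d", 1:25)))
  expect_warning(kclique_fscores(list(c("A", "B", "C")), big, size_cap = 20),
                 "larger than 20")
})

test_that("evaluate_all is 1.0 on identical collections and 0 after filtering", {
  col <- complex_collection(list(c("A", "B", "C"), c("D", "E", "F", "G")))
  rep_ <- evaluate_all(col, col)
  expect_true(all(abs(as.numeric(rep_[1, ]) - 1) < 1e-12))
  expect_warning(z <- evaluate_all(list(c("X", "Y", "Z")), col),
                 "filtered away")
  expect_true(all(as.numeric(z[1, ]) == 0))
})

test_that("every metric is order-invariant and within [0,1]", {
  set.seed(5)
  universe <- sprintf("u%02d", 1:14)
  pred <- random_member_sets(4, universe, min_size = 3)
  known <- complex_collection(random_member_sets(3, universe, min_size = 3))
  r1 <- suppressWarnings(evaluate_all(pred, known))
  perm_known <- complex_collection(known$members[c(3, 1, 2)])
  r2 <- suppressWarnings(evaluate_all(pred[c(2, 4, 1, 3)], perm_known))
  expect_equal(r1, r2)
  vals <- as.numeric(r1[1, ])
  expect_true(all(vals >= 0 & vals <= 1))
  # the F-score lies between its precision and recall components
  expect_gte(r1$fmm_fscore, min(r1$fmm_precision, r1$fmm_recall) - 1e-12)
  expect_lte(r1$fmm_fscore, max(r1$fmm_precision, r1$fmm_recall) + 1e-12)
})

test_that("a fixed 3-vs-2 fixture matches a first-principles recomputation", {
  # known universe covers every predicted member, so node filtering
  # (which evaluate_all applies first) is a no-op here
  pred <- list(c("A", "B", "C"), c("C", "D", "E"), c("F", "G", "H"))
  known <- complex_collection(list(c("A", "B", "C", "D"),
                                  c("E", "F", "G", "H")))
  rep_ <- evaluate_all(pred, known)
  # brute force every metric from scratch
  S <- outer(1:3, 1:2, Vectorize(function(i, j) {
    brute_fsim(pred[[i]], known$members[[j]])
  }))
  W <- brute_matching_weight(S)
  expect_equal(rep_$fmm_precision, W / 3)
  expect_equal(rep_$fmm_recall, W / 2)
  p <- mean(apply(S, 1, max)); r <- mean(apply(S, 2, max))
  expect_equal(rep_$cmmf, 2 * p * r / (p + r))
  T_ <- outer(1:2, 1:3, Vectorize(function(i, j) {
    length(intersect(known$members[[i]], pred[[j]]))
  }))
  expect_equal(rep_$spa,
               sqrt(sum(apply(T_, 1, max)) / sum(lengths(known$members)) *
                      sum(apply(T_, 2, max)) / sum(T_)))
  expect_equal(rep_$unspa,
               sqrt(mean(apply(T_, 1, max) / lengths(known$members)) *
                      mean(apply(T_, 2, max) / lengths(pred))))
})
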