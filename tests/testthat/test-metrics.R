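test_that("every shipped matrix converts to a valid normalized cost model", {
  for (name in builtin_matrices()) {
    m <- read_score_matrix(name)
    expect_true(isSymmetric(unname(m$M)))
    dm <- distance_model(m)
    expect_equal(unname(diag(dm$C)), rep(0, 20))
    expect_equal(dm$C, t(dm$C))
    expect_true(all(dm$C >= 0 & dm$C <= 1))
    expect_equal(max(dm$C), 1)
    # self first in every similarity ranking
    for (a in aa_alphabet())
      expect_identical(dm$neighbor_rank[[a]][1], a)
  }
})

test_that("cost normalization matches a brute-force scan of all pairs", {
  m <- read_score_matrix("BLOSUM62")
  dm <- distance_model(m)
  D <- outer(diag(m$M), diag(m$M), `+`) - 2 * m$M
  expect_equal(dm$D_max, max(D))
  expect_equal(dm$C["A", "R"],
               (m$M["A", "A"] + m$M["R", "R"] - 2 * m$M["A", "R"]) / max(D))
})

test_that("malformed matrix files are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("  A C", "A 4 0", "C 0"), f)
  expect_error(read_score_matrix(f), "malformed")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("  A C", "A 4 0", "C 0 9"), f2)
  expect_error(read_score_matrix(f2), "missing entries")
})

test_that("weighted edit distance equals the recursive oracle on all short pairs", {
  dm <- distance_model("BLOSUM50")
  letters3 <- c("A", "C", "D")
  strs <- ""
  for (len in 1:4)
    strs <- c(strs, apply(expand.grid(rep(list(letters3), len)), 1,
                          paste, collapse = ""))
  pairs <- expand.grid(a = strs, b = strs, stringsAsFactors = FALSE)
  ours <- mapply(weighted_edit_distance, pairs$a, pairs$b,
                 MoreArgs = list(model = dm))
  ref <- mapply(ed_oracle, pairs$a, pairs$b, MoreArgs = list(model = dm))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("unit-cost weighted edit distance is the classical Levenshtein distance", {
  um <- unit_cost_model()
  withr::with_seed(11, {
    a <- vapply(sample(0:12, 1000, replace = TRUE), random_seq, "")
    b <- vapply(sample(0:12, 1000, replace = TRUE), random_seq, "")
  })
  ours <- mapply(weighted_edit_distance, a, b, MoreArgs = list(model = um))
  classical <- diag(adist(a, b))
  expect_equal(unname(ours), as.numeric(classical))
})

test_that("distance is symmetric, zero on identity, and bounded by delete-all", {
  dm <- distance_model("BLOSUM62")
  withr::with_seed(5, {
    for (rep in 1:50) {
      a <- random_seq(sample(0:15, 1))
      b <- random_seq(sample(0:15, 1))
      dab <- weighted_edit_distance(a, b, dm)
      expect_equal(dab, weighted_edit_distance(b, a, dm))
      expect_lte(dab, dm$indel_cost * (nchar(a) + nchar(b)) + 1e-12)
      expect_equal(weighted_edit_distance(a, a, dm), 0)
    }
  })
  expect_equal(weighted_edit_distance("A", "", dm), 1)
})

test_that("expected substitution cost: unit matrix gives 1, closed form matches direct sum", {
  expect_equal(expected_substitution_cost(unit_cost_model()), 1)
  dm <- distance_model("BLOSUM50")
  # direct double sum over all 380 ordered pairs, uniform background
  tot <- 0
  for (i in aa_alphabet())
    for (j in aa_alphabet())
      if (i != j) tot <- tot + dm$C[i, j]
  expect_equal(expected_substitution_cost(dm), tot / 380)
  # monte-carlo audit within 3 standard errors of the closed form
  ec <- expected_substitution_cost(dm)
  mc <- expected_substitution_cost(dm, method = "monte_carlo",
                                   n_samples = 1e5, seed = 99)
  subs <- dm$C[row(dm$C) != col(dm$C)]
  se <- sd(subs) / sqrt(1e5 * 19 / 20)
  expect_lt(abs(mc - ec), 3 * se)
  expect_error(expected_substitution_cost(dm, background = c(A = 1)),
               "degenerate")
})

test_that("model building and expected cost are deterministic", {
  d1 <- distance_model("BLOSUM62")
  d2 <- distance_model("BLOSUM62")
  expect_identical(d1, d2)
  expect_identical(expected_substitution_cost(d1),
                   expected_substitution_cost(d2))
})

test_that("triangle inequality audit is empty for unit costs and self-consistent otherwise", {
  expect_identical(nrow(triangle_inequality_audit(unit_cost_model())), 0L)
  dm <- distance_model("BLOSUM50")
  viol <- triangle_inequality_audit(dm)
  # every reported violation re-checks against the raw costs
  if (nrow(viol) > 0) {
    for (r in seq_len(nrow(viol)))
      expect_gt(dm$C[viol$i[r], viol$k[r]],
                dm$C[viol$i[r], viol$j[r]] + dm$C[viol$j[r], viol$k[r]])
  }
  # and no violation was missed: exhaustive re-scan agrees on the count
  cnt <- 0
  for (i in aa_alphabet())
    for (j in aa_alphabet())
      for (k in aa_alphabet())
        if (dm$C[i, k] > dm$C[i, j] + dm$C[j, k] + 1e-12) cnt <- cnt + 1
  expect_identical(nrow(viol), as.integer(cnt))
})

test_that("unit-cost triangle inequality holds on random string triples", {
  um <- unit_cost_model()
  withr::with_seed(21, {
    for (rep in 1:30) {
      x <- random_seq(sample(1:10, 1))
      y <- random_seq(sample(1:10, 1))
      z <- random_seq(sample(1:10, 1))
      expect_lte(weighted_edit_distance(x, z, um),
                 weighted_edit_distance(x, y, um) +
                   weighted_edit_distance(y, z, um) + 1e-12)
    }
  })
})
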