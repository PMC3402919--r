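# exhaustive Steiner-repeat check for short strings under unit costs:
# fixed-length unit decomposition, consensus enumerated over the 3-letter
# sub-alphabet, distances from an independent classical implementation
brute_steiner_check <- function(s, p, mu, cc, letters = c("A", "C", "D")) {
  stopifnot(nchar(s) %% p == 0)
  t <- nchar(s) %/% p
  units <- substring(s, (0:(t - 1)) * p + 1, (1:t) * p)
  cand <- apply(expand.grid(rep(list(letters), p)), 1, paste, collapse = "")
  cond_a <- all(adist(units[-t], units[-1]) [cbind(1:(t - 1), 1:(t - 1))] <=
                  cc * mu * p + 1e-9)
  if (!cond_a) return(FALSE)
  any(vapply(cand, function(x)
    all(adist(x, units) <= mu * p + 1e-9), TRUE))
}

test_that("a perfect tandem array validates with zero divergence", {
  dm <- distance_model("BLOSUM62")
  unit <- "MKTAYIAW"
  s <- strrep(unit, 5)
  tr <- get_tr(s, nchar(unit), 1, dm, mu = 0.3, c = 1.5)
  expect_false(is.null(tr))
  expect_identical(tr$start, 1L)
  expect_identical(tr$end, nchar(s))
  expect_equal(tr$copy_number, 5)
  expect_identical(tr$consensus, unit)
  expect_equal(tr$divergence, 0)
  # perfect repeats verify even with a zero budget
  expect_true(verify_tr(tr, dm, mu = 0))
})

test_that("condition (a) flips exactly at its budget boundary", {
  um <- unit_cost_model()  # E_C = 1, distances integral
  L <- 20L; mu <- 0.4; cc <- 1.5  # (a) budget = 12, (b) budget = 8
  base <- strrep("A", L)
  flip <- function(s, at) {
    res <- strsplit(s, "")[[1]]; res[at] <- "C"
    paste(res, collapse = "")
  }
  make_pair <- function(m) {
    x1 <- base
    x2 <- Reduce(flip, 1:m, accumulate = FALSE, init = base)
    # midpoint certificate: first floor(m/2) differing columns from x2
    cons <- Reduce(flip, seq_len(m %/% 2), init = base)
    list(units = c(x1, x2), consensus = cons)
  }
  at_budget <- make_pair(12)   # pair distance 12 = c*mu*L exactly
  over <- make_pair(13)        # 13 > 12: condition (a) must reject
  expect_true(verify_tr(at_budget, um, mu = mu, c = cc))
  expect_false(verify_tr(over, um, mu = mu, c = cc))
  # the same certificates stay within (b): distances 6 and 7 vs budget 8
  expect_lte(as.numeric(adist(at_budget$consensus, at_budget$units[2])),
             mu * L)
})

test_that("condition (a) never rejects once mu >= 1/c", {
  um <- unit_cost_model()
  # with mu = 1/c the pairwise budget is c*mu*L*E_C = L, and two
  # equal-length units can never exceed distance L, so (a) cannot reject
  withr::with_seed(71, {
    for (rep in 1:25) {
      L <- sample(4:12, 1)
      a <- random_seq(L)
      b <- random_seq(L)
      d <- weighted_edit_distance(a, b, um)
      expect_lte(d, 1.5 * (1 / 1.5) * L * 1 + 1e-9)
    }
  })
})

test_that("reports are monotone in mu when condition (a) is vacuous", {
  dm <- distance_model("BLOSUM50")
  pl <- generate_planted_tr(200, "WKTAYIAWQRQ", 5, sub_rate = 0.1, seed = 5)
  tr <- get_tr(pl$seq, nchar(pl$unit), pl$start, dm, mu = 0.3, c = 1.5)
  expect_false(is.null(tr))
  for (mu2 in c(0.7, 0.8, 1)) # all >= 1/c
    expect_true(verify_tr(tr, dm, mu = mu2, c = 1.5))
})

test_that("verification is sound against exhaustive Steiner enumeration", {
  um <- unit_cost_model()
  n_true <- 0L; n_false <- 0L
  withr::with_seed(73, {
    cases <- list()
    for (rep in 1:40) {
      p <- sample(2:4, 1)
      t <- sample(2:4, 1)
      if (rep <= 20) {
        # near-perfect arrays: a repeat with at most one mutated position
        u <- random_seq(p, letters = c("A", "C", "D"))
        s <- strrep(u, t)
        if (runif(1) < 0.7) {
          at <- sample(nchar(s), 1)
          res <- strsplit(s, "")[[1]]
          res[at] <- sample(setdiff(c("A", "C", "D"), res[at]), 1)
          s <- paste(res, collapse = "")
        }
      } else {
        s <- random_seq(p * t, letters = c("A", "C", "D"))
      }
      cases[[rep]] <- list(s = s, p = p, t = t, mu = sample(c(0.2, 0.4), 1))
    }
  })
  for (cs in cases) {
    units <- substring(cs$s, (0:(cs$t - 1)) * cs$p + 1, (1:cs$t) * cs$p)
    ours <- verify_tr(list(units = units), um, mu = cs$mu, c = 1.5)
    brute <- brute_steiner_check(cs$s, cs$p, cs$mu, 1.5)
    # the center-star consensus is a certificate: it can only under-report
    if (ours) expect_true(brute)
    if (ours) n_true <- n_true + 1L else n_false <- n_false + 1L
    if (!brute) expect_false(ours)
  }
  expect_gt(n_true, 0L)
  expect_gt(n_false, 0L)
})

test_that("random sequences yield no repeat at moderate budgets", {
  dm <- distance_model("BLOSUM50")
  none <- 0L
  for (trial in 1:100) {
    s <- random_seq(100, seed = 4000 + trial)
    k <- 10 + (trial %% 10)
    tr <- get_tr(s, k, 30, dm, mu = 0.3, c = 1.5)
    if (is.null(tr)) none <- none + 1L
  }
  expect_gte(none, 99L)
})

test_that("a mutated planted repeat is recovered across most of its span", {
  dm <- distance_model("BLOSUM50")
  got <- 0L
  for (trial in 1:30) {
    pl <- generate_planted_tr(300, "MKTAYIAWQRQISFVKSHFS", 6,
                              sub_rate = 0.1, seed = 300 + trial)
    tr <- get_tr(pl$seq, nchar(pl$unit), pl$start + nchar(pl$unit), dm,
                 mu = 0.3, c = 1.5)
    if (!is.null(tr) &&
        min(tr$end, pl$end) - max(tr$start, pl$start) + 1 >=
          0.9 * (pl$end - pl$start + 1))
      got <- got + 1L
  }
  expect_gte(got, 27L)
})

test_that("reported repeats re-verify from scratch", {
  dm <- distance_model("BLOSUM50")
  pl <- generate_planted_tr(400, "ADKGYWQRNCEH", 7, sub_rate = 0.12,
                            indel_rate = 0.02, seed = 77)
  trs <- run_ptr_pipeline(pl$seq, tr_config())
  expect_gt(length(trs), 0)
  for (tr in trs) expect_true(verify_tr(tr, dm))
})

test_that("enclosure and shortest-period filters behave as specified", {
  mk <- function(start, end, period)
    list(start = start, end = end, period = as.integer(period))
  nested <- list(mk(10L, 100L, 10L), mk(20L, 60L, 10L))
  expect_identical(filter_maximal(nested), nested[1])
  disjoint <- list(mk(1L, 50L, 5L), mk(60L, 110L, 5L))
  expect_length(filter_maximal(disjoint), 2L)
  # identical spans, different periods: enclosure keeps both...
  same_span <- list(mk(1L, 80L, 8L), mk(1L, 80L, 4L))
  expect_length(filter_maximal(same_span), 2L)
  # ...and the shortest period wins the span
  kept <- filter_minp(same_span)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$period, 4L)
  # duplicates collapse to one
  dup <- list(mk(1L, 40L, 4L), mk(1L, 40L, 4L))
  expect_length(filter_minp(dup), 1L)
  # combined output is pairwise non-nested
  mixed <- list(mk(1L, 100L, 10L), mk(5L, 50L, 5L), mk(1L, 100L, 5L),
                mk(120L, 150L, 3L))
  out <- filter_minp(filter_maximal(mixed))
  spans <- vapply(out, function(t) c(t$start, t$end), c(0L, 0L))
  for (a in seq_len(ncol(spans)))
    for (b in seq_len(ncol(spans)))
      if (a != b)
        expect_false(spans[1, b] <= spans[1, a] && spans[2, b] >= spans[2, a])
})
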