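#' Grow a candidate tandem repeat from a seeded (period, position) pair
#'
#' Starting from the seed unit `seq[i .. i+k-1]`, the repeat is extended one
#' unit at a time, rightward and then leftward.  At each step the next
#' window is aligned against the current consensus (a single prefix DP gives
#' the distance of the consensus to every candidate unit end), the unit
#' length minimizing the weighted edit distance is chosen among lengths
#' within `max(2, ceiling(mu * p))` of the consensus length, and the unit is
#' accepted while its distance stays within `mu * |unit| * E_C` inflated by
#' a small growth slack (1.2 by default; final acceptance always re-checks
#' the strict budgets).  The consensus is re-derived after every acceptance.
#' A fractional trailing (and leading) unit is kept when its pro-rata budget
#' is met.  The finished candidate gets a center-star consensus (seeded by
#' the unit closest to all others) and is trimmed from the ends until it
#' passes [verify_tr()], or discarded.
#'
#' @param seq Character string (the full parent sequence).
#' @param k Candidate period.
#' @param i Candidate 1-based start position.
#' @param model A [distance_model()]; `E_C` is computed (uniform background)
#'   if unset.
#' @param mu Divergence budget, in `[0, 1]`.
#' @param c Consecutive-copy budget multiplier, in `[1, 2]`.
#' @param slack Growth slack multiplier applied during extension only.
#' @return A `tandem_repeat` object, or `NULL` when no valid repeat exists
#'   at this candidate.
#' @export
get_tr <- function(seq, k, i, model, mu = 0.3, c = 1.5, slack = 1.2) {
  model <- ensure_ec(model)
  get_tr_encoded(aa_encode(seq, warn = FALSE), k, i, model, mu, c, slack)
}

ensure_ec <- function(model, background = "uniform") {
  if (is.null(model$E_C))
    model$E_C <- expected_substitution_cost(model, background)
  model
}

TOL <- 1e-9

get_tr_encoded <- function(code, k, i, model, mu, cc, slack = 1.2) {
  n <- length(code)
  if (k < 1L || i < 1L || i + k - 1L > n) return(NULL)
  E <- model$E_C
  cons <- code[i:(i + k - 1L)]
  units <- list(cons)

  # rightward growth
  r <- extend_units(code, cons, units, j = i + k, model, mu, cc, E, slack)
  units <- r$units; cons <- r$cons
  partial_right <- find_partial(code, cons, r$j, model, mu, E)
  end <- r$j - 1L + length(partial_right)

  # leftward growth: identical procedure on the reversed sequence with the
  # reversed consensus (edit distance is reversal-invariant)
  rcode <- rev(code)
  l <- extend_units(rcode, rev(cons), lapply(rev(units), rev),
                    j = n - i + 2L, model, mu, cc, E, slack)
  n_left <- length(l$units) - length(units)
  if (n_left > 0L) {
    left_units <- lapply(l$units[length(l$units):(length(units) + 1L)], rev)
    units <- c(left_units, units)
    cons <- rev(l$cons)
  }
  partial_left <- rev(find_partial(rcode, l$cons, l$j, model, mu, E))
  start <- (n - (l$j - 1L) + 1L) - length(partial_left)

  # final consensus: center-star over the full units
  cons <- center_star_consensus(units, model)

  # alignment-optimal re-segmentation of the full-unit region against the
  # consensus (wraparound-style tandem alignment): greedy growth leaves
  # drifted unit boundaries that inflate unit-to-consensus distances
  for (iter in 1:2) {
    reg <- unlist(units)
    seg <- tandem_segment_cpp(reg, cons, model$Cx, model$indel_cost)
    if (seg$m >= 2L) {
      bnd <- c(seg$starts[!is.na(seg$starts)], length(reg) + 1L)
      if (length(bnd) >= 3L && bnd[1L] == 1L && !is.unsorted(bnd)) {
        new_units <- lapply(seq_len(length(bnd) - 1L), function(u)
          reg[bnd[u]:(bnd[u + 1L] - 1L)])
        new_units <- new_units[lengths(new_units) > 0L]
        if (length(new_units) >= 2L) units <- new_units
      }
    }
    cons <- center_star_consensus(units, model)
  }

  # strict verification; divergent units are trimmed from the ends, and an
  # interior violation splits the array, keeping the longer valid side
  repeat {
    if (length(units) < 2L) return(NULL)
    tr <- build_tr(code, start, units, partial_left, partial_right,
                   cons, model, mu, cc)
    v <- verify_details(tr, model, mu, cc)
    if (v$partial_left_bad) {
      start <- start + length(partial_left); partial_left <- integer(0)
      next
    }
    if (v$partial_right_bad) {
      partial_right <- integer(0)
      next
    }
    if (v$ok) return(tr)
    t <- length(units)
    if (v$bad_b[1L] || v$bad_a[1L]) {
      start <- start + length(partial_left) + length(units[[1L]])
      partial_left <- integer(0)
      units <- units[-1L]
    } else if (v$bad_b[t] || v$bad_a[t - 1L]) {
      partial_right <- integer(0)
      units <- units[-length(units)]
    } else {
      # interior offender: split there and keep the longer side
      u <- min(c(which(v$bad_b), which(v$bad_a) + 1L))
      left <- units[seq_len(u - 1L)]
      right <- units[u:t][-1L]
      if (v$bad_a[u - 1L] && !v$bad_b[u]) right <- units[u:t]
      if (sum(lengths(left)) + length(partial_left) >=
            sum(lengths(right)) + length(partial_right)) {
        units <- left
        partial_right <- integer(0)
      } else {
        drop <- length(partial_left) +
          sum(lengths(units[seq_len(t - length(right))]))
        start <- start + drop
        partial_left <- integer(0)
        units <- right
      }
    }
    if (length(units) < 2L) return(NULL)
    cons <- center_star_consensus(units, model)
  }
}

# Greedy unit-by-unit extension at increasing positions; returns the grown
# unit list, the evolved consensus and the first unconsumed position.
# The growth gate uses the adjacent-copy budget c*mu*|unit|*E_C (times the
# slack): early in growth the consensus is dominated by the previous unit,
# so the measured distance behaves like a pair distance, and gating at the
# tighter per-unit budget truncates valid arrays.  Final acceptance
# re-checks the strict budgets.
extend_units <- function(code, cons, units, j, model, mu, cc, E, slack) {
  n <- length(code)
  repeat {
    Lc <- length(cons)
    if (j > n) break
    d <- max(2L, ceiling(mu * Lc))
    lmin <- max(1L, Lc - d)
    lmax <- min(n - j + 1L, Lc + d)
    if (lmax < lmin) break
    win <- code[j:(j + lmax - 1L)]
    D <- wed_table_cpp(cons, win, model$Cx, model$indel_cost)
    ls <- lmin:lmax
    dist <- D[Lc + 1L, ls + 1L]
    ok <- dist <= cc * mu * ls * E * slack + TOL
    if (!any(ok)) break
    cand <- ls[ok]
    dc <- dist[ok]
    pick <- order(dc, abs(cand - Lc), cand)[1L]
    l <- cand[pick]
    units[[length(units) + 1L]] <- code[j:(j + l - 1L)]
    j <- j + l
    cons <- consensus_cpp(units, cons, model$Cx, model$indel_cost, 20L)
    if (length(cons) == 0L) break
  }
  list(units = units, cons = cons, j = j)
}

# Fractional unit at position j: longest segment matching the consensus
# prefix of the same length within the strict pro-rata budget.
find_partial <- function(code, cons, j, model, mu, E) {
  n <- length(code)
  maxl <- min(length(cons) - 1L, n - j + 1L)
  if (maxl < 1L) return(integer(0))
  D <- wed_table_cpp(cons, code[j:(j + maxl - 1L)], model$Cx,
                     model$indel_cost)
  for (l in maxl:1) {
    if (D[l + 1L, l + 1L] <= mu * l * E + TOL)
      return(code[j:(j + l - 1L)])
  }
  integer(0)
}

center_star_consensus <- function(units, model) {
  t <- length(units)
  if (t == 1L) return(units[[1L]])
  tot <- numeric(t)
  for (u in seq_len(t))
    for (v in seq_len(t))
      if (u != v)
        tot[u] <- tot[u] + wed_cpp(units[[u]], units[[v]], model$Cx,
                                   model$indel_cost)
  center <- units[[which.min(tot)]]
  consensus_cpp(units, center, model$Cx, model$indel_cost, 20L)
}

build_tr <- function(code, start, units, partial_left, partial_right,
                     cons, model, mu, cc) {
  start <- as.integer(start)
  span <- length(partial_left) + sum(lengths(units)) + length(partial_right)
  end <- start + span - 1L
  p <- length(cons)
  E <- model$E_C
  div <- vapply(units, function(u)
    wed_cpp(cons, u, model$Cx, model$indel_cost) / (length(u) * E), 0)
  structure(list(
    seq_id = NA_character_,
    start = start, end = end,
    period = p,
    units = units,
    partial_left = partial_left,
    partial_right = partial_right,
    consensus = aa_decode(cons),
    consensus_code = cons,
    copy_number = span / p,
    divergence = mean(div),
    mu = mu, c = cc), class = "tandem_repeat")
}

#' @export
print.tandem_repeat <- function(x, ...) {
  cat(sprintf("<tandem_repeat> [%d-%d] period %d x %.1f copies, consensus %s, divergence %.3f\n",
              x$start, x$end, x$period, x$copy_number,
              if (nchar(x$consensus) > 30)
                paste0(substr(x$consensus, 1, 27), "...") else x$consensus,
              x$divergence))
  invisible(x)
}

#' Verify a candidate tandem repeat against the weighted Steiner criterion
#'
#' A repeat `x_1 x_2 .. x_t` is valid when (a) every consecutive pair of
#' full units satisfies `d(x_i, x_{i+1}) <= c * mu * |x_i| * E_C` and (b)
#' every full unit is within `mu * |x_i| * E_C` of the consensus, which
#' certifies the existence of a Steiner string within budget.  A fractional
#' leading/trailing unit of length l is checked pro-rata against the
#' matching consensus suffix/prefix with budget `mu * l * E_C`.  Condition
#' (a) normalizes by the first unit of each pair, as defined, and is vacuous
#' when `mu >= 1/c`.
#'
#' @param tr A `tandem_repeat` from [get_tr()], or a list with at least
#'   `units` (character vector or list of strings) and optionally
#'   `consensus` (computed center-star if absent) and
#'   `partial_left`/`partial_right`.
#' @param model A [distance_model()].
#' @param mu,c Budget parameters (defaults taken from the object when
#'   present).
#' @return Logical flag.
#' @export
verify_tr <- function(tr, model, mu = NULL, c = NULL) {
  model <- ensure_ec(model)
  tr <- canonicalize_tr(tr, model)
  if (is.null(mu)) mu <- tr$mu
  if (is.null(c)) c <- tr$c
  stopifnot(is.numeric(mu), is.numeric(c))
  v <- verify_details(tr, model, mu, c)
  v$ok && !v$partial_left_bad && !v$partial_right_bad
}

canonicalize_tr <- function(tr, model) {
  if (is.character(tr$units))
    tr$units <- as.list(tr$units)
  if (is.character(tr$units[[1L]]))
    tr$units <- lapply(tr$units, aa_encode, warn = FALSE)
  if (is.null(tr$consensus_code)) {
    tr$consensus_code <- if (!is.null(tr$consensus))
      aa_encode(tr$consensus, warn = FALSE)
    else center_star_consensus(tr$units, model)
  }
  if (is.character(tr$partial_left))
    tr$partial_left <- aa_encode(tr$partial_left, warn = FALSE)
  if (is.character(tr$partial_right))
    tr$partial_right <- aa_encode(tr$partial_right, warn = FALSE)
  tr
}

verify_details <- function(tr, model, mu, cc) {
  units <- tr$units
  cons <- tr$consensus_code
  E <- model$E_C
  t <- length(units)
  out <- list(ok = FALSE, bad_b = TRUE, bad_a = logical(0),
              partial_left_bad = FALSE, partial_right_bad = FALSE)
  if (t < 2L) return(out)
  bad_b <- logical(t)
  for (u in seq_len(t))
    bad_b[u] <- wed_cpp(cons, units[[u]], model$Cx, model$indel_cost) >
      mu * length(units[[u]]) * E + TOL
  bad_a <- logical(max(t - 1L, 0L))
  for (u in seq_len(t - 1L))
    bad_a[u] <- wed_cpp(units[[u]], units[[u + 1L]], model$Cx,
                        model$indel_cost) >
      cc * mu * length(units[[u]]) * E + TOL
  pl <- tr$partial_left
  if (length(pl) > 0L) {
    suff <- cons[(length(cons) - length(pl) + 1L):length(cons)]
    out$partial_left_bad <-
      wed_cpp(suff, pl, model$Cx, model$indel_cost) >
        mu * length(pl) * E + TOL
  }
  pr <- tr$partial_right
  if (length(pr) > 0L) {
    pref <- cons[seq_along(pr)]
    out$partial_right_bad <-
      wed_cpp(pref, pr, model$Cx, model$indel_cost) >
        mu * length(pr) * E + TOL
  }
  out$bad_b <- bad_b
  out$bad_a <- bad_a
  out$ok <- !any(bad_b) && !any(bad_a)
  out
}

#' Drop tandem repeats completely enclosed in another
#'
#' @param trs List of `tandem_repeat` objects for one sequence.
#' @return Filtered list: no repeat's span is strictly contained in
#'   another's (equal spans both survive; see [filter_minp()]).
#' @export
filter_maximal <- function(trs) {
  if (length(trs) < 2L) return(trs)
  starts <- vapply(trs, `[[`, 0L, "start")
  ends <- vapply(trs, `[[`, 0L, "end")
  keep <- vapply(seq_along(trs), function(a) {
    !any(starts <= starts[a] & ends >= ends[a] &
           (starts != starts[a] | ends != ends[a]))
  }, TRUE)
  trs[keep]
}

#' Among repeats with identical span, keep the shortest period
#'
#' @param trs List of `tandem_repeat` objects.
#' @return Filtered list with one repeat per distinct span.
#' @export
filter_minp <- function(trs) {
  if (length(trs) < 2L) return(trs)
  key <- vapply(trs, function(t) paste(t$start, t$end), "")
  p <- vapply(trs, `[[`, 0L, "period")
  sel <- tapply(seq_along(trs), key, function(idx) idx[which.min(p[idx])])
  trs[sort(unlist(sel))]
}
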