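#' Create an empty period-weighting state
#'
#' Holds the anti-smear weights `w0`, the multiplicity weights `w1`, and the
#' bounded queue `Q` of recently detected distances.  One state is used per
#' sequence block; the queue starts empty at each block.
#'
#' @param max_period Largest period that can be observed (the block length).
#' @param h Hits recorded per probe (default 5).
#' @param H Queue capacity (default 20).
#' @param L Number of top-ranked periods retained (default 50).
#' @return An object of class `period_weight_state`.
#' @export
period_weight_state <- function(max_period, h = 5L, H = 20L, L = 50L) {
  structure(list(w0 = numeric(max_period), w1 = NULL, Q = integer(0),
                 h = as.integer(h), H = as.integer(H), L = as.integer(L)),
            class = "period_weight_state")
}

#' @export
print.period_weight_state <- function(x, ...) {
  cat("<period_weight_state>", sum(x$w0 > 0), "periods weighted, |Q| =",
      length(x$Q), "/", x$H, "\n")
  invisible(x)
}

#' Anti-smear weight update for one probe
#'
#' Indels between two matching probes shift the detected period, smearing
#' the period histogram around the true value.  The anti-smear rule credits
#' a detected period `k_g` with `sum_{k in Q} 2^-|k_g - k|`, where `Q` holds
#' the last `H` detected distances, so periods recurring near-by in the scan
#' reinforce each other with exponentially decaying influence.  All
#' increments for the probe are evaluated against the queue state *before*
#' this probe's values are enqueued (making the update order-independent
#' within the probe); afterwards the queue keeps the last `H` distances.
#'
#' @param state A [period_weight_state()].
#' @param k_list Periods detected at one probe position, in scan order
#'   (at most `h` of them).
#' @return The updated state.
#' @export
anti_smear_update <- function(state, k_list) {
  k_list <- as.integer(k_list)
  Q <- state$Q
  if (length(Q) > 0L) {
    for (kg in k_list)
      state$w0[kg] <- state$w0[kg] + sum(2^(-abs(kg - Q)))
  }
  Q <- c(Q, k_list)
  if (length(Q) > state$H) Q <- Q[(length(Q) - state$H + 1L):length(Q)]
  state$Q <- Q
  state
}

#' Multiplicity weighting of periods
#'
#' A repeat with many copies also produces matches at integer multiples of
#' its period; the multiplicity weight folds those back:
#' `w1(k) = sum_{m >= 1} w0(m k)`, summed over observed periods.
#'
#' @param state A [period_weight_state()] with `w0` populated.
#' @return The state with `w1` computed.
#' @export
multiplicity_weight <- function(state) {
  w0 <- state$w0
  w1 <- numeric(length(w0))
  # candidate periods are the observed ones; each observed multiple m*k
  # folds its weight back onto k
  support <- which(w0 > 0)
  for (k in support)
    w1[k] <- sum(w0[support[support %% k == 0L]])
  state$w1 <- w1
  state
}

#' Top-ranked candidate periods
#'
#' Periods sorted by multiplicity weight `w1`, decreasing; ties broken by
#' the smaller period; truncated to the state's `L`.
#'
#' @param state A [period_weight_state()] after [multiplicity_weight()].
#' @return Integer vector of at most `L` periods.
#' @export
get_top_periods <- function(state) {
  if (is.null(state$w1)) stop("call multiplicity_weight() first")
  cand <- which(state$w1 > 0)
  cand <- cand[order(-state$w1[cand], cand)]
  head(cand, state$L)
}

# Accumulate a scan-ordered hit stream into a weighting state.  The C++ fast
# path replicates anti_smear_update() probe by probe; `fast = FALSE` runs the
# R reference implementation (used to cross-check the fast path).
accumulate_hits <- function(state, hits, fast = TRUE) {
  if (nrow(hits) == 0L) return(multiplicity_weight(state))
  new_probe <- c(TRUE, diff(hits$pos) != 0L | diff(hits$shape) != 0L)
  pid <- cumsum(new_probe)
  if (fast) {
    state$w0 <- state$w0 +
      weight_accumulate_cpp(pid, hits$k, state$H, length(state$w0))
    state$Q <- utils::tail(hits$k, state$H)
  } else {
    for (ks in split(hits$k, pid)) state <- anti_smear_update(state, ks)
  }
  multiplicity_weight(state)
}
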