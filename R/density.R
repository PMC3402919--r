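#' Positions contributing to a candidate period
#'
#' A hit with period `m * k` (integer `m >= 1`) contributes to period `k`
#' through the multiplicity weighting; its first-probe position is taken,
#' and positions shared by several hit pairs are counted once.
#'
#' @param hits Hit table from [find_gapped_qgrams()].
#' @param k Candidate period.
#' @return Sorted integer vector of unique 1-based positions.
#' @export
collect_contributors <- function(hits, k) {
  sort(unique(hits$pos[hits$k %% k == 0L]))
}

#' Positional k-density candidate localization
#'
#' Let `f` be the 0/1 membership indicator of contributing positions along
#' the sequence and `F(i) = sum_{j=i}^{i+k-1} f(j)` its k-window smoothing.
#' Candidate start positions are those windows whose density reaches the
#' threshold `t(k) = alpha * mean(F)` (the mean taken over all window
#' positions, zero-density windows included).  A window must additionally
#' contain at least one contributing probe, so an empty contributor set
#' yields no candidates.
#'
#' @param seq_len Sequence (block) length.
#' @param k Candidate period.
#' @param contributors Positions from [collect_contributors()].
#' @param alpha Threshold proportionality constant (default 1).
#' @return Increasing integer vector of candidate 1-based start positions
#'   `i` with `i + k - 1 <= seq_len`.
#' @export
positional_density <- function(seq_len, k, contributors, alpha = 1) {
  if (alpha <= 0) stop("alpha must be positive")
  if (seq_len <= k) return(integer(0))
  f <- numeric(seq_len)
  f[contributors] <- 1
  cs <- c(0, cumsum(f))
  i <- seq_len(seq_len - k + 1L)
  F_win <- cs[i + k] - cs[i]
  t_k <- alpha * mean(F_win)
  i[F_win >= t_k - 1e-9 & F_win >= 1]
}

# Collapse runs of consecutive candidate positions, keeping the first of
# each maximal run: validation re-derives exact boundaries, so probing every
# in-run offset would only re-discover the same repeat.
coalesce_candidates <- function(positions) {
  if (length(positions) == 0L) return(integer(0))
  positions[c(TRUE, diff(positions) != 1L)]
}
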