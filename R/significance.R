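#' Shuffle-based significance of detected repeat lengths
#'
#' Pairs every input sequence with one composition-preserving shuffle, runs
#' the detector on both, and compares the longest reported repeat lengths
#' with a one-tailed Wilcoxon signed-rank test (alternative: original
#' longer than shuffled).  Lengths are floored at the 6-residue reporting
#' limit; pairs where neither run reports a repeat are ties and are
#' excluded, and zero differences after flooring are dropped as standard
#' signed-rank zero-differences.  A p-value below 0.05 rejects the null
#' that the detected repeat lengths are indistinguishable from what the
#' shuffled (composition-matched random) sequences produce.
#'
#' @param sequences Character vector of sequences (one length class), or a
#'   list of such vectors for several classes.
#' @param config A [tr_config()].
#' @param seed Master seed; per-pair shuffle seeds are derived as
#'   `(seed * 100003 + index) mod (2^31 - 1)`.
#' @return Data frame with one row per class: `class`, `n_pairs`,
#'   `n_ties_excluded`, `n_used`, `statistic` (V, the positive-rank sum) and
#'   `p_value` (one-tailed; `NA` when every pair is tied).
#' @export
wilcoxon_shuffle_test <- function(sequences, config = tr_config(),
                                  seed = 1L) {
  if (!is.list(sequences)) sequences <- list(all = sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("class", seq_along(sequences))
  rows <- lapply(names(sequences), function(cls) {
    seqs <- sequences[[cls]]
    orig <- numeric(0); shuf <- numeric(0); tie <- logical(0)
    for (idx in seq_along(seqs)) {
      s <- seqs[[idx]]
      pseed <- (seed * 100003 + idx) %% 2147483647
      ctrl <- shuffle_sequence(s, pseed)
      a <- longest_ftr(s, config)
      b <- longest_ftr(ctrl, config)
      orig <- c(orig, a$length)
      shuf <- c(shuf, b$length)
      tie <- c(tie, !a$found && !b$found)
    }
    w <- wilcoxon_signed_rank(orig[!tie], shuf[!tie])
    data.frame(class = cls, n_pairs = length(seqs),
               n_ties_excluded = sum(tie), n_used = w$n_used,
               statistic = w$statistic, p_value = w$p_value)
  })
  do.call(rbind, rows)
}

# One-tailed (greater) paired Wilcoxon signed-rank wrapper: zero differences
# dropped; exact null when stats::wilcox.test can use it, normal
# approximation otherwise.
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  keep <- d != 0
  n_used <- sum(keep)
  if (n_used == 0L)
    return(list(n_used = 0L, statistic = NA_real_, p_value = NA_real_))
  w <- suppressWarnings(
    wilcox.test(x[keep], y[keep], paired = TRUE, alternative = "greater"))
  list(n_used = n_used, statistic = unname(w$statistic),
       p_value = w$p.value)
}

#' Parameter sweep over shuffled-background repeat lengths
#'
#' Reproduces the tuning experiment structure: for every combination of
#' sequence length, `mu`, `c` and `z`, generate `n` random
#' composition-matched sequences, run the detector, and record the mean
#' length of the longest reported repeat (0 when nothing is found).  The
#' mean longest length grows with `mu` and with `c`; the sweep quantifies
#' the false-structure ceiling that detection thresholds must clear.
#'
#' @param lengths Sequence lengths (classes).
#' @param mu_values,c_values,z_values Parameter grids.
#' @param metric Metric passed to [tr_config()].
#' @param n Sequences per class.
#' @param seed Master seed.
#' @param composition Background composition for the random sequences.
#' @return Data frame with columns `length`, `mu`, `c`, `z` and
#'   `mean_longest`.
#' @export
parameter_sweep <- function(lengths, mu_values = 0.3, c_values = 1.5,
                            z_values = 1L, metric = "unit", n = 20L,
                            seed = 1L,
                            composition = proteome_composition()) {
  grid <- expand.grid(length = lengths, mu = mu_values, c = c_values,
                      z = z_values)
  seqs <- lapply(lengths, function(len)
    vapply(seq_len(n), function(i)
      random_protein(len, composition,
                     seed = (seed * 7919 + len * 1009 + i) %% 2147483647),
      ""))
  names(seqs) <- as.character(lengths)
  grid$mean_longest <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cfg <- tr_config(metric = metric, z = grid$z[r], mu = grid$mu[r],
                     c = grid$c[r])
    longest <- vapply(seqs[[as.character(grid$length[r])]], function(s) {
      trs <- run_ptr_pipeline(s, cfg)
      if (length(trs) == 0L) return(0)
      max(vapply(trs, function(t) t$end - t$start + 1L, 0L))
    }, 0)
    grid$mean_longest[r] <- mean(longest)
  }
  grid
}
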