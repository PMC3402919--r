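#' Detector configuration
#'
#' Bundles every tunable of the detection pipeline with its default.
#'
#' @param metric `"unit"` for the classical edit distance, the name of a
#'   packaged matrix (`"BLOSUM45"`, `"BLOSUM50"`, `"BLOSUM62"`, `"BLOSUM80"`,
#'   `"BLOSUM90"`), a path to an NCBI-format matrix file, or a ready
#'   [distance_model()].  Default `"BLOSUM50"`.
#' @param z Gapped q-gram ranking slack (1 = exact matching; 3 and 5 admit
#'   near-similar residues).
#' @param mu Divergence budget in `[0, 1]` (default 0.3).
#' @param c Consecutive-copy budget multiplier in `[1, 2]` (default 1.5;
#'   `c = 2` is the loose setting for low-divergence repeats).
#' @param L Number of top-weighted candidate periods examined (default 50).
#' @param block_len Block length for the scan, in residues (default 2000).
#' @param block_overlap Overlap between consecutive blocks (default
#'   `block_len / 2`); repeats crossing block borders are recovered because
#'   unit extension runs over the full sequence, not the block.
#' @param h Occurrences recorded per q-gram probe (default 5).
#' @param H Anti-smear queue capacity (default 20).
#' @param alpha Positional-density threshold constant (default 1).
#' @param include_2gram Add the (2,1)-seed `##` to the shape family?
#' @param min_total_len Minimum reported repeat length, residues (default 6).
#' @param background Residue background for `E_C`: `"uniform"` (default),
#'   `"sequence"` (composition of the scanned sequence) or a named
#'   frequency vector.
#' @param indel_cost Insertion/deletion cost (default 1).
#' @return An object of class `tr_config`.
#' @export
tr_config <- function(metric = "BLOSUM50", z = 1L, mu = 0.3, c = 1.5,
                      L = 50L, block_len = 2000L,
                      block_overlap = block_len %/% 2L,
                      h = 5L, H = 20L, alpha = 1,
                      include_2gram = FALSE, min_total_len = 6L,
                      background = "uniform", indel_cost = 1) {
  stopifnot(mu >= 0, mu <= 1, c >= 1, c <= 2, z >= 1, L >= 1,
            block_len > 1, block_overlap >= 0, block_overlap < block_len,
            h >= 1, H >= 1, alpha > 0, min_total_len >= 1)
  model <- if (inherits(metric, "distance_model")) metric
           else distance_model(metric, indel_cost)
  structure(list(model = model, z = as.integer(z), mu = mu, c = c,
                 L = as.integer(L), block_len = as.integer(block_len),
                 block_overlap = as.integer(block_overlap),
                 h = as.integer(h), H = as.integer(H), alpha = alpha,
                 include_2gram = include_2gram,
                 min_total_len = as.integer(min_total_len),
                 background = background),
            class = "tr_config")
}

#' @export
print.tr_config <- function(x, ...) {
  cat("<tr_config>", x$model$source,
      sprintf("| z=%d mu=%g c=%g L=%d block=%d/%d h=%d H=%d alpha=%g\n",
              x$z, x$mu, x$c, x$L, x$block_len, x$block_overlap, x$h, x$H,
              x$alpha))
  invisible(x)
}

#' Detect fuzzy tandem repeats in one sequence
#'
#' Runs the full detection pipeline on a single sequence: block splitting,
#' gapped q-gram scanning, anti-smear and multiplicity weighting, top-L
#' period selection, positional k-density localization, unit extension and
#' Steiner-consensus validation, then the enclosure and shortest-period
#' report filters.  Coordinates are 1-based inclusive in the input sequence.
#'
#' @param seq Character string over the amino-acid alphabet (ambiguity
#'   codes are remapped with a warning; X matches nothing and costs the
#'   maximal substitution).
#' @param config A [tr_config()].
#' @return List of `tandem_repeat` objects, sorted by start position.
#' @export
run_ptr_pipeline <- function(seq, config = tr_config()) {
  code <- aa_encode(seq)
  model <- config$model
  bg <- config$background
  if (identical(bg, "sequence")) {
    tab <- table(factor(c(AA_ALPHABET, "X")[pmin(code, 21L)],
                        levels = AA_ALPHABET))
    bg <- as.numeric(tab) / max(sum(tab), 1L)
    names(bg) <- AA_ALPHABET
    if (sum(bg) == 0) bg <- "uniform"
  }
  model <- ensure_ec(model, bg)
  n <- length(code)
  shapes <- tr_shapes(config$include_2gram)
  min_span <- min(vapply(shapes, `[[`, 0L, "s"))
  if (n < min_span + 2L) {
    warning("sequence too short to scan (", n, " residues)")
    return(list())
  }

  step <- config$block_len - config$block_overlap
  starts <- seq.int(1L, max(n - config$block_overlap, 1L), by = step)
  starts <- starts[starts <= n]

  trs <- list()
  seen <- character(0)
  for (bs in starts) {
    be <- min(bs + config$block_len - 1L, n)
    block <- code[bs:be]
    hits <- scan_encoded(block, shapes, config$z, model, config$h)
    state <- period_weight_state(length(block), config$h, config$H, config$L)
    state <- accumulate_hits(state, hits)
    for (k in get_top_periods(state)) {
      contrib <- collect_contributors(hits, k)
      dens <- positional_density(length(block), k, contrib, config$alpha)
      cand <- coalesce_candidates(dens)
      # also probe the first contributing position of each candidate run:
      # the run start is a window position and may precede the repeat itself
      runs <- split(dens, cumsum(c(TRUE, diff(dens) != 1L)))
      anchors <- vapply(runs, function(r) {
        inside <- contrib[contrib >= min(r) & contrib <= max(r) + k - 1L]
        if (length(inside)) inside[1L] else min(r)
      }, 0L)
      cand <- sort(unique(c(cand, anchors)))
      for (ib in cand) {
        i <- bs + ib - 1L
        key <- paste(k, i)
        if (key %in% seen) next
        seen <- c(seen, key)
        if (covered_by(trs, i, k, config$mu)) next
        tr <- get_tr_encoded(code, k, i, model, config$mu, config$c)
        if (is.null(tr)) next
        if (tr$copy_number < 2 - TOL) next
        if (tr$end - tr$start + 1L < config$min_total_len) next
        trs[[length(trs) + 1L]] <- tr
      }
    }
    if (be >= n) break
  }
  # harmonic re-probing: a repeat whose base-period decomposition breaks at
  # a locally divergent copy can still be valid at twice or three times the
  # period (longer units average the divergence out), so re-seed accepted
  # repeats at small multiples of their period around their boundaries
  for (tr0 in trs) {
    p <- tr0$period
    for (mult in 2:4) {
      k <- mult * p
      if (k > n %/% 2L) next
      anchors <- c(tr0$start, tr0$start + p, tr0$start - p,
                   tr0$end - k + 1L, tr0$end - k - p + 1L)
      for (i in unique(pmax(1L, anchors))) {
        if (i + k - 1L > n) next
        key <- paste(k, i)
        if (key %in% seen) next
        seen <- c(seen, key)
        tr <- get_tr_encoded(code, k, i, model, config$mu, config$c)
        if (is.null(tr)) next
        if (tr$copy_number < 2 - TOL) next
        if (tr$end - tr$start + 1L < config$min_total_len) next
        trs[[length(trs) + 1L]] <- tr
      }
    }
  }
  trs <- filter_minp(filter_maximal(trs))
  trs <- merge_loci(trs)
  trs[order(vapply(trs, `[[`, 0L, "start"),
            vapply(trs, `[[`, 0L, "end"))]
}

# Reporting cleanup: shifted re-readings of one locus (same period, spans
# overlapping by more than half of the shorter) collapse to the longest
# span; ties break to the earlier start.  Distinct overlapping repeats with
# different periods are untouched.
merge_loci <- function(trs) {
  if (length(trs) < 2L) return(trs)
  spans <- vapply(trs, function(t) t$end - t$start + 1L, 0L)
  ord <- order(-spans, vapply(trs, `[[`, 0L, "start"))
  kept <- list()
  for (a in ord) {
    dup <- FALSE
    for (b in seq_along(kept)) {
      k <- kept[[b]]
      if (k$period != trs[[a]]$period) next
      ov <- min(k$end, trs[[a]]$end) - max(k$start, trs[[a]]$start) + 1L
      if (ov > 0.5 * min(k$end - k$start + 1L, spans[a])) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- trs[[a]]
  }
  kept
}

# Cheap candidate pruning: a (k, i) whose whole seed window lies strictly
# inside an accepted repeat of a harmonically related period, away from its
# ends, would only re-derive that repeat.  Candidates near a repeat's ends
# are kept: they may extend it further.
covered_by <- function(trs, i, k, mu) {
  margin <- ceiling(mu * k) + 1L
  for (t in trs) {
    if (i >= t$start + margin && i + k - 1L <= t$end - margin &&
        (k %% t$period == 0L || t$period %% k == 0L))
      return(TRUE)
  }
  FALSE
}

#' Detect fuzzy tandem repeats in a set of sequences
#'
#' @param x A named character vector of sequences, a
#'   `Biostrings::AAStringSet`, or the path of a FASTA file.
#' @param config A [tr_config()].
#' @return A data frame with one row per reported repeat: `seq` (sequence
#'   id), `start`, `end` (1-based inclusive), `period`, `copies` (fractional,
#'   1 decimal), `total_len`, `consensus` and `divergence` (mean unit
#'   divergence relative to the budget scale).  An attribute `"n_sequences"`
#'   records how many sequences were scanned (needed by [scan_summary()]).
#' @export
detect_trs <- function(x, config = tr_config()) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readAAStringSet(x)
  if (inherits(x, "XStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- if (is.null(nm)) paste0("seq", seq_along(x)) else nm
  }
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  rows <- list()
  for (id in names(x)) {
    trs <- run_ptr_pipeline(x[[id]], config)
    for (tr in trs)
      rows[[length(rows) + 1L]] <- data.frame(
        seq = id, start = tr$start, end = tr$end, period = tr$period,
        copies = round(tr$copy_number, 1),
        total_len = tr$end - tr$start + 1L,
        consensus = tr$consensus,
        divergence = tr$divergence)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(seq = character(0), start = integer(0),
                         end = integer(0), period = integer(0),
                         copies = numeric(0), total_len = integer(0),
                         consensus = character(0), divergence = numeric(0))
  out <- out[order(out$seq, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sequences") <- length(x)
  out
}

#' Fraction of sequences containing a long repeat
#'
#' Corpus-level summary: the percentage of scanned sequences containing at
#' least one reported repeat of total length at least `min_len`.
#'
#' @param tr_table Result of [detect_trs()] (or a data frame with `seq` and
#'   `total_len` columns).
#' @param min_len Length threshold in residues (14, 20, 30 and 40 are the
#'   conventional reporting thresholds).
#' @param n_sequences Total number of scanned sequences; taken from the
#'   `"n_sequences"` attribute of `tr_table` when absent.
#' @return A percentage in `[0, 100]`.
#' @export
scan_summary <- function(tr_table, min_len = 14, n_sequences = NULL) {
  if (is.null(n_sequences)) n_sequences <- attr(tr_table, "n_sequences")
  if (is.null(n_sequences) || n_sequences < 1)
    stop("empty corpus: n_sequences must be a positive count")
  hit <- unique(tr_table$seq[tr_table$total_len >= min_len])
  100 * length(hit) / n_sequences
}

#' Write a repeat table as TSV
#'
#' @param tr_table Result of [detect_trs()].
#' @param path Output file path (`""` for stdout).
#' @param zero_based Write 0-based inclusive coordinates instead of the
#'   1-based default.
#' @return Invisibly, the written data frame.
#' @export
write_tr_table <- function(tr_table, path = "", zero_based = FALSE) {
  out <- tr_table
  if (zero_based) {
    out$start <- out$start - 1L
    out$end <- out$end - 1L
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
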