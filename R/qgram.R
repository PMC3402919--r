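#' Enumerate the gapped q-gram seed family
#'
#' The period scan uses the complete family of 3-grams with span 2 to 4:
#' the (3,4)-shapes `##--#`, `#-#-#`, `#--##`, the (3,3)-shapes `#-##`,
#' `##-#`, and the ungapped (3,2)-shape `###` - six seeds in all.  A shape is
#' the set of sampled offsets; the first and last position of a shape are
#' always sampled.  The additional (2,1)-shape `##` can be appended but is
#' off by default (with two positions there is no "free" position, so its
#' homology test degenerates to exact equality and it mostly adds noise from
#' single-residue coincidences).
#'
#' @param include_2gram Append the (2,1)-shape `##`?
#' @return List of `tr_shape` objects, each with `q` (sampled positions),
#'   `s` (span) and `offsets` (0-based, starting at 0).
#' @export
tr_shapes <- function(include_2gram = FALSE) {
  shapes <- list()
  for (s in c(4L, 3L, 2L))
    for (m in seq_len(s - 1L))
      shapes[[length(shapes) + 1L]] <-
        structure(list(q = 3L, s = s, offsets = c(0L, m, s)),
                  class = "tr_shape")
  if (include_2gram)
    shapes[[length(shapes) + 1L]] <-
      structure(list(q = 2L, s = 1L, offsets = c(0L, 1L)),
                class = "tr_shape")
  shapes
}

#' @export
print.tr_shape <- function(x, ...) {
  pic <- rep("-", x$s + 1L)
  pic[x$offsets + 1L] <- "#"
  cat("<tr_shape> (", x$q, ",", x$s, ") ", paste(pic, collapse = ""), "\n",
      sep = "")
  invisible(x)
}

#' Extract the residues a shape samples at a position
#'
#' @param seq Character string over the amino-acid alphabet.
#' @param shape A `tr_shape` from [tr_shapes()].
#' @param i 1-based start position; `i + shape$s` must not exceed the
#'   sequence length.
#' @return Character vector of `shape$q` residues.
#' @export
extract_gram <- function(seq, shape, i) {
  res <- strsplit(toupper(seq), "")[[1]]
  idx <- i + shape$offsets
  if (i < 1L || max(idx) > length(res))
    stop("gram position out of range: i = ", i, ", span = ", shape$s,
         ", length = ", length(res))
  res[idx]
}

#' Test whether two q-grams are homologous under ranking slack z
#'
#' Two 3-grams match when at least two positions carry identical residues
#' and the residue in the (at most one) differing position of each gram is
#' among the top-z most similar residues of the other, mutually, under the
#' model's similarity ranking.  `z = 1` demands exact identity.  For
#' 2-grams both positions must be identical.  A gram containing X never
#' matches anything.
#'
#' @param g1,g2 Character vectors of equal length (2 or 3), as returned by
#'   [extract_gram()].
#' @param z Ranking slack, a positive integer (1, 3, 5, ...).
#' @param model A [distance_model()].
#' @return Logical flag.
#' @export
grams_homologous <- function(g1, g2, z, model) {
  if (z < 1) stop("ranking slack z must be >= 1")
  a <- aa_encode(g1, warn = FALSE)
  b <- aa_encode(g2, warn = FALSE)
  stopifnot(length(a) == length(b), length(a) %in% c(2L, 3L))
  same <- a == b & a != X_CODE
  diffs <- which(!same)
  if (length(diffs) == 0L) return(TRUE)
  if (length(diffs) > 1L || length(a) == 2L) return(FALSE)
  ra <- g1[diffs]
  rb <- g2[diffs]
  if (ra == "X" || rb == "X") return(FALSE)
  rb %in% head(model$neighbor_rank[[ra]], z) &&
    ra %in% head(model$neighbor_rank[[rb]], z)
}

#' Scan a sequence for homologous gapped q-gram pairs
#'
#' For every shape and every start position i, the next `h_next` positions
#' j > i carrying a gram homologous to the one at i are recorded as hits
#' with period `k = j - i`.  Hits are returned in scan order (outer loop
#' over i, then shapes, then increasing j), which is the order the
#' anti-smear queue must consume them in.
#'
#' @param seq Character string.
#' @param shapes List of shapes from [tr_shapes()].
#' @param z Ranking slack (see [grams_homologous()]).
#' @param model A [distance_model()].
#' @param h_next Number of following occurrences recorded per probe
#'   (default 5).
#' @return Data frame with columns `pos` (1-based first-probe position),
#'   `k` (period) and `shape` (index into `shapes`).
#' @export
find_gapped_qgrams <- function(seq, shapes = tr_shapes(), z = 1,
                               model = unit_cost_model(), h_next = 5) {
  if (h_next < 1) stop("h_next must be >= 1")
  code <- aa_encode(seq, warn = FALSE)
  scan_encoded(code, shapes, z, model, h_next)
}

scan_encoded <- function(code, shapes, z, model, h_next) {
  zok <- z_compat(model, z)
  off <- lapply(shapes, `[[`, "offsets")
  hits <- scan_block_cpp(code, off, as.integer(h_next), zok, X_CODE)
  data.frame(pos = hits$pos, k = hits$k, shape = hits$shape)
}
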