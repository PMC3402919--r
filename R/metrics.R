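#' Read an amino-acid scoring matrix in NCBI text layout
#'
#' Parses the standard square matrix format used by BLAST and the original
#' BLOSUM distribution: comment lines starting with `#`, a header row of
#' residue letters, and one labelled row per residue.  Rows and columns for
#' the ambiguity codes B, Z, X and the stop `*` are read but excluded from
#' the canonical alphabet.
#'
#' @param path Path to a matrix file, or the name of a packaged matrix
#'   (`"BLOSUM45"`, `"BLOSUM50"`, `"BLOSUM62"`, `"BLOSUM80"`, `"BLOSUM90"`).
#' @return An object of class `substitution_matrix`: a list with `name`,
#'   `alphabet` (the 20 canonical letters, alphabetical) and `M`, the
#'   symmetric 20 x 20 integer similarity matrix.
#' @export
read_score_matrix <- function(path) {
  name <- path
  if (!file.exists(path)) {
    pkg_path <- system.file("extdata", "matrices", paste0(path, ".txt"),
                            package = "fuzzytr")
    if (!nzchar(pkg_path))
      stop("matrix file not found and not a packaged matrix: ", path)
    path <- pkg_path
  } else {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("malformed matrix file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1])))
  if (any(lengths(vals) != length(header)) || anyNA(unlist(vals)))
    stop("malformed matrix file: ragged or non-numeric rows in ", path)
  M_full <- do.call(rbind, vals)
  dimnames(M_full) <- list(labels, header)
  keep <- AA_ALPHABET
  if (!all(keep %in% labels) || !all(keep %in% header))
    stop("malformed matrix: missing entries for canonical residues")
  M <- M_full[keep, keep, drop = FALSE]
  if (!isTRUE(all.equal(M, t(M))))
    stop("malformed matrix: similarity scores are not symmetric")
  structure(list(name = name, alphabet = keep, M = M),
            class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix>", x$name, "-",
      nrow(x$M), "x", ncol(x$M), "similarity scores\n")
  invisible(x)
}

#' Names of the scoring matrices shipped with the package
#' @return Character vector of matrix names accepted by
#'   [read_score_matrix()] and [distance_model()].
#' @export
builtin_matrices <- function() {
  files <- list.files(system.file("extdata", "matrices", package = "fuzzytr"),
                      pattern = "\\.txt$")
  sub("\\.txt$", "", files)
}

#' Convert a similarity matrix into a normalized substitution-cost model
#'
#' A similarity score matrix `M` is turned into substitution costs
#' `C[i,j] = D[i,j] / D_max` with `D[i,j] = M[i,i] + M[j,j] - 2 M[i,j]` and
#' `D_max` the maximum of `D` over all residue pairs, so `C[i,i] = 0`,
#' `C` is symmetric, and the most distant pair has cost exactly 1.  The model
#' also carries per-residue similarity rankings (self first, then decreasing
#' similarity, ties broken alphabetically), used by the gapped q-gram
#' homology test, and an indel cost (1 by default).
#'
#' The expected substitution cost `E_C` is left unset; compute it with
#' [expected_substitution_cost()] (the detection pipeline does this
#' automatically).
#'
#' @param m A `substitution_matrix`, or a name/path accepted by
#'   [read_score_matrix()], or `"unit"` for the classical unweighted edit
#'   distance (every substitution costs 1).
#' @param indel_cost Cost of an insertion or deletion (default 1).
#' @return An object of class `distance_model` with elements `source`, `C`
#'   (20 x 20 costs in `[0,1]`), `Cx` (21 x 21, including the X row, where any
#'   substitution touching X costs 1), `D_max`, `indel_cost`, `E_C` (`NULL`
#'   until estimated) and `neighbor_rank`.
#' @export
distance_model <- function(m = "BLOSUM50", indel_cost = 1) {
  if (is.character(m) && length(m) == 1L && identical(m, "unit"))
    return(unit_cost_model(indel_cost))
  if (is.character(m)) m <- read_score_matrix(m)
  stopifnot(inherits(m, "substitution_matrix"))
  M <- m$M
  Dm <- outer(diag(M), diag(M), `+`) - 2 * M
  D_max <- max(Dm)
  C <- Dm / D_max
  dimnames(C) <- dimnames(M)
  nr <- lapply(AA_ALPHABET, function(a) {
    others <- setdiff(AA_ALPHABET, a)
    sims <- M[a, others]
    c(a, others[order(-sims, others)])
  })
  names(nr) <- AA_ALPHABET
  new_distance_model(m$name, C, D_max, indel_cost, nr)
}

#' @rdname distance_model
#' @export
unit_cost_model <- function(indel_cost = 1) {
  C <- 1 - diag(20)
  dimnames(C) <- list(AA_ALPHABET, AA_ALPHABET)
  # all non-self residues are equally (dis)similar; ranking falls back to
  # alphabetical order after self
  nr <- lapply(AA_ALPHABET, function(a) c(a, setdiff(AA_ALPHABET, a)))
  names(nr) <- AA_ALPHABET
  new_distance_model("unit", C, 2, indel_cost, nr)
}

new_distance_model <- function(source, C, D_max, indel_cost, neighbor_rank) {
  Cx <- matrix(1, 21, 21)
  Cx[1:20, 1:20] <- C
  Cx[21, 21] <- 0
  structure(list(source = source, C = C, Cx = Cx, D_max = D_max,
                 indel_cost = indel_cost, E_C = NULL,
                 neighbor_rank = neighbor_rank),
            class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat("<distance_model>", x$source,
      "| indel =", x$indel_cost,
      "| D_max =", x$D_max,
      "| E_C =", if (is.null(x$E_C)) "(unset)" else format(x$E_C, digits = 4),
      "\n")
  invisible(x)
}

#' Weighted edit distance between two amino-acid sequences
#'
#' Minimum total cost over edit scripts transforming `a` into `b`, where
#' insertions and deletions cost `model$indel_cost` and substituting residue
#' i for j costs `model$C[i,j]`.  With the unit-cost model this is the
#' classical Levenshtein distance.
#'
#' @param a,b Character strings (or vectors of single letters) over the
#'   amino-acid alphabet.
#' @param model A [distance_model()].
#' @return A single non-negative number; symmetric in `a`, `b`.
#' @export
weighted_edit_distance <- function(a, b, model) {
  wed_cpp(aa_encode(a), aa_encode(b), model$Cx, model$indel_cost)
}

#' Expected substitution cost under a background composition
#'
#' The per-substitution budget of the repeat definition scales with `E_C`,
#' the expected cost of substituting one residue for another, conditional on
#' the two residues differing:
#' `E_C = sum_{i != j} p_i p_j C[i,j] / sum_{i != j} p_i p_j`.
#' Conditioning on a true substitution makes the unit-cost matrix give
#' `E_C = 1` exactly, so the budget `mu * p * E_C` reduces to the classical
#' `mu * p` mismatch allowance.
#'
#' @param model A [distance_model()].
#' @param background Named residue frequency vector (positive, summing to 1),
#'   or `"uniform"` (default).
#' @param method `"closed_form"` (exact double sum, default) or
#'   `"monte_carlo"` (sampling audit of the closed form).
#' @param n_samples,seed Monte-Carlo sample count and RNG seed.
#' @return The expected substitution cost, in `(0, 1]`.
#' @export
expected_substitution_cost <- function(model, background = "uniform",
                                       method = c("closed_form", "monte_carlo"),
                                       n_samples = 1e5, seed = 1L) {
  method <- match.arg(method)
  p <- normalize_background(background)
  if (any(p >= 1 - 1e-12))
    stop("degenerate background: one residue has frequency 1")
  if (method == "closed_form") {
    P <- outer(p, p)
    diag(P) <- 0
    return(sum(P * model$C[names(p), names(p)]) / sum(P))
  }
  with_seed(seed, {
    i <- sample(names(p), n_samples, replace = TRUE, prob = p)
    j <- sample(names(p), n_samples, replace = TRUE, prob = p)
    keep <- i != j
    mean(model$C[cbind(i[keep], j[keep])])
  })
}

normalize_background <- function(background) {
  if (identical(background, "uniform"))
    return(setNames(rep(1 / 20, 20), AA_ALPHABET))
  stopifnot(is.numeric(background), !is.null(names(background)))
  background <- background[AA_ALPHABET]
  background[is.na(background)] <- 0
  names(background) <- AA_ALPHABET
  if (any(background < 0) || sum(background) <= 0)
    stop("background frequencies must be non-negative with positive sum")
  background / sum(background)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Audit the triangle inequality of a substitution-cost model
#'
#' BLOSUM-derived costs are near-metric but not guaranteed metric; this scans
#' all ordered residue triples (i, j, k) and reports every violation
#' `C[i,k] > C[i,j] + C[j,k]` beyond a 1e-12 tolerance.  An empty result
#' certifies that the weighted edit distance built on the model is a
#' pseudometric.
#'
#' @param model A [distance_model()].
#' @return Data frame with columns `i`, `j`, `k`, `excess` (one row per
#'   violating triple; zero rows when the costs are metric).
#' @export
triangle_inequality_audit <- function(model) {
  C <- model$C
  g <- expand.grid(i = AA_ALPHABET, j = AA_ALPHABET, k = AA_ALPHABET,
                   stringsAsFactors = FALSE)
  lhs <- C[cbind(g$i, g$k)]
  rhs <- C[cbind(g$i, g$j)] + C[cbind(g$j, g$k)]
  bad <- lhs > rhs + 1e-12
  data.frame(g[bad, , drop = FALSE], excess = (lhs - rhs)[bad],
             row.names = NULL)
}

# Mutual z-similarity compatibility matrix: zok[a,b] is TRUE when b is among
# the top-z entries of a's similarity ranking and vice versa.  Row/column 21
# (X) is all FALSE: X never matches any gram, not even itself.
z_compat <- function(model, z) {
  if (z < 1) stop("ranking slack z must be >= 1")
  top <- lapply(model$neighbor_rank, head, z)
  zok <- matrix(FALSE, 21, 21)
  for (a in seq_len(20))
    for (b in seq_len(20))
      zok[a, b] <- AA_ALPHABET[b] %in% top[[AA_ALPHABET[a]]] &&
                   AA_ALPHABET[a] %in% top[[AA_ALPHABET[b]]]
  zok
}
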