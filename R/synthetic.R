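#' Average amino-acid composition of well-curated proteomes
#'
#' Frequencies close to the long-run UniProtKB averages, used as the default
#' background when generating random protein-like sequences.
#'
#' @return Named numeric vector over the 20 canonical residues, summing to 1.
#' @export
proteome_composition <- function() {
  comp <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
            E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
            M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
            Y = 2.92, V = 6.87)
  comp <- comp[order(names(comp))]
  comp / sum(comp)
}

#' Random protein-like sequence
#'
#' @param n Length in residues.
#' @param composition Named residue frequency vector (defaults to
#'   [proteome_composition()]), or `"uniform"`.
#' @param seed Optional RNG seed (the caller's RNG state is preserved).
#' @return Character string of length `n`.
#' @export
random_protein <- function(n, composition = proteome_composition(),
                           seed = NULL) {
  p <- normalize_background(composition)
  draw <- function() paste(sample(names(p), n, replace = TRUE, prob = p),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Composition-preserving shuffle of a sequence
#'
#' Uniform random permutation of the residues: the residue multiset is
#' preserved exactly, destroying any positional structure.  Used to build
#' control sequences with the residue composition of real proteins.
#'
#' @param seq Character string.
#' @param seed RNG seed (required for reproducibility; the caller's RNG
#'   state is preserved).
#' @return Character string of the same length and composition.
#' @export
shuffle_sequence <- function(seq, seed) {
  res <- strsplit(seq, "")[[1]]
  if (length(res) < 2L) return(seq)
  with_seed(seed, paste(sample(res), collapse = ""))
}

#' Plant a mutated tandem array in a random background
#'
#' Builds a background sequence from the given composition, then implants
#' `copies` tandem copies of `unit`, each copy independently mutated:
#' substitutions at rate `sub_rate` per position (the replacement drawn from
#' the composition, never equal to the original), and indels at rate
#' `indel_rate` per position (insertion or deletion with equal probability;
#' inserted residues drawn from the composition).
#'
#' @param length Total sequence length.
#' @param unit Repeat unit (character string).
#' @param copies Number of planted copies (at least 2).
#' @param sub_rate,indel_rate Per-position mutation rates in `[0, 1]`.
#' @param composition Background residue frequencies.
#' @param seed RNG seed.
#' @return List with `seq`, the planted span `start`/`end` (1-based
#'   inclusive), `unit`, and `n_sub`/`n_indel`, the realized mutation
#'   counts.
#' @export
generate_planted_tr <- function(length, unit, copies, sub_rate = 0,
                                indel_rate = 0,
                                composition = proteome_composition(),
                                seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            copies >= 2)
  p <- normalize_background(composition)
  u <- strsplit(toupper(unit), "")[[1]]
  gen <- function() {
    n_sub <- 0L; n_indel <- 0L
    mutate <- function(x) {
      if (sub_rate > 0) {
        hit <- which(runif(length(x)) < sub_rate)
        for (h in hit) {
          repeat {
            r <- sample(names(p), 1L, prob = p)
            if (r != x[h]) break
          }
          x[h] <- r
        }
        n_sub <<- n_sub + length(hit)
      }
      if (indel_rate > 0) {
        hit <- which(runif(length(x)) < indel_rate)
        n_indel <<- n_indel + length(hit)
        for (h in rev(hit)) {
          if (runif(1) < 0.5) x <- x[-h]
          else x <- append(x, sample(names(p), 1L, prob = p), after = h)
        }
      }
      x
    }
    arr <- unlist(lapply(seq_len(copies), function(.) mutate(u)))
    if (length(arr) > length)
      stop("planted array longer than the sequence: ", length(arr), " > ",
           length)
    n_bg <- length - length(arr)
    at <- if (n_bg > 0) sample.int(n_bg + 1L, 1L) - 1L else 0L
    bg <- if (n_bg > 0) sample(names(p), n_bg, replace = TRUE, prob = p)
          else character(0)
    tail_bg <- if (at < n_bg) bg[(at + 1L):n_bg] else character(0)
    seq <- c(bg[seq_len(at)], arr, tail_bg)
    list(seq = paste(seq, collapse = ""), start = at + 1L,
         end = at + length(arr), unit = unit,
         n_sub = n_sub, n_indel = n_indel)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Length of the longest detected repeat in a sequence
#'
#' Runs the detector and returns the longest reported repeat's total length,
#' floored at the 6-residue reporting limit: a sequence in which nothing is
#' found scores 6 (with `found = FALSE`), so paired comparisons against
#' shuffles are well defined.
#'
#' @param seq Character string.
#' @param config A [tr_config()].
#' @return List with `length` (>= 6) and `found` (logical).
#' @export
longest_ftr <- function(seq, config = tr_config()) {
  trs <- run_ptr_pipeline(seq, config)
  if (length(trs) == 0L) return(list(length = 6, found = FALSE))
  spans <- vapply(trs, function(t) t$end - t$start + 1L, 0L)
  list(length = max(max(spans), 6), found = TRUE)
}
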