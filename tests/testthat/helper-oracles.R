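# Independent reference implementations used to cross-check the package.

# Weighted edit distance by direct recursion on the defining recurrence,
# memoized; character-level, independent of the package's DP code path.
ed_oracle <- function(a, b, model) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <-
      if (i == 0L) j * model$indel_cost
      else if (j == 0L) i * model$indel_cost
      else min(rec(i - 1L, j) + model$indel_cost,
               rec(i, j - 1L) + model$indel_cost,
               rec(i - 1L, j - 1L) + model$C[A[i], B[j]])
    memo[[key]] <- val
    val
  }
  rec(length(A), length(B))
}

# Mutual top-z compatibility derived directly from the model's similarity
# rankings (20 x 20, over letters).
zok_oracle <- function(model, z) {
  top <- lapply(model$neighbor_rank, head, z)
  ok <- matrix(FALSE, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  for (a in aa_alphabet())
    for (b in aa_alphabet())
      ok[a, b] <- (b %in% top[[a]]) && (a %in% top[[b]])
  ok
}

# Quadratic all-pairs q-gram scanner: for every shape and start position,
# every later homologous gram, truncated to the first h_next per probe.
naive_qgram_scan <- function(seq, shapes, z, model, h_next) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  zok <- zok_oracle(model, z)
  grams <- lapply(shapes, function(sh) {
    n0 <- n - sh$s
    if (n0 < 1L) return(NULL)
    G <- vapply(sh$offsets, function(o) res[seq_len(n0) + o], character(n0))
    if (n0 == 1L) G <- matrix(G, nrow = 1L)
    G
  })
  out <- list()
  for (ii in seq_len(n)) {
    for (si in seq_along(shapes)) {
      sh <- shapes[[si]]
      G <- grams[[si]]
      n0 <- if (is.null(G)) 0L else nrow(G)
      if (ii >= n0) next
      jj <- (ii + 1L):n0
      eq <- matrix(G[jj, , drop = FALSE] ==
                     rep(G[ii, ], each = length(jj)), nrow = length(jj))
      n_eq <- rowSums(eq)
      hom <- n_eq == sh$q
      if (sh$q == 3L) {
        one <- which(n_eq == 2L)
        for (w in one) {
          col <- which(!eq[w, ])
          hom[w] <- zok[G[ii, col], G[jj[w], col]]
        }
      }
      hit <- head(jj[hom], h_next)
      for (j in hit)
        out[[length(out) + 1L]] <- c(ii, j - ii, si)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pos = integer(0), k = integer(0), shape = integer(0)))
  m <- do.call(rbind, out)
  data.frame(pos = m[, 1], k = m[, 2], shape = m[, 3])
}

# Direct evaluation of the anti-smear (queue of last H distances) and
# multiplicity weighting recurrences over a scan-ordered hit stream.
ref_weights <- function(hits, H, maxk) {
  w0 <- numeric(maxk)
  Q <- integer(0)
  if (nrow(hits) > 0L) {
    pid <- cumsum(c(TRUE, diff(hits$pos) != 0L | diff(hits$shape) != 0L))
    for (ks in split(hits$k, pid)) {
      for (kg in ks) w0[kg] <- w0[kg] + sum(2^(-abs(kg - Q)))
      Q <- tail(c(Q, ks), H)
    }
  }
  w1 <- numeric(maxk)
  for (k in which(w0 > 0)) {
    mult <- seq(k, maxk, by = k)
    w1[k] <- sum(w0[mult][w0[mult] > 0])
  }
  list(w0 = w0, w1 = w1)
}

random_seq <- function(n, letters = aa_alphabet(), seed = NULL) {
  draw <- function() paste(sample(letters, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# fraction of the planted span covered by the best single reported repeat
best_overlap <- function(trs, start, end) {
  if (length(trs) == 0L) return(0)
  ov <- vapply(trs, function(t)
    max(0L, min(t$end, end) - max(t$start, start) + 1L), 0L)
  max(ov) / (end - start + 1L)
}

# exact one-tailed signed-rank p-value by enumeration of all 2^n sign
# assignments under the null (no ties in |d|)
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  null_W <- as.matrix(signs) %*% r
  mean(null_W >= W)
}

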