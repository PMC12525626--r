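# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms / naive enumeration.

# Horn's quaternion method for rigid superposition (independent of the
# SVD-based Kabsch implementation under test).
quaternion_superpose_rmsd <- function(fixed, mobile) {
  P <- as.matrix(mobile)
  Q <- as.matrix(fixed)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- t(Pc) %*% Qc
  N <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    nrow = 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

# Exact hypergeometric upper tail by direct pmf summation with choose().
brute_hyper_tail <- function(k, n, K, N) {
  i <- max(k, 0):min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive per-position loop re-implementation of the TTS formula.
brute_tts <- function(octapeptide, pssm) {
  aa <- strsplit(octapeptide, "")[[1]]
  prod <- 1
  m <- 0
  for (p in pssm$scored_positions) {
    w <- if (aa[p] %in% colnames(pssm$weights)) {
      pssm$weights[p, aa[p]]
    } else 0
    if (w == 0) return(0)
    prod <- prod * w / max(pssm$weights[p, ])
    m <- m + 1
  }
  prod^(1 / m)
}

# Exhaustive window scan used as the scanning oracle.
brute_scan <- function(sequence, pssm, threshold) {
  L <- nchar(sequence)
  if (L < 8) return(data.frame(start = integer(), tts = numeric()))
  rows <- lapply(seq_len(L - 7), function(s) {
    oct <- substring(sequence, s, s + 7)
    data.frame(start = s, octapeptide = oct,
               tts = brute_tts(oct, pssm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$tts >= threshold, , drop = FALSE]
}

# All-pairs O(n^2) distance filter (contact-census oracle).
brute_pairs_within <- function(xa, xb, cutoff) {
  hits <- 0L
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      if (sqrt(sum((xa[i, ] - xb[j, ])^2)) <= cutoff) hits <- hits + 1L
    }
  }
  hits
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# Small synthetic spec used across tests to keep runtimes low.
small_spec <- function(seed, ...) {
  synthetic_spec(seed = seed, n_proteins = 14L, protein_length = 200L,
                 planted_pos8 = c(S = 5L, T = 2L, Y = 2L), ...)
}
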