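# Independent oracles, kept deliberately separate from the package's code
# paths: brute-force Smith-Waterman, hypergeometric enumeration, concordant
# pair counting, and a stand-alone mutual-information / greedy-mRMR
# implementation.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Affine-gap local alignment by direct matrix fill; a gap of length L costs
# open + L * extend (the convention the package's aligner uses).
sw_oracle <- function(a, b, open = 10, extend = 1, S = blosum62) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# P(X >= k) by enumerating every n-subset of a universe with K successes.
hypergeom_enum_oracle <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# AUC as the fraction of concordant positive/negative pairs, ties 1/2.
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Discrete mutual information by explicit probability loops.
mi_oracle <- function(x, y) {
  xs <- unique(x); ys <- unique(y)
  n <- length(x)
  total <- 0
  for (a in xs) for (b in ys) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0)
      total <- total + pab * log(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  total
}

# Greedy MID selection re-implemented from scratch on discrete features.
mrmr_oracle <- function(feature_df, labels, k) {
  fn <- names(feature_df)
  rel <- vapply(fn, function(f) mi_oracle(feature_df[[f]], labels), 0)
  sel <- character(0)
  while (length(sel) < min(k, length(fn))) {
    rest <- setdiff(fn, sel)
    crit <- vapply(rest, function(f) {
      red <- if (length(sel))
        mean(vapply(sel, function(s) mi_oracle(feature_df[[f]],
                                               feature_df[[s]]), 0))
      else 0
      rel[f] - red
    }, 0)
    ord <- order(-crit, rest)
    sel <- c(sel, rest[ord[1]])
  }
  sel
}
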