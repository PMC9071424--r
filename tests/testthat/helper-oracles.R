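# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations (enumeration, closed forms) kept
# separate from the package code paths they check.

# brute-force motif scan: test every window against the position sets
brute_force_scan <- function(seqs, pattern) {
  pattern <- motif_pattern(pattern)
  width <- length(pattern)
  out <- list()
  for (id in names(seqs)) {
    chars <- strsplit(seqs[[id]], "")[[1]]
    if (length(chars) < width) next
    for (s in seq_len(length(chars) - width + 1L)) {
      ok <- TRUE
      for (j in seq_len(width)) {
        if (!chars[[s + j - 1L]] %in% pattern[[j]]) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1L]] <-
          data.frame(protein_id = id, start = s,
                     matched = paste(chars[s:(s + width - 1L)], collapse = ""),
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein_id = character(), start = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# hypergeometric upper-tail sum for over-representation (direct summation)
hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand-coded Welch two-sided t-test p-value (formula, not stats::t.test)
welch_p_hand <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(tstat), df)
}

# random protein sequence from the 20 standard letters
random_protein <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# physical root of the single-site mass-balance quadratic, solved with
# polyroot (independent of the closed-form implementation)
fraction_bound_polyroot <- function(L, kd, T) {
  roots <- Re(polyroot(c(T * L, -(T + L + kd), 1)))  # B^2 - bB + TL = 0
  b <- min(roots)                                    # physical root <= min(T, L)
  b / T
}
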