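# Independent oracles used across the suite.  These deliberately avoid the
# package's vectorized code paths: plain loops, plain string ops.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Naive sliding-window scan: every window on both strands with Hamming
# distance to the consensus within budget.  O(L * 6) loop.
oracle_scan <- function(seq, consensus = "TTGCGG", max_mismatch = 1L) {
  L <- nchar(seq)
  out <- list()
  if (L >= 6L) {
    for (i in 1:(L - 5L)) {
      win <- substr(seq, i, i + 5L)
      if (grepl("N", win)) next
      for (strand in c("+", "-")) {
        local_win <- if (strand == "+") win else oracle_revcomp(win)
        mm <- sum(strsplit(local_win, "")[[1]] !=
          strsplit(consensus, "")[[1]])
        if (mm <= max_mismatch) {
          out[[length(out) + 1L]] <- data.frame(
            start = i - 1L, strand = strand, mismatches = mm,
            observed = local_win, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      start = integer(), strand = character(),
      mismatches = integer(), observed = character()
    ))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

# All 4096 hexamers, in a fixed order.
all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g, 1, paste, collapse = "")
}

# Brute-force log-odds score of one word (independent of log_odds_score).
oracle_score <- function(word, prob, background) {
  w <- strsplit(word, "")[[1]]
  total <- 0
  for (j in 1:6) total <- total + log2(prob[w[j], j] / background[w[j]])
  total
}

# Background probability of a word.
oracle_word_prob <- function(word, background) {
  prod(background[strsplit(word, "")[[1]]])
}

# Random DNA string from the current RNG stream.
rand_dna <- function(n, gc = 0.435) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
    collapse = ""
  )
}
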