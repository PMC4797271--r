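test_that("single-element matches are found in motif-local orientation", {
  m <- find_re_matches("TTGCGG", max_mismatch = 0)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$strand, "+")
  expect_equal(m$observed, "TTGCGG")

  m2 <- find_re_matches("CCGCAA", max_mismatch = 0)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$strand, "-")
  expect_equal(m2$observed, "TTGCGG")

  expect_equal(nrow(find_re_matches("", max_mismatch = 0)), 0L)
  expect_equal(nrow(find_re_matches("ACGT", max_mismatch = 0)), 0L)
  # N never matches
  expect_equal(nrow(find_re_matches("TTGCGN", max_mismatch = 1)), 0L)
})

test_that("an implanted element in random background is recovered exactly", {
  seq <- withr::with_seed(11, rand_dna(1000, gc = 0.435))
  substr(seq, 501, 506) <- "TTGCGG"
  hits <- find_re_matches(seq, max_mismatch = 0)
  expect_true(500 %in% hits$start[hits$strand == "+"])
  # Full equality with the naive sliding-window oracle at budget 1.
  hits1 <- find_re_matches(seq, max_mismatch = 1)
  orc <- oracle_scan(seq, max_mismatch = 1)
  expect_equal(nrow(hits1), nrow(orc))
  expect_equal(hits1$start, orc$start)
  expect_equal(hits1$strand, orc$strand)
  expect_equal(hits1$mismatches, orc$mismatches)
  expect_equal(hits1$observed, orc$observed)
})

test_that("pairing builds DR and IR units with the right geometry", {
  # DR, spacer 5, plus strand
  p <- pair_sites(find_re_matches("TTGCGGACGTATTGCGG", max_mismatch = 0))
  expect_equal(nrow(p), 1L)
  expect_equal(p$topology, "DR")
  expect_equal(p$spacer, 5L)
  expect_equal(p$strand, "+")

  # IR, spacer 4, strand "."
  p2 <- pair_sites(find_re_matches("TTGCGGACGTCCGCAA", max_mismatch = 0))
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$topology, "IR")
  expect_equal(p2$spacer, 4L)
  expect_equal(p2$strand, ".")
  expect_equal(p2$re_first, "TTGCGG")
  expect_equal(p2$re_second, "TTGCGG")

  # Reverse complement of the DR: minus strand, mirrored coordinates.
  rc <- revcomp("TTGCGGACGTATTGCGG")
  p3 <- pair_sites(find_re_matches(rc, max_mismatch = 0))
  expect_equal(p3$topology, "DR")
  expect_equal(p3$strand, "-")
  expect_equal(p3$spacer, 5L)
  expect_equal(p3$first_start, 0L)
  expect_equal(p3$second_end, 17L)

  # Everted arrangement (CCGCAA ... TTGCGG) is not an IR.
  p4 <- pair_sites(find_re_matches("CCGCAAACGTTTGCGG", max_mismatch = 0))
  expect_equal(nrow(p4), 0L)
})

test_that("the stringent scan enforces optimal spacer and 1-mismatch budget", {
  expect_equal(nrow(scan_stringent("TTGCGGAAAAATTGCGT")), 1L) # 1 mismatch
  expect_equal(nrow(scan_stringent("TTGCGGAAAAATTGCTT")), 0L) # 2 mismatches
  expect_equal(nrow(scan_stringent("TTGCGGAAAATTGCGG")), 0L) # spacer 4
  # IR scanning is opt-in, at its own optimal spacer.
  expect_equal(nrow(scan_stringent("TTGCGGACGTCCGCAA")), 0L)
  expect_equal(
    nrow(scan_stringent("TTGCGGACGTCCGCAA", include_ir = TRUE)), 1L
  )
})

test_that("scanning is strand-symmetric and IR sets are self-symmetric", {
  withr::with_seed(23, {
    for (trial in 1:10) {
      seq <- rand_dna(300)
      # implant one DR and one IR well apart
      substr(seq, 21, 37) <- "TTGCGGAACGTTTGCGG"
      substr(seq, 121, 136) <- "TTGCGGACGTCCGCAA"
      L <- nchar(seq)
      fwd <- pair_sites(find_re_matches(seq, max_mismatch = 1))
      rev <- pair_sites(find_re_matches(revcomp(seq), max_mismatch = 1))
      # Mirror reverse-scan coordinates back to the forward frame.
      mirror <- data.frame(
        topology = rev$topology,
        first_start = L - rev$second_end,
        second_end = L - rev$first_start,
        strand = ifelse(rev$strand == ".", ".",
          ifelse(rev$strand == "+", "-", "+")
        )
      )
      key <- function(d) {
        o <- order(d$first_start, d$topology, d$strand)
        paste(d$topology, d$first_start, d$second_end, d$strand)[o]
      }
      expect_identical(key(fwd), key(mirror))
      # IR hits are identical between seq and its reverse complement.
      ir_f <- fwd[fwd$topology == "IR", ]
      ir_m <- mirror[mirror$topology == "IR", ]
      expect_identical(
        paste(ir_f$first_start, ir_f$second_end),
        paste(ir_m$first_start, ir_m$second_end)[order(ir_m$first_start)]
      )
    }
  })
})

test_that("relaxed scanning applies exact p-value thresholds", {
  m <- build_pfm(rep("TTGCGG", 4), pseudocount = 0.25)
  # Threshold 1: every window on both strands passes.
  seq <- withr::with_seed(5, rand_dna(40))
  all_pass <- find_re_matches(seq, m,
    mode = "relaxed",
    pvalue_threshold = 1
  )
  expect_equal(nrow(all_pass), 2L * (nchar(seq) - 5L))
  # A strict threshold keeps the consensus (p = (1/4)^6 under uniform bg).
  hit <- find_re_matches("TTGCGG", m,
    mode = "relaxed",
    pvalue_threshold = 1e-3
  )
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$pvalue, 0.25^6, tolerance = 1e-9)
  expect_error(
    find_re_matches("TTGCGG", m, mode = "relaxed", pvalue_threshold = 0),
    "pvalue_threshold"
  )
  expect_error(
    find_re_matches("TTGCGG", motif_model(), mode = "relaxed"),
    "PFM"
  )
})

test_that("score p-value DP equals exhaustive enumeration over hexamers", {
  m <- build_pfm(c("TTGCGG", "TTGCGT", "ATGCGG", "TTGCGG"),
    pseudocount = 0.25,
    background = c(A = 0.28, C = 0.22, G = 0.22, T = 0.28)
  )
  w <- 0.01
  tab <- score_pvalue_table(m, bin_width = w)
  # Oracle: enumerate all 4096 words with the same discretized per-column
  # scores and accumulate exact background tail probabilities.
  p <- (m$pfm + m$pseudocount)
  p <- sweep(p, 2, colSums(p), "/")
  lom <- log2(p / m$background)
  K <- round(lom / w)
  words <- all_hexamers()
  ks <- vapply(words, function(word) {
    idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
    sum(K[cbind(idx, 1:6)])
  }, numeric(1))
  probs <- vapply(words, oracle_word_prob, numeric(1),
    background = m$background
  )
  for (s in sample(tab$score, 25)) {
    k <- round(s / w)
    expect_equal(
      tab$pvalue[tab$score == s],
      sum(probs[ks >= k]),
      tolerance = 1e-12
    )
  }
  # Tail is monotone non-increasing and starts at 1.
  expect_true(all(diff(tab$pvalue) <= 1e-12))
  expect_equal(tab$pvalue[1], 1)
  # Continuous brute-force scores agree within the discretization error.
  cont <- vapply(words, oracle_score, numeric(1),
    prob = p, background = m$background
  )
  expect_true(max(abs(cont - ks * w)) <= 6 * w / 2)
})

test_that("p-value of the top score is the background mass of one word", {
  m <- build_pfm(rep("TTGCGG", 2), pseudocount = 0.01)
  tab <- score_pvalue_table(m)
  expect_equal(tab$pvalue[nrow(tab)], 0.25^6, tolerance = 1e-12)
  expect_error(score_pvalue_table(m, bin_width = 0), "bin_width")
})

test_that("overlap deduplication keeps the best pair per cluster", {
  # Three consecutive elements -> two overlapping DR pairs sharing one RE.
  seq <- "TTGCGGAAAAATTGCGTAAAAGTTGCGG"
  m <- find_re_matches(seq, max_mismatch = 1)
  p <- pair_sites(m, spacers = list(DR = c(4L, 5L), IR = integer()))
  expect_gte(nrow(p), 2L)
  d <- dedupe_pairs(p)
  expect_equal(nrow(d), 1L)
  expect_equal(d$mm_first + d$mm_second, min(p$mm_first + p$mm_second))
})
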