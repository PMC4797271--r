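# Construct a classified pair record directly (motif-local words).
mk_pair <- function(topology, spacer, re1 = "TTGCGG", re2 = "TTGCGG") {
  tibble::tibble(
    seq_id = "probe", topology = topology, strand = "+",
    first_start = 0L, first_end = 6L,
    second_start = 6L + spacer, second_end = 12L + spacer,
    spacer = as.integer(spacer), re_first = re1, re_second = re2,
    mm_first = as.integer(mismatch_count(re1, "TTGCGG")),
    mm_second = as.integer(mismatch_count(re2, "TTGCGG")),
    combined_score = NA_real_
  )
}

test_that("spacer rules reproduce the measured optima and tolerances", {
  dr5 <- classify_pair(mk_pair("DR", 5))
  expect_equal(dr5$affinity, "OPTIMAL")
  expect_equal(dr5$fold_penalty, 1)

  dr4 <- classify_pair(mk_pair("DR", 4))
  expect_equal(dr4$affinity, "REDUCED")
  expect_equal(dr4$fold_penalty, 2)

  ir4 <- classify_pair(mk_pair("IR", 4))
  expect_equal(ir4$affinity, "OPTIMAL")
  ir5 <- classify_pair(mk_pair("IR", 5))
  expect_equal(ir5$fold_penalty, 2)

  # All other tested lengths abolish binding, including adding a full turn.
  for (n in c(1:3, 6:10, 15)) {
    expect_equal(classify_pair(mk_pair("DR", n))$affinity, "NONE")
  }
  for (n in c(1:3, 6:10, 14)) {
    expect_equal(classify_pair(mk_pair("IR", n))$affinity, "NONE")
  }
  # Untested spacers default to NONE with an untested flag.
  u <- classify_pair(mk_pair("DR", 12))
  expect_equal(u$affinity, "NONE")
  expect_match(u$provenance, "untested")
})

test_that("central-GC substitutions split the two topologies", {
  # Motif-local G3->T is tolerated at 2-fold; C4->A abolishes.
  g3t <- classify_pair(mk_pair("DR", 5, re2 = "TTTCGG"))
  expect_equal(g3t$affinity, "REDUCED")
  expect_equal(g3t$fold_penalty, 2)

  c4a <- classify_pair(mk_pair("DR", 5, re2 = "TTGAGG"))
  expect_equal(c4a$affinity, "NONE")

  # The identical plus-strand mutations of an IR's second element map to
  # the opposite motif-local changes, so outcomes swap.
  ir <- scan_stringent("TTGCGGACGTCCGCAA",
    max_mismatch = 1,
    include_ir = TRUE
  )
  expect_equal(nrow(ir), 1L)
  # plus-strand C4->A on CCGCAA = motif-local G3->T: binds, 2-fold reduced
  ir_c4a <- scan_stringent("TTGCGGACGTCCGAAA",
    max_mismatch = 1,
    include_ir = TRUE
  )
  cls <- classify_pair(ir_c4a)
  expect_equal(cls$affinity, "REDUCED")
  expect_equal(cls$fold_penalty, 2)
  # plus-strand G3->T on CCGCAA = motif-local C4->A: abolished
  ir_g3t <- scan_stringent("TTGCGGACGTCCTCAA",
    max_mismatch = 1,
    include_ir = TRUE
  )
  expect_equal(classify_pair(ir_g3t)$affinity, "NONE")
})

test_that("point-substitution rules follow the mutation map", {
  # Position-1 transition (T->C) tolerated at 2-fold, either element.
  p1 <- classify_pair(mk_pair("DR", 5, re1 = "CTGCGG"))
  expect_equal(p1$affinity, "REDUCED")
  expect_equal(p1$fold_penalty, 2)
  # Transitions at every other position abolish.
  for (v in c("TCGCGG", "TTACGG", "TTGTGG", "TTGCAG", "TTGCGA")) {
    expect_equal(classify_pair(mk_pair("DR", 5, re1 = v))$affinity, "NONE")
  }
  # Untested transversions abolish with a flag.
  u <- classify_pair(mk_pair("DR", 5, re1 = "GTGCGG"))
  expect_equal(u$affinity, "NONE")
  expect_match(u$provenance, "untested")
  # Two substitutions in one element abolish even if each is tolerated.
  two <- classify_pair(mk_pair("DR", 5, re1 = "CTTCGG"))
  expect_equal(two$affinity, "NONE")
})

test_that("penalties compose multiplicatively and commutatively", {
  # spacer x2, RE1 pos1 x2, RE2 pos1 x2 -> 8-fold, flagged extrapolated.
  comp <- classify_pair(mk_pair("DR", 4, re1 = "CTGCGG", re2 = "CTGCGG"))
  expect_equal(comp$fold_penalty, 8)
  expect_equal(comp$affinity, "REDUCED")
  expect_match(comp$provenance, "extrapolated")
  # Swapping which element carries the mutation changes nothing.
  a <- classify_pair(mk_pair("DR", 5, re1 = "CTGCGG"))
  b <- classify_pair(mk_pair("DR", 5, re2 = "CTGCGG"))
  expect_equal(a$fold_penalty, b$fold_penalty)
  expect_equal(a$affinity, b$affinity)
})

test_that("adding a mismatch never improves the affinity class", {
  rank <- c(OPTIMAL = 3, REDUCED = 2, NONE = 1)
  base_variants <- list(
    mk_pair("DR", 5), mk_pair("DR", 4), mk_pair("IR", 4),
    mk_pair("DR", 5, re1 = "CTGCGG"), mk_pair("DR", 5, re2 = "TTTCGG")
  )
  withr::with_seed(31, {
    for (bp in base_variants) {
      r0 <- rank[classify_pair(bp)$affinity]
      for (k in 1:10) {
        pos <- sample(6, 1)
        re <- if (runif(1) < 0.5) "re_first" else "re_second"
        word <- bp[[re]]
        cur <- substr(word, pos, pos)
        substr(word, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
        worse <- bp
        worse[[re]] <- word
        worse$mm_first <- as.integer(mismatch_count(worse$re_first, "TTGCGG"))
        worse$mm_second <- as.integer(mismatch_count(worse$re_second, "TTGCGG"))
        expect_lte(rank[classify_pair(worse)$affinity], r0)
      }
    }
  })
})

test_that("classification is strand-invariant", {
  probes <- c(
    "TTGCGGACGTATTGCGG", # perfect DR
    "TTGCGGACGTATTTCGG", # DR with motif-local G3->T
    "TTGCGGACGTCCGCAA" # perfect IR
  )
  for (s in probes) {
    f <- classify_pair(scan_stringent(s, include_ir = TRUE, max_mismatch = 1))
    r <- classify_pair(scan_stringent(revcomp(s),
      include_ir = TRUE,
      max_mismatch = 1
    ))
    expect_equal(nrow(f), 1L)
    expect_equal(f$affinity, r$affinity)
    expect_equal(f$fold_penalty, r$fold_penalty)
  }
})

test_that("an isolated element never binds, whatever its score", {
  sites <- find_re_matches("TTGCGG", max_mismatch = 1)
  cls <- classify_single_re(sites)
  expect_true(all(cls$affinity == "NONE"))
  one_mm <- classify_single_re(find_re_matches("TTGCGT", max_mismatch = 1))
  expect_true(all(one_mm$affinity == "NONE"))
})

test_that("Hill occupancy has the closed-form landmarks", {
  expect_equal(occupancy(0, K_d = 2.4, n_H = 1.4), 0)
  for (nh in c(0.5, 1, 1.4, 3)) {
    expect_equal(occupancy(2.4, K_d = 2.4, n_H = nh), 0.5)
  }
  expect_equal(occupancy(4.8, K_d = 2.4, n_H = 1), 2 / 3)
  # strictly increasing in concentration; decreasing in K_d
  cs <- seq(0.1, 10, by = 0.1)
  expect_true(all(diff(occupancy(cs, 2.4, 1.4)) > 0))
  expect_lt(occupancy(1, K_d = 5, n_H = 1.4), occupancy(1, K_d = 2, n_H = 1.4))
  expect_error(occupancy(-1, 2.4, 1.4), "non-negative")
})

test_that("cooperative coupling rescues clustered degenerate sites only", {
  deg <- function(start) {
    p <- mk_pair("DR", 5, re1 = "TTGCCG", re2 = "TGGCGG") # untested singles
    p$first_start <- start
    p$first_end <- start + 6L
    p$second_start <- start + 11L
    p$second_end <- start + 17L
    p
  }
  cluster <- classify_pair(dplyr::bind_rows(deg(0), deg(40), deg(80)))
  expect_true(all(cluster$affinity == "NONE"))
  pb <- promoter_binding(cluster, coupling_window = 60)
  expect_true(all(pb$sites$bindable))
  expect_equal(pb$model$n_H, 1.4)
  expect_equal(pb$model$K_d_eff, 1.2 * 8) # 8x K0 sentinel for rescued sites

  # The same site alone stays unbindable.
  alone <- promoter_binding(classify_pair(deg(0)))
  expect_false(any(alone$sites$bindable))
  expect_true(is.na(alone$model$K_d_eff))

  # An optimal IR rescues a degenerate DR within the window.
  ir <- classify_pair(mk_pair("IR", 4))
  mix <- dplyr::bind_rows(ir, classify_pair(deg(40)))
  pb2 <- promoter_binding(mix, coupling_window = 60)
  expect_true(all(pb2$sites$bindable))
  expect_equal(pb2$model$K_d_eff, 1.2) # best site is the optimal IR
  # ... but not outside the window.
  pb3 <- promoter_binding(
    dplyr::bind_rows(ir, classify_pair(deg(200))),
    coupling_window = 60
  )
  expect_equal(sum(pb3$sites$bindable), 1L)

  # A spacer-violating NONE is not "degenerate" and is never rescued.
  bad_spacer <- classify_pair(mk_pair("DR", 8))
  pb4 <- promoter_binding(dplyr::bind_rows(ir, bad_spacer))
  expect_false(pb4$sites$bindable[2])
})

test_that("affinity rules round-trip through YAML and reject bad schema", {
  rules <- default_affinity_rules()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_affinity_rules(rules, f)
  back <- read_affinity_rules(f)
  expect_equal(as.data.frame(back$spacer), as.data.frame(rules$spacer))
  expect_equal(
    as.data.frame(back$substitution),
    as.data.frame(rules$substitution)
  )
  # Classifier behaves identically under the reloaded table.
  p <- mk_pair("DR", 5, re1 = "CTGCGG")
  expect_equal(
    classify_pair(p, rules = back)$fold_penalty,
    classify_pair(p, rules = rules)$fold_penalty
  )
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(schema = "something-else"), bad)
  expect_error(read_affinity_rules(bad), "schema")
})
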