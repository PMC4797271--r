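test_that("background generation is a pure function of its config", {
  cfg <- generator_config(seed = 1)
  expect_identical(random_background(10, cfg), random_background(10, cfg))
  expect_identical(
    random_background(500, generator_config(seed = 5)),
    random_background(500, generator_config(seed = 5))
  )
  expect_false(identical(
    random_background(500, generator_config(seed = 5)),
    random_background(500, generator_config(seed = 6))
  ))
  expect_equal(nchar(random_background(1, cfg)), 1L)
  expect_true(random_background(1, cfg) %in% c("A", "C", "G", "T"))
  expect_error(random_background(0, cfg), "positive")
})

test_that("background composition tracks the configured GC content", {
  s <- random_background(1e5, generator_config(seed = 2, gc_content = 0.5))
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 1e5
  expect_gte(gc, 0.49)
  expect_lte(gc, 0.51)
  # First-order chain keeps the stationary composition.
  s1 <- random_background(
    1e5,
    generator_config(seed = 2, gc_content = 0.435, markov_order = 1)
  )
  gc1 <- sum(strsplit(s1, "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc1 - 0.435), 0.01)
})

test_that("implants round-trip through the scanner", {
  bg <- random_background(60, generator_config(seed = 3))
  res <- implant_pair(bg, "DR", 5, position = 20)
  found <- scan_stringent(res$seq, max_mismatch = 0)
  expect_equal(found$first_start, res$truth$first_start)
  expect_equal(found$second_end, res$truth$second_end)
  expect_equal(found$strand, "+")

  # IR is self-symmetric: a minus-strand request renders identically.
  r_plus <- implant_pair(bg, "IR", 4, strand = "+", position = 20)
  r_minus <- implant_pair(bg, "IR", 4, strand = "-", position = 20)
  expect_identical(r_plus$seq, r_minus$seq)
  expect_equal(r_plus$truth$strand, ".")

  # An abolished-by-mutation DR is still found (1 mismatch) but
  # classifies NONE.
  mut <- implant_pair(bg, "DR", 5,
    substitutions = list(re1 = NULL, re2 = c("4" = "A")), position = 20
  )
  hit <- scan_stringent(mut$seq, max_mismatch = 1)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mm_second, 1L)
  expect_equal(classify_pair(hit)$affinity, "NONE")

  # Overlapping implants raise a placement error.
  expect_error(
    implant_pair(res, "DR", 5, position = 25),
    "overlap"
  )
  expect_error(implant_pair(bg, "DR", 5, position = 55), "fit")
})

test_that("the probe panel matches its construction contract", {
  cfg <- generator_config(seed = 7)
  panel <- make_probe_panel(cfg)
  expect_identical(panel$probes, make_probe_panel(cfg)$probes) # deterministic

  probe <- function(id) panel$probes$seq[panel$probes$probe_id == id]
  expect_equal(unique(nchar(panel$probes$seq)), 50L)

  # PDR: exactly one stringent DR hit at the recorded center position.
  pdr_hits <- scan_stringent(probe("PDR"), max_mismatch = 0)
  expect_equal(nrow(pdr_hits), 1L)
  expect_equal(
    pdr_hits$first_start,
    panel$truth$first_start[panel$truth$probe_id == "PDR"]
  )
  # NC: zero stringent hits of either topology.
  expect_equal(
    nrow(scan_stringent(probe("NC"), max_mismatch = 1, include_ir = TRUE)),
    0L
  )
  # Spacer series carries the full affinity ladder.
  dr_series <- panel$truth[grepl("^DR_n", panel$truth$probe_id), ]
  cls <- classify_pair(dr_series)
  expect_equal(
    cls$affinity[order(cls$spacer)],
    c(rep("NONE", 3), "REDUCED", "OPTIMAL", rep("NONE", 6))
  )
  ir_series <- classify_pair(panel$truth[grepl("^IR_n", panel$truth$probe_id), ])
  expect_equal(
    ir_series$affinity[order(ir_series$spacer)],
    c(rep("NONE", 3), "OPTIMAL", "REDUCED", rep("NONE", 6))
  )
  # Central-GC quartet: outcomes split by topology.
  quartet <- classify_pair(
    panel$truth[panel$truth$probe_id %in%
      c("PDR_G3T", "PDR_C4A", "PIR_G3T", "PIR_C4A"), ]
  )
  got <- setNames(quartet$affinity, quartet$probe_id)
  expect_equal(got[["PDR_G3T"]], "REDUCED")
  expect_equal(got[["PDR_C4A"]], "NONE")
  expect_equal(got[["PIR_G3T"]], "NONE")
  expect_equal(got[["PIR_C4A"]], "REDUCED")
})

test_that("implant -> scan round trips recover every truth record", {
  # Property version of the recovery study (acceptance runs 1000 trials).
  withr::with_seed(13, {
    for (trial in 1:50) {
      bg <- rand_dna(200)
      topo <- sample(c("DR", "IR"), 1)
      spacer <- if (topo == "DR") 5L else 4L
      pos <- sample(0:(200 - 12 - spacer), 1)
      res <- implant_pair(bg, topo, spacer,
        strand = sample(c("+", "-"), 1), position = pos
      )
      found <- scan_stringent(res$seq, max_mismatch = 0, include_ir = TRUE)
      key <- paste(found$topology, found$first_start, found$second_end)
      expect_true(
        paste(
          res$truth$topology, res$truth$first_start,
          res$truth$second_end
        ) %in% key
      )
    }
  })
})

test_that("simulated titrations are exact at zero noise and seeded", {
  concs <- 0.075 * 2^(0:7)
  tc <- simulate_titration(
    K_d = 2.4, n_H = 1.4, concs = concs,
    noise_sd = 0, replicates = 2, seed = 5
  )
  expect_equal(
    tc$fraction_bound,
    rep(occupancy(concs, 2.4, 1.4), 2)
  )
  tc2 <- simulate_titration(noise_sd = 0.05, replicates = 3, seed = 8)
  expect_identical(tc2, simulate_titration(
    noise_sd = 0.05,
    replicates = 3, seed = 8
  ))
  expect_true(all(tc2$fraction_bound >= 0 & tc2$fraction_bound <= 1))
  # Multiplicative noise is scale-proportional: zero signal stays zero.
  tm <- simulate_titration(
    concs = c(0, 1, 2, 4), noise_sd = 0.2,
    replicates = 2, seed = 1, noise = "multiplicative"
  )
  expect_true(all(tm$fraction_bound[tm$conc_uM == 0] == 0))
})

test_that("promoter fixtures carry exactly their declared sites", {
  for (kind in c("class_III", "single_dr", "pel_like", "no_sites")) {
    fx <- make_promoter_fixture(kind, generator_config(seed = 11))
    found <- scan_stringent(fx$seq,
      max_mismatch = 1, include_ir = TRUE,
      seq_id = fx$seq_id
    )
    expect_equal(nrow(found), nrow(fx$sites))
    if (nrow(found) > 0) {
      expect_setequal(found$first_start, fx$sites$first_start)
    }
    ann <- detect_core_promoter(fx$seq, seq_id = fx$seq_id)
    expect_equal(ann$found, "pair")
    expect_equal(ann$minus35_start, fx$annotation$minus35_start)
    expect_equal(ann$minus10_start, fx$annotation$minus10_start)
    expect_true(ann$extended_minus10)
  }
})
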