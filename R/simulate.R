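#' Generator configuration
#'
#' Bundles the seed and composition settings shared by all synthetic-data
#' generators.  Identical configurations produce byte-identical output.
#'
#' @param seed Integer RNG seed.
#' @param gc_content Fraction G+C of background sequence, in (0, 1).
#'   Default 0.435 (B. subtilis-like genome composition).
#' @param markov_order 0 (i.i.d. bases) or 1 (first-order chain with the
#'   same stationary composition and mild local persistence).
#' @param persistence Self-transition excess for `markov_order = 1`
#'   (probability mass added to repeating the previous base).
#' @param probe_length Probe length in nt for [make_probe_panel()]
#'   (default 50, the short double-stranded EMSA fragments).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, gc_content = 0.435,
                             markov_order = 0L, persistence = 0.1,
                             probe_length = 50L) {
  if (gc_content <= 0 || gc_content >= 1) {
    abort("`gc_content` must lie strictly between 0 and 1")
  }
  if (!markov_order %in% c(0L, 1L)) abort("`markov_order` must be 0 or 1")
  structure(
    list(
      seed = as.integer(seed), gc_content = gc_content,
      markov_order = as.integer(markov_order),
      persistence = persistence, probe_length = as.integer(probe_length)
    ),
    class = "generator_config"
  )
}

# Draw n bases from the current RNG stream at the configured composition.
random_bases <- function(n, config) {
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (config$markov_order == 0L) {
    return(sample(DNA_BASES, n, replace = TRUE, prob = p))
  }
  # Order-1 chain: with probability `persistence` repeat the previous base,
  # otherwise draw fresh from the composition; stationary distribution = p.
  fresh <- sample(DNA_BASES, n, replace = TRUE, prob = p)
  if (n == 1L) {
    return(fresh)
  }
  stay <- stats::runif(n - 1L) < config$persistence
  out <- fresh
  for (i in which(stay)) out[i + 1L] <- out[i]
  out
}

#' Random background sequence
#'
#' Seeded i.i.d. (or first-order Markov) sequence at the configured base
#' composition.  A pure function of its arguments: the same `config` always
#' returns the same string.
#'
#' @param length Sequence length (> 0).
#' @param config A [generator_config()].
#' @return A DNA string.
#' @examples
#' random_background(20, generator_config(seed = 7))
#' @export
random_background <- function(length, config = generator_config()) {
  if (length < 1L) abort("`length` must be positive")
  withr::with_seed(
    config$seed,
    paste(random_bases(length, config), collapse = "")
  )
}

# Apply motif-local substitutions (named vector position -> base) to a word.
apply_substitutions <- function(word, subs) {
  if (is.null(subs) || length(subs) == 0L) {
    return(word)
  }
  chars <- strsplit(word, "")[[1]]
  pos <- as.integer(names(subs))
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > length(chars))) {
    abort("substitution positions must lie in 1..6")
  }
  if (any(!toupper(subs) %in% DNA_BASES)) {
    abort("substitution bases must be A/C/G/T")
  }
  chars[pos] <- toupper(subs)
  paste(chars, collapse = "")
}

#' Implant a paired site into a sequence
#'
#' Overwrites the two recognition-element blocks of an IR or DR arrangement
#' at a given position (0-based start of the left block), leaving the spacer
#' nucleotides as they were, and records a truth entry for scanner
#' round-trip tests.  Substitutions are given in motif-local coordinates per
#' element.  An IR is its own reverse complement, so a minus-strand IR
#' request renders identically to plus and the truth strand is `"."`.
#'
#' @param x A DNA string or an `implant_result` from a previous call
#'   (implants accumulate; overlaps raise a placement error).
#' @param topology `"DR"` or `"IR"`.
#' @param spacer Spacer length in nt (>= 0).
#' @param substitutions List with elements `re1` and `re2`, each a named
#'   character vector `position -> base` (motif-local), or `NULL`.
#' @param strand `"+"` or `"-"` (ignored up to bookkeeping for IR).
#' @param position 0-based start of the left element block.
#' @param consensus Consensus hexamer.
#' @return An `implant_result`: list with `seq` (the modified string) and
#'   `truth` (tibble of expected paired sites, one row per implant).
#' @examples
#' res <- implant_pair(strrep("A", 30), "DR", 5, position = 5)
#' res$truth
#' @export
implant_pair <- function(x, topology = c("DR", "IR"), spacer,
                         substitutions = list(re1 = NULL, re2 = NULL),
                         strand = "+", position, consensus = "TTGCGG") {
  topology <- match.arg(topology)
  if (inherits(x, "implant_result")) {
    seq <- x$seq
    truth <- x$truth
  } else {
    seq <- check_dna(x, "x")
    truth <- NULL
  }
  if (spacer < 0) abort("`spacer` must be >= 0")
  L <- nchar(seq)
  span <- 12L + as.integer(spacer)
  if (position < 0 || position + span > L) {
    abort("implant does not fit inside the sequence")
  }
  re1 <- apply_substitutions(consensus, substitutions$re1)
  re2 <- apply_substitutions(consensus, substitutions$re2)
  mm1 <- length(substitutions$re1)
  mm2 <- length(substitutions$re2)

  first_start <- as.integer(position)
  first_end <- first_start + 6L
  second_start <- first_end + as.integer(spacer)
  second_end <- second_start + 6L
  if (!is.null(truth) && nrow(truth) > 0L) {
    clash <- any(first_start < truth$second_end & second_end > truth$first_start)
    if (clash) abort("implant overlaps a previously implanted feature")
  }

  if (topology == "DR") {
    if (strand == "+") {
      left <- re1
      right <- re2
      re_first <- re1
      re_second <- re2
      mmf <- mm1
      mms <- mm2
    } else {
      # Minus-strand DR: plus rendering CCGCAA-type; biological first
      # element sits rightmost on plus.
      left <- revcomp(re2)
      right <- revcomp(re1)
      re_first <- re2
      re_second <- re1
      mmf <- mm2
      mms <- mm1
    }
    out_strand <- strand
  } else {
    left <- re1
    right <- revcomp(re2)
    re_first <- re1
    re_second <- re2
    mmf <- mm1
    mms <- mm2
    out_strand <- "."
  }
  substr(seq, first_start + 1L, first_end) <- left
  substr(seq, second_start + 1L, second_end) <- right

  row <- tibble::tibble(
    topology = topology, strand = out_strand,
    first_start = first_start, first_end = first_end,
    second_start = second_start, second_end = second_end,
    spacer = as.integer(spacer),
    re_first = re_first, re_second = re_second,
    mm_first = as.integer(mmf), mm_second = as.integer(mms)
  )
  structure(
    list(seq = seq, truth = dplyr::bind_rows(truth, row)),
    class = "implant_result"
  )
}

# One centered probe: background + implant; returns list(seq, truth row).
centered_probe <- function(config, topology, spacer, substitutions = NULL,
                           strand = "+") {
  L <- config$probe_length
  span <- 12L + as.integer(spacer)
  if (span > L) abort("arrangement longer than the probe")
  bg <- paste(random_bases(L, config), collapse = "")
  implant_pair(bg, topology, spacer,
    substitutions = substitutions %||% list(re1 = NULL, re2 = NULL),
    strand = strand, position = (L - span) %/% 2L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the 50-bp probe panel
#'
#' Rebuilds, with seeded backgrounds, the synthetic EMSA probe set: the
#' perfect direct repeat (PDR), perfect inverted repeat (PIR), a single
#' recognition element (RE), a negative control (NC) in which the 12 RE
#' nucleotides are position-randomized and post-verified to contain zero
#' stringent hits (reshuffled up to `max_retries` times, never emitted
#' unverified), the spacer-swap series (DR n = 1–10 and 15; IR n = 1–10 and
#' 14) and the central-GC mutant quartet of the second element (plus-strand
#' G->T and C->A on each topology).
#'
#' @param config A [generator_config()].
#' @param model A [motif_model()] (consensus + grammar used for
#'   construction and NC verification).
#' @param max_retries NC reshuffle bound.
#' @return A list of class `probe_panel`: `$probes` (tibble `probe_id`,
#'   `group`, `topology`, `spacer`, `seq`, `description`) and `$truth`
#'   (expected paired sites keyed by `probe_id`).
#' @export
make_probe_panel <- function(config = generator_config(),
                             model = motif_model(), max_retries = 100L) {
  cons <- model$consensus
  g <- model$grammar
  withr::with_seed(config$seed, {
    probes <- list()
    truth <- list()
    add <- function(id, group, res, topology = NA, spacer = NA,
                    description = "") {
      probes[[id]] <<- tibble::tibble(
        probe_id = id, group = group, topology = topology,
        spacer = spacer, seq = res$seq, description = description
      )
      if (!is.null(res$truth)) {
        truth[[id]] <<- dplyr::mutate(res$truth,
          probe_id = id,
          .before = 1
        )
      }
    }

    add(
      "PDR", "reference",
      centered_probe(config, "DR", g$DR$optimal_spacer),
      "DR", g$DR$optimal_spacer, "perfect direct repeat"
    )
    add(
      "PIR", "reference",
      centered_probe(config, "IR", g$IR$optimal_spacer),
      "IR", g$IR$optimal_spacer, "perfect inverted repeat"
    )

    # Single RE probe: one element, no partner.
    L <- config$probe_length
    bg <- paste(random_bases(L, config), collapse = "")
    pos <- (L - 6L) %/% 2L
    substr(bg, pos + 1L, pos + 6L) <- cons
    probes[["RE"]] <- tibble::tibble(
      probe_id = "RE", group = "reference", topology = NA_character_,
      spacer = NA_integer_, seq = bg,
      description = "single recognition element"
    )

    # NC: PDR layout with the 12 RE nucleotides shuffled in place,
    # re-verified to carry zero stringent hits (either topology).
    pdr_truth <- truth[["PDR"]]
    re_pos <- c(
      seq(pdr_truth$first_start + 1L, pdr_truth$first_end),
      seq(pdr_truth$second_start + 1L, pdr_truth$second_end)
    )
    nc <- NULL
    for (i in seq_len(max_retries)) {
      cand <- strsplit(probes[["PDR"]]$seq, "")[[1]]
      cand[re_pos] <- sample(cand[re_pos])
      cand <- paste(cand, collapse = "")
      hits <- scan_stringent(cand, model,
        max_mismatch = 1L,
        include_ir = TRUE
      )
      if (nrow(hits) == 0L) {
        nc <- cand
        break
      }
    }
    if (is.null(nc)) {
      abort("could not build a clean negative control within `max_retries`")
    }
    probes[["NC"]] <- tibble::tibble(
      probe_id = "NC", group = "reference", topology = NA_character_,
      spacer = NA_integer_, seq = nc,
      description = "negative control (RE nucleotides position-randomized)"
    )

    for (n in c(1:10, 15L)) {
      add(
        sprintf("DR_n%02d", n), "spacer_series_DR",
        centered_probe(config, "DR", n), "DR", n,
        sprintf("DR spacer swap, n = %d", n)
      )
    }
    for (n in c(1:10, 14L)) {
      add(
        sprintf("IR_n%02d", n), "spacer_series_IR",
        centered_probe(config, "IR", n), "IR", n,
        sprintf("IR spacer swap, n = %d", n)
      )
    }

    # Central-GC quartet: identical plus-strand substitutions in the second
    # element of each topology (motif-local images differ by construction).
    add(
      "PDR_G3T", "central_GC",
      centered_probe(config, "DR", g$DR$optimal_spacer,
        substitutions = list(re1 = NULL, re2 = c("3" = "T"))
      ),
      "DR", g$DR$optimal_spacer, "PDR second element G3->T (plus strand)"
    )
    add(
      "PDR_C4A", "central_GC",
      centered_probe(config, "DR", g$DR$optimal_spacer,
        substitutions = list(re1 = NULL, re2 = c("4" = "A"))
      ),
      "DR", g$DR$optimal_spacer, "PDR second element C4->A (plus strand)"
    )
    add(
      "PIR_G3T", "central_GC",
      centered_probe(config, "IR", g$IR$optimal_spacer,
        substitutions = list(re1 = NULL, re2 = c("4" = "A"))
      ),
      "IR", g$IR$optimal_spacer,
      "PIR second element G3->T on plus strand (motif-local C4->A)"
    )
    add(
      "PIR_C4A", "central_GC",
      centered_probe(config, "IR", g$IR$optimal_spacer,
        substitutions = list(re1 = NULL, re2 = c("3" = "T"))
      ),
      "IR", g$IR$optimal_spacer,
      "PIR second element C4->A on plus strand (motif-local G3->T)"
    )

    structure(
      list(
        probes = dplyr::bind_rows(probes),
        truth = dplyr::bind_rows(truth)
      ),
      class = "probe_panel"
    )
  })
}

#' Simulate an EMSA titration
#'
#' Draws fraction-bound values from the Hill isotherm with additive
#' truncated-Gaussian noise (multiplicative optional), emulating replicate
#' densitometry measurements.  Deterministic given `seed`.
#'
#' @param K_d,n_H Generating Hill parameters (defaults: the cooperative
#'   core-module fit, `K_d` 2.4 uM, `n_H` 1.4).
#' @param concs Concentration grid in uM (default a 2-fold series
#'   0.075–9.6 uM).
#' @param noise_sd Gaussian noise SD on the fraction scale (>= 0).
#' @param replicates Number of replicates.
#' @param seed RNG seed.
#' @param noise `"additive"` (truncated to `[0, 1]`) or `"multiplicative"`
#'   (`theta * (1 + eps)`, then truncated).
#' @param probe_id Probe label in the output.
#' @return A tidy titration tibble: `probe_id`, `replicate`, `conc_uM`,
#'   `fraction_bound`.
#' @examples
#' simulate_titration(noise_sd = 0, replicates = 1, seed = 1)
#' @export
simulate_titration <- function(K_d = 2.4, n_H = 1.4,
                               concs = 0.075 * 2^(0:7),
                               noise_sd = 0, replicates = 3L, seed = 1L,
                               noise = c("additive", "multiplicative"),
                               probe_id = "core_module") {
  noise <- match.arg(noise)
  if (any(concs < 0)) abort("`concs` must be non-negative")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  theta <- occupancy(concs, K_d, n_H)
  withr::with_seed(seed, {
    purrr::map(seq_len(replicates), function(r) {
      eps <- stats::rnorm(length(concs), 0, noise_sd)
      fb <- if (noise == "additive") theta + eps else theta * (1 + eps)
      tibble::tibble(
        probe_id = probe_id, replicate = r, conc_uM = concs,
        fraction_bound = pmin(pmax(fb, 0), 1)
      )
    }) %>% dplyr::bind_rows()
  })
}

#' Synthetic promoter fixtures
#'
#' Builds a ~260-bp promoter with a planted core promoter (`TTGACA`, 17-nt
#' separation, extended-10 `TG` + `TATAAT`) and one of several site layouts
#' observed in ComA-regulated promoters:
#'
#' * `class_III` — perfect IR at the class I position (20 nt upstream of
#'   -35) plus perfect DR adjacent to -35 (class II position).
#' * `single_dr` — one perfect minus-strand DR ending 30 nt upstream of
#'   -35 (the isolated non-canonical site layout).
#' * `dr_cluster` — three degenerate DRs (one untested substitution per
#'   element) clustered upstream, no core module.
#' * `degenerate_dr` — a single degenerate DR in isolation.
#' * `core_module` — perfect IR plus degenerate DR at the -35-adjacent
#'   position.
#' * `core_module_no_ir` — the same degenerate DR without its IR partner.
#' * `pel_like` — `dr_cluster` plus `core_module` (cluster-amplified
#'   promoter layout).
#' * `no_sites` — core promoter only.
#'
#' The background is redrawn (bounded retries) until a stringent scan
#' (<= 1 mismatch per element, both topologies) recovers exactly the
#' implanted truth, so fixtures carry no accidental extra sites.
#'
#' @param kind Fixture layout (see above).
#' @param config A [generator_config()].
#' @param seq_length Total promoter length (default 260 nt).
#' @param max_retries Background redraw bound.
#' @return A list: `seq_id`, `seq`, `sites` (truth paired-site tibble),
#'   `annotation` (core-promoter truth tibble).
#' @export
make_promoter_fixture <- function(kind = c(
                                    "class_III", "single_dr", "dr_cluster",
                                    "degenerate_dr", "core_module",
                                    "core_module_no_ir", "pel_like",
                                    "no_sites"
                                  ),
                                  config = generator_config(),
                                  seq_length = 260L, max_retries = 50L) {
  kind <- match.arg(kind)
  m35s <- 200L # 0-based start of the -35 hexamer
  m10s <- m35s + 6L + 17L # 17-nt separation
  deg1 <- list(re1 = c("5" = "C"), re2 = NULL) # untested transversions:
  deg2 <- list(re1 = NULL, re2 = c("2" = "G")) # degenerate but unbindable
  degb <- list(re1 = c("5" = "C"), re2 = c("2" = "G"))

  implants <- switch(kind,
    class_III = list(
      list("IR", 4L, NULL, "+", 164L), # ends 180, 20 nt upstream of -35
      list("DR", 5L, NULL, "+", 181L) # ends 198, adjacent to -35
    ),
    single_dr = list(list("DR", 5L, NULL, "-", 153L)), # ends 170
    dr_cluster = list(
      list("DR", 5L, degb, "+", 63L),
      list("DR", 5L, deg1, "+", 103L),
      list("DR", 5L, deg2, "+", 143L)
    ),
    degenerate_dr = list(list("DR", 5L, degb, "+", 103L)),
    core_module = list(
      list("IR", 4L, NULL, "+", 164L),
      list("DR", 5L, deg2, "+", 181L)
    ),
    core_module_no_ir = list(list("DR", 5L, deg2, "+", 181L)),
    pel_like = list(
      list("DR", 5L, degb, "+", 63L),
      list("DR", 5L, deg1, "+", 103L),
      list("DR", 5L, deg2, "+", 143L),
      list("IR", 4L, NULL, "+", 164L),
      list("DR", 5L, deg2, "+", 181L)
    ),
    no_sites = list()
  )

  seq_id <- paste0("synthetic_", kind)
  result <- NULL
  withr::with_seed(config$seed, {
    for (try in seq_len(max_retries)) {
      seq <- paste(random_bases(seq_length, config), collapse = "")
      substr(seq, m35s + 1L, m35s + 6L) <- "TTGACA"
      substr(seq, m10s - 1L, m10s) <- "TG"
      substr(seq, m10s + 1L, m10s + 6L) <- "TATAAT"
      res <- list(seq = seq, truth = NULL)
      class(res) <- "implant_result"
      for (im in implants) {
        res <- implant_pair(res, im[[1]], im[[2]],
          substitutions = im[[3]] %||% list(re1 = NULL, re2 = NULL),
          strand = im[[4]], position = im[[5]]
        )
      }
      found <- scan_stringent(res$seq,
        max_mismatch = 1L, include_ir = TRUE,
        seq_id = seq_id
      )
      truth <- res$truth %||%
        tibble::tibble(first_start = integer(), second_start = integer())
      same <- nrow(found) == nrow(truth) &&
        (nrow(found) == 0L ||
          identical(
            found[order(found$first_start), c("first_start", "second_start")],
            truth[
              order(truth$first_start),
              c("first_start", "second_start")
            ]
          ))
      if (same) {
        sites <- if (is.null(res$truth)) {
          found
        } else {
          dplyr::mutate(res$truth, seq_id = seq_id, .before = 1)
        }
        result <- list(
          seq_id = seq_id, seq = res$seq, sites = sites,
          annotation = tibble::tibble(
            seq_id = seq_id,
            minus35_start = m35s, minus35_end = m35s + 6L,
            minus10_start = m10s, minus10_end = m10s + 6L,
            extended_minus10 = TRUE, source = "truth"
          )
        )
        break
      }
    }
  })
  if (is.null(result)) {
    abort("could not build a clean promoter fixture within `max_retries`")
  }
  result
}
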