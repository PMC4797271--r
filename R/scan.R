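#' Find recognition-element matches on both strands
#'
#' Slides the hexamer over every window of `seq` and its reverse complement.
#' In `stringent` mode a window matches when its Hamming distance to the
#' consensus (in motif-local orientation) is at most `max_mismatch`; in
#' `relaxed` mode when the exact tail p-value of its log-odds score is at
#' most `pvalue_threshold`.  Windows containing N never match.
#'
#' Coordinates are 0-based half-open on the plus strand throughout the
#' package; `observed` is always the motif-local word (reverse-complemented
#' for minus-strand matches).
#'
#' @param seq DNA string (A/C/G/T/N).
#' @param model A [motif_model()]; relaxed mode needs a PFM.
#' @param mode `"stringent"` or `"relaxed"`.
#' @param max_mismatch Mismatch budget per element (stringent mode).
#' @param pvalue_threshold Per-element p-value cutoff (relaxed mode).
#' @param seq_id Identifier recorded in the output.
#' @param pvalue_table Optional precomputed [score_pvalue_table()]; computed
#'   on the fly when needed.
#'
#' @return A tibble with one row per match: `seq_id`, `start`, `end`
#'   (0-based half-open), `strand`, `observed`, `mismatches`, `score`,
#'   `pvalue`, sorted by (start, strand).
#' @examples
#' find_re_matches("TTGCGGAAAAATTGCGG", max_mismatch = 0)
#' @export
find_re_matches <- function(seq, model = motif_model(),
                            mode = c("stringent", "relaxed"),
                            max_mismatch = 1L, pvalue_threshold = 1e-3,
                            seq_id = "seq", pvalue_table = NULL) {
  mode <- match.arg(mode)
  seq <- check_dna(seq, "seq")
  empty <- tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), observed = character(),
    mismatches = integer(), score = double(), pvalue = double()
  )
  L <- nchar(seq)
  if (L < 6L) {
    return(empty)
  }
  if (mode == "stringent" &&
    (!is.numeric(max_mismatch) || max_mismatch < 0)) {
    abort("`max_mismatch` must be >= 0")
  }
  if (mode == "relaxed") {
    if (!is.numeric(pvalue_threshold) || pvalue_threshold <= 0 ||
      pvalue_threshold > 1) {
      abort("`pvalue_threshold` must lie in (0, 1]")
    }
    if (is.null(model$pfm)) {
      abort("relaxed mode needs a PFM; build the model with build_pfm()")
    }
  }

  chars <- strsplit(seq, "")[[1]]
  nwin <- L - 5L
  cons <- strsplit(model$consensus, "")[[1]]
  cons_rc <- strsplit(revcomp(model$consensus), "")[[1]]

  mm_p <- integer(nwin)
  mm_m <- integer(nwin)
  has_n <- logical(nwin)
  for (j in 1:6) {
    cj <- chars[j:(j + nwin - 1L)]
    has_n <- has_n | !(cj %in% DNA_BASES)
    mm_p <- mm_p + (cj != cons[j])
    mm_m <- mm_m + (cj != cons_rc[j])
  }

  score_p <- score_m <- rep(NA_real_, nwin)
  pv_p <- pv_m <- rep(NA_real_, nwin)
  have_pwm <- !is.null(model$pfm) && all(prob_matrix(model) > 0)
  if (have_pwm) {
    lom <- log_odds_matrix(model)
    # Minus-strand score of plus window w = score of revcomp(w): the base at
    # plus offset j maps to motif column 7-j with the complementary base.
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    lom_rc <- lom
    for (b in DNA_BASES) lom_rc[b, ] <- rev(lom[comp[b], ])
    score_p <- numeric(nwin)
    score_m <- numeric(nwin)
    for (j in 1:6) {
      ri <- match(chars[j:(j + nwin - 1L)], DNA_BASES)
      ri[is.na(ri)] <- 1L # placeholder; N windows dropped below
      score_p <- score_p + lom[ri + (j - 1L) * 4L]
      score_m <- score_m + lom_rc[ri + (j - 1L) * 4L]
    }
    score_p[has_n] <- -Inf
    score_m[has_n] <- -Inf
    if (mode == "relaxed") {
      if (is.null(pvalue_table)) pvalue_table <- score_pvalue_table(model)
      pv_p <- score_tail_pvalue(score_p, pvalue_table)
      pv_m <- score_tail_pvalue(score_m, pvalue_table)
    }
  }

  if (mode == "stringent") {
    keep_p <- !has_n & mm_p <= max_mismatch
    keep_m <- !has_n & mm_m <= max_mismatch
  } else {
    keep_p <- !has_n & !is.na(pv_p) & pv_p <= pvalue_threshold
    keep_m <- !has_n & !is.na(pv_m) & pv_m <= pvalue_threshold
  }

  row_for <- function(idx, on_plus) {
    if (!length(idx)) {
      return(empty)
    }
    win <- substring(seq, idx, idx + 5L)
    tibble::tibble(
      seq_id = seq_id,
      start = idx - 1L,
      end = idx + 5L,
      strand = if (on_plus) "+" else "-",
      observed = if (on_plus) win else revcomp(win),
      mismatches = if (on_plus) mm_p[idx] else mm_m[idx],
      score = if (on_plus) score_p[idx] else score_m[idx],
      pvalue = if (on_plus) pv_p[idx] else pv_m[idx]
    )
  }
  out <- dplyr::bind_rows(
    row_for(which(keep_p), TRUE),
    row_for(which(keep_m), FALSE)
  )
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Exact null distribution of the log-odds score
#'
#' Computes `P(score >= s)` for a random hexamer drawn from the model
#' background, by discretizing the per-column scores to integer bins and
#' convolving the column distributions (the standard exact-p-value dynamic
#' program for PWM scanning).  Tail probabilities are exact for the
#' discretized score; the discretization error of any word's score is at
#' most half a bin per column.
#'
#' @param model A [motif_model()] with a PFM.
#' @param bin_width Score discretization width (log2-odds units), > 0.
#' @return A tibble of class `score_pvalue_table` with columns `score`
#'   (bin centers), `prob` (point mass) and `pvalue` (tail `P(S >= score)`),
#'   in increasing score order; `attr(, "bin_width")` records the bin.
#' @examples
#' m <- build_pfm(c("TTGCGG", "TTGCGG"), pseudocount = 0.25)
#' tab <- score_pvalue_table(m)
#' head(tab)
#' @export
score_pvalue_table <- function(model, bin_width = 0.01) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    abort("`bin_width` must be a single positive number")
  }
  lom <- log_odds_matrix(model)
  K <- round(lom / bin_width)
  bg <- model$background
  lo <- 0L
  v <- 1
  for (j in 1:6) {
    kj <- K[, j]
    lo2 <- lo + min(kj)
    hi2 <- lo + max(kj) + length(v) - 1L
    v2 <- numeric(hi2 - lo2 + 1L)
    for (b in 1:4) {
      off <- lo + kj[b] - lo2
      idx <- seq_along(v) + off
      v2[idx] <- v2[idx] + v * bg[b]
    }
    v <- v2
    lo <- lo2
  }
  keep <- v > 0
  scores <- (lo + seq_along(v) - 1L) * bin_width
  tail <- rev(cumsum(rev(v)))
  out <- tibble::tibble(
    score = scores[keep],
    prob = v[keep],
    pvalue = pmin(tail[keep], 1)
  )
  class(out) <- c("score_pvalue_table", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

# Tail p-value of observed scores against a score_pvalue_table.
score_tail_pvalue <- function(score, table) {
  w <- attr(table, "bin_width")
  k <- round(score / w) * w
  out <- rep(NA_real_, length(score))
  finite <- is.finite(score)
  # P(S >= s): first table row with score >= k - w/2
  idx <- findInterval(k[finite] - w / 2, table$score, left.open = TRUE) + 1L
  out[finite] <- ifelse(idx > nrow(table), 0, table$pvalue[pmax(idx, 1L)])
  out[!finite & !is.na(score)] <- 1
  out
}

#' Pair element matches into inverted- and direct-repeat units
#'
#' Joins single-element matches from one sequence into topology units:
#' a DR is two same-strand matches (plus-strand rendering
#' `TTGCGG-N_n-TTGCGG` on `+`, `CCGCAA-N_n-CCGCAA` on `-`); an IR is a plus
#' match followed by a minus match (plus-strand rendering
#' `TTGCGG-N_n-CCGCAA`), reported with strand `"."` because the arrangement
#' is its own reverse complement.  The spacer is `second.start - first.end`
#' on the plus strand.  Pairs may share an element; all are reported (see
#' [dedupe_pairs()]).
#'
#' @param matches Tibble from [find_re_matches()] (single `seq_id`).
#' @param spacers Named list of allowed spacer sets per topology,
#'   e.g. `list(DR = 5L, IR = 4L)`.
#' @param topologies Topologies to emit (`"DR"`, `"IR"` or both).
#'
#' @return A tibble with one row per paired site: `seq_id`, `topology`,
#'   `strand`, `first_start`, `first_end`, `second_start`, `second_end`,
#'   `spacer`, `re_first`, `re_second` (motif-local words in plus-coordinate
#'   order), `mm_first`, `mm_second`, `combined_score`.
#' @export
pair_sites <- function(matches,
                       spacers = list(DR = c(4L, 5L), IR = c(4L, 5L)),
                       topologies = c("DR", "IR")) {
  empty <- tibble::tibble(
    seq_id = character(), topology = character(), strand = character(),
    first_start = integer(), first_end = integer(),
    second_start = integer(), second_end = integer(), spacer = integer(),
    re_first = character(), re_second = character(),
    mm_first = integer(), mm_second = integer(), combined_score = double()
  )
  if (nrow(matches) == 0L) {
    return(empty)
  }
  if (length(unique(matches$seq_id)) > 1L) {
    abort("`pair_sites()` expects matches from a single seq_id")
  }
  n <- nrow(matches)
  ij <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) %>%
    dplyr::filter(.data$i != .data$j)
  a <- matches[ij$i, ]
  b <- matches[ij$j, ]
  sp <- b$start - a$end
  left_first <- a$start < b$start

  pick <- function(cond, topology, strand) {
    keep <- which(cond)
    if (!length(keep)) {
      return(empty)
    }
    tibble::tibble(
      seq_id = a$seq_id[keep],
      topology = topology,
      strand = strand[keep],
      first_start = a$start[keep], first_end = a$end[keep],
      second_start = b$start[keep], second_end = b$end[keep],
      spacer = sp[keep],
      re_first = a$observed[keep], re_second = b$observed[keep],
      mm_first = a$mismatches[keep], mm_second = b$mismatches[keep],
      combined_score = a$score[keep] + b$score[keep]
    )
  }
  out <- empty
  if ("DR" %in% topologies) {
    cond <- left_first & a$strand == b$strand & sp %in% spacers$DR
    out <- dplyr::bind_rows(out, pick(cond, "DR", a$strand))
  }
  if ("IR" %in% topologies) {
    cond <- left_first & a$strand == "+" & b$strand == "-" &
      sp %in% spacers$IR
    out <- dplyr::bind_rows(out, pick(cond, "IR", rep(".", nrow(a))))
  }
  out %>%
    dplyr::distinct(
      .data$seq_id, .data$topology, .data$strand,
      .data$first_start, .data$second_start,
      .keep_all = TRUE
    ) %>%
    dplyr::arrange(.data$first_start, .data$second_start, .data$topology)
}

#' Stringent paired-site scan
#'
#' The genome-scan rule used to find isolated non-canonical sites: optimal
#' spacer required, at most `max_mismatch` (default 1) mismatched nucleotide
#' per recognition element.  By default only DR units (spacer exactly 5) are
#' reported; IR scanning (spacer exactly 4) is opt-in.
#'
#' @param seq DNA string.
#' @param model A [motif_model()].
#' @param max_mismatch Per-element mismatch budget (default 1).
#' @param include_ir Also report IR units at their optimal spacer.
#' @param seq_id Identifier recorded in the output.
#' @return A paired-site tibble (see [pair_sites()]).
#' @examples
#' scan_stringent("TTGCGGAAAAATTGCGT")
#' @export
scan_stringent <- function(seq, model = motif_model(), max_mismatch = 1L,
                           include_ir = FALSE, seq_id = "seq") {
  m <- find_re_matches(seq, model,
    mode = "stringent",
    max_mismatch = max_mismatch, seq_id = seq_id
  )
  g <- model$grammar
  topo <- if (include_ir) c("DR", "IR") else "DR"
  pair_sites(m,
    spacers = list(
      DR = g$DR$optimal_spacer,
      IR = g$IR$optimal_spacer
    ),
    topologies = topo
  )
}

#' Relaxed paired-site scan
#'
#' PWM-based scan: each element must pass the exact-score p-value threshold;
#' both topologies are paired at their optimal and tolerated spacers.
#'
#' @inheritParams scan_stringent
#' @param pvalue_threshold Per-element p-value cutoff (default 1e-3).
#' @param pvalue_table Optional precomputed [score_pvalue_table()].
#' @return A paired-site tibble (see [pair_sites()]).
#' @export
scan_relaxed <- function(seq, model, pvalue_threshold = 1e-3,
                         seq_id = "seq", pvalue_table = NULL) {
  m <- find_re_matches(seq, model,
    mode = "relaxed",
    pvalue_threshold = pvalue_threshold,
    seq_id = seq_id, pvalue_table = pvalue_table
  )
  g <- model$grammar
  pair_sites(m, spacers = list(
    DR = c(g$DR$optimal_spacer, g$DR$tolerated_spacer),
    IR = c(g$IR$optimal_spacer, g$IR$tolerated_spacer)
  ))
}

#' Resolve overlapping paired sites
#'
#' Pairs may share a recognition element; this documented post-filter groups
#' pairs whose footprints overlap (per seq_id) and keeps the best of each
#' cluster: highest `combined_score`, or fewest total mismatches when scores
#' are absent.
#'
#' @param pairs A paired-site tibble.
#' @return The filtered tibble.
#' @export
dedupe_pairs <- function(pairs) {
  if (nrow(pairs) < 2L) {
    return(pairs)
  }
  pairs %>%
    dplyr::group_by(.data$seq_id) %>%
    dplyr::arrange(.data$first_start, .by_group = TRUE) %>%
    dplyr::mutate(
      cluster = cumsum(.data$first_start >=
        dplyr::lag(cummax(.data$second_end), default = -1L))
    ) %>%
    dplyr::group_by(.data$seq_id, .data$cluster) %>%
    dplyr::arrange(
      dplyr::desc(dplyr::coalesce(.data$combined_score, -Inf)),
      .data$mm_first + .data$mm_second,
      .by_group = TRUE
    ) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"cluster") %>%
    dplyr::arrange(.data$seq_id, .data$first_start)
}
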