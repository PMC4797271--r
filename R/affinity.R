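#' Empirical affinity rule table
#'
#' Encodes the EMSA-derived binding rules for paired sites as data: a spacer
#' table and a single-substitution table, composed multiplicatively on an
#' apparent fold penalty (1 = optimal, 2 = roughly 2-fold reduced, `Inf` =
#' no binding observed up to the highest tested concentration).
#'
#' Spacer rules (spacer series tested at n = 1–10 plus 15 for DR, 14 for
#' IR): DR 5 nt optimal, 4 tolerated at twice the concentration, all other
#' tested lengths abolish binding; IR 4 nt optimal, 5 tolerated, others
#' abolish.  Untested spacers default to no binding, flagged `untested`.
#'
#' Substitution rules are expressed in motif-local coordinates of the
#' consensus `TTGCGG`: a position-1 transition (T->C) and the position-3
#' G->T transversion each cost 2-fold; the position-4 C->A transversion and
#' every other tested transition abolish binding; remaining (untested)
#' single substitutions default to no binding with an `untested` flag; two
#' or more substitutions in one element abolish binding.  Reading elements
#' motif-locally makes the central-GC behavior of the two topologies emerge
#' from one table: the identical plus-strand mutation of the second IR
#' element maps to the opposite motif-local rule.
#'
#' @param consensus Consensus hexamer the substitution table refers to.
#' @return A list of class `affinity_rules` with tibbles `spacer` and
#'   `substitution`, plus `consensus` and `note` fields.
#' @examples
#' rules <- default_affinity_rules()
#' rules$spacer
#' @export
default_affinity_rules <- function(consensus = "TTGCGG") {
  consensus <- check_dna(consensus, "consensus", allow_n = FALSE)
  spacer <- dplyr::bind_rows(
    tibble::tibble(
      topology = "DR", spacer = c(1:10, 15L),
      penalty = ifelse(c(1:10, 15L) == 5L, 1,
        ifelse(c(1:10, 15L) == 4L, 2, Inf)
      ),
      tested = TRUE
    ),
    tibble::tibble(
      topology = "IR", spacer = c(1:10, 14L),
      penalty = ifelse(c(1:10, 14L) == 4L, 1,
        ifelse(c(1:10, 14L) == 5L, 2, Inf)
      ),
      tested = TRUE
    )
  )
  cons <- strsplit(consensus, "")[[1]]
  sub <- tidyr::expand_grid(position = 1:6, to = DNA_BASES) %>%
    dplyr::mutate(from = cons[.data$position]) %>%
    dplyr::filter(.data$to != .data$from) %>%
    dplyr::mutate(
      transition = .data$to == TRANSITION[.data$from],
      penalty = dplyr::case_when(
        .data$position == 1L & .data$transition ~ 2,
        .data$position == 3L & .data$from == "G" & .data$to == "T" ~ 2,
        TRUE ~ Inf
      ),
      tested = .data$transition |
        (.data$position == 3L & .data$to == "T") |
        (.data$position == 4L & .data$to == "A")
    ) %>%
    dplyr::select("position", "from", "to", "penalty", "tested")
  structure(
    list(
      consensus = consensus,
      spacer = spacer,
      substitution = sub,
      note = paste(
        "Point-substitution penalties follow the main-text reading",
        "(all point mutations reduce affinity; only position-1 transitions",
        "are tolerated at ~2-fold) rather than the figure legend's",
        "'no change' category."
      )
    ),
    class = "affinity_rules"
  )
}

#' Write / read an affinity rule table as YAML
#'
#' The rule table is plain data, so users can extend the substitution map
#' (e.g. after testing further mutants) and reload it.
#'
#' @param rules An `affinity_rules` object.
#' @param path File path.
#' @return `write_affinity_rules()` returns `path` invisibly;
#'   `read_affinity_rules()` returns an `affinity_rules` object.
#' @export
write_affinity_rules <- function(rules, path) {
  stopifnot(inherits(rules, "affinity_rules"))
  enc <- function(df) {
    df <- as.data.frame(df)
    if ("penalty" %in% names(df)) {
      df$penalty <- ifelse(is.infinite(df$penalty), "none", df$penalty)
    }
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  yaml::write_yaml(
    list(
      schema = "comascan-affinity-rules/1",
      consensus = rules$consensus,
      note = rules$note,
      spacer = enc(rules$spacer),
      substitution = enc(rules$substitution)
    ),
    path
  )
  invisible(path)
}

#' @rdname write_affinity_rules
#' @export
read_affinity_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "comascan-affinity-rules/1")) {
    abort("unrecognized affinity rule schema")
  }
  dec <- function(lst) {
    df <- dplyr::bind_rows(lapply(lst, tibble::as_tibble))
    pen <- as.character(df$penalty)
    num <- rep(Inf, length(pen))
    num[pen != "none"] <- as.numeric(pen[pen != "none"])
    df$penalty <- num
    df
  }
  out <- default_affinity_rules(raw$consensus)
  out$spacer <- dec(raw$spacer) %>%
    dplyr::mutate(spacer = as.integer(.data$spacer))
  out$substitution <- dec(raw$substitution) %>%
    dplyr::mutate(position = as.integer(.data$position))
  out$note <- raw$note
  out
}

# Penalty + provenance for one motif-local element sequence.
re_penalty <- function(observed, rules) {
  mm <- mismatch_count(observed, rules$consensus)
  pos <- attr(mm, "positions")
  if (length(pos) == 0L) {
    return(list(penalty = 1, rules = character()))
  }
  if (length(pos) >= 2L) {
    return(list(
      penalty = Inf,
      rules = sprintf("%d substitutions in one RE: none", length(pos))
    ))
  }
  obs <- strsplit(observed, "")[[1]][pos]
  hit <- rules$substitution %>%
    dplyr::filter(.data$position == pos, .data$to == obs)
  if (nrow(hit) != 1L) {
    return(list(penalty = Inf, rules = "unknown substitution: none"))
  }
  lab <- sprintf(
    "RE pos%d %s>%s: %s%s", pos, hit$from, hit$to,
    ifelse(is.infinite(hit$penalty), "none",
      paste0("x", format(hit$penalty))
    ),
    ifelse(hit$tested, "", " [untested]")
  )
  list(penalty = hit$penalty, rules = lab)
}

#' Classify paired sites by empirical binding affinity
#'
#' Applies the EMSA rule cascade to each paired site: the spacer rule for
#' its topology and the single-substitution rule for each recognition
#' element, composing fold penalties multiplicatively.  The result is an
#' affinity label — `OPTIMAL` (penalty 1), `REDUCED` (finite penalty > 1) or
#' `NONE` (no binding up to the tested concentration ceiling; penalty
#' `Inf`) — with a provenance string listing every triggered rule.
#' Compositions of two or more finite penalties were never tested jointly
#' and are flagged `extrapolated`.
#'
#' @param pairs A paired-site tibble from [pair_sites()] or the scanners.
#' @param rules An `affinity_rules` table (default
#'   [default_affinity_rules()]).
#' @return `pairs` with columns `affinity`, `fold_penalty` and `provenance`
#'   added.
#' @examples
#' p <- scan_stringent("TTGCGGAAAAATTGCGG")
#' classify_pair(p)[, c("topology", "spacer", "affinity", "fold_penalty")]
#' @export
classify_pair <- function(pairs, rules = default_affinity_rules()) {
  needed <- c("topology", "spacer", "re_first", "re_second")
  if (!all(needed %in% names(pairs))) {
    abort(paste(
      "pairs lack motif-local element sequences; expected columns:",
      paste(needed, collapse = ", ")
    ))
  }
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs,
      affinity = character(), fold_penalty = double(),
      provenance = character()
    ))
  }
  res <- purrr::pmap(
    list(pairs$topology, pairs$spacer, pairs$re_first, pairs$re_second),
    function(topology, spacer, re_first, re_second) {
      prov <- character()
      srow <- rules$spacer %>%
        dplyr::filter(.data$topology == !!topology, .data$spacer == !!spacer)
      if (nrow(srow) == 1L) {
        sp_pen <- srow$penalty
        prov <- c(prov, sprintf(
          "%s spacer %d: %s", topology, spacer,
          ifelse(is.infinite(sp_pen), "none", paste0("x", format(sp_pen)))
        ))
      } else {
        sp_pen <- Inf
        prov <- c(prov, sprintf(
          "%s spacer %d: none [untested]",
          topology, spacer
        ))
      }
      p1 <- re_penalty(re_first, rules)
      p2 <- re_penalty(re_second, rules)
      prov <- c(prov, p1$rules, p2$rules)
      pen <- sp_pen * p1$penalty * p2$penalty
      n_finite <- sum(c(sp_pen, p1$penalty, p2$penalty) > 1 &
        is.finite(c(sp_pen, p1$penalty, p2$penalty)))
      if (is.finite(pen) && n_finite >= 2L) {
        prov <- c(prov, "composed penalties [extrapolated]")
      }
      list(
        affinity = if (is.infinite(pen)) {
          "NONE"
        } else if (pen == 1) "OPTIMAL" else "REDUCED",
        fold_penalty = pen,
        provenance = paste(prov, collapse = "; ")
      )
    }
  )
  pairs %>%
    dplyr::mutate(
      affinity = purrr::map_chr(res, "affinity"),
      fold_penalty = purrr::map_dbl(res, "fold_penalty"),
      provenance = purrr::map_chr(res, "provenance")
    )
}

#' Classify isolated single recognition elements
#'
#' A single element never supports binding on its own, even at an 8-fold
#' higher concentration than the paired sites need, so isolated matches are
#' always `NONE` regardless of score.  Cooperative rescue by nearby sites is
#' handled by [promoter_binding()].
#'
#' @param sites A match tibble from [find_re_matches()].
#' @return `sites` with `affinity`, `fold_penalty`, `provenance` columns.
#' @export
classify_single_re <- function(sites) {
  dplyr::mutate(sites,
    affinity = "NONE",
    fold_penalty = Inf,
    provenance = "single RE: no binding in isolation"
  )
}

#' Hill occupancy
#'
#' Fractional occupancy `theta(c) = c^n_H / (K_d^n_H + c^n_H)`; the
#' cooperative binding isotherm fitted to quantitative EMSA titrations.
#'
#' @param conc Protein concentration(s), uM, >= 0.
#' @param K_d Apparent dissociation constant, uM (> 0).
#' @param n_H Apparent Hill coefficient (> 0).
#' @return Occupancy in `[0, 1]`, same length as `conc`.
#' @examples
#' occupancy(2.4, K_d = 2.4, n_H = 1.4) # 0.5 at the midpoint
#' @export
occupancy <- function(conc, K_d = 2.4, n_H = 1.4) {
  if (any(conc < 0)) abort("`conc` must be non-negative")
  if (K_d <= 0 || n_H <= 0) abort("`K_d` and `n_H` must be positive")
  cn <- conc^n_H
  cn / (K_d^n_H + cn)
}

#' Cooperative bindability of sites within a promoter
#'
#' Implements the cluster logic seen in quantitative EMSAs on multi-site
#' promoters: a site classified `NONE` purely through sequence degeneracy
#' (correct-spacer topology, at most `degenerate_max_mismatch` mismatches
#' per element) is promoted to bindable when at least one other bindable or
#' degenerate site lies within `coupling_window` nt — isolated degenerate
#' sites stay unbindable.  Promoters with two or more bindable sites get the
#' cooperative Hill coefficient (default 1.4); single-site promoters are
#' non-cooperative (`n_H = 1`).  The promoter-level effective `K_d` is
#' `K0_reference` times the fold penalty of the best bindable site (promoted
#' degenerate sites use the "more than 8-fold" concentration bound as a
#' numeric sentinel).
#'
#' @param pairs A classified paired-site tibble (see [classify_pair()]),
#'   sharing one `seq_id`.
#' @param coupling_window Maximum gap (nt) between site footprints for
#'   cooperative coupling.  Default 60.
#' @param degenerate_max_mismatch Mismatch budget per element below which a
#'   `NONE` site counts as merely degenerate.  Default 2.
#' @param K0_reference Apparent concentration scale (uM) at which complexes
#'   with an optimal site become visible.  Default 1.2.
#' @param n_H_cooperative Hill coefficient assigned to promoters with >= 2
#'   bindable sites.  Default 1.4.
#' @param rules Affinity rule table used to decide which spacers are valid
#'   topology spacers (default [default_affinity_rules()]).
#' @return A list of class `promoter_binding`: `$sites` (the input with
#'   `degenerate`, `bindable` and `effective_fold` columns) and `$model`
#'   (one-row tibble: `n_sites`, `n_bindable`, `n_H`, `K_d_eff`).
#' @export
promoter_binding <- function(pairs, coupling_window = 60,
                             degenerate_max_mismatch = 2L,
                             K0_reference = 1.2, n_H_cooperative = 1.4,
                             rules = default_affinity_rules()) {
  if (!"affinity" %in% names(pairs)) {
    abort("run classify_pair() before promoter_binding()")
  }
  n <- nrow(pairs)
  if (n == 0L) {
    sites <- dplyr::mutate(pairs,
      degenerate = logical(), bindable = logical(),
      effective_fold = double()
    )
    model <- tibble::tibble(
      n_sites = 0L, n_bindable = 0L, n_H = 1,
      K_d_eff = NA_real_
    )
    return(structure(list(sites = sites, model = model),
      class = "promoter_binding"
    ))
  }
  spacer_ok <- purrr::map2_lgl(pairs$topology, pairs$spacer, function(t, s) {
    row <- rules$spacer %>%
      dplyr::filter(.data$topology == t, .data$spacer == s)
    nrow(row) == 1L && is.finite(row$penalty)
  })
  degenerate <- pairs$affinity == "NONE" & spacer_ok &
    pairs$mm_first <= degenerate_max_mismatch &
    pairs$mm_second <= degenerate_max_mismatch
  bindable0 <- pairs$affinity != "NONE"
  candidate <- bindable0 | degenerate
  gap <- function(i, j) {
    max(
      0,
      max(pairs$first_start[i], pairs$first_start[j]) -
        min(pairs$second_end[i], pairs$second_end[j])
    )
  }
  promoted <- vapply(seq_len(n), function(i) {
    if (!degenerate[i] || bindable0[i]) {
      return(FALSE)
    }
    any(vapply(
      setdiff(seq_len(n), i),
      function(j) candidate[j] && gap(i, j) <= coupling_window,
      logical(1)
    ))
  }, logical(1))
  bindable <- bindable0 | promoted
  # "More than 8-fold" concentration bound stands in numerically for
  # degenerate sites that bind only through coupling.
  eff <- ifelse(bindable0, pairs$fold_penalty, ifelse(bindable, 8, Inf))
  n_bind <- sum(bindable)
  model <- tibble::tibble(
    n_sites = n,
    n_bindable = n_bind,
    n_H = if (n_bind >= 2L) n_H_cooperative else 1,
    K_d_eff = if (n_bind >= 1L) K0_reference * min(eff[bindable]) else NA_real_
  )
  structure(
    list(
      sites = dplyr::mutate(pairs,
        degenerate = degenerate,
        bindable = bindable, effective_fold = eff
      ),
      model = model
    ),
    class = "promoter_binding"
  )
}

#' @export
print.promoter_binding <- function(x, ...) {
  cat("<promoter_binding>\n")
  print(x$model)
  cat("sites:\n")
  print(dplyr::select(
    x$sites, dplyr::any_of(c(
      "topology", "spacer", "first_start", "second_end",
      "affinity", "degenerate", "bindable", "effective_fold"
    ))
  ))
  invisible(x)
}
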