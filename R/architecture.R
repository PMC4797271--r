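#' Detect a bacterial core promoter (-35 / -10) heuristically
#'
#' Scores every -10 candidate (`TATAAT`, up to `max_mm10` mismatches, with a
#' bonus for the extended-10 `TG` dinucleotide immediately upstream) against
#' every -35 candidate (`TTGACA`, up to `max_mm35` mismatches) at a 15–21 nt
#' separation on the plus strand, and returns the best-scoring pair.  When
#' no pair reaches `score_floor` the function reports none-found (or a
#' lone -10, flagged, when one scores well on its own) rather than guessing.
#' The score is `(2 - mm10) + (3 - mm35) + TG bonus`.
#'
#' @param seq Promoter sequence (plus strand, 5' upstream to 3' downstream).
#' @param seq_id Identifier recorded in the output.
#' @param search_window Optional 0-based `c(start, end)` restricting the
#'   search; default the whole sequence.
#' @param max_mm10,max_mm35 Mismatch ceilings for the two hexamers (2 and 3).
#' @param separation Allowed nt between the -35 end and the -10 start
#'   (default 15–21).
#' @param tg_bonus Score bonus for the extended-10 TG (default 1).
#' @param score_floor Minimum pair score reported (default 4).
#' @return A one-row tibble: `seq_id`, `found` (`"pair"`, `"minus10_only"`
#'   or `"none"`), `minus35_start/end`, `minus10_start/end` (0-based
#'   half-open; NA when absent), `extended_minus10`, `score`, `source`.
#' @examples
#' seq <- paste0(
#'   strrep("A", 40), "TTGACA", strrep("C", 15), "TG", "TATAAT",
#'   strrep("A", 20)
#' )
#' detect_core_promoter(seq)
#' @export
detect_core_promoter <- function(seq, seq_id = "promoter",
                                 search_window = NULL,
                                 max_mm10 = 2L, max_mm35 = 3L,
                                 separation = c(15L, 21L), tg_bonus = 1,
                                 score_floor = 4) {
  seq <- check_dna(seq, "seq")
  L <- nchar(seq)
  win <- search_window %||% c(0L, L)
  if (win[1] < 0 || win[2] > L || win[1] >= win[2]) {
    abort("`search_window` must lie within the sequence")
  }
  none <- tibble::tibble(
    seq_id = seq_id, found = "none",
    minus35_start = NA_integer_, minus35_end = NA_integer_,
    minus10_start = NA_integer_, minus10_end = NA_integer_,
    extended_minus10 = FALSE, score = NA_real_, source = "detected"
  )
  sub <- substr(seq, win[1] + 1L, win[2])
  if (nchar(sub) < 6L) {
    return(none)
  }
  chars <- strsplit(sub, "")[[1]]
  nwin <- length(chars) - 5L
  hex_mm <- function(word) {
    w <- strsplit(word, "")[[1]]
    mm <- integer(nwin)
    for (j in 1:6) mm <- mm + (chars[j:(j + nwin - 1L)] != w[j])
    mm
  }
  mm10 <- hex_mm("TATAAT")
  mm35 <- hex_mm("TTGACA")
  cand10 <- which(mm10 <= max_mm10)
  cand35 <- which(mm35 <= max_mm35)
  has_tg <- function(i10) {
    i10 >= 3L && chars[i10 - 2L] == "T" && chars[i10 - 1L] == "G"
  }

  best <- NULL
  for (i10 in cand10) {
    lo <- i10 - 6L - separation[2]
    hi <- i10 - 6L - separation[1]
    for (i35 in cand35[cand35 >= lo & cand35 <= hi]) {
      s <- (2 - mm10[i10]) + (3 - mm35[i35]) + tg_bonus * has_tg(i10)
      if (s >= score_floor && (is.null(best) || s > best$s)) {
        best <- list(i10 = i10, i35 = i35, s = s)
      }
    }
  }
  off <- win[1]
  if (!is.null(best)) {
    return(tibble::tibble(
      seq_id = seq_id, found = "pair",
      minus35_start = off + best$i35 - 1L,
      minus35_end = off + best$i35 + 5L,
      minus10_start = off + best$i10 - 1L,
      minus10_end = off + best$i10 + 5L,
      extended_minus10 = has_tg(best$i10),
      score = best$s, source = "detected"
    ))
  }
  # Lone -10: only a perfect TATAAT qualifies, flagged by `found`.
  exact10 <- cand10[mm10[cand10] == 0L]
  if (length(exact10)) {
    i10 <- exact10[which.max(vapply(exact10, has_tg, logical(1)))]
    return(tibble::tibble(
      seq_id = seq_id, found = "minus10_only",
      minus35_start = NA_integer_, minus35_end = NA_integer_,
      minus10_start = off + i10 - 1L,
      minus10_end = off + i10 + 5L,
      extended_minus10 = has_tg(i10),
      score = 2 + tg_bonus * has_tg(i10), source = "detected"
    ))
  }
  none
}

#' Validate a user-supplied core-promoter annotation
#'
#' Checks that the -35 lies upstream of the -10 and that their separation is
#' within 15–21 nt (warns outside that range, as real promoters rarely
#' stray further).
#'
#' @param ann A one-row annotation tibble (columns as produced by
#'   [detect_core_promoter()]).
#' @return `ann`, invisibly, with `source` set to `"user"` if missing.
#' @export
validate_annotation <- function(ann) {
  if (!is.na(ann$minus35_start) && !is.na(ann$minus10_start)) {
    if (ann$minus35_end > ann$minus10_start) {
      abort("-35 element must lie upstream of the -10 element")
    }
    sep <- ann$minus10_start - ann$minus35_end
    if (sep < 15 || sep > 21) {
      warn(sprintf("-35/-10 separation of %d nt is outside 15-21 nt", sep))
    }
  }
  if (!"source" %in% names(ann)) ann$source <- "user"
  invisible(ann)
}

#' Classify a promoter's binding-site architecture
#'
#' Positions bindable paired sites relative to the -35 hexamer and assigns
#' the promoter class: a class II site overlaps, or ends within `prox_max`
#' nt of, the -35; a class I site lies wholly at least `dist_min` nt
#' upstream of it.  A promoter with both is class III; a core module
#' (class II site plus a bindable partner within `core_gap` upstream) with
#' two or more further bindable DRs upstream is `cluster_plus_core`.
#' Assignment is positional; topology is recorded (the expected-activity
#' annotation notes whether a DR holds the class II position, the
#' arrangement that drives strong output) but not required.
#'
#' Bindability is decided by [promoter_binding()], so clustered degenerate
#' sites participate while isolated ones do not.
#'
#' @param pairs Classified paired-site tibble (see [classify_pair()]) for
#'   one promoter.
#' @param ann Core-promoter annotation (one row; `minus35_start` required —
#'   run [detect_core_promoter()] first).
#' @param prox_max Max nt between a class II site's downstream edge and the
#'   -35 upstream edge (default 5).
#' @param dist_min Min nt between a class I site's downstream edge and the
#'   -35 upstream edge (default 20).
#' @param coupling_window,degenerate_max_mismatch,K0_reference,n_H_cooperative
#'   Passed to [promoter_binding()].
#' @param core_gap Allowed gap (nt) between the class II site and its
#'   upstream core-module partner, default `c(0, 30)`.
#' @return An object of class `promoter_architecture`: list with
#'   `promoter_id`, `arch_class` (`"I"`, `"II"`, `"III"`,
#'   `"cluster_plus_core"` or `"none"`), `sites` (tibble with `role` and
#'   `dist_to_minus35` columns), `expected_activity` (`"high"` when a DR
#'   holds the class II position, else `"low"` / `NA`), `binding` (the
#'   [promoter_binding()] result) and `annotation`.
#' @export
classify_architecture <- function(pairs, ann, prox_max = 5L, dist_min = 20L,
                                  coupling_window = 60,
                                  degenerate_max_mismatch = 2L,
                                  K0_reference = 1.2, n_H_cooperative = 1.4,
                                  core_gap = c(0L, 30L)) {
  if (nrow(ann) != 1L) abort("`ann` must be a one-row annotation")
  if (is.na(ann$minus35_start)) {
    abort("annotation lacks a -35 element; run detect_core_promoter() first")
  }
  if (!"affinity" %in% names(pairs)) {
    abort("run classify_pair() on the paired sites first")
  }
  if (nrow(pairs) > 0 && "seq_id" %in% names(pairs) &&
    any(pairs$seq_id != ann$seq_id)) {
    abort("`pairs` and `ann` refer to different sequences")
  }
  pb <- promoter_binding(pairs,
    coupling_window = coupling_window,
    degenerate_max_mismatch = degenerate_max_mismatch,
    K0_reference = K0_reference,
    n_H_cooperative = n_H_cooperative
  )
  sites <- pb$sites
  m35s <- ann$minus35_start
  m35e <- ann$minus35_end
  if (nrow(sites) > 0L) {
    sites <- sites %>%
      dplyr::mutate(
        dist_to_minus35 = m35s - .data$second_end,
        role = dplyr::case_when(
          !.data$bindable ~ "unbound",
          .data$second_end >= m35s - prox_max &
            .data$first_start < m35e ~ "class_II",
          .data$dist_to_minus35 >= dist_min ~ "class_I",
          TRUE ~ "intermediate"
        )
      )
  } else {
    sites <- dplyr::mutate(sites,
      dist_to_minus35 = integer(), role = character()
    )
  }

  class2 <- sites[sites$role == "class_II", , drop = FALSE]
  class1 <- sites[sites$role == "class_I", , drop = FALSE]

  # Core module: class II site + nearest upstream bindable partner within
  # the (loosely constrained) core gap.
  core_partner <- NULL
  if (nrow(class2) > 0L) {
    c2 <- class2[which.max(class2$second_end), ]
    up <- sites[sites$bindable & sites$second_end <= c2$first_start, ,
      drop = FALSE
    ]
    if (nrow(up) > 0L) {
      gap <- c2$first_start - up$second_end
      ok <- gap >= core_gap[1] & gap <= core_gap[2]
      if (any(ok)) core_partner <- up[which.min(gap + ifelse(ok, 0, Inf)), ]
    }
  }
  cluster <- tibble::tibble()
  if (!is.null(core_partner)) {
    cluster <- sites[sites$bindable & sites$topology == "DR" &
      sites$second_end <= core_partner$first_start, ,
    drop = FALSE
    ]
    sites$role[sites$bindable &
      sites$first_start %in% cluster$first_start] <- "cluster"
  }

  arch_class <- if (!is.null(core_partner) && nrow(cluster) >= 2L) {
    "cluster_plus_core"
  } else if (nrow(class1) > 0L && nrow(class2) > 0L) {
    "III"
  } else if (nrow(class2) > 0L) {
    "II"
  } else if (nrow(class1) > 0L) {
    "I"
  } else {
    "none"
  }
  expected_activity <- if (nrow(class2) > 0L) {
    if (any(class2$topology == "DR")) "high" else "low"
  } else {
    NA_character_
  }

  structure(
    list(
      promoter_id = ann$seq_id,
      arch_class = arch_class,
      sites = sites,
      expected_activity = expected_activity,
      binding = pb,
      annotation = ann
    ),
    class = "promoter_architecture"
  )
}

#' @export
print.promoter_architecture <- function(x, ...) {
  cat("<promoter_architecture>", x$promoter_id, "\n")
  cat("  class            :", x$arch_class, "\n")
  cat("  expected activity:", x$expected_activity, "\n")
  cat(sprintf(
    "  sites            : %d (%d bindable)\n",
    nrow(x$sites), sum(x$sites$bindable)
  ))
  invisible(x)
}

#' Tidy a promoter architecture
#'
#' @param x A `promoter_architecture`.
#' @param ... Unused.
#' @return The per-site tibble with `role` and `dist_to_minus35`.
#' @export
tidy.promoter_architecture <- function(x, ...) {
  x$sites
}

#' One-row summary of a promoter architecture
#'
#' @param x A `promoter_architecture`.
#' @param ... Unused.
#' @return One-row tibble: `promoter_id`, `arch_class`, site/role counts,
#'   `expected_activity`, `n_H`, `K_d_eff`.
#' @export
glance.promoter_architecture <- function(x, ...) {
  tibble::tibble(
    promoter_id = x$promoter_id,
    arch_class = x$arch_class,
    n_sites = nrow(x$sites),
    n_bindable = sum(x$sites$bindable),
    n_class_I = sum(x$sites$role == "class_I"),
    n_class_II = sum(x$sites$role == "class_II"),
    n_cluster = sum(x$sites$role == "cluster"),
    expected_activity = x$expected_activity,
    n_H = x$binding$model$n_H,
    K_d_eff = x$binding$model$K_d_eff
  )
}

#' Map of a classified promoter
#'
#' Draws the promoter as a line with the -35/-10 hexamers and each paired
#' site as a labelled segment colored by role.
#'
#' @param x A `promoter_architecture`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.promoter_architecture <- function(x, ...) {
  ann <- x$annotation
  core <- tibble::tibble(
    element = c("-35", "-10"),
    start = c(ann$minus35_start, ann$minus10_start),
    end = c(ann$minus35_end, ann$minus10_end)
  )
  sites <- x$sites
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_rect(
      data = core,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = -0.12, ymax = 0.12
      ),
      fill = "grey30"
    ) +
    ggplot2::geom_text(
      data = core,
      ggplot2::aes(
        x = (.data$start + .data$end) / 2, y = -0.3,
        label = .data$element
      ),
      size = 3
    )
  if (nrow(sites) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = sites,
      ggplot2::aes(
        xmin = .data$first_start, xmax = .data$second_end,
        ymin = 0.18, ymax = 0.45, fill = .data$role
      )
    ) +
      ggplot2::geom_text(
        data = sites,
        ggplot2::aes(
          x = (.data$first_start + .data$second_end) / 2,
          y = 0.55, label = .data$topology
        ),
        size = 3
      )
  }
  p + ggplot2::ylim(-0.6, 0.8) +
    ggplot2::labs(
      x = "position (nt)", y = NULL,
      title = sprintf("%s: class %s", x$promoter_id, x$arch_class)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
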