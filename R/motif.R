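#' Hexameric recognition-element motif model
#'
#' A `motif_model` bundles everything needed to recognize one hexameric
#' recognition element (RE) and to interpret pairs of REs as inverted (IR)
#' or direct (DR) repeats: the consensus word, an optional position frequency
#' matrix (PFM) compiled from aligned sites, a pseudocount, a background base
#' composition, and the spacer grammar of the two topologies.  The defaults
#' describe the ComA element: consensus `TTGCGG`, IR optimal spacer 4 nt
#' (5 tolerated), DR optimal spacer 5 nt (4 tolerated).
#'
#' @param consensus 6-letter DNA word (A/C/G/T only).
#' @param pfm Optional 4 x 6 count matrix, rows in A, C, G, T order.  Column
#'   sums must be equal (every aligned site covers every column).
#' @param nsites Number of aligned sites behind `pfm` (recorded for
#'   reporting; inferred from column sums when a PFM is given).
#' @param pseudocount Non-negative count added to every PFM cell before
#'   normalization.  Default 0.25 (uniform Laplace-style quarter-count).
#' @param background Named probability vector over A, C, G, T; strictly
#'   positive, summing to 1.  Used by log-odds scoring (information content
#'   always uses the uniform logo convention).
#' @param grammar Spacer grammar, a list with elements `IR` and `DR`, each
#'   holding `optimal_spacer` and `tolerated_spacer` (nt between hexamers).
#'
#' @return An object of class `motif_model`.
#' @seealso [build_pfm()], [information_content()], [log_odds_score()],
#'   [find_re_matches()]
#' @examples
#' m <- motif_model()
#' m$consensus
#' @export
motif_model <- function(consensus = "TTGCGG",
                        pfm = NULL,
                        nsites = NA_integer_,
                        pseudocount = 0.25,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        grammar = default_topology_grammar()) {
  consensus <- check_dna(consensus, "consensus", allow_n = FALSE)
  if (nchar(consensus) != 6L) {
    abort("`consensus` must be a hexamer (6 letters)")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    abort("`pseudocount` must be a single non-negative number")
  }
  background <- background[DNA_BASES]
  if (anyNA(background) || any(background <= 0) ||
    abs(sum(background) - 1) > 1e-9) {
    abort("`background` must give positive probabilities for A,C,G,T summing to 1")
  }
  if (!is.null(pfm)) {
    pfm <- as.matrix(pfm)
    if (nrow(pfm) != 4L || ncol(pfm) != 6L || any(pfm < 0)) {
      abort("`pfm` must be a non-negative 4 x 6 matrix (rows A,C,G,T)")
    }
    rownames(pfm) <- DNA_BASES
    cs <- colSums(pfm)
    if (diff(range(cs)) > 1e-9) {
      abort("PFM column sums differ: every aligned site must cover all 6 columns")
    }
    nsites <- as.integer(round(cs[1]))
  }
  structure(
    list(
      consensus = consensus,
      pfm = pfm,
      nsites = nsites,
      pseudocount = pseudocount,
      background = background,
      grammar = grammar
    ),
    class = "motif_model"
  )
}

#' Default IR/DR spacer grammar
#'
#' IR: 4 nt optimal, 5 tolerated.  DR: 5 nt optimal, 4 tolerated.
#'
#' @return A named list with `IR` and `DR` components.
#' @export
default_topology_grammar <- function() {
  list(
    IR = list(optimal_spacer = 4L, tolerated_spacer = 5L),
    DR = list(optimal_spacer = 5L, tolerated_spacer = 4L)
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model>\n")
  cat("  consensus :", x$consensus, "\n")
  if (is.null(x$pfm)) {
    cat("  pfm       : <none> (consensus-only model)\n")
  } else {
    cat("  pfm       :", x$nsites, "aligned sites, pseudocount",
      x$pseudocount, "\n")
  }
  cat("  background:", paste(sprintf("%s=%.3f", DNA_BASES, x$background),
    collapse = " "
  ), "\n")
  g <- x$grammar
  cat(sprintf(
    "  grammar   : IR spacer %d (tol %d) | DR spacer %d (tol %d)\n",
    g$IR$optimal_spacer, g$IR$tolerated_spacer,
    g$DR$optimal_spacer, g$DR$tolerated_spacer
  ))
  invisible(x)
}

#' Compile a position frequency matrix from aligned sites
#'
#' Tallies base counts per column from equal-length hexamer sites (for
#' example the recognition elements cut out of a set of target promoters)
#' and returns a [motif_model()] carrying the counts.  The consensus defaults
#' to the per-column count argmax (alphabetical tie-break) unless one is
#' supplied.
#'
#' @param aligned_sites Character vector of aligned 6-mers (A/C/G/T only).
#' @param pseudocount Pseudocount stored on the model (see [motif_model()]).
#' @param consensus Optional consensus to store instead of the argmax.
#' @param background,grammar Passed through to [motif_model()].
#'
#' @return A `motif_model` with `pfm` filled in (raw counts; the pseudocount
#'   is applied at normalization time).
#' @examples
#' m <- build_pfm(c("TTGCGG", "ATGCGG", "TTGCGG"), pseudocount = 0.25)
#' m$pfm
#' @export
build_pfm <- function(aligned_sites, pseudocount = 0.25, consensus = NULL,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      grammar = default_topology_grammar()) {
  if (length(aligned_sites) < 1L) {
    abort("need at least one aligned site")
  }
  aligned_sites <- toupper(aligned_sites)
  for (s in aligned_sites) {
    if (nchar(s) != 6L) {
      abort(paste0("aligned site '", s, "' is not a hexamer"))
    }
    if (grepl("[^ACGT]", s)) {
      abort(paste0("aligned site '", s, "' contains non-ACGT characters"))
    }
  }
  mat <- matrix(0L, nrow = 4L, ncol = 6L, dimnames = list(DNA_BASES, NULL))
  split <- strsplit(aligned_sites, "")
  for (j in 1:6) {
    tab <- table(factor(vapply(split, `[[`, character(1), j),
      levels = DNA_BASES
    ))
    mat[, j] <- as.integer(tab)
  }
  if (is.null(consensus)) {
    consensus <- paste(DNA_BASES[apply(mat, 2, which.max)], collapse = "")
  }
  motif_model(
    consensus = consensus, pfm = mat, pseudocount = pseudocount,
    background = background, grammar = grammar
  )
}

# Pseudocount-normalized probability matrix; 4 x 6, columns sum to 1.
prob_matrix <- function(model) {
  if (is.null(model$pfm)) {
    abort("model has no PFM; build one with build_pfm()")
  }
  p <- model$pfm + model$pseudocount
  sweep(p, 2, colSums(p), "/")
}

# Log2-odds matrix against the model background; errors on zero cells.
log_odds_matrix <- function(model) {
  p <- prob_matrix(model)
  if (any(p == 0)) {
    abort(paste0(
      "PFM has zero-probability cells; use a nonzero `pseudocount` ",
      "to score with log-odds"
    ))
  }
  log2(p / model$background)
}

#' Per-column information content (bits)
#'
#' The sequence-logo letter-height convention: `IC_j = 2 + sum_b p_bj log2
#' p_bj` with pseudocount-normalized probabilities and a uniform background,
#' so each column lies in `[0, 2]` bits (2 = fully conserved, 0 = uniform).
#'
#' @param model A [motif_model()] with a PFM.
#' @return Numeric vector of 6 values in bits.
#' @examples
#' information_content(build_pfm(c("TTGCGG", "TTGCGG"), pseudocount = 0))
#' @export
information_content <- function(model) {
  p <- prob_matrix(model)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)
  pmin(pmax(ic, 0), 2)
}

#' Hamming distance between a window and the consensus
#'
#' @param window,consensus 6-letter DNA words.
#' @return Integer mismatch count with attribute `positions` giving the
#'   1-based mismatching columns.
#' @examples
#' mismatch_count("TTGCGT", "TTGCGG")
#' @export
mismatch_count <- function(window, consensus) {
  window <- check_dna(window, "window")
  consensus <- check_dna(consensus, "consensus", allow_n = FALSE)
  if (nchar(window) != 6L || nchar(consensus) != 6L) {
    abort("`window` and `consensus` must both be hexamers")
  }
  w <- strsplit(window, "")[[1]]
  k <- strsplit(consensus, "")[[1]]
  pos <- which(w != k)
  structure(length(pos), positions = pos)
}

#' Log-odds score of a hexamer window
#'
#' `sum_j log2(p[w_j, j] / background[w_j])` over the six columns of the
#' pseudocount-normalized PFM.  Windows containing N score `-Inf`.
#'
#' @param window 6-letter DNA word.
#' @param model A [motif_model()] with a PFM (nonzero probabilities).
#' @return A single numeric score (log2 odds).
#' @export
log_odds_score <- function(window, model) {
  window <- check_dna(window, "window")
  if (nchar(window) != 6L) abort("`window` must be a hexamer")
  lom <- log_odds_matrix(model)
  w <- strsplit(window, "")[[1]]
  if (any(!w %in% DNA_BASES)) {
    return(-Inf)
  }
  sum(lom[cbind(match(w, DNA_BASES), 1:6)])
}

#' Read aligned binding sites from FASTA or plain text
#'
#' Files starting with `>` are parsed as FASTA (via Biostrings); anything
#' else is taken as newline-delimited hexamers (blank lines and `#` comments
#' skipped).
#'
#' @param path Path to the file.
#' @return Character vector of uppercase site strings.
#' @export
read_aligned_sites <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    x <- Biostrings::readDNAStringSet(path)
    return(unname(toupper(as.character(x))))
  }
  x <- readLines(path)
  x <- trimws(x)
  toupper(x[nzchar(x) & !startsWith(x, "#")])
}

#' Export a PFM as tab-separated counts
#'
#' Writes a 4 x 6 matrix with a `base` column (A/C/G/T) and columns
#' `pos1..pos6`.
#'
#' @param model A [motif_model()] with a PFM.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(model, path) {
  if (is.null(model$pfm)) abort("model has no PFM")
  df <- tibble::as_tibble(model$pfm, .name_repair = ~ paste0("pos", 1:6))
  df <- dplyr::bind_cols(tibble::tibble(base = DNA_BASES), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a PFM written by [write_pfm()]
#'
#' @param path Path to the TSV.
#' @inheritParams build_pfm
#' @return A `motif_model`.
#' @export
read_pfm <- function(path, pseudocount = 0.25, consensus = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!identical(df$base, DNA_BASES)) {
    abort("PFM file must have rows A, C, G, T in order")
  }
  mat <- as.matrix(df[, paste0("pos", 1:6)])
  rownames(mat) <- DNA_BASES
  if (is.null(consensus)) {
    consensus <- paste(DNA_BASES[apply(mat, 2, which.max)], collapse = "")
  }
  motif_model(consensus = consensus, pfm = mat, pseudocount = pseudocount)
}

#' Export the motif in MEME minimal format
#'
#' Letter-probability matrix block understood by the MEME suite tools.
#'
#' @param model A [motif_model()] with a PFM.
#' @param path Output path.
#' @param name Motif name in the file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(model, path, name = model$consensus) {
  p <- prob_matrix(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", DNA_BASES, model$background), collapse = " "),
    "",
    paste("MOTIF", name),
    sprintf(
      "letter-probability matrix: alength= 4 w= 6 nsites= %d E= 0",
      ifelse(is.na(model$nsites), 0L, model$nsites)
    )
  ), con)
  for (j in 1:6) {
    writeLines(paste(sprintf("%.6f", p[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' Bar plot of per-column information content with letter annotation
#'
#' A compact logo substitute: one bar per motif column, height = information
#' content in bits, labelled with the majority base.
#'
#' @param model A [motif_model()] with a PFM.
#' @return A ggplot object.
#' @export
plot_information_content <- function(model) {
  ic <- information_content(model)
  p <- prob_matrix(model)
  df <- tibble::tibble(
    position = factor(1:6),
    bits = ic,
    base = DNA_BASES[apply(p, 2, which.max)]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$base),
      vjust = -0.4, fontface = "bold"
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 2.2)) +
    ggplot2::labs(
      x = "motif position", y = "information content (bits)",
      title = paste("Recognition element", model$consensus)
    ) +
    ggplot2::theme_minimal()
}
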