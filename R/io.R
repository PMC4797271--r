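#' Read a (multi-record) FASTA file
#'
#' @param path Path to an uncompressed or gzipped FASTA file.
#' @return A tibble with columns `seq_id` (name up to the first whitespace)
#'   and `seq` (uppercase DNA).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
    }
  )
  if (length(x) == 0L) abort(paste0("FASTA '", path, "' has no records"))
  if (any(Biostrings::width(x) == 0L)) {
    abort(paste0("FASTA '", path, "' contains empty records"))
  }
  tibble::tibble(
    seq_id = sub("\\s.*$", "", names(x)),
    seq = unname(toupper(as.character(x)))
  )
}

#' Write sequences to FASTA
#'
#' @param df Tibble with `seq_id` and `seq` columns (the [read_fasta()]
#'   layout; [make_probe_panel()] probes work after renaming `probe_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path) {
  x <- Biostrings::DNAStringSet(setNames(df$seq, df$seq_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Paired sites / matches -> GRanges (1-based inclusive) for export.
sites_to_granges <- function(x) {
  if ("topology" %in% names(x)) {
    gr <- GenomicRanges::GRanges(
      seqnames = x$seq_id,
      ranges = IRanges::IRanges(
        start = x$first_start + 1L,
        end = x$second_end
      ),
      strand = ifelse(x$strand == ".", "*", x$strand)
    )
    S4Vectors::mcols(gr)$type <- ifelse(x$topology == "IR", "IR_site", "DR_site")
    S4Vectors::mcols(gr)$spacer <- x$spacer
    S4Vectors::mcols(gr)$mismatches <- x$mm_first + x$mm_second
    if ("combined_score" %in% names(x)) {
      S4Vectors::mcols(gr)$score <- x$combined_score
    }
    if ("affinity" %in% names(x)) {
      S4Vectors::mcols(gr)$affinity <- x$affinity
      S4Vectors::mcols(gr)$fold_penalty <- ifelse(
        is.infinite(x$fold_penalty), "none", as.character(x$fold_penalty)
      )
    }
    nm <- sprintf(
      "%s_%s_%d", x$seq_id,
      ifelse(x$topology == "IR", "IR", "DR"), x$first_start
    )
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = x$seq_id,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      strand = x$strand
    )
    S4Vectors::mcols(gr)$type <- "RE_match"
    S4Vectors::mcols(gr)$mismatches <- x$mismatches
    if (any(!is.na(x$score))) S4Vectors::mcols(gr)$score <- x$score
    if (any(!is.na(x$pvalue))) S4Vectors::mcols(gr)$pvalue <- x$pvalue
    nm <- sprintf("%s_RE_%d%s", x$seq_id, x$start, x$strand)
  }
  names(gr) <- make.unique(nm)
  gr
}

#' Export matches or paired sites as GFF3 / BED6
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' inclusive convention (BED stays 0-based half-open).  Feature types are
#' `RE_match`, `IR_site`, `DR_site`; spacer, mismatch, score, p-value and
#' affinity annotations travel as GFF3 attributes.
#'
#' @param x A match tibble ([find_re_matches()]) or paired-site tibble
#'   ([pair_sites()], optionally classified).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path) {
  gr <- sites_to_granges(x)
  S4Vectors::mcols(gr)$ID <- names(gr)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
write_bed <- function(x, path) {
  gr <- sites_to_granges(x)
  S4Vectors::mcols(gr)$name <- names(gr)
  sc <- S4Vectors::mcols(gr)$score
  S4Vectors::mcols(gr)$score <- if (is.null(sc) || all(is.na(sc))) {
    0L
  } else {
    pmax(0L, pmin(1000L, as.integer(round(100 * sc))))
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write titration tables
#'
#' The TSV dialect has columns `probe_id`, `replicate`, `conc_uM`,
#' `fraction_bound`.
#'
#' @param path File path.
#' @return A tibble in the dialect above.
#' @export
read_titration_tsv <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      replicate = readr::col_integer(),
      conc_uM = readr::col_double(),
      fraction_bound = readr::col_double()
    )
  )
  req <- c("probe_id", "replicate", "conc_uM", "fraction_bound")
  if (!all(req %in% names(df))) {
    abort(paste(
      "titration TSV needs columns:",
      paste(req, collapse = ", ")
    ))
  }
  df
}

#' @rdname read_titration_tsv
#' @param df A titration tibble.
#' @export
write_titration_tsv <- function(df, path) {
  readr::write_tsv(df, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every stage parameter with its documented default, under a versioned
#' schema key.  Round-trips losslessly through YAML; unknown keys in a file
#' are errors, not warnings.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    schema = "comascan-config/1",
    seed = 1L,
    scan = list(
      mode = "stringent",
      max_mismatch = 1L,
      include_ir = TRUE,
      pvalue_threshold = 1e-3,
      pseudocount = 0.25
    ),
    affinity = list(
      K0_reference = 1.2,
      coupling_window = 60L,
      degenerate_max_mismatch = 2L,
      n_H_cooperative = 1.4
    ),
    architecture = list(
      prox_max = 5L,
      dist_min = 20L,
      core_gap = c(0L, 30L),
      upstream_window = 300L
    ),
    fit = list(
      n_boot = 1000L,
      bounds = list(K_d = c(1e-3, 1e3), n_H = c(0.3, 5))
    ),
    simulate = list(
      gc_content = 0.435,
      markov_order = 0L,
      probe_length = 50L
    )
  )
}

# Recursively check cfg keys against a reference; unknown keys are errors.
check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra)) {
    abort(paste0(
      "unknown config key(s): ",
      paste0(path, extra, collapse = ", ")
    ))
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns the full configuration (file values
#'   over defaults); `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- default_config()
  if (!identical(raw$schema, ref$schema)) {
    abort(paste0(
      "config schema must be '", ref$schema, "', got '",
      raw$schema %||% "<missing>", "'"
    ))
  }
  check_config_keys(raw, ref)
  merge <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]]) &&
        !is.null(names(base[[k]]))) {
        base[[k]] <- merge(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge(ref, raw)
}

#' @rdname read_run_config
#' @param config A configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the scan / classify / architecture pipeline
#'
#' For every FASTA record: scan for paired sites (stringent or relaxed per
#' the config), classify their empirical affinity, detect the core
#' promoter, and — where a -35 was found — classify the promoter
#' architecture.  Every applied default is logged to stderr via
#' [message()].
#'
#' @param fasta Path to a FASTA file, or a tibble from [read_fasta()].
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional output directory; when given, writes
#'   `sites.gff3`, `sites.bed`, `report.tsv` and `config.yaml`.
#' @param model A [motif_model()].
#' @return A list of class `pipeline_result`: `$sites` (classified paired
#'   sites, all records), `$architectures` (one-row-per-promoter glance
#'   table) and `$config`.
#' @export
run_pipeline <- function(fasta, config = default_config(), out_dir = NULL,
                         model = motif_model()) {
  seqs <- if (is.character(fasta)) read_fasta(fasta) else fasta
  check_config_keys(config, default_config())
  message(
    "scan mode: ", config$scan$mode,
    " (max_mismatch ", config$scan$max_mismatch,
    ", pvalue_threshold ", config$scan$pvalue_threshold, ")"
  )
  sc <- config$scan
  pvt <- NULL
  if (sc$mode == "relaxed" && !is.null(model$pfm)) {
    pvt <- score_pvalue_table(model)
  }
  all_sites <- list()
  arch <- list()
  for (i in seq_len(nrow(seqs))) {
    id <- seqs$seq_id[i]
    s <- seqs$seq[i]
    pairs <- if (sc$mode == "stringent") {
      scan_stringent(s, model,
        max_mismatch = sc$max_mismatch,
        include_ir = sc$include_ir, seq_id = id
      )
    } else {
      scan_relaxed(s, model,
        pvalue_threshold = sc$pvalue_threshold,
        seq_id = id, pvalue_table = pvt
      )
    }
    pairs <- classify_pair(pairs)
    all_sites[[id]] <- pairs
    ann <- detect_core_promoter(s, seq_id = id)
    if (ann$found == "pair") {
      pa <- classify_architecture(
        pairs, ann,
        prox_max = config$architecture$prox_max,
        dist_min = config$architecture$dist_min,
        coupling_window = config$affinity$coupling_window,
        degenerate_max_mismatch = config$affinity$degenerate_max_mismatch,
        K0_reference = config$affinity$K0_reference,
        n_H_cooperative = config$affinity$n_H_cooperative,
        core_gap = config$architecture$core_gap
      )
      arch[[id]] <- glance(pa)
    } else {
      message(
        "no core promoter found for ", id,
        "; architecture not classified"
      )
    }
  }
  sites <- dplyr::bind_rows(all_sites)
  architectures <- dplyr::bind_rows(arch)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(sites) > 0L) {
      write_gff3(sites, file.path(out_dir, "sites.gff3"))
      write_bed(sites, file.path(out_dir, "sites.bed"))
    }
    readr::write_tsv(sites, file.path(out_dir, "sites.tsv"))
    if (nrow(architectures) > 0L) {
      readr::write_tsv(architectures, file.path(out_dir, "report.tsv"))
    }
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  structure(
    list(sites = sites, architectures = architectures, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  paired sites :", nrow(x$sites), "\n")
  cat("  promoters    :", nrow(x$architectures), "\n")
  if (nrow(x$architectures) > 0L) print(x$architectures)
  invisible(x)
}
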