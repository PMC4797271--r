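#' Fit the Hill binding model to an EMSA titration
#'
#' Nonlinear least squares of `theta(c) = c^n_H / (K_d^n_H + c^n_H)` to
#' fraction-bound densitometry data.  By default the mean fraction bound per
#' concentration is fitted (matching the convention of averaging replicate
#' gels before curve fitting); set `per_replicate = TRUE` to fit all points.
#' Optimization is bounded Levenberg–Marquardt ([minpack.lm::nlsLM()]) with
#' `K_d` initialized at the concentration nearest half-occupancy (linear
#' interpolation) and `n_H` at 1.
#'
#' @param data A tidy titration table with columns `conc_uM` and
#'   `fraction_bound`, optionally `replicate` and `probe_id` (the TSV
#'   dialect read by [read_titration_tsv()]).
#' @param bounds Named list with `K_d` and `n_H` ranges.  Defaults
#'   `K_d` in `[1e-3, 1e3]` uM, `n_H` in `[0.3, 5]`.
#' @param init Optional named list overriding the automatic start values.
#' @param per_replicate Fit every replicate point instead of per-
#'   concentration means.
#'
#' @return An object of class `hill_fit` with elements `K_d`, `n_H`,
#'   `se_Kd`, `se_nH`, `rss`, `converged`, `n_obs`, `data` (the input),
#'   `fit` (the underlying `nls` object or `NULL`) and `message`.
#'   Non-convergence is reported via `converged = FALSE`, not an error.
#' @examples
#' tc <- simulate_titration(K_d = 2.4, n_H = 1.4, noise_sd = 0, seed = 1)
#' fit <- fit_hill(tc)
#' coef(fit)
#' @export
fit_hill <- function(data,
                     bounds = list(K_d = c(1e-3, 1e3), n_H = c(0.3, 5)),
                     init = NULL, per_replicate = FALSE) {
  req <- c("conc_uM", "fraction_bound")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns conc_uM and fraction_bound")
  }
  if (any(data$conc_uM < 0)) abort("concentrations must be non-negative")
  bad <- data$fraction_bound < 0 | data$fraction_bound > 1
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf(
      "%d fraction_bound values outside [0, 1] clipped on input",
      sum(bad, na.rm = TRUE)
    ))
    data$fraction_bound <- pmin(pmax(data$fraction_bound, 0), 1)
  }
  if (length(unique(data$conc_uM)) < 4L) {
    abort("need at least 4 distinct concentrations to fit a Hill curve")
  }
  means <- data %>%
    dplyr::group_by(.data$conc_uM) %>%
    dplyr::summarise(fraction_bound = mean(.data$fraction_bound)) %>%
    dplyr::arrange(.data$conc_uM)
  if (all(means$fraction_bound == 0) || all(means$fraction_bound == 1)) {
    abort("all fractions are 0 (or all 1): Hill parameters are not identifiable")
  }
  if (max(means$fraction_bound) < 0.5 || min(means$fraction_bound) > 0.5) {
    warn("titration does not span the apparent midpoint; estimates may be weak")
  }

  fit_df <- if (per_replicate) {
    data[, req]
  } else {
    means
  }
  # K_d start: concentration where the mean curve crosses 0.5.
  if (is.null(init)) {
    nz <- means[means$conc_uM > 0, ]
    k0 <- tryCatch(
      approx(nz$fraction_bound, nz$conc_uM, xout = 0.5, ties = mean)$y,
      error = function(e) NA_real_
    )
    if (is.na(k0)) k0 <- median(nz$conc_uM)
    init <- list(K_d = k0, n_H = 1)
  }
  init$K_d <- min(max(init$K_d, bounds$K_d[1]), bounds$K_d[2])
  init$n_H <- min(max(init$n_H, bounds$n_H[1]), bounds$n_H[2])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      fraction_bound ~ conc_uM^n_H / (K_d^n_H + conc_uM^n_H),
      data = fit_df,
      start = list(K_d = init$K_d, n_H = init$n_H),
      lower = c(bounds$K_d[1], bounds$n_H[1]),
      upper = c(bounds$K_d[2], bounds$n_H[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(
      K_d = NA_real_, n_H = NA_real_, se_Kd = NA_real_, se_nH = NA_real_,
      rss = NA_real_, converged = FALSE, n_obs = nrow(fit_df),
      data = data, fit = NULL, message = conditionMessage(fit),
      bounds = bounds
    )
    return(structure(out, class = "hill_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) c(K_d = NA_real_, n_H = NA_real_)
  )
  structure(
    list(
      K_d = unname(cf["K_d"]), n_H = unname(cf["n_H"]),
      se_Kd = unname(se["K_d"]), se_nH = unname(se["n_H"]),
      rss = sum(resid(fit)^2), converged = fit$convInfo$isConv,
      n_obs = nrow(fit_df), data = data, fit = fit,
      message = fit$convInfo$stopMessage, bounds = bounds
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>\n")
  if (!x$converged && is.null(x$fit)) {
    cat("  fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  K_d = %.4g uM (se %.3g)\n", x$K_d, x$se_Kd))
  cat(sprintf("  n_H = %.4g     (se %.3g)\n", x$n_H, x$se_nH))
  cat(sprintf(
    "  rss = %.4g on %d points; converged: %s\n",
    x$rss, x$n_obs, x$converged
  ))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(K_d = object$K_d, n_H = object$n_H)
}

#' @export
predict.hill_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- sort(unique(object$data$conc_uM))
  occupancy(conc, K_d = object$K_d, n_H = object$n_H)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K_d", "n_H"),
    estimate = c(x$K_d, x$n_H),
    std.error = c(x$se_Kd, x$se_nH)
  )
}

#' One-row summary of a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `K_d`, `n_H`, `rss`, `converged`, `nobs`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    K_d = x$K_d, n_H = x$n_H, rss = x$rss,
    converged = x$converged, nobs = x$n_obs
  )
}

#' Plot a titration with its Hill fit
#'
#' Points are per-concentration means (error bars = replicate SD where
#' replicates exist); the line is the fitted isotherm on a log concentration
#' axis.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  df <- object$data %>%
    dplyr::group_by(.data$conc_uM) %>%
    dplyr::summarise(
      mean = mean(.data$fraction_bound),
      sd = stats::sd(.data$fraction_bound)
    )
  pos <- df$conc_uM[df$conc_uM > 0]
  grid <- exp(seq(log(min(pos) / 2), log(max(pos) * 2), length.out = 200))
  curve <- tibble::tibble(
    conc_uM = grid,
    fraction = occupancy(grid, object$K_d, object$n_H)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_uM)) +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(y = .data$fraction),
      linewidth = 0.8
    ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sd,
        ymax = .data$mean + .data$sd
      ),
      width = 0.05, na.rm = TRUE
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "protein concentration (uM)", y = "fraction bound",
      title = sprintf(
        "Hill fit: K_d = %.3g uM, n_H = %.3g",
        object$K_d, object$n_H
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bootstrap confidence intervals for Hill parameters
#'
#' Case resampling over replicates: whole replicate series are drawn with
#' replacement, the model refitted on each resample, and percentile
#' intervals reported.  Deterministic given `seed`.
#'
#' @param data A titration table with a `replicate` column (>= 2 replicates).
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param level Interval coverage (default 0.9).
#' @param ... Passed on to [fit_hill()].
#' @return A tibble: `term`, `estimate`, `lower`, `upper`, `level`,
#'   `n_boot_ok` (resamples that converged).
#' @export
bootstrap_ci <- function(data, n_boot = 1000, seed = 1, level = 0.9, ...) {
  if (!"replicate" %in% names(data)) {
    abort("`data` needs a `replicate` column for case resampling")
  }
  reps <- unique(data$replicate)
  if (length(reps) < 2L) {
    abort("bootstrap needs at least 2 replicates")
  }
  fit0 <- fit_hill(data, ...)
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      take <- sample(reps, length(reps), replace = TRUE)
      boot <- purrr::imap(take, function(r, k) {
        d <- data[data$replicate == r, ]
        d$replicate <- k
        d
      }) %>% dplyr::bind_rows()
      f <- tryCatch(
        suppressWarnings(fit_hill(boot, ...)),
        error = function(e) NULL
      )
      if (is.null(f) || !f$converged) {
        return(c(K_d = NA_real_, n_H = NA_real_))
      }
      coef(f)
    })
  })
  mat <- do.call(rbind, draws)
  ok <- stats::complete.cases(mat)
  a <- (1 - level) / 2
  qs <- apply(mat[ok, , drop = FALSE], 2, quantile, probs = c(a, 1 - a))
  tibble::tibble(
    term = c("K_d", "n_H"),
    estimate = c(fit0$K_d, fit0$n_H),
    lower = qs[1, ],
    upper = qs[2, ],
    level = level,
    n_boot_ok = sum(ok)
  )
}
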