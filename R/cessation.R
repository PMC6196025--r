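#' Reversal specification
#'
#' @param fraction remaining-gap fraction defining the reversal threshold
#'   (default 0.25): an ex-smoker counts as reversed once it has covered
#'   at least `1 - fraction` of the gap between the current-smoker and
#'   never-smoker medians, i.e. it lies within `fraction` of the gap of
#'   the never-smoker median.
#' @param bins quit-year bin edges (left-open, right-closed except the
#'   first bin which starts at 0); defaults to the display categories
#'   `< 1`, `1-5`, `> 5` years.
#' @param gap_covered alternative reading of the statistic: when `TRUE`, a
#'   subject counts as reversed once it has covered at least `fraction`
#'   of the gap (sensitivity analysis; not the default).
#' @return A `reversal_spec` object.
#' @export
reversal_spec <- function(fraction = 0.25, bins = c(0, 1, 5, Inf),
                          gap_covered = FALSE) {
  stopifnot(fraction > 0, fraction < 1, !is.unsorted(bins),
            length(bins) >= 2)
  structure(list(fraction = fraction, bins = bins,
                 gap_covered = gap_covered),
            class = "reversal_spec")
}

#' Reversal threshold from group medians
#'
#' `median_never - fraction * (median_never - median_current)`: the
#' residual level at which an ex-smoker has covered `1 - fraction` of the
#' gap toward the never-smoker median. With medians -0.234 (current) and
#' 0.037 (never) at fraction 0.25 the threshold is -0.031.
#'
#' @param median_current,median_never group medians of covariate-adjusted
#'   residuals.
#' @param fraction remaining-gap fraction (default 0.25).
#' @return Threshold, rounded to three decimals.
#' @export
#' @examples
#' reversal_threshold(-0.234, 0.037)
reversal_threshold <- function(median_current, median_never,
                               fraction = 0.25) {
  stopifnot(is.finite(median_current), is.finite(median_never))
  round(median_never - fraction * (median_never - median_current), 3)
}

#' Absolute gap between group medians
#'
#' @inheritParams reversal_threshold
#' @return `|median_never - median_current|`, three decimals.
#' @export
#' @examples
#' median_gap(-0.234, 0.037)
median_gap <- function(median_current, median_never) {
  stopifnot(is.finite(median_current), is.finite(median_never))
  round(abs(median_never - median_current), 3)
}

#' Classify a subject as reversed
#'
#' A value counts as reversed once it lies at or beyond the threshold in
#' the direction of the never-smoker median; overshooting beyond the
#' never-smoker median still counts as reversed.
#'
#' @param value covariate-adjusted residual of the subject.
#' @param threshold from [reversal_threshold()].
#' @param direction `sign(median_never - median_current)`; must be +1 or
#'   -1.
#' @return Logical.
#' @export
classify_reversed <- function(value, threshold, direction) {
  if (any(direction == 0)) {
    stop("direction must be nonzero (equal medians leave the site ",
         "undefined)", call. = FALSE)
  }
  (value - threshold) * direction >= 0
}

#' Reversal rates by quit-year bin
#'
#' Computes, for one site, the per-bin fraction of ex-smokers whose
#' covariate-adjusted residual has crossed the reversal threshold toward
#' the never-smoker median. Empty bins are reported as `NA`, never as 0.
#'
#' @param ex_values residuals of ex-smokers.
#' @param quit_years years since cessation, aligned with `ex_values`.
#' @param medians named numeric vector with elements `current` and
#'   `never` (group medians of the adjusted residuals).
#' @param spec a [reversal_spec()].
#' @param site_id optional site label carried into the output.
#' @return A `reversal_summary` tibble: one row per bin with `site_id`,
#'   `median_current`, `median_never`, `delta`, `threshold`, `bin`,
#'   `n_ex`, `n_reversed`, `rate`.
#' @export
#' @examples
#' reversal_rates(c(-0.02, -0.1, -0.2, 0.01, -0.05, -0.15),
#'                quit_years = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
#'                medians = c(current = -0.234, never = 0.037))
reversal_rates <- function(ex_values, quit_years,
                           medians, spec = reversal_spec(),
                           site_id = NA_character_) {
  stopifnot(length(ex_values) == length(quit_years),
            all(c("current", "never") %in% names(medians)))
  mc <- medians[["current"]]
  mn <- medians[["never"]]
  direction <- sign(mn - mc)
  if (direction == 0) {
    warning("equal group medians: reversal undefined, site skipped")
    return(NULL)
  }
  thr <- if (spec$gap_covered) {
    round(mc + spec$fraction * (mn - mc), 3)
  } else {
    reversal_threshold(mc, mn, spec$fraction)
  }
  reversed <- classify_reversed(ex_values, thr, direction)

  edges <- spec$bins
  bin_label <- function(lo, hi) {
    if (is.infinite(hi)) sprintf("> %g y", lo)
    else if (lo == edges[1]) sprintf("< %g y", hi)
    else sprintf("%g-%g y", lo, hi)
  }
  idx <- cut(quit_years, breaks = edges, right = TRUE,
             include.lowest = TRUE, labels = FALSE)
  rows <- purrr::map_dfr(seq_len(length(edges) - 1L), function(b) {
    in_bin <- which(!is.na(idx) & idx == b)
    n_ex <- length(in_bin)
    n_rev <- sum(reversed[in_bin])
    tibble::tibble(
      bin = bin_label(edges[b], edges[b + 1]),
      n_ex = n_ex,
      n_reversed = n_rev,
      rate = if (n_ex == 0) NA_real_ else n_rev / n_ex
    )
  })
  out <- dplyr::mutate(rows,
                       site_id = site_id,
                       median_current = mc,
                       median_never = mn,
                       delta = median_gap(mc, mn),
                       threshold = thr,
                       .before = 1)
  structure(out, class = c("reversal_summary", class(out)))
}

#' Reversal summary for every significant site
#'
#' Runs [reversal_rates()] per site on a matrix of covariate-adjusted
#' residuals, using the current- and never-smoker group medians.
#'
#' @param residuals numeric sites x subjects matrix of adjusted residuals
#'   (e.g. from [residualize_matrix()]).
#' @param subjects subject tibble aligned with the columns.
#' @param sites site ids (rows of `residuals`) to summarise; defaults to
#'   all rows.
#' @param spec a [reversal_spec()].
#' @return A `reversal_summary` tibble stacked over sites.
#' @export
reversal_summary <- function(residuals, subjects, sites = NULL,
                             spec = reversal_spec()) {
  sub <- subjects[match(colnames(residuals), subjects$subject_id), ]
  if (is.null(sites)) sites <- rownames(residuals)
  cur <- sub$smoking_status == "current"
  nev <- sub$smoking_status == "never"
  exs <- sub$smoking_status == "ex"
  out <- purrr::map(sites, function(s) {
    v <- residuals[s, ]
    med <- c(current = stats::median(v[cur], na.rm = TRUE),
             never = stats::median(v[nev], na.rm = TRUE))
    suppressWarnings(
      reversal_rates(v[exs], sub$quit_years[exs], med, spec, site_id = s))
  })
  res <- dplyr::bind_rows(out)
  structure(res, class = c("reversal_summary", class(res)))
}

#' Plot reversal rates across quit-year bins
#'
#' @param object a `reversal_summary`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.reversal_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$bin <- factor(df$bin, levels = unique(df$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$rate,
                                   group = .data$site_id)) +
    ggplot2::geom_line(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "years since cessation", y = "reversal rate") +
    ggplot2::theme_minimal()
}
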