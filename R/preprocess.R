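#' Probe/gene quality-control filter
#'
#' Removes sites whose missing fraction exceeds `max_missing_frac`
#' (default 1%) and sites annotated to the X or Y chromosome, preserving
#' the order of the remaining sites.
#'
#' @param x an [omics_matrix()].
#' @param max_missing_frac maximum tolerated fraction of masked subjects
#'   per site.
#' @return A list: `matrix` (filtered [omics_matrix()]) and `report`
#'   (a `qc_report`: input/removed/output counts and per-filter site
#'   lists).
#' @export
qc_filter <- function(x, max_missing_frac = 0.01) {
  stopifnot(inherits(x, "omics_matrix"))
  ann <- x$annotation
  ids <- rownames(x$values)
  if (!all(ids %in% ann[[1]])) {
    missing <- setdiff(ids, ann[[1]])
    stop("annotation is missing site(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  chrom <- as.character(ann$chrom)
  sex_chrom <- chrom %in% c("X", "Y", "chrX", "chrY", "23", "24")

  miss_frac <- if (is.null(x$mask)) rep(0, nrow(x$values))
               else rowMeans(x$mask)
  too_missing <- miss_frac > max_missing_frac & !sex_chrom

  keep <- !(sex_chrom | miss_frac > max_missing_frac)
  out <- omics_matrix(x$values[keep, , drop = FALSE],
                      ann[keep, , drop = FALSE], x$assay,
                      if (is.null(x$mask)) NULL
                      else x$mask[keep, , drop = FALSE])
  report <- structure(list(
    n_input_sites = nrow(x$values),
    n_removed_missingness = sum(too_missing),
    n_removed_sex_chrom = sum(sex_chrom),
    n_output_sites = sum(keep),
    removed_missingness = ids[too_missing],
    removed_sex_chrom = ids[sex_chrom]
  ), class = "qc_report")
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input %d sites; removed %d (missingness) + %d (chrX/Y); kept %d\n",
              x$n_input_sites, x$n_removed_missingness,
              x$n_removed_sex_chrom, x$n_output_sites))
  invisible(x)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles of their Blom-adjusted ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with offset `c = 3/8` by default.
#' Ties receive the average rank; missing values stay missing. The result
#' is a strictly monotone function of the input ranks, so it is invariant
#' to any strictly increasing transform of the input.
#'
#' @param values numeric vector with at least 3 non-missing, non-constant
#'   values.
#' @param offset rank offset constant (Blom's 3/8).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' rank_inverse_normal(c(3, 1, 4, 1, 5))
rank_inverse_normal <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 3) {
    stop("need at least 3 non-missing values", call. = FALSE)
  }
  if (max(v) == min(v)) {
    stop("cannot rank-transform a constant vector", call. = FALSE)
  }
  n <- length(v)
  r <- rank(v, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Covariate residuals from a (mixed) linear model
#'
#' Regresses `values` on the fixed covariates, with optional random
#' intercepts for the grouping factors, and returns the residuals after
#' removing both the fitted fixed part and the BLUPs of the random
#' effects. With no grouping factors this reduces exactly to ordinary
#' least-squares residuals. Grouping factors whose random-effect structure
#' is unidentifiable (one observation per level throughout) are dropped
#' with a fall-back to OLS.
#'
#' @param values numeric response vector.
#' @param data data frame holding the covariates (same row order).
#' @param fixed character vector of fixed covariate column names.
#' @param random character vector of grouping factor column names (random
#'   intercepts), or `NULL`.
#' @return Numeric residual vector (mean approximately 0); `NA` where
#'   `values` is `NA`.
#' @export
residualize <- function(values, data, fixed = character(),
                        random = NULL) {
  stopifnot(length(values) == nrow(data))
  ok <- stats::complete.cases(values, data[, c(fixed, random), drop = FALSE])
  df <- data[ok, , drop = FALSE]
  df$.y <- values[ok]

  rhs <- if (length(fixed) == 0) "1" else paste(fixed, collapse = " + ")
  out <- rep(NA_real_, length(values))

  use_random <- character()
  if (!is.null(random)) {
    for (g in random) {
      ng <- length(unique(df[[g]]))
      if (ng > 1 && ng < nrow(df)) use_random <- c(use_random, g)
    }
  }

  if (length(use_random) > 0) {
    fml <- stats::as.formula(paste(
      ".y ~", rhs, "+",
      paste(sprintf("(1 | %s)", use_random), collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    res <- stats::residuals(fit)
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs))
    mm <- stats::model.matrix(fml, data = df)
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    res <- stats::residuals(stats::lm(fml, data = df))
  }
  out[ok] <- res
  out
}

#' Residualize every site of an omics matrix
#'
#' Applies [rank_inverse_normal()] (optionally) then [residualize()] to
#' each row, per-site complete-case.
#'
#' @param x an [omics_matrix()].
#' @param subjects subject tibble (columns matched by `subject_id` to the
#'   matrix columns).
#' @param fixed,random passed to [residualize()].
#' @param transform `"rank_int"` (default) or `"identity"`.
#' @return Numeric matrix of residuals, same dimnames as `x$values`.
#' @export
residualize_matrix <- function(x, subjects,
                               fixed = c("age", "bmi", "alcohol", "batch"),
                               random = c("family_id"),
                               transform = c("rank_int", "identity")) {
  stopifnot(inherits(x, "omics_matrix"))
  transform <- match.arg(transform)
  sub <- subjects[match(colnames(x$values), subjects$subject_id), ]
  vals <- x$values
  if (!is.null(x$mask)) vals[x$mask] <- NA
  out <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))

  transform_y <- function(v) {
    if (transform == "rank_int") rank_inverse_normal(v) else v
  }

  # shared design across sites: fit one mixed-model template on the first
  # complete site and refit per row (exact, much faster); rows with
  # missing values fall back to a per-site fit on their complete cases
  use_random <- character()
  if (!is.null(random)) {
    for (g in random) {
      ng <- length(unique(sub[[g]]))
      if (ng > 1 && ng < nrow(sub)) use_random <- c(use_random, g)
    }
  }
  tmpl <- NULL
  if (length(use_random) > 0 && !anyNA(vals)) {
    df <- sub
    df$.y <- transform_y(vals[1, ])
    fml <- stats::as.formula(paste(
      ".y ~", paste(fixed, collapse = " + "), "+",
      paste(sprintf("(1 | %s)", use_random), collapse = " + ")))
    tmpl <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.conv.grad = "ignore",
                   check.conv.hess = "ignore",
                   calc.derivs = FALSE)))),
      error = function(e) NULL)
  }
  for (i in seq_len(nrow(vals))) {
    v <- transform_y(vals[i, ])
    if (!is.null(tmpl) && !anyNA(v)) {
      out[i, ] <- tryCatch(
        stats::residuals(suppressMessages(suppressWarnings(
          lme4::refit(tmpl, newresp = v)))),
        error = function(e) residualize(v, sub, fixed = fixed,
                                        random = random))
    } else {
      out[i, ] <- residualize(v, sub, fixed = fixed, random = random)
    }
  }
  out
}
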