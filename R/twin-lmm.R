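#' Specification of the twin association model
#'
#' Describes the per-site model contrasting current smokers against never
#' smokers: a linear mixed model with the smoking indicator as the
#' exposure, fixed covariates, and random intercepts for family plus an
#' extra pair-level intercept that is active only within MZ pairs (the
#' zygosity component). Ex-smokers are excluded from the design.
#'
#' @param outcome_transform `"rank_int"` (rank inverse-normal per site,
#'   the default) or `"identity"`.
#' @param fixed fixed-effect covariate column names in the subject table.
#'   Blood-mode analyses append the seven estimated cell-count columns
#'   here as plain numeric covariates.
#' @param p_method `"lrt"` (1-df likelihood-ratio of full vs null
#'   maximum-likelihood fits, the default) or `"f"` (Wald-F
#'   approximation from the full fit).
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome_transform = c("rank_int", "identity"),
                       fixed = c("age", "bmi", "alcohol", "batch"),
                       p_method = c("lrt", "f")) {
  structure(list(outcome_transform = match.arg(outcome_transform),
                 fixed = fixed,
                 p_method = match.arg(p_method)),
            class = "model_spec")
}

# analysis frame for a current-vs-never contrast: exposure indicator,
# usable covariates (constants dropped), grouping factors.
# Random terms are only retained when identifiable: family needs at least
# one multi-member family, the MZ-pair component at least one MZ pair.
build_design <- function(subjects, spec) {
  keep <- subjects$smoking_status %in% c("current", "never")
  d <- subjects[keep, , drop = FALSE]
  if (length(unique(d$smoking_status)) < 2 ||
      min(table(d$smoking_status)) < 2) {
    stop("need at least 2 subjects per exposure level (current / never)",
         call. = FALSE)
  }
  d$smoke <- as.integer(d$smoking_status == "current")
  fixed <- spec$fixed[vapply(spec$fixed, function(f) {
    length(unique(d[[f]])) > 1
  }, logical(1))]
  # centre and scale numeric covariates: improves mixed-model conditioning
  # and leaves the exposure coefficient and test untouched
  for (f in fixed) {
    if (is.numeric(d[[f]])) d[[f]] <- as.numeric(scale(d[[f]]))
  }
  d$mz_pair <- ifelse(d$zygosity == "MZ", d$family_id,
                      paste0(".solo.", d$subject_id))
  fam_tab <- table(d$family_id)
  random <- character()
  if (any(fam_tab > 1)) random <- "family_id"
  if (any(d$zygosity == "MZ") &&
      any(table(d$mz_pair) > 1)) random <- c(random, "mz_pair")
  list(data = d, fixed = fixed, random = random, keep = keep)
}

fit_formulas <- function(fixed, random) {
  rhs0 <- if (length(fixed) == 0) "1" else paste(fixed, collapse = " + ")
  re <- if (length(random) == 0) "" else
    paste("+", paste(sprintf("(1 | %s)", random), collapse = " + "))
  list(full = stats::as.formula(paste(".y ~ smoke +", rhs0, re)),
       null = stats::as.formula(paste(".y ~", rhs0, re)))
}

lmm_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore",
                    calc.derivs = FALSE)
}

# extract (coef, se, p) for the smoke term from fitted full/null models
extract_smoke <- function(full, null, p_method, mixed) {
  if (mixed) {
    cf <- lme4::fixef(full)["smoke"]
    se <- sqrt(diag(as.matrix(stats::vcov(full)))[
      match("smoke", names(lme4::fixef(full)))])
    n <- stats::nobs(full)
    p_fix <- length(lme4::fixef(full))
  } else {
    sm <- summary(full)$coefficients
    cf <- sm["smoke", 1]
    se <- sm["smoke", 2]
    n <- stats::nobs(full)
    p_fix <- nrow(sm)
  }
  if (p_method == "f") {
    fstat <- (cf / se)^2
    p <- stats::pf(fstat, 1, n - p_fix, lower.tail = FALSE)
  } else {
    ll <- 2 * (as.numeric(stats::logLik(full)) -
                 as.numeric(stats::logLik(null)))
    p <- stats::pchisq(max(ll, 0), df = 1, lower.tail = FALSE)
  }
  c(coef = unname(cf), se = unname(se), p = unname(p))
}

#' Fit the twin mixed model at a single site
#'
#' Fits the full model (exposure + covariates + random intercepts for
#' family and the MZ-pair component) and the null model without the
#' exposure, both by maximum likelihood, and returns the exposure
#' coefficient, its standard error and the full-vs-null p-value
#' (1-df likelihood ratio by default). When no random term is
#' identifiable (e.g. an all-singleton cohort) the engine reduces to
#' ordinary least squares with the corresponding F/likelihood-ratio test.
#'
#' @param outcome numeric vector, one value per subject row.
#' @param subjects subject tibble.
#' @param spec a [model_spec()].
#' @return Named numeric vector `coef`, `se`, `p` (all `NA` on a failed
#'   fit).
#' @export
fit_site <- function(outcome, subjects, spec = model_spec()) {
  des <- build_design(subjects, spec)
  d <- des$data
  y <- outcome[des$keep]
  if (spec$outcome_transform == "rank_int") y <- rank_inverse_normal(y)
  d$.y <- y
  fml <- fit_formulas(des$fixed, des$random)
  mixed <- length(des$random) > 0
  res <- tryCatch({
    if (mixed) {
      full <- suppressMessages(suppressWarnings(
        lme4::lmer(fml$full, data = d, REML = FALSE,
                   control = lmm_control())))
      null <- suppressMessages(suppressWarnings(
        lme4::lmer(fml$null, data = d, REML = FALSE,
                   control = lmm_control())))
    } else {
      full <- stats::lm(fml$full, data = d)
      null <- stats::lm(fml$null, data = d)
    }
    extract_smoke(full, null, spec$p_method, mixed)
  }, error = function(e) c(coef = NA_real_, se = NA_real_, p = NA_real_))
  res
}

#' Run the association scan over an omics matrix
#'
#' Per-site [fit_site()] contrasting current vs never smokers, with
#' Benjamini-Hochberg q-values and significance calls at `fdr_level`.
#' For speed, one full and one null model template are fitted and then
#' refitted with each site's (transformed) outcome, which is exact
#' because the design is shared across sites; sites with missing values
#' are refitted from scratch on their complete cases.
#'
#' @param x an [omics_matrix()].
#' @param subjects subject tibble covering the matrix columns.
#' @param spec a [model_spec()].
#' @param fdr_level FDR significance level (default 0.01).
#' @return An `assoc_table` tibble: `site_id`, `region_label`, `coef`,
#'   `se`, `p`, `q`, `direction` (`hypo`/`hyper` in current smokers;
#'   a coefficient of exactly 0 counts as `hyper`), `significant`.
#' @export
run_association <- function(x, subjects, spec = model_spec(),
                            fdr_level = 0.01) {
  stopifnot(inherits(x, "omics_matrix"))
  sub <- subjects[match(colnames(x$values), subjects$subject_id), ]
  if (any(is.na(sub$subject_id))) {
    stop("subjects table does not cover all matrix columns", call. = FALSE)
  }
  des <- build_design(sub, spec)
  d <- des$data
  vals <- x$values[, des$keep, drop = FALSE]
  if (!is.null(x$mask)) vals[x$mask[, des$keep, drop = FALSE]] <- NA
  fml <- fit_formulas(des$fixed, des$random)
  mixed <- length(des$random) > 0

  transform_y <- function(v) {
    if (spec$outcome_transform == "rank_int") rank_inverse_normal(v) else v
  }

  n_sites <- nrow(vals)
  out <- matrix(NA_real_, n_sites, 3,
                dimnames = list(rownames(vals), c("coef", "se", "p")))

  if (mixed) {
    d$.y <- transform_y(vals[1, ])
    tmpl_full <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml$full, data = d, REML = FALSE,
                 control = lmm_control()))), error = function(e) NULL)
    tmpl_null <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(fml$null, data = d, REML = FALSE,
                 control = lmm_control()))), error = function(e) NULL)
    fit_fresh <- function(d2) {
      full <- suppressMessages(suppressWarnings(
        lme4::lmer(fml$full, data = d2, REML = FALSE,
                   control = lmm_control())))
      null <- suppressMessages(suppressWarnings(
        lme4::lmer(fml$null, data = d2, REML = FALSE,
                   control = lmm_control())))
      extract_smoke(full, null, spec$p_method, TRUE)
    }
    for (i in seq_len(n_sites)) {
      v <- vals[i, ]
      out[i, ] <- tryCatch({
        if (anyNA(v) || is.null(tmpl_full) || is.null(tmpl_null)) {
          ok <- !is.na(v)
          d2 <- d[ok, , drop = FALSE]
          d2$.y <- transform_y(v[ok])
          fit_fresh(d2)
        } else {
          y <- transform_y(v)
          # refit is fast but occasionally fails from the template's
          # starting values; fall back to a fresh fit in that case
          tryCatch({
            full <- suppressMessages(suppressWarnings(
              refit_quiet(tmpl_full, y)))
            null <- suppressMessages(suppressWarnings(
              refit_quiet(tmpl_null, y)))
            extract_smoke(full, null, spec$p_method, TRUE)
          }, error = function(e) {
            d2 <- d
            d2$.y <- y
            fit_fresh(d2)
          })
        }
      }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    }
  } else {
    mm <- stats::model.matrix(fml$full, data = d)
    mm0 <- stats::model.matrix(fml$null, data = d)
    for (i in seq_len(n_sites)) {
      out[i, ] <- tryCatch({
        v <- transform_y(vals[i, ])
        ok <- !is.na(v)
        ols_smoke(mm[ok, , drop = FALSE], mm0[ok, , drop = FALSE], v[ok],
                  spec$p_method)
      }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    }
  }

  ann <- x$annotation
  tbl <- tibble::tibble(
    site_id = rownames(vals),
    region_label = if ("region_label" %in% names(ann)) ann$region_label
                   else if ("gene_name" %in% names(ann)) ann$gene_name
                   else NA_character_,
    coef = out[, "coef"],
    se = out[, "se"],
    p = out[, "p"],
    q = bh_fdr(out[, "p"]),
    direction = ifelse(out[, "coef"] < 0, "hypo", "hyper")
  )
  tbl$significant <- !is.na(tbl$q) & tbl$q < fdr_level
  structure(tbl, class = c("assoc_table", class(tbl)),
            fdr_level = fdr_level, assay = x$assay,
            n_flagged = sum(is.na(out[, "p"])))
}

# refit with convergence checks relaxed (matches the template's control)
refit_quiet <- function(object, newresp) {
  lme4::refit(object, newresp = newresp)
}

# closed-form OLS for the smoke contrast (used when no random term is
# identifiable); LRT and F variants
ols_smoke <- function(mm, mm0, y, p_method) {
  fit <- stats::lm.fit(mm, y)
  k <- match("smoke", colnames(mm))
  rss1 <- sum(fit$residuals^2)
  n <- length(y)
  p1 <- fit$rank
  xtx_inv <- chol2inv(chol(crossprod(mm)))
  sigma2 <- rss1 / (n - p1)
  se <- sqrt(sigma2 * xtx_inv[k, k])
  cf <- fit$coefficients[k]
  if (p_method == "f") {
    fit0 <- stats::lm.fit(mm0, y)
    rss0 <- sum(fit0$residuals^2)
    fstat <- (rss0 - rss1) / (rss1 / (n - p1))
    p <- stats::pf(fstat, 1, n - p1, lower.tail = FALSE)
  } else {
    fit0 <- stats::lm.fit(mm0, y)
    rss0 <- sum(fit0$residuals^2)
    lrt <- n * log(rss0 / rss1)
    p <- stats::pchisq(max(lrt, 0), 1, lower.tail = FALSE)
  }
  c(coef = unname(cf), se = unname(se), p = unname(p))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjusted p-values; `NA` p-values stay `NA` and do not count
#' toward the number of tests.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Bonferroni significance threshold
#'
#' `alpha / m`, reported to three significant figures.
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests (>= 1).
#' @return The adjusted threshold.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 42)
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  signif(alpha / m, 3)
}

#' Fraction of hypo-methylated signals
#'
#' Percentage of sites whose coefficient is negative (lower level in
#' current smokers), to one decimal. A coefficient of exactly zero counts
#' as hyper (fixed tie rule).
#'
#' @param table a tibble with a `coef` column (e.g. an `assoc_table`).
#' @return Percentage (0-100), one decimal.
#' @export
summarize_directions <- function(table) {
  stopifnot(nrow(table) > 0, "coef" %in% names(table))
  round(100 * mean(table$coef < 0, na.rm = TRUE), 1)
}

#' Region summary of an association table
#'
#' Counts distinct region labels and the percentage of sites per region
#' class. A label matching a cytogenetic band (e.g. `2q37.1`) is classed
#' intergenic, anything else as a gene.
#'
#' @param table a tibble with a `region_label` column.
#' @return A list: `n_unique_regions`, `class_fractions` (named percent
#'   vector, one decimal).
#' @export
summarize_regions <- function(table) {
  stopifnot(nrow(table) > 0)
  if (!"region_label" %in% names(table) ||
      any(is.na(table$region_label))) {
    stop("every site needs a region_label", call. = FALSE)
  }
  lab <- table$region_label
  cls <- ifelse(grepl("^[0-9]+[pq][0-9]", lab), "intergenic", "gene")
  fr <- round(100 * table(cls) / length(cls), 1)
  list(n_unique_regions = length(unique(lab)),
       class_fractions = stats::setNames(as.numeric(fr), names(fr)))
}

#' @importFrom generics glance
#' @export
glance.assoc_table <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    fdr_level = attr(x, "fdr_level"),
    n_flagged = attr(x, "n_flagged"),
    pct_hypo = summarize_directions(x)
  )
}

#' Volcano-style plot of an association table
#'
#' @param object an `assoc_table`.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.assoc_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coef,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "smoking coefficient (SD units)",
                  y = expression(-log[10](p)),
                  colour = paste0("FDR < ",
                                  attr(object, "fdr_level"))) +
    ggplot2::theme_minimal()
}
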