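#' Assign a longitudinal cessation category
#'
#' Five trajectories between the two phenotype time points: constant
#' smokers (S-S), quitters over the interval (S-E), recent ex-smokers who
#' stay ex (E1-E5: 1 to 5 quit years at time point 1), long-term
#' ex-smokers (E5+: more than 5 quit years), and never smokers (N-N).
#' Anything else (including ex-smokers with under one quit year at time
#' point 1 and relapse paths) is `"unclassified"`.
#'
#' @param status_t1,status_t2 smoking status at the two time points
#'   (`"current"`, `"ex"`, `"never"`).
#' @param quit_years_t1 years since cessation at time point 1 (needed for
#'   ex-smokers; `NA` otherwise).
#' @return Character vector of categories.
#' @export
#' @examples
#' assign_cessation_category("current", "ex", NA)
#' assign_cessation_category("ex", "ex", 3)
assign_cessation_category <- function(status_t1, status_t2,
                                      quit_years_t1 = NA_real_) {
  n <- max(length(status_t1), length(status_t2), length(quit_years_t1))
  status_t1 <- rep_len(status_t1, n)
  status_t2 <- rep_len(status_t2, n)
  quit_years_t1 <- rep_len(quit_years_t1, n)
  dplyr::case_when(
    status_t1 == "current" & status_t2 == "current" ~ "S-S",
    status_t1 == "current" & status_t2 == "ex" ~ "S-E",
    status_t1 == "ex" & status_t2 == "ex" &
      !is.na(quit_years_t1) & quit_years_t1 >= 1 &
      quit_years_t1 <= 5 ~ "E1-E5",
    status_t1 == "ex" & status_t2 == "ex" &
      !is.na(quit_years_t1) & quit_years_t1 > 5 ~ "E5+",
    status_t1 == "never" & status_t2 == "never" ~ "N-N",
    TRUE ~ "unclassified"
  )
}

#' Marker-phenotype association with an optional smoking interaction
#'
#' Linear regression of an adiposity phenotype on a marker (methylation or
#' expression residual), adjusting for age, BMI and smoking status. The
#' main-effect estimate comes from the model without an interaction; the
#' interaction p-value compares the model with a marker-by-smoking-status
#' term against it.
#'
#' @param data data frame with the phenotype, marker and covariates.
#' @param phenotype,marker column names.
#' @param covariates covariate column names (default age, BMI, smoking
#'   status).
#' @param test_interaction add and test a `marker x smoking status` term.
#' @param bonferroni_m number of tests used for the significance flag
#'   (threshold `0.05 / bonferroni_m`); `NULL` skips the flag.
#' @return One-row tibble: `phenotype`, `marker`, `beta`, `se`, `p_main`,
#'   `p_interaction` (`NA` unless requested), `significant`.
#' @export
associate_phenotype <- function(data, phenotype, marker,
                                covariates = c("age", "bmi",
                                               "smoking_status"),
                                test_interaction = TRUE,
                                bonferroni_m = NULL) {
  cols <- c(phenotype, marker, covariates)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  names(d)[1:2] <- c(".pheno", ".marker")
  rhs <- paste(c(".marker", covariates), collapse = " + ")
  fml_main <- stats::as.formula(paste(".pheno ~", rhs))
  mm <- stats::model.matrix(fml_main, data = d)
  if (qr(mm)$rank < ncol(mm)) {
    qd <- qr(mm)
    dropped <- colnames(mm)[qd$pivot[(qd$rank + 1):ncol(mm)]]
    stop("rank-deficient design; dropped term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit_main <- stats::lm(fml_main, data = d)
  sm <- summary(fit_main)$coefficients
  beta <- sm[".marker", 1]
  se <- sm[".marker", 2]
  p_main <- sm[".marker", 4]

  p_int <- NA_real_
  smoking_cov <- intersect(covariates,
                           c("smoking_status", "smoke", "group"))
  if (test_interaction && length(smoking_cov) > 0) {
    fml_int <- stats::update(fml_main,
                             stats::as.formula(paste(
                               ". ~ . + .marker:", smoking_cov[1])))
    fit_int <- stats::lm(fml_int, data = d)
    p_int <- stats::anova(fit_main, fit_int)[2, "Pr(>F)"]
  }
  thr <- if (is.null(bonferroni_m)) NA_real_
         else bonferroni_threshold(0.05, bonferroni_m)
  tibble::tibble(phenotype = phenotype, marker = marker,
                 beta = beta, se = se, p_main = p_main,
                 p_interaction = p_int,
                 significant = if (is.na(thr)) NA else p_main < thr)
}

#' Predict future phenotype change from a baseline marker
#'
#' Tests whether the change in a phenotype between time points depends on
#' a baseline marker differently in the exposure-change group (subjects
#' who quit recently: categories S-E and E1-E5) than in the reference
#' group (E5+, S-S, N-N). Fits
#' `delta ~ marker + group + marker:group (+ covariates)`; the
#' interaction p-value comes from a full-vs-reduced model comparison, and
#' the marker's unadjusted R-squared within the exposure-change group is
#' reported as percent variance explained.
#'
#' @param data data frame with one row per subject.
#' @param marker column name of the baseline marker level.
#' @param delta column name of the phenotype change (t2 minus t1).
#' @param group column name of a two-level group factor/character;
#'   the exposure-change level is named by `exposure_level`.
#' @param exposure_level value of `group` identifying the
#'   exposure-change group (default `"exposure-change"`).
#' @param covariates optional additional covariate column names.
#' @return One-row tibble: `marker`, `n_exposure`, `n_reference`,
#'   `interaction_p`, `var_explained_pct`, `low_n` (flag when the
#'   exposure-change group has fewer than 5 subjects).
#' @export
predict_future_change <- function(data, marker, delta, group,
                                  exposure_level = "exposure-change",
                                  covariates = character()) {
  cols <- c(marker, delta, group, covariates)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  names(d)[1:3] <- c(".marker", ".delta", ".group")
  d$.group <- factor(d$.group == exposure_level,
                     levels = c(FALSE, TRUE),
                     labels = c("reference", "exposure"))
  n_exp <- sum(d$.group == "exposure")
  n_ref <- sum(d$.group == "reference")
  if (n_exp == 0 || n_ref == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  rhs_cov <- if (length(covariates) == 0) "" else
    paste("+", paste(covariates, collapse = " + "))
  fml_red <- stats::as.formula(paste(".delta ~ .marker + .group", rhs_cov))
  fml_full <- stats::as.formula(paste(".delta ~ .marker * .group", rhs_cov))
  fit_red <- stats::lm(fml_red, data = d)
  fit_full <- stats::lm(fml_full, data = d)
  p_int <- stats::anova(fit_red, fit_full)[2, "Pr(>F)"]

  de <- d[d$.group == "exposure", ]
  r2 <- if (nrow(de) >= 3) {
    summary(stats::lm(.delta ~ .marker, data = de))$r.squared
  } else NA_real_

  tibble::tibble(marker = marker, n_exposure = n_exp, n_reference = n_ref,
                 interaction_p = p_int,
                 var_explained_pct = 100 * r2,
                 low_n = n_exp < 5)
}

#' Scan a marker panel for future-change interactions
#'
#' Applies [predict_future_change()] to every row of a marker matrix and
#' flags significance at the panel Bonferroni threshold `0.05 / m`.
#'
#' @param markers sites x subjects matrix of baseline marker levels.
#' @param phenotypes longitudinal phenotype tibble (needs `subject_id`,
#'   `status_t1`, `status_t2`, `quit_years_t1` and the `delta` column or
#'   the `_t1`/`_t2` pair it derives from).
#' @param delta_from phenotype stem, e.g. `"vfm"`; the change is
#'   `vfm_t2 - vfm_t1`.
#' @return Tibble with one row per marker plus `significant` at the panel
#'   Bonferroni threshold (attribute `threshold`).
#' @export
scan_future_change <- function(markers, phenotypes, delta_from = "vfm") {
  ph <- phenotypes
  ph$category <- assign_cessation_category(ph$status_t1, ph$status_t2,
                                           ph$quit_years_t1)
  ph <- ph[ph$category != "unclassified", ]
  ph$group <- ifelse(ph$category %in% c("S-E", "E1-E5"),
                     "exposure-change", "reference")
  ph$delta <- ph[[paste0(delta_from, "_t2")]] -
    ph[[paste0(delta_from, "_t1")]]
  ids <- intersect(ph$subject_id, colnames(markers))
  ph <- ph[match(ids, ph$subject_id), ]

  out <- purrr::map_dfr(rownames(markers), function(s) {
    d <- ph
    d$marker <- markers[s, ids]
    res <- tryCatch(
      predict_future_change(d, "marker", "delta", "group"),
      error = function(e) tibble::tibble(
        marker = s, n_exposure = sum(d$group == "exposure-change"),
        n_reference = sum(d$group == "reference"),
        interaction_p = NA_real_, var_explained_pct = NA_real_,
        low_n = TRUE))
    res$marker <- s
    res
  })
  m <- nrow(out)
  thr <- bonferroni_threshold(0.05, m)
  out$significant <- !is.na(out$interaction_p) & out$interaction_p < thr
  structure(out, threshold = thr, class = c("future_change_scan",
                                            class(out)))
}
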