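#' Sites-by-subjects omics container
#'
#' Thin container pairing a numeric sites x subjects matrix with a site
#' annotation tibble. Methylation values are beta values in (0, 1);
#' expression values are non-negative RPKM-like abundances.
#'
#' @param values numeric matrix, rows = sites (named), columns = subjects
#'   (named).
#' @param annotation tibble with one row per site; the first column must
#'   hold the site ids matching `rownames(values)`.
#' @param assay `"methylation"` or `"expression"`.
#' @param mask optional logical matrix (same shape): `TRUE` marks a value
#'   flagged missing (e.g. failed detection).
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, annotation, assay, mask = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  id_col <- annotation[[1]]
  if (!identical(rownames(values), as.character(id_col))) {
    stop("annotation rows must match the matrix rows (same ids, same order)",
         call. = FALSE)
  }
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(values)))
  structure(list(values = values, annotation = annotation, assay = assay,
                 mask = mask),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix: %s> %d sites x %d subjects\n", x$assay,
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$mask)) {
    cat(sprintf("  %.2f%% values masked\n", 100 * mean(x$mask)))
  }
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Long-format view of an omics matrix
#'
#' @param x an [omics_matrix()].
#' @param ... unused.
#' @return Tibble with columns `site_id`, `subject_id`, `value`.
#' @importFrom generics tidy
#' @export
tidy.omics_matrix <- function(x, ...) {
  tibble::tibble(
    site_id = rep(rownames(x$values), times = ncol(x$values)),
    subject_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

# shared latent machinery: family + MZ-extra + batch + smoking decay +
# optional cis-genotype term + residual, all on the latent scale
simulate_latent <- function(subjects, effects, tau, config,
                            dosage_term = NULL) {
  n_sites <- length(effects)
  n <- nrow(subjects)
  fam <- as.integer(factor(subjects$family_id))
  mz_pair <- ifelse(subjects$zygosity == "MZ", subjects$family_id,
                    paste0("solo_", subjects$subject_id))
  mzf <- as.integer(factor(mz_pair))
  batchf <- as.integer(factor(subjects$batch))
  s_tot <- latent_sd(config)

  fam_eff <- matrix(stats::rnorm(n_sites * max(fam),
                                 sd = sqrt(config$var_family)),
                    nrow = n_sites)[, fam, drop = FALSE]
  mz_eff <- matrix(stats::rnorm(n_sites * max(mzf),
                                sd = sqrt(config$var_mz_extra)),
                   nrow = n_sites)[, mzf, drop = FALSE]
  batch_eff <- matrix(stats::rnorm(n_sites * max(batchf),
                                   sd = sqrt(config$var_batch)),
                      nrow = n_sites)[, batchf, drop = FALSE]
  resid <- matrix(stats::rnorm(n_sites * n, sd = sqrt(config$var_resid)),
                  nrow = n_sites)
  tau <- rep_len(tau, n_sites)
  decay <- matrix(0, n_sites, n)
  decay[, subjects$smoking_status == "current"] <- 1
  ex <- which(subjects$smoking_status == "ex")
  if (length(ex) > 0) {
    decay[, ex] <- exp(-outer(1 / tau, subjects$quit_years[ex]))
  }
  smoke_term <- (effects * s_tot) * decay

  lat <- fam_eff + mz_eff + batch_eff + resid + smoke_term
  if (!is.null(dosage_term)) lat <- lat + dosage_term
  lat
}

#' Generate methylation beta values
#'
#' Latent value per probe and subject = probe baseline + family effect +
#' extra MZ-shared effect + batch effect + smoking term + optional
#' cis-SNP term + residual; the reported beta value is the inverse logit
#' of the latent value, hence strictly inside (0, 1). The smoking term is
#' `true_effect` (in latent-SD units) for current smokers,
#' `true_effect * exp(-quit_years / tau)` for ex-smokers and 0 for never
#' smokers.
#'
#' @param subjects subject tibble from [generate_cohort()].
#' @param truth matching `truth_table`.
#' @param config the [cohort_config()].
#' @param genotypes optional genotype object from [generate_genotypes()];
#'   when supplied, probes with a truth-table meQTL gain a cis dosage term.
#' @return An [omics_matrix()] of beta values with the probe annotation.
#' @export
generate_methylation <- function(subjects, truth, config, genotypes = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  set.seed(seed_stream(config$seed, 1L))
  pr <- truth$probes
  # probe baselines span the beta range without piling mass at the bounds
  baseline <- stats::qlogis(stats::runif(nrow(pr), 0.05, 0.95))

  dosage_term <- NULL
  if (!is.null(genotypes)) {
    has_qtl <- which(!is.na(pr$meqtl_snp_id))
    if (length(has_qtl) > 0) {
      dosage_term <- matrix(0, nrow(pr), nrow(subjects))
      s_tot <- latent_sd(config)
      dos <- genotypes$dosages[pr$meqtl_snp_id[has_qtl], , drop = FALSE]
      dos <- sweep(dos, 1, rowMeans(dos))
      dosage_term[has_qtl, ] <- pr$meqtl_beta[has_qtl] * s_tot * dos
    }
  }

  lat <- simulate_latent(subjects, pr$true_effect, pr$tau, config,
                         dosage_term)
  lat <- lat + baseline
  beta <- stats::plogis(lat)
  dimnames(beta) <- list(pr$probe_id, subjects$subject_id)

  mask <- NULL
  if (config$missing_frac > 0) {
    mask <- matrix(stats::runif(length(beta)) < config$missing_frac,
                   nrow(beta), ncol(beta), dimnames = dimnames(beta))
  }
  ann <- pr[, c("probe_id", "chrom", "pos", "region_label", "region_class")]
  out <- omics_matrix(beta, ann, "methylation", mask)
  attr(out, "latent") <- lat
  out
}

#' Generate gene expression abundances
#'
#' Same latent structure as [generate_methylation()] on a log-abundance
#' scale, exponentiated to non-negative RPKM-like values. For the coupled
#' genes in the truth table, the expression latent subtracts
#' `kappa * (centred latent of the paired probe)`, inducing the negative
#' methylation-expression correlation characteristic of regulatory smoking
#' signals.
#'
#' @inheritParams generate_methylation
#' @param methylation the [omics_matrix()] from [generate_methylation()]
#'   (required when the truth table has coupled genes: coupling reuses its
#'   latent values).
#' @return An [omics_matrix()] of non-negative abundances.
#' @export
generate_expression <- function(subjects, truth, config,
                                methylation = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  set.seed(seed_stream(config$seed, 2L))
  gn <- truth$genes
  baseline <- stats::rnorm(nrow(gn), mean = 2, sd = 1)

  lat <- simulate_latent(subjects, gn$true_effect, gn$tau, config)
  lat <- lat + baseline

  if (nrow(truth$coupling) > 0) {
    if (is.null(methylation)) {
      stop("truth table has coupled genes but no methylation matrix was ",
           "supplied; generate methylation first", call. = FALSE)
    }
    miss <- setdiff(truth$coupling$probe_id, rownames(methylation$values))
    if (length(miss) > 0) {
      stop("coupled gene lacks a paired probe in the methylation matrix: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    probe_lat <- attr(methylation, "latent")
    if (is.null(probe_lat)) {  # fall back to the logit of the betas
      probe_lat <- stats::qlogis(methylation$values)
    } else {
      rownames(probe_lat) <- rownames(methylation$values)
    }
    for (k in seq_len(nrow(truth$coupling))) {
      g <- match(truth$coupling$gene_id[k], gn$gene_id)
      pl <- probe_lat[truth$coupling$probe_id[k], ]
      lat[g, ] <- lat[g, ] - truth$coupling$kappa[k] * (pl - mean(pl))
    }
  }

  expr <- exp(lat)
  dimnames(expr) <- list(gn$gene_id, subjects$subject_id)
  ann <- gn[, c("gene_id", "gene_name", "chrom", "pos")]
  omics_matrix(expr, ann, "expression")
}

#' Generate SNP genotypes with explicit parental transmission
#'
#' Per family, two parental diplotypes are drawn with allele frequencies
#' uniform on (0.05, 0.5) (all SNPs common, MAF > 5%). MZ twins receive
#' identical transmissions; DZ twins receive independent transmissions, so
#' their expected dosage correlation is 0.5 without any ad hoc adjustment.
#' SNP positions are anchored round-robin at probe positions so every probe
#' has at least one SNP inside the cis window (given enough SNPs).
#'
#' @inheritParams generate_methylation
#' @return A list with `dosages` (SNPs x subjects integer matrix in
#'   \{0,1,2\}) and `snp_map` (tibble: `snp_id`, `chrom`, `pos`, `maf`).
#' @export
generate_genotypes <- function(subjects, truth, config) {
  set.seed(seed_stream(config$seed, 3L))
  n_snps <- config$n_snps
  pr <- truth$probes
  anchor_probe <- ((seq_len(n_snps) - 1L) %% nrow(pr)) + 1L
  offset <- sample(1000:50000, n_snps, replace = TRUE)
  snp_map <- tibble::tibble(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    chrom = pr$chrom[anchor_probe],
    pos = pr$pos[anchor_probe] + offset,
    maf = stats::runif(n_snps, 0.05, 0.5)
  )

  fam <- factor(subjects$family_id, levels = unique(subjects$family_id))
  fam_idx <- as.integer(fam)
  n_fam <- nlevels(fam)
  n <- nrow(subjects)

  draw_hap <- function() {
    matrix(stats::rbinom(n_snps * n_fam, 1, snp_map$maf), nrow = n_snps)
  }
  # parental haplotypes: father (f1, f2) and mother (m1, m2) per family
  f1 <- draw_hap(); f2 <- draw_hap(); m1 <- draw_hap(); m2 <- draw_hap()

  # transmission choices per child: which paternal / maternal haplotype
  dosages <- matrix(0L, n_snps, n,
                    dimnames = list(snp_map$snp_id, subjects$subject_id))
  first_in_fam <- !duplicated(fam_idx)
  pat_choice_1 <- matrix(stats::rbinom(n_snps * n_fam, 1, 0.5),
                         nrow = n_snps)
  mat_choice_1 <- matrix(stats::rbinom(n_snps * n_fam, 1, 0.5),
                         nrow = n_snps)
  pat_choice_2 <- matrix(stats::rbinom(n_snps * n_fam, 1, 0.5),
                         nrow = n_snps)
  mat_choice_2 <- matrix(stats::rbinom(n_snps * n_fam, 1, 0.5),
                         nrow = n_snps)
  for (i in seq_len(n)) {
    f <- fam_idx[i]
    if (first_in_fam[i] || subjects$zygosity[i] == "MZ") {
      pc <- pat_choice_1[, f]; mc <- mat_choice_1[, f]
    } else {  # second DZ twin: independent transmission
      pc <- pat_choice_2[, f]; mc <- mat_choice_2[, f]
    }
    pat <- ifelse(pc == 1, f1[, f], f2[, f])
    mat <- ifelse(mc == 1, m1[, f], m2[, f])
    dosages[, i] <- pat + mat
  }
  list(dosages = dosages, snp_map = snp_map)
}

#' Generate longitudinal adiposity phenotypes
#'
#' Visceral fat mass (VFM), total fat mass (TFM), android-to-gynoid ratio
#' (AGR) and BMI at two time points roughly five years apart. Smoking
#' status at time point 2 follows the longitudinal design: a subset of
#' current smokers quits between time points, ex-smokers accrue the
#' interval onto their quit years, never smokers stay never. The phenotype
#' change carries (i) a positive cessation-group effect in subjects who
#' quit recently (S-E and E1-E5 categories), and (ii) an interaction at
#' the designated truth-table marker sites: within the exposure-change
#' group, the future VFM change is `interaction_beta * centred marker`.
#'
#' @inheritParams generate_methylation
#' @param methylation,expression optional omics matrices; when supplied the
#'   interaction term uses the observed marker values at the designated
#'   interaction probe / gene (log scale for expression).
#' @return Tibble: one row per phenotyped subject with `status_t1`,
#'   `status_t2`, `quit_years_t1` and VFM/TFM/AGR/BMI at both time points.
#' @export
generate_phenotypes <- function(subjects, truth, config,
                                methylation = NULL, expression = NULL) {
  set.seed(seed_stream(config$seed, 4L))
  gs <- config$pheno_group_sizes
  need <- c("S-S", "S-E", "E1-E5", "E5+", "N-N")
  stopifnot(all(need %in% names(gs)))

  cur <- which(subjects$smoking_status == "current")
  exs <- which(subjects$smoking_status == "ex")
  nev <- which(subjects$smoking_status == "never")
  ex_recent <- exs[subjects$quit_years[exs] >= 1 &
                     subjects$quit_years[exs] <= 5]
  ex_long <- exs[subjects$quit_years[exs] > 5]

  take <- function(pool, k) {
    k <- min(k, length(pool))
    if (k == 0) integer() else sample(pool, k)
  }
  id_se <- take(cur, gs[["S-E"]])
  id_ss <- take(setdiff(cur, id_se), gs[["S-S"]])
  id_e15 <- take(ex_recent, gs[["E1-E5"]])
  id_e5p <- take(ex_long, gs[["E5+"]])
  id_nn <- take(nev, gs[["N-N"]])

  idx <- c(id_ss, id_se, id_e15, id_e5p, id_nn)
  category <- rep(c("S-S", "S-E", "E1-E5", "E5+", "N-N"),
                  times = c(length(id_ss), length(id_se), length(id_e15),
                            length(id_e5p), length(id_nn)))
  m <- length(idx)
  sub <- subjects[idx, ]

  status_t2 <- dplyr::case_when(
    category == "S-S" ~ "current",
    category == "S-E" ~ "ex",
    category %in% c("E1-E5", "E5+") ~ "ex",
    TRUE ~ "never"
  )

  interval <- pmax(stats::rnorm(m, config$followup_years, 0.7), 3)

  # marker values at the designated interaction sites, standardized so
  # interaction_beta is in phenotype units per marker SD
  marker_m <- rep(0, m)
  if (!is.null(methylation)) {
    v <- methylation$values[truth$interaction$probe_id, sub$subject_id]
    marker_m <- as.numeric(scale(v))
  }
  marker_e <- rep(0, m)
  if (!is.null(expression)) {
    v <- log(expression$values[truth$interaction$gene_id, sub$subject_id])
    marker_e <- as.numeric(scale(v))
  }

  exposure_change <- category %in% c("S-E", "E1-E5")
  ib <- truth$interaction$interaction_beta
  group_gain <- config$group_effect * exposure_change

  base_vfm <- pmax(stats::rnorm(m, 1.2, 0.5), 0.1)
  base_tfm <- pmax(stats::rnorm(m, 25, 7), 5)
  base_agr <- pmax(stats::rnorm(m, 0.45, 0.12), 0.1)

  d_vfm <- group_gain + ib * (marker_m + marker_e) * exposure_change +
    stats::rnorm(m, 0, 0.25)
  d_tfm <- 2 * group_gain + stats::rnorm(m, 0, 2)
  d_agr <- 0.05 * group_gain + stats::rnorm(m, 0, 0.04)
  d_bmi <- 0.5 * group_gain + stats::rnorm(m, 0, 1)

  tibble::tibble(
    subject_id = sub$subject_id,
    category_truth = category,
    status_t1 = sub$smoking_status,
    status_t2 = status_t2,
    quit_years_t1 = sub$quit_years,
    interval_years = interval,
    vfm_t1 = base_vfm, vfm_t2 = base_vfm + d_vfm,
    tfm_t1 = base_tfm, tfm_t2 = base_tfm + d_tfm,
    agr_t1 = base_agr, agr_t2 = base_agr + d_agr,
    bmi_t1 = sub$bmi, bmi_t2 = sub$bmi + d_bmi
  )
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper running [generate_cohort()], [generate_genotypes()],
#' [generate_methylation()], [generate_expression()] and
#' [generate_phenotypes()] in order with consistent seeding.
#'
#' @param config a [cohort_config()].
#' @return A list: `subjects`, `truth`, `genotypes`, `methylation`,
#'   `expression`, `phenotypes`, `config`.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(n_probes = 30, n_genes = 15,
#'                                      n_snps = 60, seed = 7))
#' sim$methylation
simulate_cohort <- function(config) {
  cohort <- generate_cohort(config)
  genotypes <- generate_genotypes(cohort$subjects, cohort$truth, config)
  methylation <- generate_methylation(cohort$subjects, cohort$truth, config,
                                      genotypes)
  expression <- generate_expression(cohort$subjects, cohort$truth, config,
                                    methylation)
  phenotypes <- generate_phenotypes(cohort$subjects, cohort$truth, config,
                                    methylation, expression)
  list(subjects = cohort$subjects, truth = cohort$truth,
       genotypes = genotypes, methylation = methylation,
       expression = expression, phenotypes = phenotypes, config = config)
}
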