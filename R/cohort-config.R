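#' Configuration for the synthetic twin cohort
#'
#' Builds a validated configuration object describing a twin cohort with
#' monozygotic (MZ) pairs, dizygotic (DZ) pairs and unrelated singletons,
#' and the generative model for methylation, expression, genotypes and
#' longitudinal adiposity phenotypes. The defaults describe a cohort of
#' 84 MZ pairs, 112 DZ pairs and 150 singletons (542 subjects; 54 current,
#' 197 ex- and 291 never smokers), with smoking effects on the latent
#' (logit) methylation scale that decay exponentially with years since
#' cessation, slower for methylation than for expression.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons family structure counts.
#' @param n_current,n_ex,n_never smoking-status counts; must sum to the
#'   subject total `2 * (n_mz_pairs + n_dz_pairs) + n_singletons`.
#' @param n_probes,n_genes,n_snps numbers of CpG probes, genes and SNPs.
#' @param effect_meth,effect_expr lists with elements `n_signal` (number of
#'   truly associated sites), `size` (absolute effect in latent-SD units)
#'   and `frac_negative` (fraction of effects that lower the level in
#'   current smokers).
#' @param tau_meth,tau_expr reversal time constants in years; the expected
#'   residual smoking effect in an ex-smoker is
#'   `effect * exp(-quit_years / tau)`. Expression effects are emulated as
#'   shorter-lived than methylation effects, so `tau_expr <= tau_meth`.
#' @param kappa coupling strength: for the designated coupled genes the
#'   expression latent subtracts `kappa` times the centred latent of the
#'   paired probe, inducing negative methylation-expression correlation.
#' @param n_coupled_genes number of genes with probe-coupled expression.
#' @param var_family,var_mz_extra,var_batch,var_resid latent-scale variance
#'   components: family-shared, extra MZ-shared, batch (plate), residual.
#' @param frac_meqtl fraction of probes given a cis genetic effect.
#' @param meqtl_beta cis effect size in latent-SD units per allele.
#' @param cis_window cis window half-width in base pairs.
#' @param quit_years_mean,quit_years_sd moments of the gamma distribution
#'   of years since cessation among ex-smokers (truncated at 0.25 years,
#'   i.e. quit for at least 3 months).
#' @param n_batches number of batch (plate) levels.
#' @param interaction_beta phenotype-interaction effect in VFM units per
#'   marker SD: standardized marker levels at the designated sites predict
#'   future visceral-fat change in the exposure-change group only. The
#'   default (0.2, against residual noise SD 0.25) puts the within-group
#'   variance explained near 40%.
#' @param group_effect mean adiposity gain (kg, VFM scale) in subjects who
#'   quit recently between the two phenotype time points.
#' @param followup_years mean interval between phenotype time points.
#' @param pheno_group_sizes optional named vector of exact cessation-category
#'   sizes for the longitudinal phenotype subset, e.g.
#'   `c("S-S" = 12, "S-E" = 5, "E1-E5" = 13, "E5+" = 92, "N-N" = 124)`.
#' @param missing_frac Bernoulli missingness rate applied to methylation
#'   values (0 disables the mask).
#' @param frac_intergenic fraction of probes annotated to an intergenic
#'   cytogenetic band rather than a gene.
#' @param seed integer seed; all generator operations are deterministic
#'   functions of the configuration including this seed.
#'
#' @return An object of class `cohort_config` (a named list).
#' @export
#' @examples
#' cfg <- cohort_config(n_probes = 50, n_genes = 20, n_snps = 100)
#' cfg$n_mz_pairs
cohort_config <- function(n_mz_pairs = 84,
                          n_dz_pairs = 112,
                          n_singletons = 150,
                          n_current = 54,
                          n_ex = 197,
                          n_never = 291,
                          n_probes = 2000,
                          n_genes = 1000,
                          n_snps = 5000,
                          effect_meth = list(n_signal = 100, size = 1.5,
                                             frac_negative = 0.905),
                          effect_expr = list(n_signal = 100, size = 1.5,
                                             frac_negative = 0.667),
                          tau_meth = 15,
                          tau_expr = 1.5,
                          kappa = 0.5,
                          n_coupled_genes = 5,
                          var_family = 0.3,
                          var_mz_extra = 0.2,
                          var_batch = 0.05,
                          var_resid = 0.45,
                          frac_meqtl = 0.1,
                          meqtl_beta = 0.5,
                          cis_window = 1e5,
                          quit_years_mean = 24.8,
                          quit_years_sd = 13.2,
                          n_batches = 4,
                          interaction_beta = 0.2,
                          group_effect = 1,
                          followup_years = 5.1,
                          pheno_group_sizes = c("S-S" = 12, "S-E" = 5,
                                                "E1-E5" = 13, "E5+" = 92,
                                                "N-N" = 124),
                          missing_frac = 0,
                          frac_intergenic = 0.1,
                          seed = 1L) {
  counts <- c(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
              n_singletons = n_singletons, n_current = n_current,
              n_ex = n_ex, n_never = n_never, n_probes = n_probes,
              n_genes = n_genes, n_snps = n_snps)
  bad <- names(counts)[counts < 0 | counts != round(counts)]
  if (length(bad) > 0) {
    stop("counts must be non-negative integers: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_subjects <- 2L * (n_mz_pairs + n_dz_pairs) + n_singletons
  if (n_current + n_ex + n_never != n_subjects) {
    stop(sprintf(paste0("smoking-status counts (n_current=%d, n_ex=%d, ",
                        "n_never=%d) must sum to the subject total %d"),
                 n_current, n_ex, n_never, n_subjects), call. = FALSE)
  }
  vars <- c(var_family = var_family, var_mz_extra = var_mz_extra,
            var_batch = var_batch, var_resid = var_resid)
  if (any(vars < 0)) {
    stop("variance components must be non-negative: ",
         paste(names(vars)[vars < 0], collapse = ", "), call. = FALSE)
  }
  if (tau_expr > tau_meth) {
    stop("tau_expr must not exceed tau_meth ",
         "(expression effects are emulated as shorter-lived)", call. = FALSE)
  }
  if (n_coupled_genes > min(n_genes, n_probes)) {
    stop("n_coupled_genes exceeds the number of genes or probes",
         call. = FALSE)
  }
  cfg <- list(
    n_mz_pairs = as.integer(n_mz_pairs),
    n_dz_pairs = as.integer(n_dz_pairs),
    n_singletons = as.integer(n_singletons),
    n_subjects = as.integer(n_subjects),
    n_current = as.integer(n_current),
    n_ex = as.integer(n_ex),
    n_never = as.integer(n_never),
    n_probes = as.integer(n_probes),
    n_genes = as.integer(n_genes),
    n_snps = as.integer(n_snps),
    effect_meth = effect_meth,
    effect_expr = effect_expr,
    tau_meth = tau_meth,
    tau_expr = tau_expr,
    kappa = kappa,
    n_coupled_genes = as.integer(n_coupled_genes),
    var_family = var_family,
    var_mz_extra = var_mz_extra,
    var_batch = var_batch,
    var_resid = var_resid,
    frac_meqtl = frac_meqtl,
    meqtl_beta = meqtl_beta,
    cis_window = cis_window,
    quit_years_mean = quit_years_mean,
    quit_years_sd = quit_years_sd,
    n_batches = as.integer(n_batches),
    interaction_beta = interaction_beta,
    group_effect = group_effect,
    followup_years = followup_years,
    pheno_group_sizes = pheno_group_sizes,
    missing_frac = missing_frac,
    frac_intergenic = frac_intergenic,
    seed = as.integer(seed)
  )
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects: %d MZ pairs, %d DZ pairs, %d singletons\n",
              x$n_subjects, x$n_mz_pairs, x$n_dz_pairs, x$n_singletons))
  cat(sprintf("  smoking: %d current / %d ex / %d never\n",
              x$n_current, x$n_ex, x$n_never))
  cat(sprintf("  %d probes, %d genes, %d SNPs; tau_meth=%.1f, tau_expr=%.1f\n",
              x$n_probes, x$n_genes, x$n_snps, x$tau_meth, x$tau_expr))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# total latent standard deviation implied by the variance components;
# effect sizes are expressed in these units
latent_sd <- function(config) {
  sqrt(config$var_family + config$var_mz_extra + config$var_batch +
         config$var_resid)
}
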