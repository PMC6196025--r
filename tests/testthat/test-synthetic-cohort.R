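test_that("cohort configuration validates its counts and components", {
  expect_error(cohort_config(n_current = 10, n_ex = 10, n_never = 10),
               "must sum to the subject total")
  expect_error(cohort_config(n_mz_pairs = -1), "non-negative")
  expect_error(cohort_config(var_family = -0.1), "variance components")
  expect_error(cohort_config(tau_meth = 1, tau_expr = 2),
               "tau_expr must not exceed")
})

test_that("default cohort reproduces the study composition", {
  cohort <- generate_cohort(cohort_config(n_probes = 10, n_genes = 5,
                                          n_snps = 10))
  s <- cohort$subjects
  expect_equal(nrow(s), 542)
  fam_sizes <- table(table(s$family_id))
  expect_equal(unname(fam_sizes[["2"]]), 84 + 112)
  expect_equal(unname(fam_sizes[["1"]]), 150)
  expect_equal(as.vector(table(s$smoking_status)[c("current", "ex",
                                                   "never")]),
               c(54L, 197L, 291L))
  expect_equal(sum(s$zygosity == "MZ"), 168)
})

test_that("quit years exist only for ex-smokers and respect the 3-month floor", {
  s <- generate_cohort(cohort_config(n_probes = 10, n_genes = 5,
                                     n_snps = 10))$subjects
  expect_true(all(is.na(s$quit_years[s$smoking_status != "ex"])))
  expect_true(all(s$quit_years[s$smoking_status == "ex"] >= 0.25))
  # gamma moments roughly match the configured cohort history
  expect_equal(mean(s$quit_years[s$smoking_status == "ex"]), 24.8,
               tolerance = 0.15)
})

test_that("degenerate all-singleton cohort yields one family per subject", {
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 10,
                       n_current = 3, n_ex = 3, n_never = 4,
                       n_probes = 5, n_genes = 3, n_snps = 5,
                       n_coupled_genes = 1)
  s <- generate_cohort(cfg)$subjects
  expect_equal(nrow(s), 10)
  expect_equal(length(unique(s$family_id)), 10)
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_config(seed = 11)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$subjects, sim2$subjects)
  expect_identical(sim1$methylation$values, sim2$methylation$values)
  expect_identical(sim1$expression$values, sim2$expression$values)
  expect_identical(sim1$genotypes$dosages, sim2$genotypes$dosages)
  expect_identical(sim1$phenotypes, sim2$phenotypes)
})

test_that("beta values are strictly inside (0,1) for several seeds", {
  for (s in 1:3) {
    sim <- simulate_cohort(tiny_config(seed = s))
    expect_true(all(sim$methylation$values > 0 &
                      sim$methylation$values < 1))
    expect_true(all(sim$expression$values >= 0))
  }
})

test_that("every probe and gene has exactly one truth row", {
  sim <- simulate_cohort(tiny_config())
  expect_equal(sort(rownames(sim$methylation$values)),
               sort(sim$truth$probes$probe_id))
  expect_equal(anyDuplicated(sim$truth$probes$probe_id), 0L)
  expect_equal(sort(rownames(sim$expression$values)),
               sort(sim$truth$genes$gene_id))
})

test_that("ex-smoker latent shift follows the exponential decay law", {
  # Monte-Carlo oracle: with tau = 5 and quit_years = 5 the expected
  # latent shift is effect * s_tot * exp(-1)
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 300,
                       n_current = 100, n_ex = 100, n_never = 100,
                       n_probes = 400, n_genes = 5, n_snps = 10,
                       effect_meth = list(n_signal = 400, size = 1,
                                          frac_negative = 0),
                       tau_meth = 5, tau_expr = 1, n_coupled_genes = 0,
                       frac_meqtl = 0, seed = 3)
  cohort <- generate_cohort(cfg)
  sub <- cohort$subjects
  sub$quit_years[sub$smoking_status == "ex"] <- 5
  meth <- generate_methylation(sub, cohort$truth, cfg)
  lat <- attr(meth, "latent")
  ex_shift <- rowMeans(lat[, sub$smoking_status == "ex"]) -
    rowMeans(lat[, sub$smoking_status == "never"])
  s_tot <- sqrt(cfg$var_family + cfg$var_mz_extra + cfg$var_batch +
                  cfg$var_resid)
  expect_equal(mean(ex_shift), s_tot * exp(-1), tolerance = 0.03)

  # no-decay limit: tau -> Inf makes the ex shift equal the current shift
  cfg2 <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0,
                        n_singletons = 300, n_current = 100, n_ex = 100,
                        n_never = 100, n_probes = 400, n_genes = 5,
                        n_snps = 10,
                        effect_meth = list(n_signal = 400, size = 1,
                                           frac_negative = 0),
                        tau_meth = 1e9, tau_expr = 1, n_coupled_genes = 0,
                        frac_meqtl = 0, seed = 3)
  cohort2 <- generate_cohort(cfg2)   # truth carries the per-probe tau
  meth2 <- generate_methylation(sub, cohort2$truth, cfg2)
  lat2 <- attr(meth2, "latent")
  cur_shift <- rowMeans(lat2[, sub$smoking_status == "current"]) -
    rowMeans(lat2[, sub$smoking_status == "never"])
  ex_shift2 <- rowMeans(lat2[, sub$smoking_status == "ex"]) -
    rowMeans(lat2[, sub$smoking_status == "never"])
  expect_equal(mean(ex_shift2), mean(cur_shift), tolerance = 0.05)
})

test_that("MZ twins share genotypes; DZ twins share half on average", {
  cfg <- cohort_config(n_mz_pairs = 40, n_dz_pairs = 60, n_singletons = 0,
                       n_current = 20, n_ex = 60, n_never = 120,
                       n_probes = 50, n_genes = 25, n_snps = 1000,
                       n_coupled_genes = 2, seed = 5)
  cohort <- generate_cohort(cfg)
  g <- generate_genotypes(cohort$subjects, cohort$truth, cfg)
  s <- cohort$subjects
  mz_fams <- unique(s$family_id[s$zygosity == "MZ"])
  for (f in mz_fams[1:5]) {
    ids <- s$subject_id[s$family_id == f]
    expect_identical(g$dosages[, ids[1]], g$dosages[, ids[2]],
                     ignore_attr = TRUE)
  }
  # per-SNP standardized dosages: DZ within-pair correlation ~ 0.5
  dz_fams <- unique(s$family_id[s$zygosity == "DZ"])
  t1 <- s$subject_id[match(dz_fams, s$family_id)]
  t2 <- vapply(dz_fams, function(f) {
    rev(s$subject_id[s$family_id == f])[1]
  }, character(1))
  d1 <- g$dosages[, t1]; d2 <- g$dosages[, t2]
  mu <- rowMeans(cbind(d1, d2)); sdv <- apply(cbind(d1, d2), 1, sd)
  keep <- sdv > 0
  z1 <- (d1[keep, ] - mu[keep]) / sdv[keep]
  z2 <- (d2[keep, ] - mu[keep]) / sdv[keep]
  expect_equal(cor(as.vector(z1), as.vector(z2)), 0.5, tolerance = 0.05)
})

test_that("singleton-cohort genotypes satisfy Hardy-Weinberg calibration", {
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 400,
                       n_current = 100, n_ex = 100, n_never = 200,
                       n_probes = 50, n_genes = 25, n_snps = 600,
                       n_coupled_genes = 2, seed = 9)
  cohort <- generate_cohort(cfg)
  g <- generate_genotypes(cohort$subjects, cohort$truth, cfg)
  hwe_p <- apply(g$dosages, 1, function(d) {
    n <- length(d)
    p_hat <- mean(d) / 2
    if (p_hat == 0 || p_hat == 1) return(NA_real_)
    obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
    expc <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    suppressWarnings(stats::chisq.test(rbind(obs))$p.value)
    x2 <- sum((obs - expc)^2 / expc)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  })
  # calibrated: ~5% of SNPs nominally out of HWE
  expect_lt(mean(hwe_p < 0.05, na.rm = TRUE), 0.10)
})

test_that("MZ within-pair latent correlation exceeds DZ when MZ share extra variance", {
  cfg <- cohort_config(n_mz_pairs = 60, n_dz_pairs = 60, n_singletons = 0,
                       n_current = 24, n_ex = 72, n_never = 144,
                       n_probes = 200, n_genes = 10, n_snps = 20,
                       effect_meth = list(n_signal = 0, size = 0,
                                          frac_negative = 1),
                       effect_expr = list(n_signal = 0, size = 0,
                                          frac_negative = 1),
                       n_coupled_genes = 0, frac_meqtl = 0, seed = 6)
  cohort <- generate_cohort(cfg)
  meth <- generate_methylation(cohort$subjects, cohort$truth, cfg)
  lat <- attr(meth, "latent")
  s <- cohort$subjects
  pair_cor <- function(zyg) {
    fams <- unique(s$family_id[s$zygosity == zyg])
    i1 <- match(fams, s$family_id)
    i2 <- vapply(fams, function(f) rev(which(s$family_id == f))[1],
                 integer(1))
    cor(as.vector(lat[, i1]), as.vector(lat[, i2]))
  }
  expect_gt(pair_cor("MZ"), pair_cor("DZ"))
})

test_that("probe-gene coupling induces negative correlation; uncoupled pairs stay null", {
  cfg <- cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 400,
                       n_current = 100, n_ex = 100, n_never = 200,
                       n_probes = 40, n_genes = 20, n_snps = 40,
                       effect_meth = list(n_signal = 4, size = 1.5,
                                          frac_negative = 1),
                       effect_expr = list(n_signal = 4, size = 1.5,
                                          frac_negative = 0),
                       n_coupled_genes = 4, frac_meqtl = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  for (k in seq_len(nrow(sim$truth$coupling))) {
    rho <- cor(sim$methylation$values[sim$truth$coupling$probe_id[k], ],
               sim$expression$values[sim$truth$coupling$gene_id[k], ],
               method = "spearman")
    expect_lt(rho, 0)
  }
  # an arbitrary uncoupled pair stays within the null band
  un_probe <- setdiff(sim$truth$probes$probe_id,
                      sim$truth$coupling$probe_id)[1]
  un_gene <- setdiff(sim$truth$genes$gene_id,
                     sim$truth$coupling$gene_id)[1]
  rho0 <- cor(sim$methylation$values[un_probe, ],
              sim$expression$values[un_gene, ], method = "spearman")
  expect_lt(abs(rho0), 3 / sqrt(ncol(sim$methylation$values)))
})

test_that("longitudinal phenotypes carry the cessation-group gain", {
  cfg <- cohort_config(quit_years_mean = 6, quit_years_sd = 5,
                       n_probes = 40, n_genes = 20, n_snps = 40,
                       n_coupled_genes = 2, group_effect = 1,
                       interaction_beta = 0, seed = 10)
  sim <- simulate_cohort(cfg)
  ph <- sim$phenotypes
  d_vfm <- ph$vfm_t2 - ph$vfm_t1
  gain_group <- ph$category_truth %in% c("S-E", "E1-E5")
  expect_gt(mean(d_vfm[gain_group]), mean(d_vfm[ph$category_truth == "N-N"]))
  # requested composition is honoured when the pools allow it
  counts <- table(ph$category_truth)
  expect_equal(unname(counts[["N-N"]]), 124)
  expect_equal(unname(counts[["S-S"]]), 12)
  expect_equal(unname(counts[["S-E"]]), 5)
})
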