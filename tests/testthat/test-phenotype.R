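test_that("cessation categories follow their definitions", {
  expect_equal(assign_cessation_category("current", "current", NA), "S-S")
  expect_equal(assign_cessation_category("current", "ex", NA), "S-E")
  expect_equal(assign_cessation_category("ex", "ex", 3), "E1-E5")
  expect_equal(assign_cessation_category("ex", "ex", 1), "E1-E5")
  expect_equal(assign_cessation_category("ex", "ex", 5), "E1-E5")
  expect_equal(assign_cessation_category("ex", "ex", 8), "E5+")
  expect_equal(assign_cessation_category("never", "never", NA), "N-N")
  # sub-1-year ex-smokers and relapse paths stay unclassified
  expect_equal(assign_cessation_category("ex", "ex", 0.5), "unclassified")
  expect_equal(assign_cessation_category("never", "current", NA),
               "unclassified")
  expect_equal(assign_cessation_category("ex", "current", 3),
               "unclassified")
})

test_that("printed composition partitions into the 18 / 228 contrast", {
  counts <- c("S-S" = 12, "S-E" = 5, "E1-E5" = 13, "E5+" = 92,
              "N-N" = 124)
  status_t1 <- c(rep("current", 12 + 5), rep("ex", 13 + 92),
                 rep("never", 124))
  status_t2 <- c(rep("current", 12), rep("ex", 5 + 13 + 92),
                 rep("never", 124))
  qy <- c(rep(NA, 17), rep(3, 13), rep(10, 92), rep(NA, 124))
  cat <- assign_cessation_category(status_t1, status_t2, qy)
  expect_equal(as.vector(table(cat)[names(counts)]), unname(counts))
  exposure <- sum(cat %in% c("S-E", "E1-E5"))
  reference <- sum(cat %in% c("E5+", "S-S", "N-N"))
  expect_equal(exposure, 18)
  expect_equal(reference, 228)
})

test_that("marker main effect is recovered and calibrated", {
  set.seed(31)
  n <- 288
  d <- tibble::tibble(
    age = rnorm(n, 58, 9), bmi = rnorm(n, 27, 5),
    smoking_status = sample(c("current", "never"), n, replace = TRUE,
                            prob = c(0.15, 0.85)),
    marker = rnorm(n))
  d$vfm <- 2 * d$marker + 0.05 * d$bmi + rnorm(n)
  res <- associate_phenotype(d, "vfm", "marker")
  expect_equal(res$beta, 2, tolerance = 3 * res$se)
  expect_lt(res$p_main, 1e-10)

  # null marker: p roughly uniform over replicates
  ps <- replicate(200, {
    d$null_marker <- rnorm(n)
    associate_phenotype(d, "vfm", "null_marker",
                        test_interaction = FALSE)$p_main
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("interaction-only effects show up in the interaction term", {
  set.seed(32)
  n <- 300
  d <- tibble::tibble(
    age = rnorm(n, 58, 9), bmi = rnorm(n, 27, 5),
    smoking_status = rep(c("current", "never"), each = n / 2),
    marker = rnorm(n))
  d$vfm <- ifelse(d$smoking_status == "current", 1.5 * d$marker, 0) +
    rnorm(n)
  res <- associate_phenotype(d, "vfm", "marker")
  expect_lt(res$p_interaction, res$p_main)
})

test_that("rank-deficient phenotype designs are reported", {
  d <- tibble::tibble(age = rnorm(30), bmi = rnorm(30),
                      smoking_status = "current", marker = rnorm(30),
                      vfm = rnorm(30))
  d$dup <- d$age
  expect_error(associate_phenotype(d, "vfm", "marker",
                                   covariates = c("age", "dup")),
               "rank-deficient")
})

test_that("future-change interaction detects the group-specific slope", {
  set.seed(33)
  n <- 246
  grp <- c(rep("exposure-change", 18), rep("reference", n - 18))
  marker <- rnorm(n)
  delta <- ifelse(grp == "exposure-change", 2 * marker, 0) + rnorm(n, 0, 1)
  d <- tibble::tibble(marker = marker, delta = delta, group = grp)
  res <- predict_future_change(d, "marker", "delta", "group")
  expect_lt(res$interaction_p, 0.01)
  expect_gt(res$var_explained_pct, 30)
  expect_false(res$low_n)
  expect_equal(res$n_exposure, 18)
  expect_equal(res$n_reference, 228)
})

test_that("identical marker-change relations give a null interaction", {
  set.seed(34)
  n <- 400
  grp <- rep(c("exposure-change", "reference"), each = n / 2)
  marker <- rnorm(n)
  delta <- 1.2 * marker + rnorm(n, 0, 0.5)
  d <- tibble::tibble(marker = marker, delta = delta, group = grp)
  res <- predict_future_change(d, "marker", "delta", "group")
  fit <- lm(delta ~ marker * I(grp == "exposure-change"))
  expect_equal(unname(coef(fit)[4]), 0, tolerance = 0.15)
  expect_gt(res$interaction_p, 0.01)
})

test_that("variance explained is invariant to affine marker rescaling", {
  set.seed(35)
  n <- 100
  grp <- rep(c("exposure-change", "reference"), each = n / 2)
  marker <- rnorm(n)
  delta <- marker + rnorm(n)
  d1 <- tibble::tibble(marker = marker, delta = delta, group = grp)
  d2 <- tibble::tibble(marker = 100 * marker - 42, delta = delta,
                       group = grp)
  r1 <- predict_future_change(d1, "marker", "delta", "group")
  r2 <- predict_future_change(d2, "marker", "delta", "group")
  expect_equal(r1$var_explained_pct, r2$var_explained_pct,
               tolerance = 1e-10)
})

test_that("the generator's designated site carries the panel's interaction signal", {
  cfg <- cohort_config(n_probes = 60, n_genes = 30, n_snps = 60,
                       quit_years_mean = 6, quit_years_sd = 5,
                       interaction_beta = 1, n_coupled_genes = 2,
                       seed = 36)
  sim <- simulate_cohort(cfg)
  resid <- residualize_matrix(sim$methylation, sim$subjects)
  panel <- unique(c(sim$truth$interaction$probe_id,
                    rownames(resid)[1:6]))
  scan <- scan_future_change(resid[panel, , drop = FALSE],
                             sim$phenotypes)
  best <- scan$marker[which.min(scan$interaction_p)]
  expect_equal(best, sim$truth$interaction$probe_id)
})
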