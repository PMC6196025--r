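make_assoc <- function(site_id, region_label, coef, significant) {
  tibble::tibble(site_id = site_id, region_label = region_label,
                 coef = coef, significant = significant)
}

test_that("overlap logic: intersection, concordance and multi-gene labels", {
  dms <- make_assoc(c("cg1", "cg2", "cg3"),
                    c("GENEA", "GENEB", "LYST;MIR1537"),
                    c(-1, 0.5, -0.7), c(TRUE, TRUE, TRUE))
  des <- make_assoc(c("E1", "E2", "E3"),
                    c("GENEA", "GENEB", "MIR1537"),
                    c(1.2, 0.9, 0.4), c(TRUE, TRUE, TRUE))
  ov <- overlap_dms_des(dms, des)
  expect_setequal(ov$gene, c("GENEA", "GENEB", "MIR1537"))
  # GENEA: hypo-methylated + up-regulated -> concordant
  expect_true(ov$concordant[ov$gene == "GENEA"])
  # GENEB: hyper-methylated + up-regulated -> discordant
  expect_false(ov$concordant[ov$gene == "GENEB"])
  # the multi-gene label matched through its second member
  expect_true("MIR1537" %in% ov$gene)
})

test_that("disjoint significant sets give an empty overlap", {
  dms <- make_assoc("cg1", "GENEA", -1, TRUE)
  des <- make_assoc("E9", "GENEZ", 1, TRUE)
  ov <- overlap_dms_des(dms, des)
  expect_equal(nrow(ov), 0)
})

test_that("intergenic band labels never create gene overlap", {
  dms <- make_assoc(c("cg1", "cg2"), c("2q37.1", "GENEA"), c(-1, -1),
                    c(TRUE, TRUE))
  des <- make_assoc(c("E1", "E2"), c("2q37.1", "GENEA"), c(1, 1),
                    c(TRUE, TRUE))
  ov <- overlap_dms_des(dms, des)
  expect_equal(ov$gene, "GENEA")
})

test_that("overlap recovers the coupled genes from the truth table", {
  cfg <- cohort_config(n_probes = 200, n_genes = 100, n_snps = 200,
                       effect_meth = list(n_signal = 12, size = 1.5,
                                          frac_negative = 1),
                       effect_expr = list(n_signal = 12, size = 1.5,
                                          frac_negative = 0.5),
                       n_coupled_genes = 4, frac_meqtl = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  dms <- run_association(sim$methylation, sim$subjects)
  des <- run_association(sim$expression, sim$subjects)
  ov <- overlap_dms_des(dms, des)
  expect_true(all(sim$truth$coupling$gene_id %in% ov$gene))
  cpl <- ov[ov$gene %in% sim$truth$coupling$gene_id, ]
  expect_true(all(cpl$concordant))   # hypo-methylated, up-regulated
})

test_that("perfect monotone pairing gives rho = -1 and +1", {
  m <- matrix(1:10, 1, dimnames = list("cgA", sprintf("S%02d", 1:10)))
  e_neg <- matrix(10:1, 1, dimnames = list("G1", sprintf("S%02d", 1:10)))
  pairs <- tibble::tibble(probe_id = "cgA", gene_id = "G1")
  res <- meth_expr_correlation(m, e_neg, pairs)
  expect_equal(res$rho[res$group == "all"], -1)
  e_pos <- matrix(exp(1:10), 1,
                  dimnames = list("G1", sprintf("S%02d", 1:10)))
  res2 <- meth_expr_correlation(m, e_pos, pairs)
  expect_equal(res2$rho[res2$group == "all"], 1)
})

test_that("small-sample Spearman p matches full permutation enumeration at n=6", {
  x <- c(3, 1, 4, 5, 2, 6)
  y <- c(2, 6, 1, 4, 5, 3)
  # oracle: enumerate all 720 orderings of y
  perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  rho_obs <- cor(x, y, method = "spearman")
  rhos <- vapply(perm(1:6), function(p) cor(x, y[p], method = "spearman"),
                 numeric(1))
  p_enum <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)

  m <- matrix(x, 1, dimnames = list("cgA", sprintf("S%d", 1:6)))
  e <- matrix(y, 1, dimnames = list("G1", sprintf("S%d", 1:6)))
  res <- meth_expr_correlation(m, e,
                               tibble::tibble(probe_id = "cgA",
                                              gene_id = "G1"))
  expect_equal(res$p[res$group == "all"], p_enum, tolerance = 1e-10)
})

test_that("rho is invariant to monotone transforms and group ranks are local", {
  set.seed(18)
  n <- 40
  x <- rnorm(n); y <- rnorm(n)
  ids <- sprintf("S%02d", 1:n)
  m <- matrix(x, 1, dimnames = list("cgA", ids))
  e1 <- matrix(y, 1, dimnames = list("G1", ids))
  e2 <- matrix(exp(3 * y), 1, dimnames = list("G1", ids))
  p <- tibble::tibble(probe_id = "cgA", gene_id = "G1")
  r1 <- meth_expr_correlation(m, e1, p)
  r2 <- meth_expr_correlation(m, e2, p)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_true(all(abs(r1$rho) <= 1))

  # group-restricted ranks: within-group rho differs from the global one
  grp <- list(g1 = ids[1:20], g2 = ids[21:40])
  rg <- meth_expr_correlation(m, e1, p, groups = grp)
  rho_local <- rg$rho[rg$group == "g1"]
  expect_equal(rho_local, cor(x[1:20], y[1:20], method = "spearman"),
               tolerance = 1e-12)
})

test_that("tiny groups are flagged unreliable and absent sites error", {
  ids <- sprintf("S%d", 1:10)
  m <- matrix(rnorm(10), 1, dimnames = list("cgA", ids))
  e <- matrix(rnorm(10), 1, dimnames = list("G1", ids))
  p <- tibble::tibble(probe_id = "cgA", gene_id = "G1")
  res <- meth_expr_correlation(m, e, p, groups = list(small = ids[1:4]))
  expect_false(res$p_reliable[res$group == "small"])
  expect_error(
    meth_expr_correlation(m, e, tibble::tibble(probe_id = "nope",
                                               gene_id = "G1")),
    "absent sites")
})
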