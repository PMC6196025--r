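# small cohort configurations shared across test files

tiny_config <- function(seed = 1, ...) {
  cohort_config(n_mz_pairs = 10, n_dz_pairs = 12, n_singletons = 20,
                n_current = 10, n_ex = 20, n_never = 34,
                n_probes = 40, n_genes = 20, n_snps = 80,
                effect_meth = list(n_signal = 6, size = 1.5,
                                   frac_negative = 0.9),
                effect_expr = list(n_signal = 6, size = 1.5,
                                   frac_negative = 0.6),
                n_coupled_genes = 2, seed = seed, ...)
}

# all-singleton cohort: no identifiable random structure, so the mixed
# engine reduces to OLS (used for oracle-equivalence tests)
singleton_config <- function(n = 40, seed = 1, ...) {
  cohort_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = n,
                n_current = ceiling(n * 0.3), n_ex = 0,
                n_never = n - ceiling(n * 0.3),
                n_probes = 10, n_genes = 5, n_snps = 20,
                effect_meth = list(n_signal = 0, size = 0,
                                   frac_negative = 1),
                effect_expr = list(n_signal = 0, size = 0,
                                   frac_negative = 1),
                n_coupled_genes = 0, frac_meqtl = 0, seed = seed, ...)
}

# hand-rolled omics matrix for preprocessing tests
toy_matrix <- function(n_sites = 10, n_subj = 50, chrom = NULL,
                       mask = NULL, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_sites * n_subj, 0.05, 0.95), n_sites, n_subj,
              dimnames = list(sprintf("cg%04d", seq_len(n_sites)),
                              sprintf("S%03d", seq_len(n_subj))))
  if (is.null(chrom)) chrom <- rep(1L, n_sites)
  ann <- tibble::tibble(probe_id = rownames(m), chrom = chrom,
                        pos = seq_len(n_sites) * 1000L,
                        region_label = sprintf("G%03d", seq_len(n_sites)),
                        region_class = "gene")
  omics_matrix(m, ann, "methylation", mask)
}
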