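#' Generate a synthetic twin cohort
#'
#' Draws a subject table (twin structure, covariates, smoking history) and
#' the ground-truth table used by all generators and by recovery tests.
#' Smoking statuses are assigned by exact-count permutation, independently
#' of family latent effects. Years since cessation for ex-smokers follow a
#' gamma distribution with mean `quit_years_mean` and SD `quit_years_sd`,
#' truncated at 0.25 years (ex-smokers quit for at least 3 months).
#'
#' @param config a [cohort_config()].
#' @return A list with elements `subjects` (tibble: one row per subject)
#'   and `truth` (a `truth_table`: `probes`, `genes`, `coupling` and
#'   `interaction` components recording every injected effect).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_probes = 20, n_genes = 10,
#'                                         n_snps = 40))
#' nrow(cohort$subjects)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed_stream(config$seed, 0L))

  n <- config$n_subjects
  n_pairs <- config$n_mz_pairs + config$n_dz_pairs

  family_id <- sprintf("F%04d", c(rep(seq_len(n_pairs), each = 2),
                                  n_pairs + seq_len(config$n_singletons)))
  zygosity <- c(rep("MZ", 2L * config$n_mz_pairs),
                rep("DZ", 2L * config$n_dz_pairs),
                rep("singleton", config$n_singletons))
  subject_id <- sprintf("S%04d", seq_len(n))

  status <- sample(c(rep("current", config$n_current),
                     rep("ex", config$n_ex),
                     rep("never", config$n_never)))

  # cohort moments loosely follow a middle-aged female twin registry;
  # current smokers run a few years younger than never smokers
  age <- stats::rnorm(n, mean = 59, sd = 9.5) - 5 * (status == "current")
  age <- pmin(pmax(age, 30), 85)
  bmi <- pmin(pmax(stats::rnorm(n, mean = 26.9, sd = 4.8), 16), 50)
  alcohol_mean <- c(current = 11.7, ex = 10.0, never = 6.0)[status]
  alcohol <- stats::rgamma(n, shape = 2, rate = 2 / alcohol_mean)
  batch <- sample(sprintf("plate%02d", seq_len(config$n_batches)), n,
                  replace = TRUE)

  quit_years <- rep(NA_real_, n)
  ex_idx <- which(status == "ex")
  if (length(ex_idx) > 0) {
    shape <- (config$quit_years_mean / config$quit_years_sd)^2
    rate <- shape / config$quit_years_mean
    qy <- stats::rgamma(length(ex_idx), shape = shape, rate = rate)
    quit_years[ex_idx] <- pmax(qy, 0.25)
  }
  smoke_years <- rep(NA_real_, n)
  smoker_idx <- which(status != "never")
  smoke_years[smoker_idx] <- pmax(stats::rnorm(length(smoker_idx), 20, 8), 1)

  subjects <- tibble::tibble(
    subject_id = subject_id,
    family_id = family_id,
    zygosity = zygosity,
    age = age,
    bmi = bmi,
    alcohol = alcohol,
    batch = batch,
    smoking_status = status,
    quit_years = quit_years,
    smoke_years = smoke_years
  )

  truth <- build_truth_table(config)
  list(subjects = subjects, truth = truth)
}

# sample k elements from x without the length-1 surprise of sample()
sample_exact <- function(x, k) {
  if (k <= 0 || length(x) == 0) return(x[0])
  x[sample.int(length(x), k)]
}

# deterministic substream: one RNG seed per generator stage so toggling a
# stage never perturbs another stage's draws
seed_stream <- function(seed, stage) {
  (abs(as.integer(seed)) %% 1000000000L) * 2L + 1L + 97L * as.integer(stage)
}

# Ground truth: probe/gene annotation, injected effects, decay constants,
# meQTL pairs, probe-gene coupling and the phenotype-interaction sites.
build_truth_table <- function(config) {
  set.seed(seed_stream(config$seed, 9L))
  n_probes <- config$n_probes
  n_genes <- config$n_genes

  gene_id <- sprintf("G%05d", seq_len(n_genes))
  gene_chrom <- ((seq_len(n_genes) - 1L) %% 22L) + 1L
  gene_pos <- 1e6 + 2e6 * ((seq_len(n_genes) - 1L) %/% 22L)

  # probes map round-robin onto genes; a fraction is re-annotated to an
  # intergenic cytogenetic band (positions kept near the displaced gene)
  probe_gene <- ((seq_len(n_probes) - 1L) %% n_genes) + 1L
  probe_id <- sprintf("cg%08d", seq_len(n_probes))
  probe_chrom <- gene_chrom[probe_gene]
  probe_pos <- gene_pos[probe_gene] +
    1000L * ((seq_len(n_probes) - 1L) %/% n_genes) +
    sample(0:500, n_probes, replace = TRUE)
  region_label <- gene_id[probe_gene]
  n_intergenic <- floor(config$frac_intergenic * n_probes)
  if (n_intergenic > 0) {
    ig_idx <- sample.int(n_probes, n_intergenic)
    region_label[ig_idx] <- sprintf("%dq%d.%d", probe_chrom[ig_idx],
                                    30 + (ig_idx %% 9), 1 + (ig_idx %% 3))
  }
  region_class <- ifelse(grepl("^[0-9]+q", region_label), "intergenic",
                         "gene")

  # coupled genes: designated genes whose expression latent subtracts
  # kappa * (paired probe latent); both members carry strong effects so the
  # gene-level DMS/DES overlap is recoverable
  n_cpl <- config$n_coupled_genes
  eligible <- unique(probe_gene[region_class == "gene"])
  if (n_cpl > length(eligible)) {
    stop("not enough genes with a gene-annotated probe for the requested ",
         "number of coupled genes", call. = FALSE)
  }
  coupled_gene_idx <- if (n_cpl > 0) sample_exact(eligible, n_cpl)
                      else integer()
  coupled_probe_idx <- vapply(coupled_gene_idx, function(g) {
    which(probe_gene == g & region_class == "gene")[1]
  }, integer(1))

  # signal sets: coupled members always included; remaining slots filled so
  # that no uncoupled gene is hit on both layers (keeps the truth overlap
  # exactly the coupled set)
  eff_m <- config$effect_meth
  eff_e <- config$effect_expr
  n_sig_g <- min(eff_e$n_signal, n_genes)
  free_genes <- setdiff(seq_len(n_genes), coupled_gene_idx)
  sig_genes <- c(coupled_gene_idx,
                 sample_exact(free_genes, max(0, n_sig_g - n_cpl)))
  n_sig_p <- min(eff_m$n_signal, n_probes)
  probe_ok <- !(probe_gene %in% setdiff(sig_genes, coupled_gene_idx))
  free_probes <- setdiff(which(probe_ok), coupled_probe_idx)
  need_p <- max(0, n_sig_p - n_cpl)
  if (length(free_probes) < need_p) {
    # small panels: allow signal probes on signal genes rather than
    # dropping injected effects
    free_probes <- setdiff(seq_len(n_probes), coupled_probe_idx)
  }
  sig_probes <- c(coupled_probe_idx,
                  sample_exact(free_probes,
                               min(length(free_probes), need_p)))

  probe_effect <- rep(0, n_probes)
  if (length(sig_probes) > 0) {
    sgn <- ifelse(stats::runif(length(sig_probes)) < eff_m$frac_negative,
                  -1, 1)
    # coupled probes are hypomethylated in current smokers (the canonical
    # direction for smoking signals with expression consequences)
    sgn[seq_along(coupled_probe_idx)] <- -1
    probe_effect[sig_probes] <- sgn * eff_m$size
  }
  gene_effect <- rep(0, n_genes)
  if (length(sig_genes) > 0) {
    sgn <- ifelse(stats::runif(length(sig_genes)) < eff_e$frac_negative,
                  -1, 1)
    sgn[seq_along(coupled_gene_idx)] <- 1  # coupled genes up-regulated
    gene_effect[sig_genes] <- sgn * eff_e$size
  }

  # cis-meQTL assignment: each flagged probe is driven by the SNP anchored
  # at its own position (see generate_genotypes for the SNP layout)
  n_meqtl <- floor(config$frac_meqtl * n_probes)
  meqtl_probe_idx <- if (n_meqtl > 0) sample.int(n_probes, n_meqtl)
                     else integer()
  meqtl_snp <- rep(NA_character_, n_probes)
  meqtl_beta <- rep(0, n_probes)
  if (n_meqtl > 0 && config$n_snps >= 1) {
    anchor <- ((meqtl_probe_idx - 1L) %% config$n_snps) + 1L
    meqtl_snp[meqtl_probe_idx] <- sprintf("rs%06d", anchor)
    meqtl_beta[meqtl_probe_idx] <- config$meqtl_beta
  }

  # one designated interaction probe and gene (strong-effect members)
  int_probe <- if (length(sig_probes) > 0) sig_probes[1] else 1L
  int_gene <- if (length(sig_genes) > 0) sig_genes[1] else 1L

  probes <- tibble::tibble(
    probe_id = probe_id,
    chrom = probe_chrom,
    pos = as.integer(probe_pos),
    region_label = region_label,
    region_class = region_class,
    gene_id = gene_id[probe_gene],
    true_effect = probe_effect,
    tau = config$tau_meth,
    meqtl_snp_id = meqtl_snp,
    meqtl_beta = meqtl_beta,
    is_interaction_site = seq_len(n_probes) == int_probe
  )
  genes <- tibble::tibble(
    gene_id = gene_id,
    gene_name = gene_id,
    chrom = gene_chrom,
    pos = as.integer(gene_pos),
    true_effect = gene_effect,
    tau = config$tau_expr,
    is_interaction_gene = seq_len(n_genes) == int_gene
  )
  coupling <- tibble::tibble(
    gene_id = gene_id[coupled_gene_idx],
    probe_id = probe_id[coupled_probe_idx],
    kappa = config$kappa
  )
  structure(list(probes = probes, genes = genes, coupling = coupling,
                 interaction = tibble::tibble(
                   probe_id = probe_id[int_probe],
                   gene_id = gene_id[int_gene],
                   interaction_beta = config$interaction_beta)),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table>\n")
  cat(sprintf("  %d probes (%d with smoking effect, %d with cis-meQTL)\n",
              nrow(x$probes), sum(x$probes$true_effect != 0),
              sum(x$probes$meqtl_beta != 0)))
  cat(sprintf("  %d genes (%d with smoking effect), %d coupled pairs\n",
              nrow(x$genes), sum(x$genes$true_effect != 0),
              nrow(x$coupling)))
  invisible(x)
}

# multiplicative smoking term on the latent scale: full effect in current
# smokers, exponentially decayed by quit years in ex-smokers, zero in
# never smokers
smoking_decay <- function(status, quit_years, tau) {
  out <- numeric(length(status))
  out[status == "current"] <- 1
  ex <- status == "ex"
  out[ex] <- exp(-quit_years[ex] / tau)
  out
}
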