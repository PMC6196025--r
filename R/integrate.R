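#' Gene-level overlap of methylation and expression signals
#'
#' Intersects the significant differentially methylated sites (mapped to
#' genes through their region label) with the significant differentially
#' expressed genes, and flags direction concordance: a gene is concordant
#' when its CpGs are hypo-methylated and the gene up-regulated in current
#' smokers, or vice versa. Multi-gene labels (e.g. `"LYST;MIR1537"`)
#' match on any member.
#'
#' @param dms association table for methylation (needs `site_id`,
#'   `region_label`, `coef`, `significant`).
#' @param des association table for expression (needs `site_id` holding
#'   the gene id, `region_label`/gene name, `coef`, `significant`).
#' @param probe_gene_map optional tibble (`probe_id`, `gene_id`)
#'   overriding the region-label mapping.
#' @return An `overlap_result` tibble: one row per overlapping gene with
#'   `gene`, `probes` (list column of member CpGs), `n_probes`,
#'   `meth_direction`, `expr_direction`, `concordant`. The attribute
#'   `n_unmapped` counts significant probes without a gene mapping.
#' @export
overlap_dms_des <- function(dms, des, probe_gene_map = NULL) {
  sig_dms <- dms[dms$significant & !is.na(dms$significant), , drop = FALSE]
  sig_des <- des[des$significant & !is.na(des$significant), , drop = FALSE]

  if (is.null(probe_gene_map)) {
    probe_gene_map <- tidyr::separate_rows(
      tibble::tibble(probe_id = sig_dms$site_id,
                     gene_id = sig_dms$region_label),
      "gene_id", sep = ";")
    # cytogenetic band labels are not genes
    probe_gene_map <- probe_gene_map[
      !grepl("^[0-9]+[pq][0-9]", probe_gene_map$gene_id), , drop = FALSE]
  }
  mapped <- sig_dms$site_id %in% probe_gene_map$probe_id
  n_unmapped <- sum(!mapped)

  gene_key <- tibble::tibble(gene = des$site_id,
                             gene_name = des$region_label)
  des_names <- tidyr::separate_rows(gene_key, "gene_name", sep = ";")

  dms_genes <- dplyr::inner_join(
    tibble::tibble(probe_id = sig_dms$site_id, coef = sig_dms$coef),
    probe_gene_map, by = "probe_id")

  # a probe's gene matches a DES row by gene id or by gene name
  sig_gene_ids <- unique(c(sig_des$site_id,
                           des_names$gene[des_names$gene_name %in%
                                            sig_des$region_label &
                                            des_names$gene %in%
                                            sig_des$site_id]))
  hit <- dms_genes$gene_id %in% sig_des$site_id |
    dms_genes$gene_id %in% des_names$gene_name[des_names$gene %in%
                                                 sig_gene_ids]
  dms_hit <- dms_genes[hit, , drop = FALSE]

  if (nrow(dms_hit) == 0) {
    out <- tibble::tibble(gene = character(), probes = list(),
                          n_probes = integer(),
                          meth_direction = character(),
                          expr_direction = character(),
                          concordant = logical())
    return(structure(out, class = c("overlap_result", class(out)),
                     n_unmapped = n_unmapped))
  }

  # resolve each hit gene to the DES row (by id or by name)
  resolve_des <- function(g) {
    i <- which(sig_des$site_id == g)
    if (length(i) == 0) {
      i <- which(vapply(strsplit(sig_des$region_label, ";"),
                        function(nm) g %in% nm, logical(1)))
    }
    i[1]
  }

  out <- dms_hit |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(probes = list(.data$probe_id),
                     n_probes = dplyr::n(),
                     meth_coef = mean(.data$coef), .groups = "drop") |>
    dplyr::rename(gene = "gene_id")
  des_idx <- vapply(out$gene, resolve_des, integer(1))
  out$expr_coef <- sig_des$coef[des_idx]
  out$meth_direction <- ifelse(out$meth_coef < 0, "hypo", "hyper")
  out$expr_direction <- ifelse(out$expr_coef < 0, "down", "up")
  out$concordant <- (out$meth_direction == "hypo" &
                       out$expr_direction == "up") |
    (out$meth_direction == "hyper" & out$expr_direction == "down")
  structure(out, class = c("overlap_result", class(out)),
            n_unmapped = n_unmapped)
}

#' Covariate-adjusted Spearman correlation between methylation and
#' expression
#'
#' Spearman's rho and two-sided p-value per probe-gene pair, overall and
#' within subject groups (ranks recomputed within each group). P-values
#' use the t approximation for n >= 20 and the exact/Edgeworth small-
#' sample distribution below. Groups with fewer than 5 subjects report
#' rho with the p-value flagged unreliable.
#'
#' @param meth_resid,expr_resid residual matrices (sites x subjects,
#'   shared subject columns).
#' @param pairs tibble with columns `probe_id`, `gene_id`.
#' @param groups named list of subject-id vectors (e.g.
#'   `list(current = ..., never = ...)`); the overall set is always
#'   included as group `"all"`.
#' @return Tibble: `probe_id`, `gene_id`, `group`, `n`, `rho`, `p`,
#'   `p_reliable`.
#' @export
meth_expr_correlation <- function(meth_resid, expr_resid, pairs,
                                  groups = NULL) {
  shared <- intersect(colnames(meth_resid), colnames(expr_resid))
  if (length(shared) == 0) stop("no shared subjects", call. = FALSE)
  missing_p <- setdiff(pairs$probe_id, rownames(meth_resid))
  missing_g <- setdiff(pairs$gene_id, rownames(expr_resid))
  if (length(missing_p) > 0 || length(missing_g) > 0) {
    stop("pairs reference absent sites: ",
         paste(c(missing_p, missing_g), collapse = ", "), call. = FALSE)
  }
  all_groups <- c(list(all = shared), groups)

  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    purrr::map_dfr(names(all_groups), function(gname) {
      ids <- intersect(all_groups[[gname]], shared)
      x <- meth_resid[pairs$probe_id[k], ids]
      y <- expr_resid[pairs$gene_id[k], ids]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      if (n < 3) {
        return(tibble::tibble(probe_id = pairs$probe_id[k],
                              gene_id = pairs$gene_id[k], group = gname,
                              n = n, rho = NA_real_, p = NA_real_,
                              p_reliable = FALSE))
      }
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = n < 20))
      tibble::tibble(probe_id = pairs$probe_id[k],
                     gene_id = pairs$gene_id[k],
                     group = gname, n = n,
                     rho = unname(ct$estimate),
                     p = ct$p.value,
                     p_reliable = n >= 5)
    })
  })
}
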