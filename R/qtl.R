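#' cis-QTL scan on covariate-adjusted residuals
#'
#' For each site, regresses the residual vector on the dosage of every
#' SNP on the same chromosome within `window` base pairs of the site
#' position (closed window `[pos - window, pos + window]`) by simple
#' linear regression, and retains the minimum-p SNP. Monomorphic SNPs are
#' skipped and counted. Sites with no cis SNP are reported untested
#' (`n_snps_tested = 0`, statistics `NA`).
#'
#' @param residuals sites x subjects matrix of covariate-adjusted
#'   residuals (e.g. from [residualize_matrix()]).
#' @param genotypes list with `dosages` (SNPs x subjects) and `snp_map`
#'   (tibble: `snp_id`, `chrom`, `pos`), as from [generate_genotypes()].
#' @param site_positions tibble with `site_id` (or `probe_id`), `chrom`,
#'   `pos` covering the residual rows.
#' @param window cis half-width in base pairs (default 1e5).
#' @param alpha per-site significance threshold on the top SNP
#'   (default 5e-5).
#' @return A `qtl_result` tibble: `site_id`, `top_snp_id`, `beta`
#'   (residual SD per allele), `se`, `p`, `n_snps_tested`,
#'   `n_monomorphic`, `significant`.
#' @export
map_cis_qtl <- function(residuals, genotypes, site_positions,
                        window = 1e5, alpha = 5e-5) {
  id_col <- intersect(c("site_id", "probe_id"), names(site_positions))[1]
  if (is.na(id_col)) stop("site_positions needs a site_id/probe_id column",
                          call. = FALSE)
  pos_tbl <- site_positions[match(rownames(residuals),
                                  site_positions[[id_col]]), ]
  if (anyNA(pos_tbl[[id_col]])) {
    stop("site_positions does not cover all residual rows", call. = FALSE)
  }
  dos <- genotypes$dosages
  smap <- genotypes$snp_map
  shared <- intersect(colnames(residuals), colnames(dos))
  res <- residuals[, shared, drop = FALSE]
  dos <- dos[, shared, drop = FALSE]

  out <- purrr::map_dfr(seq_len(nrow(res)), function(i) {
    cis <- which(smap$chrom == pos_tbl$chrom[i] &
                   smap$pos >= pos_tbl$pos[i] - window &
                   smap$pos <= pos_tbl$pos[i] + window)
    y <- res[i, ]
    ok <- !is.na(y)
    y <- y[ok]
    n <- length(y)
    empty <- tibble::tibble(site_id = rownames(res)[i],
                            top_snp_id = NA_character_,
                            beta = NA_real_, se = NA_real_, p = NA_real_,
                            n_snps_tested = 0L, n_monomorphic = 0L)
    if (length(cis) == 0 || n < 4) return(empty)

    G <- dos[cis, ok, drop = FALSE]
    mono <- apply(G, 1, function(g) length(unique(g)) < 2)
    G <- G[!mono, , drop = FALSE]
    if (nrow(G) == 0) {
      empty$n_monomorphic <- sum(mono)
      return(empty)
    }
    gc <- sweep(G, 1, rowMeans(G))
    yc <- y - mean(y)
    sxx <- rowSums(gc^2)
    sxy <- drop(gc %*% yc)
    beta <- sxy / sxx
    rss <- sum(yc^2) - beta * sxy
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
    tt <- beta / se
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    j <- which.min(p)
    tibble::tibble(site_id = rownames(res)[i],
                   top_snp_id = smap$snp_id[cis[!mono][j]],
                   beta = unname(beta[j]), se = unname(se[j]),
                   p = unname(p[j]),
                   n_snps_tested = nrow(G),
                   n_monomorphic = sum(mono))
  })
  out$significant <- !is.na(out$p) & out$p < alpha
  structure(out, class = c("qtl_result", class(out)),
            window = window, alpha = alpha)
}

#' @export
glance.qtl_result <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x),
                 n_tested = sum(x$n_snps_tested > 0),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 window = attr(x, "window"),
                 alpha = attr(x, "alpha"))
}
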