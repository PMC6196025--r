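#' Published adipose smoking-DMS reference table
#'
#' The 42 adipose-tissue smoking differentially methylated sites (CpG id,
#' genomic location, region label, group beta means and SDs, mixed-model
#' coefficient with positive values denoting hypermethylation in current
#' smokers, and the top cis-meQTL where one was reported), shipped as a
#' plain-text fixture. Used by the summarizers (direction fractions,
#' unique regions, intergenic share) and as a realistic site panel in
#' examples.
#'
#' @return Tibble with 42 rows and columns `probe_id`, `chrom`, `pos`,
#'   `region_label`, `beta_never`, `sd_never`, `beta_current`,
#'   `sd_current`, `coef`, `se`, `p`, `cis_meqtl`.
#' @export
#' @examples
#' dms <- adipose_smoking_dms()
#' summarize_directions(dms)
adipose_smoking_dms <- function() {
  path <- system.file("extdata", "adipose_smoking_dms.tsv",
                      package = "adipotwin", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    cis_meqtl = readr::col_character(),
                    .default = readr::col_double(),
                    probe_id = readr::col_character(),
                    region_label = readr::col_character()))
}
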