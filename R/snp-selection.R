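#' Select analysis SNPs from a GWAS-catalog table
#'
#' Keeps every catalog SNP associated with a phenotype of interest at
#' genome-wide significance (`gwas_p < p_threshold`, strict) that is present
#' in the genotype data. For each significant SNP that is *not* genotyped,
#' the genotyped LD proxy with the highest `r_squared` strictly above
#' `r2_threshold` is substituted, if one exists; ties on `r_squared` are
#' broken by lexicographic proxy id. The output is deduplicated by selected
#' SNP id (a SNP significant for several phenotypes, or proxying several
#' index SNPs, enters once) while all phenotype annotations are retained in
#' a nested `annotations` column. Ordering is deterministic (by `snp_id`)
#' and invariant to catalog row order.
#'
#' @param catalog Tibble with `snp_id`, `phenotype`, optional
#'   `phenotype_group`, and `gwas_p` in `(0, 1]`; one row per
#'   SNP-phenotype pair.
#' @param genotyped_ids Character vector of SNP ids present in the genotype
#'   data.
#' @param proxies Optional tibble with `index_snp_id`, `proxy_snp_id`,
#'   `r_squared` in `[0, 1]`.
#' @param p_threshold Genome-wide significance threshold (strict `<`).
#' @param r2_threshold LD threshold for proxies (strict `>`).
#' @return Tibble with one row per selected SNP: `snp_id`, `provenance`
#'   (`"direct"` or `"proxy"`), `index_snp_id` (the proxied index SNP, `NA`
#'   for direct hits), `r_squared` (`NA` for direct hits) and `annotations`
#'   (list of tibbles with `phenotype`, `phenotype_group`, `gwas_p`).
#' @seealso [snp_annotations()] to unnest the SNP-phenotype map.
#' @export
#' @examples
#' catalog <- tibble::tibble(
#'   snp_id = c("rs1", "rs2", "rs3"),
#'   phenotype = c("schizophrenia", "schizophrenia", "bipolar disorder"),
#'   gwas_p = c(4e-8, 6e-8, 1e-9)
#' )
#' proxies <- tibble::tibble(index_snp_id = "rs3",
#'                           proxy_snp_id = c("rs3a", "rs3b"),
#'                           r_squared = c(0.9, 0.7))
#' select_snps(catalog, c("rs1", "rs2", "rs3a", "rs3b"), proxies)
select_snps <- function(catalog, genotyped_ids, proxies = NULL,
                        p_threshold = 5e-8, r2_threshold = 0.8) {
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("`p_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (r2_threshold < 0 || r2_threshold > 1) {
    stop("`r2_threshold` must lie in [0, 1]", call. = FALSE)
  }
  catalog <- tibble::as_tibble(catalog)
  stopifnot(all(c("snp_id", "phenotype", "gwas_p") %in% names(catalog)))
  if (any(catalog$gwas_p <= 0)) stop("catalog gwas_p must be > 0", call. = FALSE)
  if (!"phenotype_group" %in% names(catalog)) catalog$phenotype_group <- NA_character_

  empty <- tibble::tibble(
    snp_id = character(), provenance = character(),
    index_snp_id = character(), r_squared = numeric(),
    annotations = list()
  )
  sig <- catalog[catalog$gwas_p < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  sig <- dplyr::arrange(sig, .data$snp_id, .data$phenotype)

  sig_ids <- sort(unique(sig$snp_id))
  direct_ids <- intersect(sig_ids, genotyped_ids)
  absent_ids <- setdiff(sig_ids, genotyped_ids)

  # one row per (selected snp, index snp) before deduplication
  hits <- tibble::tibble(
    snp_id = direct_ids, provenance = rep("direct", length(direct_ids)),
    index_snp_id = rep(NA_character_, length(direct_ids)),
    r_squared = rep(NA_real_, length(direct_ids))
  )
  if (length(absent_ids) > 0 && !is.null(proxies) && nrow(proxies) > 0) {
    px <- tibble::as_tibble(proxies)
    stopifnot(all(c("index_snp_id", "proxy_snp_id", "r_squared") %in% names(px)))
    px <- px[px$index_snp_id %in% absent_ids &
               px$proxy_snp_id %in% genotyped_ids &
               px$proxy_snp_id != px$index_snp_id &
               px$r_squared > r2_threshold, , drop = FALSE]
    if (nrow(px) > 0) {
      best <- px |>
        dplyr::arrange(.data$index_snp_id, dplyr::desc(.data$r_squared),
                       .data$proxy_snp_id) |>
        dplyr::distinct(.data$index_snp_id, .keep_all = TRUE)
      hits <- dplyr::bind_rows(hits, tibble::tibble(
        snp_id = best$proxy_snp_id, provenance = "proxy",
        index_snp_id = best$index_snp_id, r_squared = best$r_squared
      ))
    }
  }
  if (nrow(hits) == 0) return(empty)

  ann_for <- function(index_ids) {
    rows <- sig[sig$snp_id %in% index_ids,
                c("phenotype", "phenotype_group", "gwas_p"), drop = FALSE]
    dplyr::arrange(dplyr::distinct(rows), .data$phenotype)
  }
  # a selected SNP annotated through every index SNP it stands for (itself
  # when direct); direct status wins over proxy when both apply
  hits |>
    dplyr::mutate(source_id = ifelse(is.na(.data$index_snp_id),
                                     .data$snp_id, .data$index_snp_id)) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      provenance = if (any(.data$provenance == "direct")) "direct" else "proxy",
      index_snp_id = if (any(.data$provenance == "direct")) NA_character_ else
        paste(sort(unique(.data$index_snp_id)), collapse = ","),
      r_squared = if (any(.data$provenance == "direct")) NA_real_ else
        max(.data$r_squared),
      annotations = list(ann_for(.data$source_id)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$snp_id)
}

#' Unnest the SNP-phenotype annotation map of a selection
#'
#' @param selected Output of [select_snps()].
#' @return Tidy tibble with one row per (snp_id, phenotype) pair.
#' @export
snp_annotations <- function(selected) {
  tidyr::unnest(selected[, c("snp_id", "provenance", "annotations")],
                "annotations")
}
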