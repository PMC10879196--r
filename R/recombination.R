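#' Identify recombining-gene (RG) pairs
#'
#' A BBH pair is called an RG pair when the two proteins are highly similar
#' (identity and both coverages strictly above the thresholds, default 0.80)
#' while the two elements are globally dissimilar (wGRR at most `max_wgrr`,
#' default 0.10, inclusive). High identity between elements that share
#' almost nothing else is the signature of a recent exchange rather than of
#' vertical descent.
#'
#' @param bbh BBH tibble from [extract_bbh()].
#' @param wgrr wGRR tibble from [compute_wgrr()], computed from the same BBH
#'   universe.
#' @param thresholds An [rg_thresholds()] object.
#' @return A tibble of RG pairs: `gene_a`, `gene_b`, `element_a`,
#'   `element_b`, `identity`, `wgrr`.
#' @export
identify_rg_pairs <- function(bbh, wgrr, thresholds = rg_thresholds()) {
  bbh |>
    dplyr::mutate(wgrr = wgrr_lookup(wgrr, .data$element_a, .data$element_b)) |>
    dplyr::filter(
      .data$identity > thresholds$min_identity,
      .data$coverage_a > thresholds$min_coverage_both,
      .data$coverage_b > thresholds$min_coverage_both,
      .data$wgrr <= thresholds$max_wgrr
    ) |>
    dplyr::select("gene_a", "gene_b", "element_a", "element_b",
                  "identity", "wgrr")
}

#' Exclude element pairs with an implausible number of exchanges
#'
#' Element pairs carrying more than `max_pair_exchanges` RG pairs (default
#' 25) are removed wholesale: such counts arise between very large replicons
#' (chromids, secondary chromosomes) where integrated prophages would
#' otherwise masquerade as massive plasmid-phage exchanges. Only the
#' exchange evidence is discarded; the genes keep their ordinary homologs
#' and fall back to the non-recombining class downstream.
#'
#' @param rg_pairs RG-pair tibble from [identify_rg_pairs()].
#' @param max_pair_exchanges Maximum RG pairs per element pair (inclusive).
#' @return A list with `kept` (RG-pair tibble) and `excluded_pairs`
#'   (tibble `element_a`, `element_b`, `n_rg_pairs`).
#' @export
apply_pair_exclusion <- function(rg_pairs, max_pair_exchanges = 25) {
  counts <- rg_pairs |>
    dplyr::count(.data$element_a, .data$element_b, name = "n_rg_pairs")
  excluded <- counts |>
    dplyr::filter(.data$n_rg_pairs > max_pair_exchanges) |>
    dplyr::arrange(.data$element_a, .data$element_b)
  kept <- rg_pairs |>
    dplyr::anti_join(excluded, by = c("element_a", "element_b"))
  list(kept = kept, excluded_pairs = excluded)
}

#' Classify genes as recombining, non-recombining, or homolog-free
#'
#' Every gene receives exactly one label: `RG` if it appears in at least one
#' retained RG pair; otherwise `NRG` if it has at least one inter-element
#' homolog in the filtered hit universe; otherwise `NRG_nh` (no homologs).
#'
#' @param genes Gene tibble.
#' @param hits Filtered inter-element hit tibble from [filter_hits()].
#' @param rg_pairs Retained RG pairs (the `kept` component of
#'   [apply_pair_exclusion()]).
#' @return A tibble `gene_id`, `element_id`, `label`, `n_rg_partners`.
#' @export
classify_genes <- function(genes, hits, rg_pairs) {
  rg_genes <- c(rg_pairs$gene_a, rg_pairs$gene_b)
  n_partners <- table(rg_genes)
  has_homolog <- unique(c(hits$query_gene, hits$target_gene))
  out <- genes |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      element_id = .data$element_id,
      label = dplyr::case_when(
        .data$gene_id %in% rg_genes ~ "RG",
        .data$gene_id %in% has_homolog ~ "NRG",
        .default = "NRG_nh"
      ),
      n_rg_partners = as.integer(ifelse(is.na(n_partners[.data$gene_id]), 0,
                                        n_partners[.data$gene_id]))
    )
  stopifnot(nrow(out) == nrow(genes))
  out
}

#' Per-element recombining-gene fractions
#'
#' Fraction of recombining genes per element, relative to RG + NRG (genes
#' without homologs do not enter the denominator). Elements whose genes are
#' all homolog-free are excluded.
#'
#' @param classification Tibble from [classify_genes()].
#' @param elements Element tibble (supplies `mge_type`).
#' @return A tibble `element_id`, `mge_type`, `n_rg`, `n_nrg`, `rg_fraction`.
#' @export
rg_fractions <- function(classification, elements) {
  classification |>
    dplyr::summarise(
      n_rg = sum(.data$label == "RG"),
      n_nrg = sum(.data$label == "NRG"),
      .by = "element_id"
    ) |>
    dplyr::filter(.data$n_rg + .data$n_nrg > 0) |>
    dplyr::mutate(rg_fraction = .data$n_rg / (.data$n_rg + .data$n_nrg)) |>
    dplyr::left_join(dplyr::select(elements, "element_id", "mge_type"),
                     by = "element_id") |>
    dplyr::select("element_id", "mge_type", "n_rg", "n_nrg", "rg_fraction")
}
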