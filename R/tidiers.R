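#' Tidy a permutation-null calibration
#'
#' @param x An `mge_null_calibration`.
#' @param ... Unused.
#' @return The per-exchange-type summary tibble.
#' @exportS3Method generics::tidy
tidy.mge_null_calibration <- function(x, ...) x$summary

#' One-row summary of a permutation-null calibration
#'
#' @param x An `mge_null_calibration`.
#' @param ... Unused.
#' @return A one-row tibble: permutation count, seed, and the range of
#'   observed/expected ratios.
#' @exportS3Method generics::glance
glance.mge_null_calibration <- function(x, ...) {
  tibble::tibble(
    n_permutations = x$n_permutations,
    seed = x$seed,
    min_ratio = min(x$summary$ratio, na.rm = TRUE),
    max_ratio = max(x$summary$ratio, na.rm = TRUE)
  )
}

#' Tidy a group-level wGRR graph (edge list)
#'
#' @param x An `mge_group_graph`.
#' @param ... Unused.
#' @return The edge tibble (`group_a`, `group_b`, `mean_wgrr`).
#' @exportS3Method generics::tidy
tidy.mge_group_graph <- function(x, ...) x$edges

#' One-row summary of a group-level wGRR graph
#'
#' @param x An `mge_group_graph`.
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts and the edge threshold.
#' @exportS3Method generics::glance
glance.mge_group_graph <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$nodes), n_edges = nrow(x$edges),
                 edge_threshold = x$edge_threshold)
}

#' Tidy a gene-flow result bundle (gene classification)
#'
#' @param x An `mge_result`.
#' @param ... Unused.
#' @return The per-gene classification tibble.
#' @exportS3Method generics::tidy
tidy.mge_result <- function(x, ...) x$classification

#' One-row summary of a gene-flow result bundle
#'
#' @param x An `mge_result`.
#' @param ... Unused.
#' @return A one-row tibble with gene-class counts, family and excluded
#'   pair totals.
#' @exportS3Method generics::glance
glance.mge_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$classification),
    n_rg = sum(x$classification$label == "RG"),
    n_nrg = sum(x$classification$label == "NRG"),
    n_nrg_nh = sum(x$classification$label == "NRG_nh"),
    n_rg_families = dplyr::n_distinct(x$families$family_id),
    n_excluded_pairs = nrow(x$excluded_pairs)
  )
}
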