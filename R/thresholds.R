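#' Homology filtering thresholds
#'
#' Thresholds applied to raw all-vs-all protein hits before bidirectional
#' best-hit (BBH) extraction. The defaults retain alignments with
#' `evalue < 1e-4`, `identity > 0.35` and at least 50% coverage of *both*
#' protein sequences.
#'
#' @param max_evalue Maximum e-value (exclusive). Default `1e-4`.
#' @param min_identity Minimum identity fraction (exclusive, strict `>`).
#'   Default `0.35`.
#' @param min_coverage_both Minimum alignment coverage of each of the two
#'   proteins (inclusive, `>=`). Default `0.50`.
#' @return A list of class `mge_homology_thresholds`.
#' @export
#' @examples
#' homology_thresholds()
homology_thresholds <- function(max_evalue = 1e-4,
                                min_identity = 0.35,
                                min_coverage_both = 0.50) {
  stopifnot(max_evalue >= 0,
            min_identity >= 0, min_identity <= 1,
            min_coverage_both >= 0, min_coverage_both <= 1)
  structure(
    list(max_evalue = max_evalue,
         min_identity = min_identity,
         min_coverage_both = min_coverage_both),
    class = "mge_homology_thresholds"
  )
}

#' Recombining-gene detection thresholds
#'
#' A BBH pair is evidence of a recent exchange when the two proteins are
#' highly similar (identity and both coverages strictly above 0.80) while the
#' two elements carrying them are globally dissimilar (wGRR at most 0.10).
#' Element pairs with more than `max_pair_exchanges` such BBHs are excluded
#' altogether: those arise between very large replicons (chromids, secondary
#' chromosomes) where the low-wGRR signal is unreliable.
#'
#' @param min_identity Minimum BBH identity (strict `>`). Default `0.80`.
#' @param min_coverage_both Minimum coverage of both proteins (strict `>`).
#'   Default `0.80`.
#' @param max_wgrr Maximum wGRR of the element pair (inclusive `<=`).
#'   Default `0.10`.
#' @param max_pair_exchanges Maximum number of qualifying BBHs per element
#'   pair; pairs exceeding this are dropped entirely. Default `25`.
#' @return A list of class `mge_rg_thresholds`.
#' @export
rg_thresholds <- function(min_identity = 0.80,
                          min_coverage_both = 0.80,
                          max_wgrr = 0.10,
                          max_pair_exchanges = 25) {
  stopifnot(min_identity > 0, min_identity <= 1,
            max_wgrr > 0, max_wgrr < 1,
            max_pair_exchanges >= 1)
  structure(
    list(min_identity = min_identity,
         min_coverage_both = min_coverage_both,
         max_wgrr = max_wgrr,
         max_pair_exchanges = max_pair_exchanges),
    class = "mge_rg_thresholds"
  )
}

#' Recombining-gene family clustering thresholds
#'
#' Family edges use inclusive (`>=`) identity and coverage cutoffs, slightly
#' more permissive than the strict (`>`) cutoffs of RG detection.
#'
#' @param min_identity Minimum identity (inclusive). Default `0.80`.
#' @param min_coverage_both Minimum coverage of both proteins (inclusive).
#'   Default `0.80`.
#' @return A list of class `mge_family_thresholds`.
#' @export
family_thresholds <- function(min_identity = 0.80, min_coverage_both = 0.80) {
  structure(
    list(min_identity = min_identity, min_coverage_both = min_coverage_both),
    class = "mge_family_thresholds"
  )
}
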