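#' Screen a collection for relatives of a reference element group
#'
#' Reports every non-reference element having, to at least one reference
#' member, a wGRR of at least `min_wgrr` *and* at least `min_homologs` BBHs
#' (both conditions on the same element pair). The homolog count is the BBH
#' count underlying the wGRR itself, i.e. at the permissive homology filter
#' level.
#'
#' @param wgrr wGRR tibble from [compute_wgrr()] (carries `n_bbh`).
#' @param reference_ids Character vector of reference element ids (e.g. the
#'   P1 phage-plasmid group).
#' @param min_wgrr Minimum wGRR (inclusive). Default `0.1`.
#' @param min_homologs Minimum BBH count (inclusive). Default `10`.
#' @return Tibble `element_id`, `best_reference`, `max_wgrr`, `n_homologs`
#'   (the BBH count to the best-wGRR reference member).
#' @export
screen_related_elements <- function(wgrr, reference_ids,
                                    min_wgrr = 0.1, min_homologs = 10) {
  if (length(reference_ids) == 0) abort("empty reference group")
  a_ref <- wgrr$element_a %in% reference_ids
  b_ref <- wgrr$element_b %in% reference_ids
  cand <- dplyr::bind_rows(
    wgrr[a_ref & !b_ref, ] |>
      dplyr::transmute(element_id = .data$element_b,
                       reference = .data$element_a,
                       wgrr = .data$wgrr, n_bbh = .data$n_bbh),
    wgrr[b_ref & !a_ref, ] |>
      dplyr::transmute(element_id = .data$element_a,
                       reference = .data$element_b,
                       wgrr = .data$wgrr, n_bbh = .data$n_bbh)
  )
  cand |>
    dplyr::filter(.data$wgrr >= min_wgrr, .data$n_bbh >= min_homologs) |>
    dplyr::arrange(dplyr::desc(.data$wgrr), .data$reference) |>
    dplyr::distinct(.data$element_id, .keep_all = TRUE) |>
    dplyr::transmute(element_id = .data$element_id,
                     best_reference = .data$reference,
                     max_wgrr = .data$wgrr,
                     n_homologs = .data$n_bbh) |>
    dplyr::arrange(.data$element_id)
}

#' Conservation profiles of candidate elements against reference families
#'
#' Each candidate gene is assigned to a reference gene family when it
#' matches a family member at `>= min_identity` identity over
#' `>= min_coverage` of both sequences; a gene matching several families is
#' assigned to the best one (highest identity, ties to the
#' lexicographically smallest family id) with a warning. A family is
#' present in a candidate when at least one of its genes is assigned to it;
#' `fraction_conserved` is the fraction of reference families present.
#'
#' @param candidates Character vector of candidate element ids.
#' @param reference_families Tibble `family_id`, `gene_id` defining the
#'   reference families.
#' @param hits Filtered hit tibble from [filter_hits()].
#' @param genes Gene tibble.
#' @param min_identity,min_coverage Match thresholds (inclusive). Default
#'   `0.80` each.
#' @return Tibble `element_id`, `fraction_conserved`, `n_families_present`,
#'   `n_families_total`, plus one logical column per reference family.
#' @export
build_conservation_profiles <- function(candidates, reference_families,
                                        hits, genes,
                                        min_identity = 0.80,
                                        min_coverage = 0.80) {
  fam_ids <- sort(unique(reference_families$family_id))
  fam_of <- stats::setNames(reference_families$family_id,
                            reference_families$gene_id)
  el <- stats::setNames(genes$element_id, genes$gene_id)
  matches <- hits |>
    dplyr::filter(.data$identity >= min_identity,
                  .data$coverage_query >= min_coverage,
                  .data$coverage_target >= min_coverage)
  long <- dplyr::bind_rows(
    tibble::tibble(gene = matches$query_gene, other = matches$target_gene,
                   identity = matches$identity),
    tibble::tibble(gene = matches$target_gene, other = matches$query_gene,
                   identity = matches$identity)
  ) |>
    dplyr::mutate(element_id = unname(el[.data$gene]),
                  family_id = unname(fam_of[.data$other])) |>
    dplyr::filter(.data$element_id %in% candidates, !is.na(.data$family_id))
  multi <- long |>
    dplyr::distinct(.data$gene, .data$family_id) |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0)
    warn(paste0(nrow(multi), " candidate gene(s) matched several families; ",
                "assigned to the best-identity family"))
  assigned <- long |>
    dplyr::arrange(dplyr::desc(.data$identity), .data$family_id) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  presence <- assigned |>
    dplyr::distinct(.data$element_id, .data$family_id) |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(names_from = "family_id", values_from = "present",
                       values_fill = FALSE)
  base <- tibble::tibble(element_id = candidates)
  missing_fams <- setdiff(fam_ids, names(presence))
  for (f in missing_fams) presence[[f]] <- logical(nrow(presence))
  out <- dplyr::left_join(base, presence, by = "element_id")
  for (f in fam_ids) out[[f]][is.na(out[[f]])] <- FALSE
  out$n_families_present <- rowSums(as.matrix(out[, fam_ids, drop = FALSE]))
  out$n_families_total <- length(fam_ids)
  out$fraction_conserved <- out$n_families_present / out$n_families_total
  dplyr::select(out, "element_id", "fraction_conserved",
                "n_families_present", "n_families_total",
                dplyr::all_of(fam_ids))
}

#' Keep candidates conserving enough reference families
#'
#' @param profiles Tibble from [build_conservation_profiles()].
#' @param min_fraction Minimum `fraction_conserved` (inclusive). Default
#'   `0.75`.
#' @return The filtered profile tibble.
#' @export
filter_close_relatives <- function(profiles, min_fraction = 0.75) {
  dplyr::filter(profiles, .data$fraction_conserved >= min_fraction)
}

#' Extract the strict persistent genome
#'
#' A family belongs to the persistent genome when it occurs in exactly one
#' copy in at least a fraction `t` of the genomes (default 0.9): widespread,
#' single-copy families are the stable backbone suitable for phylogeny.
#'
#' @param copy_numbers Long tibble `element_id`, `family_id`, `n_copies`
#'   (absent combinations mean 0 copies), or a genomes-by-families numeric
#'   matrix with dimnames.
#' @param t Minimum fraction of genomes with exactly one copy (inclusive).
#'   Default `0.9`.
#' @param n_genomes Total number of genomes; defaults to the number of
#'   distinct `element_id`s (or matrix rows).
#' @return Tibble `family_id`, `n_single_copy`, `n_genomes`,
#'   `fraction_single_copy`, restricted to persistent families.
#' @export
persistent_genome <- function(copy_numbers, t = 0.9, n_genomes = NULL) {
  if (is.matrix(copy_numbers)) {
    copy_numbers <- tibble::tibble(
      element_id = rep(rownames(copy_numbers), ncol(copy_numbers)),
      family_id = rep(colnames(copy_numbers), each = nrow(copy_numbers)),
      n_copies = as.vector(copy_numbers)
    )
  }
  n_genomes <- n_genomes %||% dplyr::n_distinct(copy_numbers$element_id)
  copy_numbers |>
    dplyr::summarise(n_single_copy = sum(.data$n_copies == 1),
                     .by = "family_id") |>
    dplyr::mutate(n_genomes = n_genomes,
                  fraction_single_copy = .data$n_single_copy / n_genomes) |>
    dplyr::filter(.data$fraction_single_copy >= t) |>
    dplyr::arrange(.data$family_id)
}
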