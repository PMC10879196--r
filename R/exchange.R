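EXCHANGE_TYPES <- c("phage-phage", "phage_plasmid-phage_plasmid",
                    "plasmid-plasmid", "phage-phage_plasmid",
                    "phage-plasmid", "phage_plasmid-plasmid")

exchange_type_label <- function(type_x, type_y) {
  paste(pmin(type_x, type_y), pmax(type_x, type_y), sep = "-")
}

#' Cluster recombining genes into families by single linkage
#'
#' RGs are connected whenever a filtered homology hit between them reaches
#' the family thresholds (inclusive: identity >= 0.80 and coverage of both
#' proteins >= 0.80 by default); families are the connected components, so
#' each member has at least one highly similar partner in its family. RG
#' pairs themselves always satisfy the (strict) detection thresholds and so
#' are edges too. Genes in no qualifying edge form singleton families.
#'
#' @param classification Tibble from [classify_genes()]; only `RG` rows are
#'   clustered.
#' @param hits Filtered hit tibble from [filter_hits()].
#' @param thresholds A [family_thresholds()] object.
#' @return A tibble `family_id`, `gene_id`. Family ids are deterministic:
#'   families are ordered by their lexicographically smallest member.
#' @export
cluster_rg_families <- function(classification, hits,
                                thresholds = family_thresholds()) {
  rg <- sort(classification$gene_id[classification$label == "RG"])
  if (length(rg) == 0)
    return(tibble::tibble(family_id = character(), gene_id = character()))
  edges <- hits |>
    dplyr::filter(
      .data$query_gene %in% rg, .data$target_gene %in% rg,
      .data$identity >= thresholds$min_identity,
      .data$coverage_query >= thresholds$min_coverage_both,
      .data$coverage_target >= thresholds$min_coverage_both
    )
  g <- igraph::graph_from_data_frame(
    edges[, c("query_gene", "target_gene")],
    directed = FALSE,
    vertices = data.frame(name = rg)
  )
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[order(vapply(members, min, character(1)))]
  tibble::tibble(
    family_id = rep(sprintf("RGF%05d", seq_along(members)),
                    lengths(members)),
    gene_id = unlist(lapply(members, sort), use.names = FALSE)
  )
}

#' Count exchange types across recombining-gene families
#'
#' For each family, record which of the six exchange types is present:
#' within-type exchange X-X when the family spans at least two distinct
#' elements of type X, between-type X-Y when it spans at least one element
#' of each. Each type is counted at most once per family, so a family found
#' in four plasmids and two phage-plasmids contributes one
#' plasmid-plasmid, one phage_plasmid-phage_plasmid and one
#' phage_plasmid-plasmid presence.
#'
#' @param families Tibble from [cluster_rg_families()].
#' @param genes Gene tibble (maps genes to elements).
#' @param elements Element tibble (maps elements to types).
#' @return A tibble `exchange_type`, `n_families` with one row for each of
#'   the six types.
#' @export
count_exchange_types <- function(families, genes, elements) {
  fam_el <- family_elements(families, genes)
  types <- stats::setNames(elements$mge_type, elements$element_id)
  single <- vapply(fam_el, function(e) length(e) < 2, logical(1))
  if (any(single))
    warn(paste0(sum(single), " famil",
                ifelse(sum(single) == 1, "y", "ies"),
                " confined to a single element contribute no exchange"))
  counts <- exchange_presence_counts(fam_el, types)
  tibble::tibble(exchange_type = EXCHANGE_TYPES,
                 n_families = as.integer(counts[EXCHANGE_TYPES]))
}

family_elements <- function(families, genes) {
  el <- stats::setNames(genes$element_id, genes$gene_id)
  split(unname(el[families$gene_id]), families$family_id) |>
    lapply(unique)
}

# presence counts over the six exchange types, given a named type vector
exchange_presence_counts <- function(fam_el, types) {
  counts <- stats::setNames(integer(length(EXCHANGE_TYPES)), EXCHANGE_TYPES)
  for (els in fam_el) {
    tt <- table(types[els])
    present <- names(tt)
    for (i in seq_along(present)) {
      if (tt[[i]] >= 2)
        counts[exchange_type_label(present[i], present[i])] <-
          counts[exchange_type_label(present[i], present[i])] + 1L
      if (i < length(present)) for (j in (i + 1):length(present)) {
        lab <- exchange_type_label(present[i], present[j])
        counts[lab] <- counts[lab] + 1L
      }
    }
  }
  counts
}

#' Permutation null for exchange-type counts
#'
#' Shuffles the type labels (phage, plasmid, phage-plasmid) across all
#' elements — preserving the exact label multiset — and recomputes the
#' exchange-type counts on the fixed family structure. The ratio of observed
#' to mean permuted counts calibrates how much each exchange type deviates
#' from what the element-type proportions alone would produce.
#'
#' @param families Tibble from [cluster_rg_families()].
#' @param genes Gene tibble.
#' @param elements Element tibble.
#' @param n_permutations Number of label shuffles. Default 100.
#' @param seed Integer seed; the permutation stream is fully reproducible.
#' @return An object of class `mge_null_calibration`: list with `summary`
#'   (tibble `exchange_type`, `observed`, `null_mean`, `null_sd`, `ratio`,
#'   `pct_of_expected`), the `permuted` count matrix, `n_permutations` and
#'   `seed`.
#' @export
permutation_null <- function(families, genes, elements,
                             n_permutations = 100, seed = 1729) {
  stopifnot(n_permutations >= 1)
  fam_el <- family_elements(families, genes)
  types <- stats::setNames(elements$mge_type, elements$element_id)
  observed <- exchange_presence_counts(fam_el, types)
  permuted <- matrix(0L, nrow = n_permutations, ncol = length(EXCHANGE_TYPES),
                     dimnames = list(NULL, EXCHANGE_TYPES))
  withr::with_seed(seed, {
    for (k in seq_len(n_permutations)) {
      shuffled <- stats::setNames(sample(unname(types)), names(types))
      permuted[k, ] <- exchange_presence_counts(fam_el, shuffled)
    }
  })
  mu <- unname(colMeans(permuted)[EXCHANGE_TYPES])
  obs <- unname(observed[EXCHANGE_TYPES])
  summary <- tibble::tibble(
    exchange_type = EXCHANGE_TYPES,
    observed = as.integer(obs),
    null_mean = mu,
    null_sd = unname(apply(permuted, 2, stats::sd)[EXCHANGE_TYPES]),
    ratio = ifelse(mu > 0, obs / mu, NA_real_)
  )
  summary$pct_of_expected <- 100 * summary$ratio
  structure(list(summary = summary, permuted = permuted,
                 n_permutations = n_permutations, seed = seed),
            class = "mge_null_calibration")
}

#' @export
print.mge_null_calibration <- function(x, ...) {
  cat("<mge_null_calibration>", x$n_permutations, "permutations, seed",
      x$seed, "\n")
  print(x$summary)
  invisible(x)
}
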