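#' Difference-sum ratio
#'
#' Bounded over/under-representation score
#' `r = (O - E_H0) / (O + E_H0)` in `[-1, 1]`, where `O` is the observed
#' fraction of a category in the focal group and `E_H0` the expected
#' fraction under equal distribution across groups. Positive values mean
#' over-representation. Vectorised; `O = E_H0 = 0` yields `NA` with a
#' warning.
#'
#' @param observed,expected Non-negative fractions or percentages (any
#'   common scale).
#' @return Numeric vector of ratios in `[-1, 1]`.
#' @export
#' @examples
#' diff_sum_ratio(8.60, 3.01) # +0.48
#' diff_sum_ratio(1.87, 3.01) # -0.23
diff_sum_ratio <- function(observed, expected) {
  stopifnot(all(observed >= 0), all(expected >= 0))
  denom <- observed + expected
  undef <- denom == 0
  if (any(undef))
    warn("diff_sum_ratio undefined where observed and expected are both 0")
  out <- rep(NA_real_, length(denom))
  out[!undef] <- (observed[!undef] - expected[!undef]) / denom[!undef]
  out
}

#' Build a 2x2 contingency table for one category
#'
#' Counts (in-category, out-of-category) by (group 1, group 2). Genes
#' without an annotation in the track count as out-of-category; genes
#' outside the two groups are ignored.
#'
#' @param gene_groups Tibble `gene_id`, `group` with exactly two group
#'   levels (e.g. RG/NRG from [enrichment_groups()]).
#' @param annotations Annotation tibble (`track`, `gene_id`, `category`).
#' @param category Category to test.
#' @param track Track to use; must be present in `annotations`.
#' @return An object of class `mge_contingency`: list with the 2x2 integer
#'   matrix `table` (rows: in/out of category; columns: groups), `category`,
#'   `track` and `groups`.
#' @export
build_contingency <- function(gene_groups, annotations, category, track) {
  ann <- annotations[annotations$track == track, ]
  if (nrow(ann) == 0)
    abort(paste0("unknown track: ", track, " (available: ",
                 paste(unique(annotations$track), collapse = ", "), ")"))
  if (!category %in% ann$category)
    abort(paste0("unknown category '", category, "' in track ", track,
                 " (available: ",
                 paste(sort(unique(ann$category)), collapse = ", "), ")"))
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0)
    abort(paste0("gene annotated in multiple categories of track ", track,
                 ": ", dup[1]))
  groups <- sort(unique(gene_groups$group))
  stopifnot(length(groups) == 2)
  in_cat <- ann$gene_id[ann$category == category]
  m <- matrix(0L, 2, 2,
              dimnames = list(c("in_category", "out_of_category"), groups))
  for (g in groups) {
    ids <- gene_groups$gene_id[gene_groups$group == g]
    m["in_category", g] <- sum(ids %in% in_cat)
    m["out_of_category", g] <- sum(!ids %in% in_cat)
  }
  structure(list(table = m, category = category, track = track,
                 groups = groups),
            class = "mge_contingency")
}

#' Gene groupings for enrichment testing
#'
#' Builds the two-level gene grouping used by [build_contingency()]:
#' either recombining vs non-recombining genes (`rg_vs_nrg`; homolog-free
#' genes excluded by default) or, among RGs only, between-type vs
#' within-type exchangers (`bmge_vs_wmge`).
#'
#' @param classification Tibble from [classify_genes()].
#' @param grouping `"rg_vs_nrg"` or `"bmge_vs_wmge"`.
#' @param flow_scope Tibble from [classify_flow_scope()]; required for
#'   `bmge_vs_wmge`.
#' @param include_nrg_nh Include homolog-free genes in the NRG group?
#'   Default `FALSE`.
#' @return Tibble `gene_id`, `group`.
#' @export
enrichment_groups <- function(classification,
                              grouping = c("rg_vs_nrg", "bmge_vs_wmge"),
                              flow_scope = NULL,
                              include_nrg_nh = FALSE) {
  grouping <- match.arg(grouping)
  if (grouping == "rg_vs_nrg") {
    keep <- classification$label %in%
      c("RG", "NRG", if (include_nrg_nh) "NRG_nh")
    tibble::tibble(
      gene_id = classification$gene_id[keep],
      group = ifelse(classification$label[keep] == "RG", "RG", "NRG")
    )
  } else {
    if (is.null(flow_scope))
      abort("bmge_vs_wmge grouping requires a flow_scope table")
    tibble::tibble(gene_id = flow_scope$gene_id, group = flow_scope$scope)
  }
}

#' Fisher exact tests with Benjamini-Hochberg correction
#'
#' Applies the exact Fisher test to each contingency table and corrects the
#' batch with Benjamini-Hochberg; the batch should contain one annotation
#' track/panel so that corrections stay independent. The focal group for
#' observed/expected fractions is the first (alphabetical) group unless
#' `focal` names another. Reported per table: observed percentage `O` of
#' the category in the focal group, expected percentage `E_H0` over both
#' groups pooled, `p`, `q`, the difference-sum ratio and a direction call
#' at `q < 0.05`.
#'
#' @param tables A list of [build_contingency()] objects (a single object is
#'   accepted).
#' @param alternative Test sidedness, as in [stats::fisher.test()]. Default
#'   two-sided.
#' @param focal Focal group name; default the first group level.
#' @return A tibble with columns `track`, `category`, `focal_group`, `O`,
#'   `E_H0`, `p`, `q`, `r_diff_sum`, `direction`, `stars`.
#' @export
fisher_bh <- function(tables, alternative = "two.sided", focal = NULL) {
  if (inherits(tables, "mge_contingency")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  rows <- purrr::map(tables, function(tb) {
    m <- tb$table
    fg <- focal %||% tb$groups[1]
    zero_margin <- any(rowSums(m) == 0) || any(colSums(m) == 0)
    p <- if (zero_margin) 1 else fisher.test(m, alternative = alternative)$p.value
    O <- 100 * m["in_category", fg] / sum(m[, fg])
    E <- 100 * sum(m["in_category", ]) / sum(m)
    tibble::tibble(track = tb$track, category = tb$category,
                   focal_group = fg, O = O, E_H0 = E, p = p,
                   zero_margin = zero_margin)
  }) |> purrr::list_rbind()
  rows$q <- p.adjust(rows$p, method = "BH")
  rows$r_diff_sum <- suppressWarnings(diff_sum_ratio(rows$O, rows$E_H0))
  rows$direction <- dplyr::case_when(
    rows$q < 0.05 & rows$O > rows$E_H0 ~ "over",
    rows$q < 0.05 & rows$O < rows$E_H0 ~ "under",
    .default = "ns"
  )
  rows$stars <- significance_stars(rows$q)
  rows
}

significance_stars <- function(q) {
  dplyr::case_when(
    q <= 1e-4 ~ "****",
    q <= 1e-3 ~ "***",
    q <= 1e-2 ~ "**",
    q <= 0.05 ~ "*",
    .default = "ns"
  )
}

#' Enrichment of annotation categories across a gene grouping
#'
#' Convenience wrapper: builds one contingency table per category of each
#' requested track and runs [fisher_bh()] per track (corrections are applied
#' within tracks so panels stay independent).
#'
#' @param classification Tibble from [classify_genes()].
#' @param annotations Annotation tibble.
#' @param grouping,flow_scope,include_nrg_nh Passed to
#'   [enrichment_groups()].
#' @param tracks Tracks to test; default all tracks present.
#' @param alternative Passed to [fisher_bh()].
#' @return Combined enrichment tibble (one row per track x category).
#' @export
test_enrichment <- function(classification, annotations,
                            grouping = "rg_vs_nrg", flow_scope = NULL,
                            include_nrg_nh = FALSE,
                            tracks = NULL, alternative = "two.sided") {
  gg <- enrichment_groups(classification, grouping, flow_scope,
                          include_nrg_nh)
  focal <- if (grouping == "rg_vs_nrg") "RG" else "bMGE"
  tracks <- tracks %||% sort(unique(annotations$track))
  purrr::map(tracks, function(tr) {
    cats <- sort(unique(annotations$category[annotations$track == tr]))
    tabs <- purrr::map(cats, function(ct)
      build_contingency(gg, annotations, ct, tr))
    fisher_bh(tabs, alternative = alternative, focal = focal)
  }) |> purrr::list_rbind()
}

#' Classify recombining genes by exchange scope
#'
#' An RG is `bMGE` when at least one of its RG partners lies on an element
#' of a different type (gene flow between MGE types), `wMGE` when all
#' partners share its own element's type.
#'
#' @param rg_pairs Retained RG pairs.
#' @param elements Element tibble (supplies `mge_type`).
#' @return Tibble `gene_id`, `scope` covering every gene in `rg_pairs`.
#' @export
classify_flow_scope <- function(rg_pairs, elements) {
  types <- stats::setNames(elements$mge_type, elements$element_id)
  long <- dplyr::bind_rows(
    tibble::tibble(gene_id = rg_pairs$gene_a,
                   own = unname(types[rg_pairs$element_a]),
                   partner = unname(types[rg_pairs$element_b])),
    tibble::tibble(gene_id = rg_pairs$gene_b,
                   own = unname(types[rg_pairs$element_b]),
                   partner = unname(types[rg_pairs$element_a]))
  )
  long |>
    dplyr::summarise(cross = any(.data$own != .data$partner),
                     .by = "gene_id") |>
    dplyr::transmute(gene_id = .data$gene_id,
                     scope = ifelse(.data$cross, "bMGE", "wMGE")) |>
    dplyr::arrange(.data$gene_id)
}

#' Classify genes by adjacency to recombining genes
#'
#' Inspects each gene's immediate neighbours along its element (wrapping
#' around on circular replicons): an RG with no RG neighbour is a
#' `single_RG`; an RG next to another RG is `RG_adjacent_to_RG`; an NRG (or
#' homolog-free gene) next to an RG is `NRG_flanking_RG`; everything else is
#' `other`. Transposase-driven co-transfer shows up as runs of adjacent RGs.
#'
#' @param classification Tibble from [classify_genes()].
#' @param genes Gene tibble (supplies positions).
#' @param elements Element tibble (supplies `topology`).
#' @return Tibble `gene_id`, `adjacency_class`.
#' @export
classify_adjacency <- function(classification, genes, elements) {
  lab <- stats::setNames(classification$label, classification$gene_id)
  topo <- stats::setNames(elements$topology, elements$element_id)
  out <- genes |>
    dplyr::arrange(.data$element_id, .data$position) |>
    dplyr::group_by(.data$element_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      is_rg <- unname(lab[df$gene_id]) == "RG"
      circular <- identical(unname(topo[key$element_id]), "circular")
      nb_rg <- neighbor_any_rg(is_rg, circular)
      tibble::tibble(
        gene_id = df$gene_id,
        adjacency_class = dplyr::case_when(
          is_rg & !nb_rg ~ "single_RG",
          is_rg & nb_rg ~ "RG_adjacent_to_RG",
          !is_rg & nb_rg ~ "NRG_flanking_RG",
          .default = "other"
        )
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "adjacency_class")
  out
}

# for each position (genes ordered along the element), is any neighbour RG?
neighbor_any_rg <- function(is_rg, circular) {
  n <- length(is_rg)
  if (n == 1) return(FALSE)
  left <- c(if (circular) is_rg[n] else FALSE, is_rg[-n])
  right <- c(is_rg[-1], if (circular) is_rg[1] else FALSE)
  left | right
}
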