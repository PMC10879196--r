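#' Filter homology hits on e-value, identity and coverage
#'
#' Retains hits with `evalue < max_evalue`, `identity > min_identity`
#' (strict) and coverage of **both** proteins `>= min_coverage_both`.
#' Hits between genes of the same element are removed.
#'
#' @param hits Homology-hit tibble (see [read_alignment_table()]).
#' @param genes Gene tibble mapping genes to elements.
#' @param thresholds A [homology_thresholds()] object.
#' @return The filtered hit tibble, with `query_element` and
#'   `target_element` columns added.
#' @export
filter_hits <- function(hits, genes, thresholds = homology_thresholds()) {
  el <- stats::setNames(genes$element_id, genes$gene_id)
  unknown <- setdiff(unique(c(hits$query_gene, hits$target_gene)),
                     genes$gene_id)
  if (length(unknown) > 0)
    abort(paste0("hits reference unknown gene_id: ",
                 paste(head(unknown, 5), collapse = ", ")))
  hits |>
    dplyr::mutate(query_element = unname(el[.data$query_gene]),
                  target_element = unname(el[.data$target_gene])) |>
    dplyr::filter(
      .data$query_element != .data$target_element,
      .data$evalue < thresholds$max_evalue,
      .data$identity > thresholds$min_identity,
      .data$coverage_query >= thresholds$min_coverage_both,
      .data$coverage_target >= thresholds$min_coverage_both
    )
}

#' Extract bidirectional best hits between every element pair
#'
#' For each unordered pair of elements (A, B), gene `a` in A and gene `b` in
#' B form a BBH when each is the other's best hit among the partner
#' element's genes. Hits are first symmetrised over direction: an unordered
#' gene pair is scored by its maximum reported bitscore, and its identity is
#' the mean over the reported directions. "Best" means highest bitscore,
#' ties broken by higher identity and then by lexicographically smaller
#' partner gene id.
#'
#' @param hits Filtered hit tibble from [filter_hits()] (must carry
#'   `query_element`/`target_element`).
#' @return A tibble of BBH pairs with canonical `gene_a < gene_b` ordering:
#'   columns `gene_a`, `gene_b`, `element_a`, `element_b`, `identity`,
#'   `coverage_a`, `coverage_b`.
#' @export
extract_bbh <- function(hits) {
  if (nrow(hits) == 0) return(empty_bbh())
  flip <- hits$query_gene > hits$target_gene
  pairs <- tibble::tibble(
    gene_a = ifelse(flip, hits$target_gene, hits$query_gene),
    gene_b = ifelse(flip, hits$query_gene, hits$target_gene),
    element_a = ifelse(flip, hits$target_element, hits$query_element),
    element_b = ifelse(flip, hits$query_element, hits$target_element),
    identity = hits$identity,
    cov_a = ifelse(flip, hits$coverage_target, hits$coverage_query),
    cov_b = ifelse(flip, hits$coverage_query, hits$coverage_target),
    bitscore = hits$bitscore
  )
  # symmetrise: one record per unordered gene pair
  sym <- pairs |>
    dplyr::summarise(
      identity = mean(.data$identity),
      coverage_a = mean(.data$cov_a),
      coverage_b = mean(.data$cov_b),
      bitscore = max(.data$bitscore),
      .by = c("gene_a", "gene_b", "element_a", "element_b")
    )
  # directed view: each unordered pair seen from both genes
  fwd <- sym |>
    dplyr::transmute(gene = .data$gene_a, partner = .data$gene_b,
                     partner_element = .data$element_b,
                     identity = .data$identity, bitscore = .data$bitscore)
  rev <- sym |>
    dplyr::transmute(gene = .data$gene_b, partner = .data$gene_a,
                     partner_element = .data$element_a,
                     identity = .data$identity, bitscore = .data$bitscore)
  best <- dplyr::bind_rows(fwd, rev) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), dplyr::desc(.data$identity),
                   .data$partner) |>
    dplyr::distinct(.data$gene, .data$partner_element, .keep_all = TRUE)
  best_of <- stats::setNames(best$partner,
                             paste(best$gene, best$partner_element,
                                   sep = "\r"))
  mutual <- sym$gene_b ==
    unname(best_of[paste(sym$gene_a, sym$element_b, sep = "\r")]) &
    sym$gene_a ==
    unname(best_of[paste(sym$gene_b, sym$element_a, sep = "\r")])
  sym[which(mutual), ] |>
    dplyr::select("gene_a", "gene_b", "element_a", "element_b",
                  "identity", "coverage_a", "coverage_b") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

empty_bbh <- function() {
  tibble::tibble(gene_a = character(), gene_b = character(),
                 element_a = character(), element_b = character(),
                 identity = double(), coverage_a = double(),
                 coverage_b = double())
}

#' Compute weighted gene repertoire relatedness (wGRR)
#'
#' For two elements A and B with P bidirectional best hits,
#' `wGRR(A,B) = sum_i id(A_i, B_i) / min(#A, #B)`,
#' where `#A`, `#B` are the elements' gene counts. The index is 0 for pairs
#' without BBHs (such pairs are omitted from the sparse result) and 1 for
#' identical elements.
#'
#' @param bbh BBH tibble from [extract_bbh()].
#' @param elements Element tibble supplying `n_genes`.
#' @return A tibble with columns `element_a`, `element_b` (lexicographic
#'   `a < b`), `wgrr` and `n_bbh`; absent pairs have wGRR 0.
#' @export
compute_wgrr <- function(bbh, elements) {
  if (any(elements$n_genes <= 0))
    abort("wGRR undefined for elements with zero genes")
  ng <- stats::setNames(elements$n_genes, elements$element_id)
  out <- bbh |>
    dplyr::summarise(sum_id = sum(.data$identity), n_bbh = dplyr::n(),
                     .by = c("element_a", "element_b")) |>
    dplyr::mutate(
      wgrr = .data$sum_id /
        pmin(unname(ng[.data$element_a]), unname(ng[.data$element_b]))
    ) |>
    dplyr::select("element_a", "element_b", "wgrr", "n_bbh")
  flip <- out$element_a > out$element_b
  tmp <- out$element_a[flip]
  out$element_a[flip] <- out$element_b[flip]
  out$element_b[flip] <- tmp
  out <- dplyr::arrange(out, .data$element_a, .data$element_b)
  if (any(out$wgrr > 1 + 1e-12))
    abort("wGRR exceeded 1; inconsistent BBH set or gene counts")
  out$wgrr <- pmin(out$wgrr, 1)
  out
}

#' Look up wGRR values for element pairs (absent pairs are 0)
#'
#' @param wgrr wGRR tibble from [compute_wgrr()].
#' @param element_a,element_b Character vectors of element ids.
#' @return Numeric vector of wGRR values.
#' @export
wgrr_lookup <- function(wgrr, element_a, element_b) {
  lo <- pmin(element_a, element_b)
  hi <- pmax(element_a, element_b)
  key <- paste(lo, hi, sep = "\r")
  tab <- stats::setNames(wgrr$wgrr, paste(wgrr$element_a, wgrr$element_b,
                                          sep = "\r"))
  v <- unname(tab[key])
  v[is.na(v)] <- 0
  v
}

#' Mean wGRR network between element groups
#'
#' Aggregates element-level wGRR to group level: the weight of edge (G1, G2)
#' is the sum of wGRR over all member pairs divided by the total number of
#' inter-group pairs (absent wGRR entries count as 0). Edges with mean wGRR
#' at or below `edge_threshold` are dropped. Ungrouped (singleton) elements
#' are excluded.
#'
#' @param wgrr wGRR tibble from [compute_wgrr()].
#' @param elements Element tibble with `group_label` (NA = singleton).
#' @param edge_threshold Minimum mean wGRR (strict `>`) for an edge.
#'   Default `0.025`.
#' @return An object of class `mge_group_graph`: list with tibbles `nodes`
#'   (`group_label`, `n_elements`, `mge_type`) and `edges` (`group_a`,
#'   `group_b`, `mean_wgrr`).
#' @export
group_mean_wgrr <- function(wgrr, elements, edge_threshold = 0.025) {
  grouped <- elements |> dplyr::filter(!is.na(.data$group_label))
  if (nrow(grouped) == 0) abort("no grouped elements")
  sizes <- dplyr::count(grouped, .data$group_label, name = "n_elements")
  if (any(sizes$n_elements == 0)) abort("group with zero members")
  nodes <- grouped |>
    dplyr::summarise(
      n_elements = dplyr::n(),
      mge_type = names(sort(table(.data$mge_type), decreasing = TRUE))[1],
      .by = "group_label"
    ) |>
    dplyr::arrange(.data$group_label)
  grp <- stats::setNames(grouped$group_label, grouped$element_id)
  w <- wgrr |>
    dplyr::mutate(group_a = unname(grp[.data$element_a]),
                  group_b = unname(grp[.data$element_b])) |>
    dplyr::filter(!is.na(.data$group_a), !is.na(.data$group_b),
                  .data$group_a != .data$group_b)
  if (nrow(w) > 0) {
    flip <- w$group_a > w$group_b
    tmp <- w$group_a[flip]
    w$group_a[flip] <- w$group_b[flip]
    w$group_b[flip] <- tmp
    sums <- w |>
      dplyr::summarise(sum_wgrr = sum(.data$wgrr),
                       .by = c("group_a", "group_b"))
  } else {
    sums <- tibble::tibble(group_a = character(), group_b = character(),
                           sum_wgrr = double())
  }
  n_of <- stats::setNames(sizes$n_elements, sizes$group_label)
  edges <- sums |>
    dplyr::mutate(mean_wgrr = .data$sum_wgrr /
                    (unname(n_of[.data$group_a]) * unname(n_of[.data$group_b]))) |>
    dplyr::filter(.data$mean_wgrr > edge_threshold) |>
    dplyr::select("group_a", "group_b", "mean_wgrr") |>
    dplyr::arrange(.data$group_a, .data$group_b)
  structure(list(nodes = nodes, edges = edges,
                 edge_threshold = edge_threshold),
            class = "mge_group_graph")
}

#' @export
print.mge_group_graph <- function(x, ...) {
  cat("<mge_group_graph>", nrow(x$nodes), "groups,", nrow(x$edges),
      "edges (mean wGRR >", x$edge_threshold, ")\n")
  invisible(x)
}
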