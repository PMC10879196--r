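#' Full pipeline configuration
#'
#' Bundles every stage's thresholds, with defaults reproducing the standard
#' analysis: homology filter 1e-4 / 0.35 / 0.50, recombining-gene detection
#' 0.80 / 0.80 / wGRR 0.10 / 25-exchange pair exclusion, family clustering
#' at inclusive 0.80 / 0.80, group-graph edge threshold 0.025, relatedness
#' screen at wGRR 0.1 with 10 homologs, close-relative cutoff 0.75 and
#' persistent-genome threshold 0.9.
#'
#' @param homology A [homology_thresholds()] object.
#' @param rg An [rg_thresholds()] object.
#' @param family A [family_thresholds()] object.
#' @param edge_threshold Group-graph edge threshold.
#' @param n_permutations Permutations for the exchange null.
#' @param alternative Fisher test sidedness.
#' @param screen_min_wgrr,screen_min_homologs Relatedness-screen cutoffs.
#' @param close_min_fraction Close-relative conservation cutoff.
#' @param persistent_t Persistent-genome presence threshold.
#' @param seed Integer seed for stochastic stages.
#' @return A list of class `mge_pipeline_config`.
#' @export
pipeline_config <- function(homology = homology_thresholds(),
                            rg = rg_thresholds(),
                            family = family_thresholds(),
                            edge_threshold = 0.025,
                            n_permutations = 100,
                            alternative = "two.sided",
                            screen_min_wgrr = 0.1,
                            screen_min_homologs = 10,
                            close_min_fraction = 0.75,
                            persistent_t = 0.9,
                            seed = 1729) {
  structure(as.list(environment()), class = "mge_pipeline_config")
}

#' Run the gene-flow analysis on in-memory tables
#'
#' Executes homology filtering, BBH extraction, wGRR, group graph,
#' recombining-gene detection with pair exclusion, family clustering,
#' exchange-type counting, the permutation null, flow-scope and adjacency
#' classification, and (when annotations are given) per-track enrichment.
#'
#' @param elements,genes Element and gene tibbles (validated).
#' @param hits Homology-hit tibble from [read_alignment_table()] /
#'   [hits_from_m8()].
#' @param annotations Optional annotation tibble.
#' @param config A [pipeline_config()].
#' @return A list of class `mge_result` holding every stage output:
#'   `filtered_hits`, `bbh`, `wgrr`, `group_graph`, `rg_pairs`,
#'   `excluded_pairs`, `classification`, `rg_fractions`, `families`,
#'   `exchange_counts`, `null_calibration`, `flow_scope`, `adjacency`,
#'   `enrichment` (NULL without annotations), and `config`.
#' @export
run_gene_flow <- function(elements, genes, hits, annotations = NULL,
                          config = pipeline_config()) {
  validate_collection(elements, genes)
  fh <- filter_hits(hits, genes, config$homology)
  bbh <- extract_bbh(fh)
  wgrr <- compute_wgrr(bbh, elements)
  gg <- if (any(!is.na(elements$group_label)))
    group_mean_wgrr(wgrr, elements, config$edge_threshold) else NULL
  rg0 <- identify_rg_pairs(bbh, wgrr, config$rg)
  excl <- apply_pair_exclusion(rg0, config$rg$max_pair_exchanges)
  cls <- classify_genes(genes, fh, excl$kept)
  fams <- cluster_rg_families(cls, fh, config$family)
  counts <- suppressWarnings(count_exchange_types(fams, genes, elements))
  null <- permutation_null(fams, genes, elements,
                           n_permutations = config$n_permutations,
                           seed = config$seed)
  scope <- classify_flow_scope(excl$kept, elements)
  adj <- classify_adjacency(cls, genes, elements)
  enr <- if (!is.null(annotations) && nrow(annotations) > 0) {
    dplyr::bind_rows(
      dplyr::mutate(test_enrichment(cls, annotations,
                                    grouping = "rg_vs_nrg",
                                    alternative = config$alternative),
                    grouping = "rg_vs_nrg"),
      if (nrow(scope) > 0 && dplyr::n_distinct(scope$scope) == 2)
        dplyr::mutate(test_enrichment(cls, annotations,
                                      grouping = "bmge_vs_wmge",
                                      flow_scope = scope,
                                      alternative = config$alternative),
                      grouping = "bmge_vs_wmge")
    )
  } else NULL
  structure(
    list(filtered_hits = fh, bbh = bbh, wgrr = wgrr, group_graph = gg,
         rg_pairs = excl$kept, excluded_pairs = excl$excluded_pairs,
         classification = cls, rg_fractions = rg_fractions(cls, elements),
         families = fams, exchange_counts = counts, null_calibration = null,
         flow_scope = scope, adjacency = adj, enrichment = enr,
         config = config),
    class = "mge_result"
  )
}

#' @export
print.mge_result <- function(x, ...) {
  cat("<mge_result>\n",
      " ", nrow(x$classification), "genes:",
      sum(x$classification$label == "RG"), "RG,",
      sum(x$classification$label == "NRG"), "NRG,",
      sum(x$classification$label == "NRG_nh"), "NRG-nh\n",
      " ", nrow(x$families |> dplyr::distinct(.data$family_id)),
      "RG families;", nrow(x$rg_pairs), "RG pairs;",
      nrow(x$excluded_pairs), "excluded element pairs\n")
  invisible(x)
}

#' Run the full pipeline from files and write every output table
#'
#' Reads the element, gene, alignment and (optional) annotation tables,
#' runs [run_gene_flow()], and writes the result bundle as deterministic
#' TSVs, each carrying a header comment with the tool version, a
#' configuration hash and the seed.
#'
#' @param element_path,gene_path,alignment_path,annotation_path Input
#'   paths; `annotation_path` may be NULL.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, the `mge_result` bundle; side effect: TSV files in
#'   `out_dir`.
#' @export
run_full_pipeline <- function(element_path, gene_path, alignment_path,
                              annotation_path = NULL, out_dir,
                              config = pipeline_config()) {
  for (p in c(element_path, gene_path, alignment_path, annotation_path)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  coll <- read_element_and_gene_tables(element_path, gene_path)
  hits <- read_alignment_table(alignment_path, coll$genes)
  ann <- if (!is.null(annotation_path)) read_annotation_table(annotation_path)
  res <- run_gene_flow(coll$elements, coll$genes, hits, ann, config)
  write_result(res, out_dir)
  invisible(res)
}

#' Write an `mge_result` bundle as TSV tables
#'
#' @param res An `mge_result` from [run_gene_flow()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    paste0("mgeflow ", as.character(utils::packageVersion("mgeflow"))),
    paste0("config_hash=", rlang::hash(res$config)),
    paste0("seed=", res$config$seed)
  )
  out <- function(x, name) {
    write_mge_tsv(x, file.path(out_dir, name), comment = hdr)
  }
  paths <- c(
    out(res$wgrr, "wgrr.tsv"),
    out(res$rg_pairs, "rg_pairs.tsv"),
    out(res$excluded_pairs, "excluded_pairs.tsv"),
    out(res$classification, "classification.tsv"),
    out(res$rg_fractions, "rg_fractions.tsv"),
    out(res$families, "families.tsv"),
    out(res$exchange_counts, "exchange_counts.tsv"),
    out(res$null_calibration$summary, "null_calibration.tsv"),
    out(res$flow_scope, "flow_scope.tsv"),
    out(res$adjacency, "adjacency.tsv")
  )
  if (!is.null(res$group_graph)) {
    paths <- c(paths, out(res$group_graph$edges, "group_graph.tsv"))
  }
  if (!is.null(res$enrichment)) {
    paths <- c(paths, out(res$enrichment, "enrichment.tsv"))
  }
  invisible(paths)
}
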