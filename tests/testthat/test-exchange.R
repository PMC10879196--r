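fam_as_list <- function(families) {
  unname(lapply(split(families$gene_id, families$family_id), sort))
}

cls_for <- function(rg_ids, genes) {
  tibble::tibble(gene_id = genes$gene_id, element_id = genes$element_id,
                 label = ifelse(genes$gene_id %in% rg_ids, "RG", "NRG"),
                 n_rg_partners = 0L)
}

test_that("transitive 80/80 similarity merges RGs into one family", {
  elements <- toy_elements(c(A = 3L, B = 3L, C = 3L))
  genes <- toy_genes(elements)
  hits <- dplyr::bind_rows(
    sym_hit("a1", "b1", 0.85),
    sym_hit("b1", "c1", 0.85),
    sym_hit("a1", "c1", 0.60)  # below family threshold
  )
  fams <- cluster_rg_families(cls_for(c("a1", "b1", "c1"), genes),
                              filter_hits(hits, genes))
  expect_equal(fam_as_list(fams), list(c("a1", "b1", "c1")))
})

test_that("family edges are inclusive at 0.80 while RG detection is strict", {
  elements <- toy_elements(c(A = 2L, B = 2L))
  genes <- toy_genes(elements)
  hits <- sym_hit("a1", "b1", 0.80, cov_q = 0.80, cov_t = 0.80)
  fams <- cluster_rg_families(cls_for(c("a1", "b1"), genes),
                              filter_hits(hits, genes))
  expect_equal(fam_as_list(fams), list(c("a1", "b1")))
})

test_that("disjoint RG pairs yield separate, deterministically named families", {
  elements <- toy_elements(c(A = 4L, B = 4L))
  genes <- toy_genes(elements)
  hits <- dplyr::bind_rows(sym_hit("a1", "b1", 0.9), sym_hit("a2", "b2", 0.9))
  fams <- cluster_rg_families(cls_for(c("a1", "b1", "a2", "b2"), genes),
                              filter_hits(hits, genes))
  expect_equal(fam_as_list(fams), list(c("a1", "b1"), c("a2", "b2")))
  expect_equal(unique(fams$family_id), c("RGF00001", "RGF00002"))
})

test_that("single-linkage families equal a BFS connected-components oracle", {
  withr::with_seed(314, {
    for (rep in 1:30) {
      n <- sample(5:50, 1)
      elements <- toy_elements(stats::setNames(rep(1L, n),
                                               sprintf("E%02d", 1:n)))
      genes <- toy_genes(elements)
      ids <- genes$gene_id
      n_edges <- sample(0:(2 * n), 1)
      ea <- sample(ids, n_edges, replace = TRUE)
      eb <- sample(ids, n_edges, replace = TRUE)
      keep <- ea != eb
      hits <- if (sum(keep) > 0) {
        purrr::map2(ea[keep], eb[keep],
                    function(a, b) sym_hit(a, b, 0.9)) |>
          purrr::list_rbind()
      } else {
        hit(character(0), character(0), double(0))
      }
      fh <- filter_hits(hits, genes)
      fams <- cluster_rg_families(cls_for(ids, genes), fh)
      expect_equal(fam_as_list(fams),
                   components_oracle(sort(ids), fh$query_gene, fh$target_gene))
    }
  })
})

test_that("exchange counting follows the worked 4-plasmid/2-P-P example", {
  elements <- toy_elements(
    stats::setNames(rep(1L, 6), sprintf("E%d", 1:6)),
    types = c(rep("plasmid", 4), rep("phage_plasmid", 2))
  )
  genes <- toy_genes(elements)
  fams <- tibble::tibble(family_id = "RGF00001", gene_id = genes$gene_id)
  counts <- count_exchange_types(fams, genes, elements)
  got <- stats::setNames(counts$n_families, counts$exchange_type)
  expect_equal(got[["plasmid-plasmid"]], 1L)
  expect_equal(got[["phage_plasmid-phage_plasmid"]], 1L)
  expect_equal(got[["phage_plasmid-plasmid"]], 1L)
  expect_equal(got[["phage-phage"]], 0L)
  expect_equal(got[["phage-plasmid"]], 0L)
  expect_equal(got[["phage-phage_plasmid"]], 0L)
})

test_that("families confined to one element contribute nothing, with warning", {
  elements <- toy_elements(c(A = 2L), types = "plasmid")
  genes <- toy_genes(elements)
  fams <- tibble::tibble(family_id = "RGF00001", gene_id = c("a1", "a2"))
  expect_warning(counts <- count_exchange_types(fams, genes, elements),
                 "single element")
  expect_true(all(counts$n_families == 0))
})

test_that("a phage-plasmid family counts only the between-type exchange", {
  elements <- toy_elements(c(A = 1L, B = 1L), types = c("phage", "plasmid"))
  genes <- toy_genes(elements)
  fams <- tibble::tibble(family_id = "RGF00001", gene_id = c("a1", "b1"))
  counts <- count_exchange_types(fams, genes, elements)
  expect_equal(sum(counts$n_families), 1L)
  expect_equal(counts$n_families[counts$exchange_type == "phage-plasmid"], 1L)
})

test_that("permutations preserve the label multiset and reproduce with a seed", {
  tb <- simulate_type_blind_families(n_per_type = c(10, 15, 5),
                                     n_families = 40, seed = 3)
  null1 <- permutation_null(tb$families, tb$genes, tb$elements,
                            n_permutations = 20, seed = 77)
  null2 <- permutation_null(tb$families, tb$genes, tb$elements,
                            n_permutations = 20, seed = 77)
  expect_identical(null1$permuted, null2$permuted)
  expect_identical(tidy(null1), tidy(null2))
  # sum of per-family presences equals each counter (no double counting)
  per_fam <- split(tb$families$gene_id, tb$families$family_id)
  expect_equal(sum(tidy(null1)$observed),
               sum(vapply(per_fam, function(g) {
                 el <- tb$genes$element_id[match(g, tb$genes$gene_id)]
                 tp <- tb$elements$mge_type[match(unique(el),
                                                  tb$elements$element_id)]
                 tt <- table(tp)
                 sum(tt >= 2) + choose(length(tt), 2)
               }, numeric(1))))
})

test_that("with a single element type the null ratio is exactly 1", {
  elements <- toy_elements(c(A = 1L, B = 1L, C = 1L),
                           types = rep("plasmid", 3))
  genes <- toy_genes(elements)
  fams <- tibble::tibble(family_id = "RGF00001",
                         gene_id = c("a1", "b1", "c1"))
  null <- permutation_null(fams, genes, elements, n_permutations = 10,
                           seed = 1)
  s <- tidy(null)
  expect_equal(s$ratio[s$exchange_type == "plasmid-plasmid"], 1)
  expect_equal(s$observed[s$exchange_type == "plasmid-plasmid"], 1L)
})
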