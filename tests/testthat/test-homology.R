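make_filtered <- function(hits, genes) filter_hits(hits, genes)

test_that("hit filtering applies the e-value, identity and coverage gates", {
  genes <- toy_genes(toy_elements(c(A = 2L, B = 2L)))
  hits <- dplyr::bind_rows(
    hit("a1", "b1", 0.40, 0.6, 0.6),          # retained
    hit("a1", "b2", 0.35, 0.9, 0.9),          # identity not strictly above
    hit("a2", "b1", 0.90, 0.49, 0.9),         # one coverage below 0.5
    hit("a2", "b2", 0.90, evalue = 1e-3),     # e-value too large
    hit("a1", "a2", 0.99)                     # intra-element
  )
  kept <- filter_hits(hits, genes)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$query_gene, "a1")
  expect_equal(kept$target_gene, "b1")
})

test_that("reciprocal best hits require mutual best in both directions", {
  genes <- toy_genes(toy_elements(c(A = 2L, B = 2L)))
  # a1's best in B is b1, and b1's best in A is a1 -> BBH;
  # a2's best is b1 too, but b1 prefers a1 -> no pair containing a2
  hits <- dplyr::bind_rows(
    hit("a1", "b1", 0.9, bitscore = 300),
    hit("a2", "b1", 0.8, bitscore = 250),
    hit("a2", "b2", 0.5, bitscore = 100)
  )
  bbh <- extract_bbh(make_filtered(hits, genes))
  expect_equal(bbh$gene_a, "a1")
  expect_equal(bbh$gene_b, "b1")
})

test_that("bitscore ties break by identity then lexicographic partner id", {
  genes <- toy_genes(toy_elements(c(A = 1L, B = 3L)))
  hits <- dplyr::bind_rows(
    hit("a1", "b2", 0.80, bitscore = 200),
    hit("a1", "b1", 0.90, bitscore = 200),  # same bitscore, higher identity
    hit("a1", "b3", 0.90, bitscore = 200)   # ties b1 fully except id order
  )
  bbh <- extract_bbh(make_filtered(hits, genes))
  expect_equal(bbh$gene_b, "b1")
})

test_that("BBH identity averages the two reported directions", {
  genes <- toy_genes(toy_elements(c(A = 1L, B = 1L)))
  hits <- dplyr::bind_rows(hit("a1", "b1", 0.90), hit("b1", "a1", 0.80))
  bbh <- extract_bbh(make_filtered(hits, genes))
  expect_equal(bbh$identity, 0.85)
})

test_that("extract_bbh matches the brute-force reciprocal-argmax oracle", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      na <- sample(2:20, 1)
      nb <- sample(2:20, 1)
      elements <- toy_elements(c(A = na, B = nb))
      genes <- toy_genes(elements)
      hits <- random_hit_table(na, nb)
      fh <- make_filtered(hits, genes)
      got <- extract_bbh(fh)
      want <- bbh_oracle(fh, genes)
      expect_equal(got[, c("gene_a", "gene_b", "identity")], want)
      expect_lte(nrow(got), min(na, nb))
      if (nrow(fh) > 0) expect_gt(nrow(got), 0)
    }
  })
})

test_that("wGRR reproduces the hand-computed toy value", {
  elements <- toy_elements(c(A = 4L, B = 6L))
  bbh <- tibble::tibble(
    gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
    element_a = "A", element_b = "B",
    identity = c(0.90, 0.80), coverage_a = 1, coverage_b = 1
  )
  w <- compute_wgrr(bbh, elements)
  expect_equal(w$wgrr, (0.90 + 0.80) / 4)  # 0.425
  expect_equal(w$n_bbh, 2L)
})

test_that("wGRR of an element against an identical copy is exactly 1", {
  elements <- toy_elements(c(A = 5L, B = 5L))
  genes <- toy_genes(elements)
  hits <- purrr::map(1:5, function(i)
    sym_hit(sprintf("a%d", i), sprintf("b%d", i), 1.0, bitscore = 500)
  ) |> purrr::list_rbind()
  bbh <- extract_bbh(make_filtered(hits, genes))
  w <- compute_wgrr(bbh, elements)
  expect_identical(w$wgrr, 1)
})

test_that("wGRR is bounded, symmetric in its key and 0 when BBHs are absent", {
  sim <- simulate_mge_collection(simulation_config(
    n_phage = 6, n_plasmid = 6, n_pp = 3, group_size = 3,
    n_planted_transfers = 5, seed = 7
  ))
  fh <- filter_hits(hits_from_m8(sim$alignment, sim$genes), sim$genes)
  w <- compute_wgrr(extract_bbh(fh), sim$elements)
  expect_true(all(w$wgrr >= 0 & w$wgrr <= 1))
  # canonical key ordering makes symmetry structural; lookup honours both
  expect_true(all(w$element_a < w$element_b))
  expect_equal(wgrr_lookup(w, w$element_b[1], w$element_a[1]), w$wgrr[1])
  expect_equal(wgrr_lookup(w, "nope", "nothere"), 0)
})

test_that("removing a hit never increases wGRR", {
  withr::with_seed(99, {
    elements <- toy_elements(c(A = 8L, B = 8L))
    genes <- toy_genes(elements)
    hits <- random_hit_table(8, 8, density = 0.7)
    fh <- make_filtered(hits, genes)
    w_full <- compute_wgrr(extract_bbh(fh), elements)
    for (drop in sample(nrow(fh), 5)) {
      w_less <- compute_wgrr(extract_bbh(fh[-drop, ]), elements)
      expect_lte(wgrr_lookup(w_less, "A", "B"), wgrr_lookup(w_full, "A", "B"))
    }
  })
})

test_that("group graph averages over all inter-group pairs, zeros included", {
  elements <- toy_elements(c(A1 = 5L, A2 = 5L, B1 = 5L),
                           groups = c("ga", "ga", "gb"))
  wgrr <- tibble::tibble(element_a = "A1", element_b = "B1",
                         wgrr = 0.2, n_bbh = 2L)
  gg <- group_mean_wgrr(wgrr, elements, edge_threshold = 0.025)
  expect_equal(gg$edges$mean_wgrr, 0.1)  # (0.2 + 0) / 2 pairs
  expect_equal(nrow(gg$nodes), 2)

  # below threshold: no edge
  gg2 <- group_mean_wgrr(wgrr, elements, edge_threshold = 0.15)
  expect_equal(nrow(gg2$edges), 0)

  # single group: one node, no edges
  solo <- toy_elements(c(A1 = 5L), groups = "ga")
  gg3 <- group_mean_wgrr(wgrr[0, ], solo)
  expect_equal(nrow(gg3$nodes), 1)
  expect_equal(nrow(gg3$edges), 0)
})

test_that("singleton elements are excluded from the group graph only", {
  elements <- toy_elements(c(A1 = 5L, A2 = 5L, S = 5L),
                           groups = c("ga", "ga", NA))
  wgrr <- tibble::tibble(element_a = c("A1", "A1"),
                         element_b = c("A2", "S"),
                         wgrr = c(0.5, 0.9), n_bbh = c(3L, 4L))
  gg <- group_mean_wgrr(wgrr, elements)
  expect_false("S" %in% gg$nodes$group_label)
  expect_equal(nrow(gg$edges), 0)  # only intra-group wGRR present
  expect_equal(wgrr_lookup(wgrr, "A1", "S"), 0.9)
})
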