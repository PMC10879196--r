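test_that("difference-sum ratio reproduces the worked examples and bounds", {
  expect_equal(round(diff_sum_ratio(8.60, 3.01), 2), 0.48)
  expect_equal(round(diff_sum_ratio(1.87, 3.01), 2), -0.23)
  expect_equal(diff_sum_ratio(5, 5), 0)
  # antisymmetry and bounds on a grid
  o <- c(0, 0.5, 1, 7, 100)
  e <- c(1, 2, 0.1, 7, 3)
  expect_equal(diff_sum_ratio(o, e), -diff_sum_ratio(e, o))
  expect_true(all(abs(diff_sum_ratio(o, e)) <= 1))
  expect_warning(r <- diff_sum_ratio(0, 0), "undefined")
  expect_true(is.na(r))
})

test_that("contingency tables count annotated genes exactly", {
  gg <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    group = rep(c("RG", "NRG"), c(10, 90))
  )
  ann <- tibble::tibble(
    track = "fn",
    gene_id = c(sprintf("g%03d", 1:3), sprintf("g%03d", 11:17), "g099"),
    category = c(rep("defense", 10), "metabolism")
  )
  tb <- build_contingency(gg, ann, "defense", "fn")
  expect_equal(unname(tb$table["in_category", "RG"]), 3L)
  expect_equal(unname(tb$table["in_category", "NRG"]), 7L)
  expect_equal(unname(tb$table["out_of_category", "RG"]), 7L)
  expect_equal(unname(tb$table["out_of_category", "NRG"]), 83L)
  expect_error(build_contingency(gg, ann, "nonexistent", "fn"),
               "available")
  expect_error(build_contingency(gg, ann, "defense", "ghost_track"),
               "unknown track")
})

test_that("Fisher p matches hypergeometric enumeration to 1e-10", {
  withr::with_seed(2024, {
    for (rep in 1:60) {
      m <- matrix(sample(0:50, 4, replace = TRUE), 2, 2,
                  dimnames = list(c("in_category", "out_of_category"),
                                  c("G1", "G2")))
      tb <- structure(list(table = m, category = "x", track = "t",
                           groups = c("G1", "G2")),
                      class = "mge_contingency")
      res <- fisher_bh(tb)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        expect_equal(res$p, 1)
      } else {
        expect_equal(res$p, fisher_oracle_two_sided(m), tolerance = 1e-10)
      }
    }
  })
})

test_that("a balanced table gives p = 1 and a zero margin is flagged", {
  m <- matrix(c(5L, 5L, 5L, 5L), 2, 2,
              dimnames = list(c("in_category", "out_of_category"),
                              c("G1", "G2")))
  tb <- structure(list(table = m, category = "x", track = "t",
                       groups = c("G1", "G2")), class = "mge_contingency")
  expect_equal(fisher_bh(tb)$p, 1)
  m0 <- m; m0["in_category", ] <- 0L
  tb0 <- structure(list(table = m0, category = "x", track = "t",
                        groups = c("G1", "G2")), class = "mge_contingency")
  r0 <- fisher_bh(tb0)
  expect_equal(r0$p, 1)
  expect_true(r0$zero_margin)
})

test_that("BH adjustment matches the hand example and never shrinks below p", {
  ps <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(ps, "BH"), c(0.03, 0.03, 0.04))
  withr::with_seed(8, {
    ps <- runif(20)
    qs <- p.adjust(ps, "BH")
    expect_true(all(qs >= ps))
    ord <- order(ps)
    expect_true(all(diff(qs[ord]) >= -1e-15))
  })
})

test_that("enrichment direction agrees with the difference-sum sign", {
  withr::with_seed(77, {
    gg <- tibble::tibble(gene_id = sprintf("g%04d", 1:600),
                         group = rep(c("RG", "NRG"), c(100, 500)))
    # plant strong enrichment of 'defense' among RG
    ann <- tibble::tibble(
      track = "fn",
      gene_id = c(sprintf("g%04d", 1:40),            # 40% of RG
                  sprintf("g%04d", 101:120)),        # 4% of NRG
      category = "defense"
    )
    res <- fisher_bh(build_contingency(gg, ann, "defense", "fn"),
                     focal = "RG")
    expect_equal(res$direction, "over")
    expect_gt(res$r_diff_sum, 0)
    expect_equal(res$O, 40)
    expect_equal(res$E_H0, 10)
  })
})

test_that("per-track testing applies BH within each track", {
  cls <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                        element_id = "A",
                        label = rep(c("RG", "NRG"), 20),
                        n_rg_partners = 0L)
  ann <- dplyr::bind_rows(
    tibble::tibble(track = "t1", gene_id = sprintf("g%02d", 1:10),
                   category = rep(c("x", "y"), 5)),
    tibble::tibble(track = "t2", gene_id = sprintf("g%02d", 11:14),
                   category = "z")
  )
  res <- test_enrichment(cls, ann)
  expect_setequal(res$track, c("t1", "t2"))
  for (tr in c("t1", "t2")) {
    sub <- res[res$track == tr, ]
    expect_equal(sub$q, p.adjust(sub$p, "BH"))
  }
})

test_that("flow scope marks cross-type exchangers as bMGE with priority", {
  elements <- toy_elements(c(P1 = 1L, P2 = 1L, P3 = 1L, F1 = 1L),
                           types = c("plasmid", "plasmid", "plasmid",
                                     "phage"))
  rg <- tibble::tibble(
    gene_a = c("p11", "p11", "p21"),
    gene_b = c("p21", "f11", "p31"),
    element_a = c("P1", "P1", "P2"),
    element_b = c("P2", "F1", "P3"),
    identity = 0.9, wgrr = 0.05
  )
  fs <- classify_flow_scope(rg, elements)
  got <- stats::setNames(fs$scope, fs$gene_id)
  expect_equal(got[["p11"]], "bMGE")  # plasmid + phage partners
  expect_equal(got[["f11"]], "bMGE")
  expect_equal(got[["p21"]], "wMGE")  # plasmid partners only
  expect_equal(got[["p31"]], "wMGE")
})

test_that("adjacency classes respect linear ends and circular wraparound", {
  elements <- dplyr::bind_rows(
    toy_elements(c(L = 3L)),                       # linear N-R-N
    toy_elements(c(M = 2L)) |> dplyr::mutate(),    # linear R-R
    toy_elements(c(O = 3L)) |>
      dplyr::mutate(topology = "circular")         # circular R-N-N
  )
  genes <- toy_genes(elements)
  cls <- tibble::tibble(
    gene_id = genes$gene_id,
    element_id = genes$element_id,
    label = c("NRG", "RG", "NRG",    # L: N R N
              "RG", "RG",            # M: R R
              "RG", "NRG", "NRG"),   # O circular: R N N
    n_rg_partners = 0L
  )
  adj <- classify_adjacency(cls, genes, elements)
  got <- stats::setNames(adj$adjacency_class, adj$gene_id)
  expect_equal(got[["l2"]], "single_RG")
  expect_equal(got[["l1"]], "NRG_flanking_RG")
  expect_equal(got[["l3"]], "NRG_flanking_RG")
  expect_equal(got[["m1"]], "RG_adjacent_to_RG")
  expect_equal(got[["m2"]], "RG_adjacent_to_RG")
  # both circular neighbours flank via wraparound
  expect_equal(got[["o2"]], "NRG_flanking_RG")
  expect_equal(got[["o3"]], "NRG_flanking_RG")
  expect_equal(got[["o1"]], "single_RG")
})
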