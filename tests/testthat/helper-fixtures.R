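# Shared in-code fixtures: tiny element/gene/hit tables built by hand.

toy_elements <- function(n_genes = c(A = 4L, B = 6L, C = 3L),
                         types = NULL, groups = NULL) {
  ids <- names(n_genes)
  tibble::tibble(
    element_id = ids,
    mge_type = types %||% rep("plasmid", length(ids)),
    group_label = groups %||% rep(NA_character_, length(ids)),
    n_genes = unname(n_genes),
    topology = rep("linear", length(ids))
  )
}

toy_genes <- function(elements, protein_length = 100L) {
  purrr::map(seq_len(nrow(elements)), function(i) {
    n <- elements$n_genes[i]
    tibble::tibble(
      gene_id = sprintf("%s%d", tolower(elements$element_id[i]), seq_len(n)),
      element_id = elements$element_id[i],
      position = seq_len(n) - 1L,
      protein_length = protein_length
    )
  }) |> purrr::list_rbind()
}

# A hit row in the internal (already-parsed) representation; symmetric
# coverages default to 1.
hit <- function(q, t, identity, cov_q = 1, cov_t = 1, evalue = 1e-50,
                bitscore = round(200 * identity)) {
  tibble::tibble(query_gene = q, target_gene = t, identity = identity,
                 coverage_query = cov_q, coverage_target = cov_t,
                 evalue = evalue, bitscore = bitscore)
}

# Both directions of a symmetric hit.
sym_hit <- function(q, t, identity, cov_q = 1, cov_t = 1, ...) {
  dplyr::bind_rows(hit(q, t, identity, cov_q, cov_t, ...),
                   hit(t, q, identity, cov_t, cov_q, ...))
}

# Random per-element-pair hit tables for BBH oracle checks.
random_hit_table <- function(n_genes_a, n_genes_b, density = 0.5) {
  ga <- sprintf("a%d", seq_len(n_genes_a))
  gb <- sprintf("b%d", seq_len(n_genes_b))
  grid <- expand.grid(q = ga, t = gb, stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < density
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) return(hit(character(0), character(0), double(0))[0, ])
  # integer bitscores force frequent ties to exercise tie-breaking
  tibble::tibble(
    query_gene = grid$q, target_gene = grid$t,
    identity = round(runif(nrow(grid), 0.36, 1), 2),
    coverage_query = 1, coverage_target = 1,
    evalue = 1e-30,
    bitscore = sample(50:60, nrow(grid), replace = TRUE)
  )
}

# Brute-force reciprocal-argmax BBH oracle (independent of extract_bbh):
# plain loops over genes, symmetric candidate set, same tie-break
# definition (max bitscore, then max identity, then smallest partner id).
bbh_oracle <- function(hits, genes) {
  el <- stats::setNames(genes$element_id, genes$gene_id)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cand <- list()
  for (i in seq_len(nrow(hits))) {
    a <- hits$query_gene[i]; b <- hits$target_gene[i]
    k <- key(a, b)
    rec <- cand[[k]]
    if (is.null(rec)) {
      cand[[k]] <- list(a = min(a, b), b = max(a, b),
                        ids = hits$identity[i], bs = hits$bitscore[i])
    } else {
      rec$ids <- c(rec$ids, hits$identity[i])
      rec$bs <- max(rec$bs, hits$bitscore[i])
      cand[[k]] <- rec
    }
  }
  best <- function(gene, partner_element) {
    bests <- NULL
    for (rec in cand) {
      partner <- if (rec$a == gene) rec$b else if (rec$b == gene) rec$a else next
      if (el[[partner]] != partner_element) next
      score <- c(rec$bs, mean(rec$ids))
      if (is.null(bests) || score[1] > bests$score[1] ||
          (score[1] == bests$score[1] && score[2] > bests$score[2]) ||
          (score[1] == bests$score[1] && score[2] == bests$score[2] &&
           partner < bests$partner)) {
        bests <- list(partner = partner, score = score)
      }
    }
    bests$partner
  }
  out <- list()
  for (rec in cand) {
    ea <- el[[rec$a]]; eb <- el[[rec$b]]
    if (ea == eb) next
    if (identical(best(rec$a, eb), rec$b) &&
        identical(best(rec$b, ea), rec$a)) {
      out[[length(out) + 1]] <- tibble::tibble(
        gene_a = rec$a, gene_b = rec$b, identity = mean(rec$ids))
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          identity = double()))
  dplyr::arrange(purrr::list_rbind(out), gene_a, gene_b)
}

# Two-sided Fisher oracle: direct enumeration of the hypergeometric support,
# summing probabilities not exceeding the observed table's (with the usual
# relative-error guard).
fisher_oracle_two_sided <- function(m) {
  x <- m[1, 1]
  k <- sum(m[1, ])   # in-category margin
  n1 <- sum(m[, 1])  # group-1 margin
  n <- sum(m)
  support <- max(0, k - (n - n1)):min(k, n1)
  probs <- stats::dhyper(support, n1, n - n1, k)
  p_obs <- stats::dhyper(x, n1, n - n1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small fully specified collection with one planted transfer and one
# vertically related pair, used across recombination/exchange tests.
toy_flow_fixture <- function() {
  elements <- toy_elements(c(A = 10L, B = 10L, C = 10L),
                           types = c("plasmid", "phage", "phage_plasmid"))
  genes <- toy_genes(elements)
  hits <- dplyr::bind_rows(
    sym_hit("a1", "b1", 0.95),   # planted transfer (low-wGRR pair)
    sym_hit("a2", "c2", 0.60),   # ordinary vertical homolog
    sym_hit("b3", "c3", 0.50)
  )
  list(elements = elements, genes = genes, hits = hits)
}

# independent single-linkage oracle: BFS on an adjacency list
components_oracle <- function(nodes, edges_a, edges_b) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_a)) {
    adj[[edges_a[i]]] <- c(adj[[edges_a[i]]], edges_b[i])
    adj[[edges_b[i]]] <- c(adj[[edges_b[i]]], edges_a[i])
  }
  seen <- character(0)
  comps <- list()
  for (start in sort(nodes)) {
    if (start %in% seen) next
    queue <- start
    comp <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, min, character(1)))]
}

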