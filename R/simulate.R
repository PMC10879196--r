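#' Configuration for a synthetic MGE collection
#'
#' Describes a collection of phages, plasmids and phage-plasmids organised
#' in groups of related elements. Elements within a group share most gene
#' families at high identity (vertical proximity), groups are connected only
#' through a small pool of anciently shared families at sub-threshold
#' identity, and a configurable number of recent transfers is planted
#' between elements of different groups, each transfer introducing a fresh
#' gene family at high identity between an otherwise unrelated pair.
#' Identities are drawn directly rather than evolved on sequences: the
#' analysis consumes only alignment summaries, so direct control keeps the
#' ground truth exact.
#'
#' @param n_phage,n_plasmid,n_pp Elements per type.
#' @param group_size Elements per relatedness group.
#' @param genes_per_element Integer range (min, max) of genes per element
#'   before planted transfers are appended.
#' @param core_families_per_group Size of each group's private core family
#'   pool.
#' @param core_retention Probability that an element retains each core
#'   family of its group.
#' @param n_ancient_families Size of the global pool of anciently shared
#'   families; each group carries `ancient_per_group` of them.
#' @param ancient_per_group Ancient families per group.
#' @param vertical_identity Identity range for cross-group homologs sharing
#'   a family by descent; must stay below the RG identity threshold.
#' @param within_group_identity Identity range for same-group homologs.
#' @param n_planted_transfers Number of planted recent-transfer events.
#' @param transfer_identity Identity range for planted transfer genes.
#' @param block_transfer_prob Probability that an event moves a contiguous
#'   block (transposon-like) rather than a single gene.
#' @param block_length Genes per block transfer; the first gene of each
#'   block is annotated as a transposase.
#' @param coverage_jitter Downward jitter on alignment coverage (0 keeps all
#'   coverages at 1).
#' @param fraction_annotated Fraction of genes receiving a functional
#'   category on the `function` track.
#' @param transfer_category Category enriched among planted transfer genes.
#' @param transfer_category_prob Probability that a transfer gene carries
#'   `transfer_category`.
#' @param max_attempts Generation attempts before giving up when the
#'   post-hoc wGRR constraints cannot be met.
#' @param seed Integer seed.
#' @return A list of class `mge_simulation_config`.
#' @export
simulation_config <- function(n_phage = 30, n_plasmid = 40, n_pp = 20,
                              group_size = 5,
                              genes_per_element = c(30L, 50L),
                              core_families_per_group = 24,
                              core_retention = 0.85,
                              n_ancient_families = 12,
                              ancient_per_group = 2,
                              vertical_identity = c(0.40, 0.75),
                              within_group_identity = c(0.85, 1.0),
                              n_planted_transfers = 50,
                              transfer_identity = c(0.85, 0.99),
                              block_transfer_prob = 0.2,
                              block_length = 2,
                              coverage_jitter = 0,
                              fraction_annotated = 0.3,
                              transfer_category = "defense",
                              transfer_category_prob = 0.5,
                              max_attempts = 20,
                              seed = 1729) {
  stopifnot(n_phage >= 0, n_plasmid >= 0, n_pp >= 0,
            group_size >= 1, length(genes_per_element) == 2,
            genes_per_element[1] >= 5,
            vertical_identity[2] < 0.80,
            within_group_identity[1] > 0.80,
            transfer_identity[1] > 0.80,
            n_planted_transfers >= 0, block_length >= 1)
  structure(as.list(environment()), class = "mge_simulation_config")
}

#' Generate a synthetic MGE collection with planted transfers
#'
#' Produces the exact tabular inputs the pipeline reads — element table,
#' gene table, alignment table in BLAST tabular (m8) dialect, annotation
#' tracks — plus a ground-truth log of every planted transfer event. The
#' generator verifies post hoc, on its own output run through the homology
#' stage, that every same-group element pair has wGRR > 0.1 and every
#' planted donor-recipient pair has wGRR <= 0.1 (with the donor and
#' recipient sharing no background family, so the pre-transfer wGRR is 0);
#' violations trigger regeneration with a derived seed and, past
#' `max_attempts`, an error. This makes downstream sensitivity and
#' false-call assertions exact rather than probabilistic.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mge_simulation` with tibbles `elements`,
#'   `genes`, `alignment` (12-column m8), `annotations`, `truth`, and the
#'   `config`.
#' @export
simulate_mge_collection <- function(config = simulation_config()) {
  for (attempt in seq_len(config$max_attempts)) {
    attempt_seed <- (config$seed + (attempt - 1L) * 131071L) %% .Machine$integer.max
    sim <- withr::with_seed(attempt_seed, generate_once(config))
    ok <- check_simulation(sim, config)
    if (ok) {
      sim$config <- config
      class(sim) <- "mge_simulation"
      return(sim)
    }
  }
  abort(paste0("could not satisfy wGRR constraints after ",
               config$max_attempts, " attempts; the configuration is ",
               "infeasible (e.g. groups too sparse or blocks too long)"))
}

generate_once <- function(cfg) {
  types <- rep(MGE_TYPES[c(1, 2, 3)],
               times = c(cfg$n_phage, cfg$n_plasmid, cfg$n_pp))
  prefix <- c(phage = "PH", plasmid = "PL", phage_plasmid = "PP")
  ids <- unlist(lapply(MGE_TYPES, function(tp) {
    n <- sum(types == tp)
    if (n == 0) character(0) else sprintf("%s%03d", prefix[[tp]], seq_len(n))
  }), use.names = FALSE)
  group_of <- unlist(lapply(MGE_TYPES, function(tp) {
    n <- sum(types == tp)
    if (n == 0) return(character(0))
    sprintf("%sG%02d", prefix[[tp]], ceiling(seq_len(n) / cfg$group_size))
  }), use.names = FALSE)
  elements <- tibble::tibble(
    element_id = ids, mge_type = types, group_label = group_of,
    topology = ifelse(types == "phage", "linear", "circular")
  )
  groups <- unique(group_of)

  # family pools: group-private cores, globally shared ancient families
  ancient_pool <- sprintf("ANC%02d", seq_len(cfg$n_ancient_families))
  fam_counter <- 0L
  group_core <- list()
  group_ancient <- list()
  for (g in groups) {
    group_core[[g]] <- sprintf("FAM%05d",
                               fam_counter + seq_len(cfg$core_families_per_group))
    fam_counter <- fam_counter + cfg$core_families_per_group
    group_ancient[[g]] <- sort(sample(ancient_pool, cfg$ancient_per_group))
  }

  # per-element family content
  fam_len <- new.env(parent = emptyenv())
  fam_length <- function(fam) {
    if (is.null(fam_len[[fam]]))
      fam_len[[fam]] <- sample(100:600, 1)
    fam_len[[fam]]
  }
  gene_rows <- vector("list", nrow(elements))
  priv_counter <- 0L
  for (i in seq_len(nrow(elements))) {
    g <- elements$group_label[i]
    core <- group_core[[g]][runif(length(group_core[[g]])) < cfg$core_retention]
    anc <- group_ancient[[g]]
    target <- sample(cfg$genes_per_element[1]:cfg$genes_per_element[2], 1)
    n_priv <- max(2L, target - length(core) - length(anc))
    priv <- sprintf("PRV%06d", priv_counter + seq_len(n_priv))
    priv_counter <- priv_counter + n_priv
    fams <- sample(c(core, anc, priv))
    gene_rows[[i]] <- tibble::tibble(
      element_id = elements$element_id[i],
      family = fams,
      position = seq_along(fams) - 1L,
      protein_length = vapply(fams, fam_length, numeric(1))
    )
  }
  genes <- dplyr::bind_rows(gene_rows)

  # planted transfers: fresh families between cross-group pairs sharing
  # no background family
  truth <- tibble::tibble(event_id = character(), donor = character(),
                          recipient = character(), donor_gene = character(),
                          recipient_gene = character(), identity = double(),
                          block = logical(), cross_type = logical())
  transfer_links <- list()
  used_pairs <- character(0)
  trf_counter <- 0L
  if (cfg$n_planted_transfers > 0) {
    for (ev in seq_len(cfg$n_planted_transfers)) {
      pick <- NULL
      for (try in 1:200) {
        pair <- sample(elements$element_id, 2)
        g1 <- elements$group_label[match(pair[1], elements$element_id)]
        g2 <- elements$group_label[match(pair[2], elements$element_id)]
        key <- paste(sort(pair), collapse = "\r")
        if (g1 != g2 && !key %in% used_pairs &&
            length(intersect(group_ancient[[g1]], group_ancient[[g2]])) == 0) {
          pick <- pair
          used_pairs <- c(used_pairs, key)
          break
        }
      }
      if (is.null(pick))
        abort("could not find an eligible donor-recipient pair for a transfer")
      is_block <- runif(1) < cfg$block_transfer_prob
      len_block <- if (is_block) cfg$block_length else 1L
      for (b in seq_len(len_block)) {
        trf_counter <- trf_counter + 1L
        fam <- sprintf("TRF%05d", trf_counter)
        idn <- round(runif(1, cfg$transfer_identity[1],
                           cfg$transfer_identity[2]), 4)
        plen <- fam_length(fam)
        new_genes <- tibble::tibble(
          element_id = pick,
          family = fam,
          position = NA_integer_,
          protein_length = plen
        )
        genes <- dplyr::bind_rows(genes, new_genes)
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          event_id = sprintf("EV%04d", ev),
          donor = pick[1], recipient = pick[2],
          donor_gene = NA_character_, recipient_gene = NA_character_,
          identity = idn, block = is_block,
          cross_type = elements$mge_type[match(pick[1], elements$element_id)] !=
            elements$mge_type[match(pick[2], elements$element_id)]
        ))
        transfer_links[[length(transfer_links) + 1L]] <-
          list(fam = fam, identity = idn,
                annotate_transposase = is_block && b == 1L)
      }
    }
  }

  # assign gene ids and final positions (transfer genes appended at the end)
  genes <- genes |>
    dplyr::group_by(.data$element_id) |>
    dplyr::mutate(position = seq_len(dplyr::n()) - 1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(gene_id = sprintf("%s_g%03d", .data$element_id,
                                    .data$position))
  elements <- elements |>
    dplyr::left_join(dplyr::count(genes, .data$element_id, name = "n_genes"),
                     by = "element_id") |>
    dplyr::select("element_id", "mge_type", "group_label", "n_genes",
                  "topology")
  # resolve truth gene ids (one donor + one recipient gene per family)
  fam_gene <- genes |>
    dplyr::select("element_id", "family", "gene_id")
  trf_fams <- sprintf("TRF%05d", seq_len(trf_counter))
  if (trf_counter > 0) {
    tg <- fam_gene[fam_gene$family %in% trf_fams, ]
    key <- paste(tg$element_id, tg$family, sep = "\r")
    lookup <- stats::setNames(tg$gene_id, key)
    truth$donor_gene <- unname(lookup[paste(truth$donor, trf_fams, sep = "\r")])
    truth$recipient_gene <- unname(lookup[paste(truth$recipient, trf_fams,
                                                sep = "\r")])
  }

  # homology links: same family, different element
  fam_groups <- split(seq_len(nrow(genes)), genes$family)
  fam_groups <- fam_groups[lengths(fam_groups) > 1]
  grp_of_el <- stats::setNames(elements$group_label, elements$element_id)
  trf_identity <- stats::setNames(
    vapply(transfer_links, function(x) x$identity, numeric(1)),
    vapply(transfer_links, function(x) x$fam, character(1))
  )
  link_rows <- lapply(names(fam_groups), function(fam) {
    idx <- fam_groups[[fam]]
    cmb <- utils::combn(idx, 2)
    i <- cmb[1, ]; j <- cmb[2, ]
    same_group <- grp_of_el[genes$element_id[i]] ==
      grp_of_el[genes$element_id[j]]
    idn <- if (startsWith(fam, "TRF")) {
      rep(unname(trf_identity[fam]), length(i))
    } else {
      ifelse(same_group,
             round(runif(length(i), cfg$within_group_identity[1],
                         cfg$within_group_identity[2]), 4),
             round(runif(length(i), cfg$vertical_identity[1],
                         cfg$vertical_identity[2]), 4))
    }
    tibble::tibble(gene_i = genes$gene_id[i], gene_j = genes$gene_id[j],
                   identity = unname(idn),
                   plen = unname(genes$protein_length[i]))
  })
  links <- dplyr::bind_rows(link_rows)
  cov <- if (cfg$coverage_jitter > 0) {
    round(runif(nrow(links), 1 - cfg$coverage_jitter, 1), 3)
  } else rep(1, nrow(links))
  alen <- pmax(1, round(links$plen * cov))
  m8_half <- tibble::tibble(
    query = links$gene_i, target = links$gene_j,
    pident = links$identity * 100,
    length = alen,
    mismatch = round((1 - links$identity) * alen),
    gapopen = 0L, qstart = 1L, qend = alen, tstart = 1L, tend = alen,
    evalue = 1e-50, bitscore = round(2 * links$identity * alen, 1)
  )
  m8_back <- m8_half
  m8_back$query <- m8_half$target
  m8_back$target <- m8_half$query
  alignment <- dplyr::bind_rows(m8_half, m8_back) |>
    dplyr::arrange(.data$query, .data$target)

  # annotation tracks
  categories <- c("defense", "metabolism", "structure", "replication",
                  "regulation")
  planted_genes <- c(truth$donor_gene, truth$recipient_gene)
  ann_fun <- genes |>
    dplyr::mutate(
      is_planted = .data$gene_id %in% planted_genes,
      u = runif(dplyr::n()),
      annotated = .data$u < cfg$fraction_annotated | .data$is_planted,
      category = dplyr::if_else(
        .data$is_planted & runif(dplyr::n()) < cfg$transfer_category_prob,
        cfg$transfer_category,
        sample(categories, dplyr::n(), replace = TRUE))
    ) |>
    dplyr::filter(.data$annotated) |>
    dplyr::transmute(track = "function", gene_id = .data$gene_id,
                     category = .data$category)
  tp_fams <- vapply(
    Filter(function(x) x$annotate_transposase, transfer_links),
    function(x) x$fam, character(1))
  ann_tp <- fam_gene |>
    dplyr::filter(.data$family %in% tp_fams) |>
    dplyr::transmute(track = "transposase", gene_id = .data$gene_id,
                     category = "transposase")
  annotations <- dplyr::bind_rows(ann_fun, ann_tp) |>
    dplyr::arrange(.data$track, .data$gene_id)

  genes <- genes |>
    dplyr::select("gene_id", "element_id", "position", "protein_length") |>
    dplyr::mutate(protein_length = as.integer(.data$protein_length)) |>
    dplyr::arrange(.data$element_id, .data$position)
  list(elements = elements, genes = genes, alignment = alignment,
       annotations = annotations, truth = truth)
}

# post-hoc wGRR guarantees: same-group pairs similar, planted pairs dissimilar
check_simulation <- function(sim, cfg) {
  hits <- hits_from_m8(sim$alignment, sim$genes)
  fh <- filter_hits(hits, sim$genes)
  w <- compute_wgrr(extract_bbh(fh), sim$elements)
  el <- sim$elements
  by_group <- split(el$element_id, el$group_label)
  for (members in by_group) {
    if (length(members) < 2) next
    cmb <- utils::combn(members, 2)
    v <- wgrr_lookup(w, cmb[1, ], cmb[2, ])
    if (any(v <= 0.1)) return(FALSE)
  }
  if (nrow(sim$truth) > 0) {
    v <- wgrr_lookup(w, sim$truth$donor, sim$truth$recipient)
    if (any(v > 0.1)) return(FALSE)
  }
  TRUE
}

#' @export
print.mge_simulation <- function(x, ...) {
  cat("<mge_simulation>", nrow(x$elements), "elements,", nrow(x$genes),
      "genes,", nrow(x$truth), "planted transfer gene pairs\n")
  invisible(x)
}

#' Write a synthetic collection to disk in the pipeline's input formats
#'
#' @param sim An `mge_simulation`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named vector of the written paths.
#' @export
write_collection <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    elements = file.path(dir, "elements.tsv"),
    genes = file.path(dir, "genes.tsv"),
    alignment = file.path(dir, "alignment.m8"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_mge_tsv(sim$elements, paths["elements"])
  write_mge_tsv(sim$genes, paths["genes"])
  aln <- sim$alignment
  con <- file(paths["alignment"], open = "wb")
  writeLines(do.call(paste, c(lapply(aln, format_tsv_col), sep = "\t")), con)
  close(con)
  write_mge_tsv(sim$annotations, paths["annotations"])
  write_mge_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Score detector output against the planted ground truth
#'
#' Sensitivity is computed over planted genes whose identity exceeds the
#' detection threshold (transfers planted below it are intentionally
#' undetectable and excluded from the denominator); the false-call rate is
#' the fraction of non-planted genes labelled RG.
#'
#' @param truth Truth tibble from [simulate_mge_collection()].
#' @param classification Tibble from [classify_genes()] on the same
#'   collection.
#' @param elements Optional element tibble; when given, the per-type
#'   breakdown uses donor-recipient type pairs (the six exchange types),
#'   otherwise within- vs between-type only.
#' @param min_identity Detection identity threshold (default 0.80, strict).
#' @return A list with `summary` (one-row tibble: `n_planted_genes`,
#'   `n_detectable`, `n_detected`, `sensitivity`, `n_false_calls`,
#'   `n_nonplanted`, `false_call_rate`) and `by_type` (per donor-recipient
#'   type pair: planted and detected gene-pair counts).
#' @export
evaluate_recovery <- function(truth, classification, elements = NULL,
                              min_identity = 0.80) {
  planted <- tibble::tibble(
    gene_id = c(truth$donor_gene, truth$recipient_gene),
    identity = rep(truth$identity, 2)
  )
  lab <- stats::setNames(classification$label, classification$gene_id)
  planted$detected <- unname(lab[planted$gene_id]) == "RG"
  detectable <- planted[planted$identity > min_identity, ]
  n_false <- sum(classification$label == "RG" &
                   !classification$gene_id %in% planted$gene_id)
  n_nonplanted <- sum(!classification$gene_id %in% planted$gene_id)
  summary <- tibble::tibble(
    n_planted_genes = nrow(planted),
    n_detectable = nrow(detectable),
    n_detected = sum(detectable$detected),
    sensitivity = ifelse(nrow(detectable) > 0,
                         mean(detectable$detected), NA_real_),
    n_false_calls = n_false,
    n_nonplanted = n_nonplanted,
    false_call_rate = n_false / n_nonplanted
  )
  scored <- truth |>
    dplyr::mutate(
      pair_detected = unname(lab[.data$donor_gene]) == "RG" &
        unname(lab[.data$recipient_gene]) == "RG"
    )
  if (!is.null(elements)) {
    tp <- stats::setNames(elements$mge_type, elements$element_id)
    scored$scope <- exchange_type_label(unname(tp[scored$donor]),
                                        unname(tp[scored$recipient]))
  } else {
    scored$scope <- ifelse(scored$cross_type, "between_types", "within_type")
  }
  by_type <- scored |>
    dplyr::summarise(n_planted = dplyr::n(),
                     n_detected = sum(.data$pair_detected),
                     .by = "scope")
  list(summary = summary, by_type = by_type)
}

#' Generate a type-blind family structure for null-model calibration
#'
#' Directly generates recombining-gene families whose member elements are
#' drawn uniformly at random, ignoring element types. Used to check that the
#' label-permutation null is calibrated: with type-blind planting every
#' observed/expected ratio should be close to 1.
#'
#' @param n_per_type Named or unnamed length-3 integer vector: elements per
#'   type (phage, plasmid, phage-plasmid).
#' @param n_families Number of families.
#' @param elements_per_family Distinct elements spanned by each family.
#' @param seed Integer seed.
#' @return A list with tibbles `elements`, `genes`, `families`.
#' @export
simulate_type_blind_families <- function(n_per_type = c(100, 100, 100),
                                         n_families = 1000,
                                         elements_per_family = 4,
                                         seed = 1729) {
  stopifnot(length(n_per_type) == 3, elements_per_family >= 2)
  types <- rep(MGE_TYPES, times = n_per_type)
  elements <- tibble::tibble(
    element_id = sprintf("E%04d", seq_along(types)),
    mge_type = types,
    group_label = NA_character_,
    n_genes = 1L,
    topology = "circular"
  )
  withr::with_seed(seed, {
    membership <- lapply(seq_len(n_families), function(f)
      sort(sample(elements$element_id, elements_per_family)))
  })
  families <- tibble::tibble(
    family_id = rep(sprintf("RGF%05d", seq_len(n_families)),
                    each = elements_per_family),
    element_id = unlist(membership, use.names = FALSE)
  )
  families$gene_id <- sprintf("%s_%s", families$element_id,
                              families$family_id)
  genes <- tibble::tibble(
    gene_id = families$gene_id,
    element_id = families$element_id,
    position = 0L,
    protein_length = 300L
  )
  list(elements = elements, genes = genes,
       families = families[, c("family_id", "gene_id")])
}
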