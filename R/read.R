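#' Read an element table
#'
#' Elements are replicons: phages, plasmids or phage-plasmids. The TSV must
#' have columns `element_id`, `mge_type`, `group_label`, `n_genes` and
#' `topology`. `group_label` may be empty/NA for singleton (ungrouped)
#' elements.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with one row per element.
#' @export
read_element_table <- function(path) {
  el <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          element_id = readr::col_character(),
                          mge_type = readr::col_character(),
                          group_label = readr::col_character(),
                          n_genes = readr::col_integer(),
                          topology = readr::col_character()
                        ))
  validate_elements(el)
  el
}

#' Read a gene table
#'
#' Genes carry an ordinal `position` (0-based) along their element and the
#' length of the encoded protein in amino acids.
#'
#' @param path Path to a TSV file with columns `gene_id`, `element_id`,
#'   `position`, `protein_length`.
#' @return A tibble with one row per gene.
#' @export
read_gene_table <- function(path) {
  g <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         gene_id = readr::col_character(),
                         element_id = readr::col_character(),
                         position = readr::col_integer(),
                         protein_length = readr::col_integer()
                       ))
  if (nrow(g) == 0) abort("no genes: the gene table is empty")
  g
}

#' Read elements and genes together, cross-validating them
#'
#' @param element_path,gene_path Paths to the element and gene TSVs.
#' @return A list with tibbles `elements` and `genes`.
#' @export
read_element_and_gene_tables <- function(element_path, gene_path) {
  elements <- read_element_table(element_path)
  genes <- read_gene_table(gene_path)
  validate_collection(elements, genes)
  list(elements = elements, genes = genes)
}

validate_elements <- function(elements) {
  dup <- elements$element_id[duplicated(elements$element_id)]
  if (length(dup) > 0)
    abort(paste0("duplicate element_id: ", paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(elements$mge_type), MGE_TYPES)
  if (length(bad) > 0)
    abort(paste0("unknown mge_type: ", paste(bad, collapse = ", "),
                 " (expected ", paste(MGE_TYPES, collapse = ", "), ")"))
  if ("topology" %in% names(elements)) {
    bad_t <- setdiff(unique(elements$topology), TOPOLOGIES)
    if (length(bad_t) > 0)
      abort(paste0("unknown topology: ", paste(bad_t, collapse = ", ")))
  }
  if (any(elements$n_genes < 1))
    abort("every element must have n_genes >= 1")
  invisible(elements)
}

#' Validate an element/gene collection
#'
#' Checks that gene ids are unique, every gene references a known element,
#' declared `n_genes` matches the gene table, and positions within each
#' element form a permutation of `0..n_genes-1`.
#'
#' @param elements,genes Element and gene tibbles.
#' @return Invisibly `TRUE`; aborts with an informative message otherwise.
#' @export
validate_collection <- function(elements, genes) {
  validate_elements(elements)
  if (nrow(genes) == 0) abort("no genes: the gene table is empty")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0)
    abort(paste0("duplicate gene_id: ", paste(unique(dup), collapse = ", ")))
  orphan <- setdiff(unique(genes$element_id), elements$element_id)
  if (length(orphan) > 0)
    abort(paste0("genes reference unknown element(s): ",
                 paste(orphan, collapse = ", ")))
  counts <- dplyr::count(genes, .data$element_id, name = "n_obs")
  chk <- dplyr::left_join(elements, counts, by = "element_id")
  chk$n_obs[is.na(chk$n_obs)] <- 0L
  off <- chk[chk$n_genes != chk$n_obs, ]
  if (nrow(off) > 0)
    abort(paste0("n_genes mismatch for element(s): ",
                 paste(sprintf("%s (declared %d, listed %d)",
                               off$element_id, off$n_genes, off$n_obs),
                       collapse = "; ")))
  byel <- split(genes$position, genes$element_id)
  for (eid in names(byel)) {
    pos <- sort(byel[[eid]])
    if (!identical(as.integer(pos), seq_along(pos) - 1L))
      abort(paste0("positions of element ", eid,
                   " are not a permutation of 0..n-1"))
  }
  invisible(TRUE)
}

M8_COLS <- c("query", "target", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "tstart", "tend", "evalue", "bitscore")

#' Read an all-vs-all protein alignment table (BLAST tabular / m8)
#'
#' Parses the 12-column BLAST `outfmt 6` dialect (query, target, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, tstart,
#' tend, evalue, bitscore). Identities are converted to fractions; coverages
#' are derived as alignment length over each protein's length (capped at 1).
#' Self-hits are dropped and duplicate (query, target) rows are reduced to
#' the one with the highest bitscore (ties: higher identity, then
#' lexicographically smaller target id).
#'
#' @param path Path to the alignment file (no header).
#' @param genes Gene tibble supplying `protein_length` for coverage.
#' @return A tibble of homology hits with columns `query_gene`,
#'   `target_gene`, `identity`, `coverage_query`, `coverage_target`,
#'   `evalue`, `bitscore`.
#' @export
read_alignment_table <- function(path, genes) {
  raw <- readr::read_tsv(path, col_names = M8_COLS, comment = "#",
                         show_col_types = FALSE,
                         col_types = readr::cols(
                           query = readr::col_character(),
                           target = readr::col_character(),
                           pident = readr::col_double(),
                           length = readr::col_double(),
                           mismatch = readr::col_double(),
                           gapopen = readr::col_double(),
                           qstart = readr::col_double(),
                           qend = readr::col_double(),
                           tstart = readr::col_double(),
                           tend = readr::col_double(),
                           evalue = readr::col_double(),
                           bitscore = readr::col_double()
                         ))
  bad <- which(is.na(raw$pident) | is.na(raw$length) | is.na(raw$evalue) |
                 is.na(raw$bitscore) | is.na(raw$query) | is.na(raw$target))
  if (length(bad) > 0)
    abort(paste0("malformed alignment row at line ", bad[1]))
  hits_from_m8(raw, genes)
}

#' Convert a parsed m8 tibble into homology hits
#'
#' @param m8 Tibble with the 12 BLAST tabular columns (see
#'   [read_alignment_table()]).
#' @param genes Gene tibble supplying `protein_length`.
#' @return A homology-hit tibble (see [read_alignment_table()]).
#' @export
hits_from_m8 <- function(m8, genes) {
  len <- stats::setNames(genes$protein_length, genes$gene_id)
  unknown <- setdiff(unique(c(m8$query, m8$target)), genes$gene_id)
  if (length(unknown) > 0)
    abort(paste0("alignment references unknown gene_id: ",
                 paste(head(unknown, 5), collapse = ", ")))
  h <- m8 |>
    dplyr::filter(.data$query != .data$target) |>
    dplyr::transmute(
      query_gene = .data$query,
      target_gene = .data$target,
      identity = .data$pident / 100,
      coverage_query = pmin(1, .data$length / unname(len[.data$query])),
      coverage_target = pmin(1, .data$length / unname(len[.data$target])),
      evalue = .data$evalue,
      bitscore = .data$bitscore
    ) |>
    dplyr::arrange(.data$query_gene, .data$target_gene,
                   dplyr::desc(.data$bitscore), dplyr::desc(.data$identity)) |>
    dplyr::distinct(.data$query_gene, .data$target_gene, .keep_all = TRUE)
  if (any(h$identity < 0 | h$identity > 1))
    abort("identity outside [0,1] after percent conversion")
  h
}

#' Read an annotation track table
#'
#' Long TSV with columns `track`, `gene_id`, `category`; at most one
#' category per gene per track.
#'
#' @param path Path to the TSV.
#' @return A tibble of annotations.
#' @export
read_annotation_table <- function(path) {
  a <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         track = readr::col_character(),
                         gene_id = readr::col_character(),
                         category = readr::col_character()
                       ))
  dup <- dplyr::count(a, .data$track, .data$gene_id) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort(paste0("gene annotated with multiple categories in one track: ",
                 dup$gene_id[1], " (track ", dup$track[1], ")"))
  a
}

#' Write a tibble as a deterministic TSV
#'
#' Rows are sorted by all key columns; an optional `#`-prefixed header
#' comment records provenance (tool version, configuration hash, seed).
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (without `#`).
#' @return Invisibly, `path`.
#' @export
write_mge_tsv <- function(x, path, comment = NULL) {
  x <- dplyr::arrange(x, dplyr::across(dplyr::everything()))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, format_tsv_col), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

format_tsv_col <- function(v) {
  if (is.numeric(v) && !is.integer(v)) {
    out <- vapply(v, function(x) format(x, digits = 15, scientific = FALSE,
                                        trim = TRUE, nsmall = 0),
                  character(1))
    out[is.na(v)] <- "NA"
    out
  } else {
    out <- as.character(v)
    out[is.na(out)] <- "NA"
    out
  }
}
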