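#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

ASSOC_TYPES <- c("causal", "preventative", "correlative", "negative")

new_assoc_tbl <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("assoc_tbl", class(tibble::tibble()))
  df
}

#' Coerce a data frame to an association table
#'
#' An association table is the package's central container: a tibble of
#' disease/gene edges with columns `disease_id`, `disease_name`,
#' `gene_symbol` and `association_type`. Rows are filtered to `keep_types`
#' and deduplicated on (disease, gene); when duplicate rows carry different
#' retained types the edge is recorded as `"causal"` if any row is causal
#' (all downstream statistics use only presence/absence of an edge).
#'
#' @param df A data frame with at least `disease_id`, `gene_symbol` and
#'   `association_type` columns. A missing `disease_name` column is filled
#'   with empty strings.
#' @param keep_types Character vector of association types to retain.
#'   Defaults to the causal and preventative types, the evidence classes
#'   treated as mechanistically causal.
#' @return An `assoc_tbl` tibble with one row per retained (disease, gene)
#'   edge.
#' @export
as_association_table <- function(df, keep_types = c("causal", "preventative")) {
  stopifnot(is.data.frame(df))
  need <- c("disease_id", "gene_symbol", "association_type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_keep <- setdiff(keep_types, ASSOC_TYPES)
  if (length(bad_keep) > 0) {
    stop("unknown association type(s) in keep_types: ",
         paste(bad_keep, collapse = ", "), call. = FALSE)
  }
  if (!"disease_name" %in% names(df)) df$disease_name <- ""
  bad <- setdiff(unique(df$association_type), ASSOC_TYPES)
  if (length(bad) > 0) {
    stop("unknown association type label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- df %>%
    dplyr::mutate(
      disease_id = as.character(.data$disease_id),
      disease_name = dplyr::coalesce(as.character(.data$disease_name), ""),
      gene_symbol = as.character(.data$gene_symbol),
      association_type = as.character(.data$association_type)
    ) %>%
    dplyr::filter(.data$association_type %in% keep_types) %>%
    # causal evidence dominates when the same edge is reported several times
    dplyr::mutate(.prio = match(.data$association_type, ASSOC_TYPES)) %>%
    dplyr::arrange(.data$disease_id, .data$gene_symbol, .data$.prio) %>%
    dplyr::distinct(.data$disease_id, .data$gene_symbol, .keep_all = TRUE) %>%
    dplyr::select("disease_id", "disease_name", "gene_symbol", "association_type")
  new_assoc_tbl(out)
}

#' Read a disease/gene association table from TSV
#'
#' Reads the tab-separated association dialect: an optional header row
#' `disease_id<TAB>disease_name<TAB>gene_symbol<TAB>association_type`
#' followed by 4-column rows (`disease_name` may be empty) or bare
#' 3-column rows (`disease_id`, `gene_symbol`, `association_type`).
#'
#' @param path Path to a UTF-8 TSV file.
#' @inheritParams as_association_table
#' @return An `assoc_tbl` tibble; see [as_association_table()].
#' @export
read_associations <- function(path, keep_types = c("causal", "preventative")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  keep_line <- nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep_line]
  lines <- lines[keep_line]
  if (length(lines) == 0) {
    return(as_association_table(
      tibble::tibble(disease_id = character(), disease_name = character(),
                     gene_symbol = character(), association_type = character()),
      keep_types))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(fields[[1]][1], "disease_id")) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  nf <- lengths(fields)
  bad <- which(nf < 3 | nf > 4)
  if (length(bad) > 0) {
    stop(sprintf("malformed row at line %d: expected 3 or 4 tab-separated columns, got %d",
                 lineno[bad[1]], nf[bad[1]]), call. = FALSE)
  }
  rows <- purrr::map(fields, function(f) {
    if (length(f) == 3) c(f[1], "", f[2], f[3]) else f
  })
  m <- do.call(rbind, rows)
  df <- tibble::tibble(
    disease_id = m[, 1], disease_name = m[, 2],
    gene_symbol = m[, 3], association_type = m[, 4]
  )
  bad_type <- which(!df$association_type %in% ASSOC_TYPES)
  if (length(bad_type) > 0) {
    stop(sprintf("unknown association type %s at line %d",
                 df$association_type[bad_type[1]], lineno[bad_type[1]]),
         call. = FALSE)
  }
  as_association_table(df, keep_types)
}

#' Write an association table to TSV
#'
#' Emits the same dialect [read_associations()] reads, including the header
#' row, so that a write/read round trip reproduces the edge set.
#'
#' @param table An `assoc_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(table, path) {
  stopifnot(inherits(table, "assoc_tbl"))
  readr::write_tsv(as.data.frame(table), path, col_names = TRUE)
  invisible(path)
}

#' Per-entity degrees of an association table
#'
#' `disease_degrees()` counts distinct genes linked to each disease;
#' `gene_degrees()` counts distinct diseases linked to each gene.
#'
#' @param table An `assoc_tbl`.
#' @return A tibble with columns `disease_id`/`gene_symbol` and `degree`.
#' @export
disease_degrees <- function(table) {
  stopifnot(inherits(table, "assoc_tbl"))
  dplyr::count(tibble::as_tibble(table), .data$disease_id, name = "degree")
}

#' @rdname disease_degrees
#' @export
gene_degrees <- function(table) {
  stopifnot(inherits(table, "assoc_tbl"))
  dplyr::count(tibble::as_tibble(table), .data$gene_symbol, name = "degree")
}

#' Filter entities by minimum degree
#'
#' Removes, in a single pass, all entities on one side of the bipartite
#' table whose degree falls below `min_degree`, together with their edges;
#' opposite-side entities left with no edges disappear with them. The
#' default reproduces the requirement that a disease have at least five
#' causal genes to enter the comparison. The pass is not iterated to a
#' joint fixpoint: disease-side and gene-side universes are constructed
#' independently.
#'
#' @param table An `assoc_tbl`.
#' @param side `"disease"` or `"gene"` — which side the threshold applies to.
#' @param min_degree Minimum number of distinct opposite-side partners
#'   (default 5).
#' @return A filtered `assoc_tbl`.
#' @export
filter_min_degree <- function(table, side = c("disease", "gene"), min_degree = 5L) {
  stopifnot(inherits(table, "assoc_tbl"), min_degree >= 1)
  side <- match.arg(side)
  key <- if (side == "disease") "disease_id" else "gene_symbol"
  out <- tibble::as_tibble(table) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) %>%
    dplyr::filter(dplyr::n() >= min_degree) %>%
    dplyr::ungroup()
  new_assoc_tbl(out)
}

#' Swap the disease and gene roles of an association table
#'
#' Returns a table in which former genes play the disease role and vice
#' versa. The overlap statistics are role-symmetric, so gene–gene
#' similarity (number of shared diseases) is computed by running the
#' disease-side machinery on the transposed table.
#'
#' @param table An `assoc_tbl`.
#' @return An `assoc_tbl` with roles exchanged (names are dropped).
#' @export
transpose_associations <- function(table) {
  stopifnot(inherits(table, "assoc_tbl"))
  out <- tibble::tibble(
    disease_id = table$gene_symbol,
    disease_name = "",
    gene_symbol = table$disease_id,
    association_type = table$association_type
  )
  new_assoc_tbl(out)
}

#' Causal gene sets per disease
#'
#' @param table An `assoc_tbl`.
#' @return A named list mapping each disease id to its character vector of
#'   causal genes (sorted).
#' @export
entity_sets <- function(table) {
  stopifnot(inherits(table, "assoc_tbl"))
  sp <- split(table$gene_symbol, table$disease_id)
  lapply(sp, function(g) sort(unique(g)))
}

# Sparse gene x disease 0/1 membership matrix.
membership_matrix <- function(table) {
  genes <- sort(unique(table$gene_symbol))
  diseases <- sort(unique(table$disease_id))
  Matrix::sparseMatrix(
    i = match(table$gene_symbol, genes),
    j = match(table$disease_id, diseases),
    x = 1,
    dims = c(length(genes), length(diseases)),
    dimnames = list(genes, diseases)
  )
}

#' Validate association-table invariants
#'
#' Checks the structural invariants of the container: recognized types,
#' no duplicate (disease, gene) edges, and degree/edge bookkeeping
#' consistency (the disease degrees and the gene degrees both sum to the
#' number of edges).
#'
#' @param table An `assoc_tbl`.
#' @return `table`, invisibly; errors on violation.
#' @export
validate_associations <- function(table) {
  stopifnot(inherits(table, "assoc_tbl"))
  if (!all(table$association_type %in% ASSOC_TYPES)) {
    stop("unknown association type present", call. = FALSE)
  }
  if (anyDuplicated(table[, c("disease_id", "gene_symbol")]) > 0) {
    stop("duplicate (disease, gene) edge", call. = FALSE)
  }
  stopifnot(
    sum(disease_degrees(table)$degree) == nrow(table),
    sum(gene_degrees(table)$degree) == nrow(table)
  )
  invisible(table)
}

#' @export
glance.assoc_tbl <- function(x, ...) {
  tibble::tibble(
    n_diseases = dplyr::n_distinct(x$disease_id),
    n_genes = dplyr::n_distinct(x$gene_symbol),
    n_edges = nrow(x)
  )
}

#' @export
print.assoc_tbl <- function(x, ...) {
  g <- glance.assoc_tbl(x)
  cat(sprintf("# Association table: %d diseases, %d genes, %d edges\n",
              g$n_diseases, g$n_genes, g$n_edges))
  NextMethod()
}
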