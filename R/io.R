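# Readers/writers for the plain-text formats the pipeline touches:
# SIF networks, GMT gene set collections, and TSV tables.

#' Read a protein-protein interaction network from a SIF file
#'
#' Accepts both the three-field dialect (`source relation target`) and the
#' bare two-field dialect (`source target`); the relation column is ignored,
#' as interaction types play no role downstream. Duplicate interactions and
#' self-interactions are removed.
#'
#' @param path path to a SIF file (whitespace- or tab-delimited).
#' @return An [interaction_network()].
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("empty network: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop_input("malformed SIF line ", bad, " (", nf[bad], " field): ", path)
  }
  ends <- t(vapply(fields, function(f) {
    if (length(f) >= 3L) c(f[[1L]], f[[3L]]) else c(f[[1L]], f[[2L]])
  }, character(2L)))
  interaction_network(ends)
}

#' Write a network as a SIF file
#'
#' Edges are written in canonical orientation with a constant `"pp"`
#' relation, sorted, so output is byte-stable for a given network.
#'
#' @param pin an [interaction_network()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(pin, path) {
  stopifnot(inherits(pin, "interaction_network"))
  lines <- sprintf("%s\tpp\t%s", pin$edges[, 1L], pin$edges[, 2L])
  writeLines(sort(lines), path)
  invisible(path)
}

#' Read a gene set collection from a GMT file
#'
#' One gene set per line: id, description, then one or more gene symbols,
#' tab-delimited. Duplicate genes within a line are collapsed.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of unique
#'   character vectors) and `descriptions` (named character vector covering
#'   exactly the same ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop_input("GMT line ", bad, " has fewer than 3 fields: ", path)
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop_input("duplicate gene set id in GMT: ", ids[duplicated(ids)][1L])
  sets <- lapply(fields, function(f) unique(trimws(f[-c(1L, 2L)])))
  names(sets) <- ids
  desc <- vapply(fields, `[[`, character(1L), 2L)
  names(desc) <- ids
  gene_set_collection(sets, desc)
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene symbols; every set
#'   must be non-empty and ids unique.
#' @param descriptions named character vector of human-readable
#'   descriptions; names must cover exactly the set ids (defaults to the
#'   ids themselves).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop_input("gene set ids must be unique, non-empty names")
  if (any(lengths(sets) == 0L)) stop_input("every gene set must be non-empty")
  if (is.null(descriptions)) descriptions <- stats::setNames(ids, ids)
  if (!setequal(names(descriptions), ids))
    stop_input("descriptions must cover exactly the gene set ids")
  structure(list(sets = lapply(sets, unique),
                 descriptions = descriptions[ids]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets, sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

#' Write a gene set collection as a GMT file
#' @param gsc a `gene_set_collection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$descriptions[[id]], gsc$sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential expression/methylation table
#'
#' The experiment input is a two- or three-column table: gene symbols,
#' optional change values (log fold change), and adjusted p values. A header
#' row is auto-detected (non-numeric last column). When a gene appears in
#' several rows (e.g. multiple probes per gene), the row with the lowest p
#' value is kept; ties keep the first occurrence.
#'
#' @param path path to a TSV file.
#' @return A `deg_table`: data.frame with columns `gene`, optionally
#'   `change`, and `p`.
#' @export
read_deg_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, blank.lines.skip = TRUE)
  if (ncol(raw) < 2L || ncol(raw) > 3L)
    stop_input("DEG table must have 2 or 3 columns, found ", ncol(raw))
  last <- suppressWarnings(as.numeric(raw[1L, ncol(raw)]))
  if (is.na(last)) raw <- raw[-1L, , drop = FALSE]  # header row
  gene <- trimws(raw[[1L]])
  p <- suppressWarnings(as.numeric(raw[[ncol(raw)]]))
  if (anyNA(p)) stop_input("non-numeric p value in DEG table")
  if (ncol(raw) == 3L) {
    change <- suppressWarnings(as.numeric(raw[[2L]]))
    if (anyNA(change)) stop_input("non-numeric change value in DEG table")
    deg_table(gene, p, change)
  } else {
    deg_table(gene, p)
  }
}

#' Construct a differential expression table
#'
#' @param gene character vector of gene symbols.
#' @param p adjusted p values in `[0, 1]`.
#' @param change optional numeric change values (log fold change); present
#'   for all rows or absent entirely.
#' @return A `deg_table` data.frame with unique gene symbols (duplicates
#'   collapsed to the minimum-p row).
#' @export
deg_table <- function(gene, p, change = NULL) {
  assert_probability(p, "adjusted p values")
  gene <- trimws(as.character(gene))
  df <- if (is.null(change)) data.frame(gene = gene, p = p,
                                        stringsAsFactors = FALSE)
        else data.frame(gene = gene, change = as.numeric(change), p = p,
                        stringsAsFactors = FALSE)
  # duplicate symbols collapse to the lowest-p record (probe rule)
  o <- order(df$p)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  df <- df[order(match(df$gene, gene)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("deg_table", "data.frame")
  df
}

#' Write a DEG table as TSV
#' @param deg a `deg_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression values matrix
#'
#' Tab-separated, genes in rows (first column = symbols, must be unique),
#' samples in columns (header, must be unique); all cells numeric.
#'
#' @param path path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- trimws(as.character(raw[[1L]]))
  if (anyDuplicated(genes))
    stop_input("duplicate gene row in expression matrix: ",
               genes[duplicated(genes)][1L])
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop_input("duplicate sample label in expression matrix")
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_input("missing value in expression matrix")
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#' @param em numeric matrix, gene rownames and sample colnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene = rownames(em), em, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene alias map
#'
#' Two-column TSV (alias, canonical symbol). Used to reconcile input gene
#' symbols with the network's naming. An alias may map to only one
#' canonical symbol.
#'
#' @param path path to a TSV file (no header).
#' @return Named character vector: `aliases -> canonical`.
#' @export
read_alias_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 2L) stop_input("alias map must have exactly 2 columns")
  alias <- trimws(raw[[1L]]); canonical <- trimws(raw[[2L]])
  dup <- alias[duplicated(alias)]
  conflict <- unique(dup[vapply(dup, function(a)
    length(unique(canonical[alias == a])) > 1L, logical(1L))])
  if (length(conflict) > 0L)
    stop_input("alias maps to multiple canonical symbols: ", conflict[1L])
  keep <- !duplicated(alias)
  stats::setNames(canonical[keep], alias[keep])
}

result_table_columns <- c("ID", "Description", "Fold_Enrichment",
                          "occurrence", "lowest_p", "highest_p",
                          "Up_regulated", "Down_regulated")

#' Write an enrichment result table as TSV
#'
#' Columns: `ID`, `Description`, `Fold_Enrichment`, `occurrence`,
#' `lowest_p`, `highest_p`, `Up_regulated`, `Down_regulated`. Gene lists
#' are `";"`-joined in alphabetical order for deterministic diffs. An empty
#' table yields a header-only file.
#'
#' @param table an `enrichment_result` (see [run_active_enrichment()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(table, path) {
  df <- as.data.frame(table)
  cols <- result_table_columns
  if ("Involved_genes" %in% names(df))  # change column absent from the input
    cols <- c(setdiff(cols, c("Up_regulated", "Down_regulated")),
              "Involved_genes")
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an enrichment result table written by [write_result_table()]
#' @param path path to the TSV file.
#' @return A data.frame with the result table columns.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(ID = "character", Description = "character",
                                   Up_regulated = "character",
                                   Down_regulated = "character"))
}
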