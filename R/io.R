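# Readers/writers for the external formats: edge lists (STRING-style TSV),
# GMT gene-set collections, trait-gene tables, gold trait lists, expression
# matrices with condition labels, and module assignments.

split_rows <- function(path, delimiter) {
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], delimiter, fixed = TRUE),
       lineno = which(keep))
}

#' Read an edge list into a gene network
#'
#' Accepts a two- or three-column delimited file (gene1, gene2, optional
#' numeric confidence such as a STRING combined_score). A header row is
#' detected and skipped. Edges below `min_confidence` are discarded
#' (inclusive threshold: an edge at exactly `min_confidence` is kept, so
#' `min_confidence = 400` reproduces a STRING "confidence 400" cut).
#' Self-loops and duplicate/reversed rows are collapsed.
#'
#' @param path file path.
#' @param min_confidence minimum edge confidence to keep; ignored when the
#'   file has no confidence column. Default 0 keeps everything.
#' @param delimiter field separator, default tab.
#' @param id_map optional two-column data frame or TSV path (id, symbol) used
#'   to translate protein identifiers (e.g. "9606.ENSP...") to gene symbols;
#'   rows with an unmapped endpoint are dropped and counted.
#' @return an undirected igraph gene network.
#' @export
read_edge_list <- function(path, min_confidence = 0, delimiter = "\t",
                           id_map = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  parsed <- split_rows(path, delimiter)
  fields <- parsed$fields
  lineno <- parsed$lineno
  if (length(fields) == 0) abort("empty edge list")
  # header: non-numeric third field, or first fields that name columns
  f1 <- fields[[1]]
  is_header <- (length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3])))) ||
    tolower(f1[1]) %in% c("gene1", "protein1", "node1", "source")
  if (is_header) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  if (length(fields) == 0) abort("edge list has a header but no data rows")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    abort(sprintf("malformed edge row at line %d: fewer than 2 fields",
                  lineno[which(nf < 2)[1]]))
  }
  has_conf <- any(nf >= 3)
  g1 <- vapply(fields, `[`, "", 1)
  g2 <- vapply(fields, `[`, "", 2)
  conf <- NULL
  if (has_conf) {
    raw <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_, "")
    conf <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(conf))
    if (length(bad) > 0) {
      abort(sprintf("malformed confidence at line %d: %s", lineno[bad[1]],
                    raw[bad[1]]))
    }
    conf[is.na(conf)] <- 0
  }
  if (!is.null(id_map)) {
    if (is.character(id_map) && length(id_map) == 1) {
      id_map <- readr::read_tsv(id_map, col_names = c("id", "symbol"),
                                col_types = "cc", progress = FALSE)
    }
    map <- setNames(canonical_symbol(id_map[[2]]), as.character(id_map[[1]]))
    m1 <- unname(map[g1])
    m2 <- unname(map[g2])
    unmapped <- is.na(m1) | is.na(m2)
    if (any(unmapped)) {
      inform(sprintf("dropping %d edge row(s) with unmapped identifiers",
                     sum(unmapped)))
    }
    g1 <- m1[!unmapped]
    g2 <- m2[!unmapped]
    if (has_conf) conf <- conf[!unmapped]
  }
  if (has_conf) {
    keep <- conf >= min_confidence
    if (!any(keep)) abort("no edges remain at this confidence threshold")
    edges <- tibble(gene1 = g1[keep], gene2 = g2[keep],
                    confidence = conf[keep])
  } else {
    edges <- tibble(gene1 = g1, gene2 = g2)
  }
  if (nrow(edges) == 0) abort("no edges remain after filtering")
  gene_network(edges)
}

#' Read a GMT gene-set collection
#'
#' Each row is `set_id TAB description TAB gene1 TAB gene2 ...`. Gene symbols
#' are case-normalized and de-duplicated within a set.
#'
#' @param path GMT file path.
#' @param source_tag free-text tag recorded on the collection (e.g. "GO_BP").
#' @return a `gene_set_collection`: named list of character gene sets, with
#'   attributes `descriptions` (named character) and `source_tag`.
#' @export
read_gmt <- function(path, source_tag = "") {
  parsed <- split_rows(path, "\t")
  fields <- parsed$fields
  ids <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate gene-set id: ", ids[duplicated(ids)][1]))
  }
  sets <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    genes <- unique(canonical_symbol(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(f) < 3 || length(genes) == 0) {
      abort(sprintf("gene set '%s' (line %d) has no genes", f[1],
                    parsed$lineno[i]))
    }
    genes
  })
  names(sets) <- ids
  gene_set_collection(
    sets,
    descriptions = setNames(vapply(fields, `[`, "", 2), ids),
    source_tag = source_tag
  )
}

#' Construct a gene-set collection
#' @param sets named list of character gene sets (non-empty, unique ids).
#' @param descriptions optional named character of per-set descriptions.
#' @param source_tag free text provenance tag.
#' @return object of class `gene_set_collection` (a named list).
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source_tag = "") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) abort("duplicate gene-set ids")
  if (any(lengths(sets) == 0)) abort("empty gene set in collection")
  sets <- lapply(sets, function(g) unique(canonical_symbol(g)))
  structure(sets, descriptions = descriptions, source_tag = source_tag,
            class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection to GMT
#' @param sets a `gene_set_collection` or named list of gene sets.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% "", sets[[id]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a trait-to-gene association table
#'
#' Two-column delimited file (trait_id, gene_symbol), one association per
#' row; rows are grouped into one gene set per trait. Rows with a blank gene
#' symbol are skipped with a warning.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return named list of character gene sets, one per trait.
#' @export
read_trait_table <- function(path, delimiter = "\t") {
  parsed <- split_rows(path, delimiter)
  fields <- parsed$fields
  if (tolower(fields[[1]][1]) %in% c("trait_id", "trait", "disease_id")) {
    fields <- fields[-1]
  }
  trait <- trimws(vapply(fields, `[`, "", 1))
  gene <- canonical_symbol(vapply(fields, function(f) {
    if (length(f) >= 2) f[2] else ""
  }, ""))
  blank <- !nzchar(gene)
  if (any(blank)) {
    warn(sprintf("skipping %d row(s) with blank gene symbol", sum(blank)))
  }
  tb <- tibble(trait = trait[!blank], gene = gene[!blank])
  traits <- lapply(split(tb$gene, tb$trait), unique)
  traits[order(names(traits))]
}

#' Write a trait-gene map as a two-column TSV
#' @param traits named list of gene sets.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  tb <- tibble(
    trait_id = rep(names(traits), lengths(traits)),
    gene = unlist(traits, use.names = FALSE)
  )
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Read a gold trait list (one trait id per line)
#' @param path file path.
#' @return character vector of trait ids.
#' @export
read_gold_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  unique(x[nzchar(x)])
}

#' Read an expression matrix with condition labels
#'
#' The expression file is a TSV with gene ids in the first column and one
#' column per sample; the condition file is a two-column TSV (sample_id,
#' condition).
#'
#' @param path expression TSV path.
#' @param condition_path condition TSV path.
#' @return an `expression_matrix`: list with `values` (genes x samples
#'   numeric matrix) and `condition` (character vector aligned to columns).
#' @export
read_expression <- function(path, condition_path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  values <- as.matrix(tb[, -1])
  rownames(values) <- canonical_symbol(tb[[1]])
  cond_tb <- readr::read_tsv(condition_path,
                             col_names = c("sample_id", "condition"),
                             col_types = "cc", progress = FALSE)
  if (tolower(cond_tb$sample_id[1]) == "sample_id") cond_tb <- cond_tb[-1, ]
  cond <- setNames(cond_tb$condition, cond_tb$sample_id)
  missing <- setdiff(colnames(values), names(cond))
  if (length(missing) > 0) {
    abort(paste0("samples without condition label: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  expression_matrix(values, cond[colnames(values)])
}

#' Construct an expression matrix object
#' @param values genes x samples numeric matrix with dimnames.
#' @param condition per-sample condition labels (length = ncol(values)).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            length(condition) == ncol(values))
  rownames(values) <- canonical_symbol(rownames(values))
  structure(list(values = values, condition = as.character(condition)),
            class = "expression_matrix")
}

#' Read module assignments (gene, module_label TSV)
#' @param path two-column TSV path.
#' @return named list: module label -> character gene set.
#' @export
read_module_assignments <- function(path) {
  parsed <- split_rows(path, "\t")
  fields <- parsed$fields
  if (tolower(fields[[1]][1]) %in% c("gene", "gene_id", "symbol")) {
    fields <- fields[-1]
  }
  gene <- canonical_symbol(vapply(fields, `[`, "", 1))
  label <- trimws(vapply(fields, `[`, "", 2))
  mods <- lapply(split(gene, label), unique)
  mods[order(names(mods))]
}
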