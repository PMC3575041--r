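# Field-restricted boolean keyword search over OMIM-style entry snapshots,
# followed by gene -> protein and gene -> article joins over NCBI-style
# two-column association tables.

# TRUE when text contains >= 1 keyword from each group, matched
# case-insensitively as whole words ("colon" does not fire inside
# "semicolon" or "colonic").
.keyword_group_regex <- function(keywords) {
  escaped <- gsub("([^[:alnum:]_ ])", "\\\\\\1", keywords)
  paste0("\\b(", paste(escaped, collapse = "|"), ")\\b")
}

.matches_keyword_groups <- function(text, site_keywords, disease_keywords) {
  grepl(.keyword_group_regex(site_keywords), text, ignore.case = TRUE, perl = TRUE) &&
    grepl(.keyword_group_regex(disease_keywords), text, ignore.case = TRUE, perl = TRUE)
}

#' Keyword query for OMIM-style entries
#'
#' Boolean keyword combination `(any site keyword) AND (any disease
#' keyword)`, matched case-insensitively on whole words within the selected
#' fields.  Defaults are the colorectal-cancer combination
#' `(colon | colorectal | colonic | rectal) AND (cancer | carcinoma |
#' adenoma)` over title and allelic-variant text.
#'
#' @param site_keywords,disease_keywords Non-empty keyword groups.
#' @param fields Fields searched, a subset of `title`, `allelic_variants`,
#'   `other_text`.
#' @return A `keyword_query` list.
#' @export
keyword_query <- function(site_keywords = c("colon", "colorectal", "colonic", "rectal"),
                          disease_keywords = c("cancer", "carcinoma", "adenoma"),
                          fields = c("title", "allelic_variants")) {
  if (length(site_keywords) == 0L || length(disease_keywords) == 0L) {
    stop("both keyword groups must be non-empty", call. = FALSE)
  }
  fields <- match.arg(fields, c("title", "allelic_variants", "other_text"),
                      several.ok = TRUE)
  structure(list(site_keywords = as.character(site_keywords),
                 disease_keywords = as.character(disease_keywords),
                 fields = fields),
            class = "keyword_query")
}

#' Read an OMIM-style entry snapshot
#'
#' JSON-lines file, one entry per line with keys `mim_id`, `title`,
#' `allelic_variants` (array of free-text blocks) and optional `other_text`.
#'
#' @param path Snapshot file path.
#' @return A tibble with columns `mim_id`, `title`, `allelic_variants`
#'   (list-column of character vectors) and `other_text`.
#' @export
read_omim_snapshot <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  entries <- purrr::map(lines, jsonlite::fromJSON)
  out <- tibble::tibble(
    mim_id = vapply(entries, function(e) as.character(e$mim_id), character(1L)),
    title = vapply(entries, function(e) as.character(e$title %||% ""), character(1L)),
    allelic_variants = purrr::map(entries, function(e) {
      as.character(e$allelic_variants %||% character())
    }),
    other_text = vapply(entries, function(e) as.character(e$other_text %||% ""),
                        character(1L))
  )
  if (anyDuplicated(out$mim_id)) {
    stop("duplicate mim_id in snapshot: ",
         out$mim_id[anyDuplicated(out$mim_id)], call. = FALSE)
  }
  out
}

#' Search OMIM-style entries by boolean keyword query
#'
#' An entry matches when the concatenation of its selected fields contains at
#' least one site keyword AND at least one disease keyword (the groups may
#' fire in different fields).  Input order is preserved.
#'
#' @param snapshot Tibble from [read_omim_snapshot()].
#' @param query A [keyword_query()].
#' @return The matching rows of `snapshot`, in input order.
#' @export
search_entries <- function(snapshot, query = keyword_query()) {
  stopifnot(inherits(query, "keyword_query"))
  texts <- vapply(seq_len(nrow(snapshot)), function(i) {
    parts <- character()
    if ("title" %in% query$fields) parts <- c(parts, snapshot$title[i])
    if ("allelic_variants" %in% query$fields) {
      parts <- c(parts, snapshot$allelic_variants[[i]])
    }
    if ("other_text" %in% query$fields) parts <- c(parts, snapshot$other_text[i])
    paste(parts, collapse = "\n")
  }, character(1L))
  keep <- vapply(texts, .matches_keyword_groups, logical(1L),
                 site_keywords = query$site_keywords,
                 disease_keywords = query$disease_keywords,
                 USE.NAMES = FALSE)
  snapshot[keep, , drop = FALSE]
}

#' Read a two-column association table
#'
#' Tab-separated (source ID, target ID) pairs; `#` header/comment lines are
#' skipped and duplicate pairs collapsed.  Covers 2-column extracts of the
#' NCBI gene-to-accession / gene-to-PubMed style files and MIM-to-gene maps.
#'
#' @param path File path.
#' @param kind One of `mim_to_gene`, `gene_to_protein`, `gene_to_article`.
#' @return A `gene_link_table` tibble with columns `source_id`, `target_id`
#'   and a `kind` attribute.
#' @export
read_link_table <- function(path, kind = c("mim_to_gene", "gene_to_protein", "gene_to_article")) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short) > 0L) {
    stop("association table line ", short[1L], " has fewer than 2 columns",
         call. = FALSE)
  }
  out <- tibble::tibble(
    source_id = vapply(fields, `[[`, character(1L), 1L),
    target_id = vapply(fields, `[[`, character(1L), 2L)
  )
  if (any(!nzchar(out$source_id)) || any(!nzchar(out$target_id))) {
    stop("association table contains empty IDs", call. = FALSE)
  }
  out <- dplyr::distinct(out)
  attr(out, "kind") <- kind
  class(out) <- c("gene_link_table", class(out))
  out
}

#' Gene link table from in-memory pairs
#'
#' @param source_id,target_id Equal-length character vectors.
#' @inheritParams read_link_table
#' @export
gene_link_table <- function(source_id, target_id,
                            kind = c("mim_to_gene", "gene_to_protein", "gene_to_article")) {
  kind <- match.arg(kind)
  out <- dplyr::distinct(tibble::tibble(source_id = as.character(source_id),
                                        target_id = as.character(target_id)))
  if (any(!nzchar(out$source_id)) || any(!nzchar(out$target_id))) {
    stop("IDs must be non-empty", call. = FALSE)
  }
  attr(out, "kind") <- kind
  class(out) <- c("gene_link_table", class(out))
  out
}

#' Genes linked to matched OMIM entries
#'
#' @param entries Matched entries from [search_entries()].
#' @param mim_to_gene A `gene_link_table` of kind `mim_to_gene`.
#' @return Sorted character vector of gene IDs (duplicates collapsed).
#'   MIM IDs absent from the table contribute nothing and are reported in a
#'   message.
#' @export
genes_from_entries <- function(entries, mim_to_gene) {
  stopifnot(inherits(mim_to_gene, "gene_link_table"),
            identical(attr(mim_to_gene, "kind"), "mim_to_gene"))
  mims <- unique(entries$mim_id)
  unlinked <- setdiff(mims, mim_to_gene$source_id)
  if (length(unlinked) > 0L) {
    message("mim_id(s) with no gene link: ", paste(unlinked, collapse = ", "))
  }
  sort(unique(mim_to_gene$target_id[mim_to_gene$source_id %in% mims]))
}

#' Targets linked to a gene set
#'
#' Union of the targets (protein accessions or article IDs) of the given
#' genes in a `gene_to_protein` or `gene_to_article` table.
#'
#' @param gene_ids Character vector of gene IDs.
#' @param table A `gene_link_table` of kind `gene_to_protein` or
#'   `gene_to_article`.
#' @return Sorted character vector of target IDs.
#' @export
link_targets <- function(gene_ids, table) {
  stopifnot(inherits(table, "gene_link_table"))
  kind <- attr(table, "kind")
  if (!kind %in% c("gene_to_protein", "gene_to_article")) {
    stop("table kind must be gene_to_protein or gene_to_article, got ", kind,
         call. = FALSE)
  }
  sort(unique(table$target_id[table$source_id %in% unique(gene_ids)]))
}

#' End-to-end OMIM extraction
#'
#' Runs the three-step extraction: keyword search over the snapshot, MIM to
#' gene join, then gene to protein and gene to article joins.
#'
#' @param snapshot Tibble from [read_omim_snapshot()].
#' @param mim_to_gene,gene_to_protein,gene_to_article `gene_link_table`s.
#' @param query A [keyword_query()].
#' @return A list with `entries` (matched rows), `genes`, `proteins`,
#'   `articles` (sorted ID vectors) and `summary` (a one-row tibble of
#'   counts).
#' @export
extract_condition_genes <- function(snapshot, mim_to_gene, gene_to_protein,
                                    gene_to_article, query = keyword_query()) {
  entries <- search_entries(snapshot, query)
  genes <- genes_from_entries(entries, mim_to_gene)
  proteins <- link_targets(genes, gene_to_protein)
  articles <- link_targets(genes, gene_to_article)
  list(
    entries = entries, genes = genes, proteins = proteins, articles = articles,
    summary = tibble::tibble(entries = nrow(entries), genes = length(genes),
                             proteins = length(proteins),
                             articles = length(articles))
  )
}
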