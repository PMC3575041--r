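# Validation of candidate relations by MeSH-term co-occurrence search in a
# literature index: a relation passes when at least one indexed article is
# annotated with a MeSH term of each concept plus the context term.

#' MeSH terms of a concept
#'
#' All non-suppressed atom term strings of `cui` from the MeSH-like source
#' vocabulary, deduplicated case-insensitively (original casing of the first
#' occurrence kept) with the preferred atom's term first.  An empty result is
#' valid: such a relation cannot be validated and fails with a hit count of
#' zero.
#'
#' @param cui Concept unique identifier.
#' @param kb A `terminology_kb`.
#' @param mesh_sab Source-vocabulary tag of the MeSH-like source.
#' @return Character vector of MeSH terms (possibly empty), preferred first.
#' @export
mesh_terms_for <- function(cui, kb, mesh_sab = "MSH") {
  atoms <- kb_atoms_by_cui(kb, cui)
  atoms <- atoms[atoms$source_vocabulary == mesh_sab &
                   .not_suppressed(atoms$suppress), , drop = FALSE]
  if (nrow(atoms) == 0L) return(character())
  atoms <- atoms[order(atoms$ispref != "Y"), , drop = FALSE] # stable: preferred first
  terms <- atoms$term_string
  terms[!duplicated(tolower(terms))]
}

#' Build a MeSH co-occurrence validation query
#'
#' Renders the fixed template
#' `"{x}[MeSH Terms] AND {y}[MeSH Terms] AND {context}[MeSH Terms]"`.
#' The context term restricts hits to the condition of interest.
#'
#' @param x_term,y_term MeSH terms of the two concepts under validation.
#' @param context_term Context MeSH term; default `"Colorectal neoplasms"`.
#' @return A `validation_query` list with fields `x_term`, `y_term`,
#'   `context_term` and the `rendered` query string.
#' @export
build_query <- function(x_term, y_term, context_term = "Colorectal neoplasms") {
  for (term in list(x_term, y_term, context_term)) {
    if (!is.character(term) || length(term) != 1L || !nzchar(term)) {
      stop("all query terms must be non-empty strings", call. = FALSE)
    }
  }
  structure(list(
    x_term = x_term, y_term = y_term, context_term = context_term,
    rendered = sprintf("%s[MeSH Terms] AND %s[MeSH Terms] AND %s[MeSH Terms]",
                       x_term, y_term, context_term)
  ), class = "validation_query")
}

#' Read an offline literature index
#'
#' One record per line, tab-separated: record ID, then `;`-joined MeSH
#' annotation terms.  `#` comment lines are skipped.
#'
#' @param path Index file path.
#' @return A `lit_index` tibble with columns `record_id` and `terms`
#'   (list-column of character vectors).
#' @export
read_literature_index <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 1L)
  if (length(bad) > 0L) stop("empty index record at line ", bad[1L], call. = FALSE)
  out <- tibble::tibble(
    record_id = vapply(fields, `[[`, character(1L), 1L),
    terms = purrr::map(fields, function(f) {
      if (length(f) < 2L) return(character())
      trimws(strsplit(f[[2L]], ";", fixed = TRUE)[[1L]])
    })
  )
  class(out) <- c("lit_index", class(out))
  out
}

#' Offline literature index from in-memory records
#'
#' @param record_id Character vector of record IDs.
#' @param terms List of character vectors (MeSH annotations per record).
#' @export
literature_index <- function(record_id = character(), terms = list()) {
  stopifnot(length(record_id) == length(terms))
  out <- tibble::tibble(record_id = as.character(record_id),
                        terms = purrr::map(terms, as.character))
  class(out) <- c("lit_index", class(out))
  out
}

#' Write an offline literature index
#'
#' @param index A `lit_index` tibble.
#' @param path Output path.
#' @export
write_literature_index <- function(index, path) {
  lines <- paste0(index$record_id, "\t",
                  vapply(index$terms, paste, character(1L), collapse = ";"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Live E-utilities search backend
#'
#' Describes the standard literature search endpoint (`esearch`, result
#' count only, no record fetch).  Requests are throttled to at most 3 per
#' second and retried up to `retries` times with exponential backoff;
#' transient network failures and malformed responses raise distinct
#' errors — a failure never silently counts as zero hits.
#'
#' @param base_url Search endpoint URL (point at a local stub in tests).
#' @param db Literature database name.
#' @param retries Retry attempts on transient failure.
#' @param min_interval Minimum seconds between requests.
#' @export
eutils_backend <- function(base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi",
                           db = "pubmed", retries = 3L, min_interval = 1 / 3) {
  structure(list(base_url = base_url, db = db, retries = as.integer(retries),
                 min_interval = min_interval),
            class = "eutils_backend")
}

# Extract the result count from an esearch XML document.  Malformed
# documents (no Count node) are an error, never a silent zero.
.parse_esearch_count <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text),
                  error = function(e) stop("malformed search response: not XML",
                                           call. = FALSE))
  node <- xml2::xml_find_first(doc, "/eSearchResult/Count")
  if (inherits(node, "xml_missing")) {
    stop("malformed search response: no Count field", call. = FALSE)
  }
  count <- suppressWarnings(as.integer(xml2::xml_text(node)))
  if (is.na(count) || count < 0L) {
    stop("malformed search response: non-numeric Count", call. = FALSE)
  }
  count
}

#' Article count for a validation query
#'
#' Dispatches on the index backend: an offline `lit_index` counts bundled
#' records whose annotation set contains all three query terms
#' (case-insensitively); an `eutils_backend` queries the live search
#' endpoint and reads its result count.
#'
#' @param query A [build_query()] result.
#' @param index A `lit_index` or an [eutils_backend()].
#' @return Non-negative integer article count.
#' @export
count_hits <- function(query, index) {
  stopifnot(inherits(query, "validation_query"))
  UseMethod("count_hits", index)
}

#' @export
count_hits.lit_index <- function(query, index) {
  wanted <- tolower(c(query$x_term, query$y_term, query$context_term))
  sum(vapply(index$terms, function(tms) all(wanted %in% tolower(tms)),
             logical(1L)))
}

#' @export
count_hits.eutils_backend <- function(query, index) {
  url <- paste0(index$base_url, "?db=", utils::URLencode(index$db, reserved = TRUE),
                "&term=", utils::URLencode(query$rendered, reserved = TRUE),
                "&rettype=count")
  last_transient <- NULL
  for (attempt in seq_len(index$retries)) {
    Sys.sleep(index$min_interval * if (attempt == 1L) 1 else 2^(attempt - 1L))
    body <- tryCatch(paste(readLines(url, warn = FALSE), collapse = "\n"),
                     error = function(e) e)
    if (inherits(body, "error")) {
      last_transient <- body
      next
    }
    return(.parse_esearch_count(body)) # malformed response: not retried
  }
  stop("transient search backend failure after ", index$retries, " attempts: ",
       conditionMessage(last_transient), call. = FALSE)
}

#' @export
count_hits.default <- function(query, index) {
  stop("no literature backend for class ", paste(class(index), collapse = "/"),
       call. = FALSE)
}

#' Validate candidate relations by literature co-occurrence
#'
#' For each candidate, extracts the MeSH term sets of both concepts from the
#' knowledge base and tries every (x, y) term combination — preferred terms
#' first — until a query hits or the combinations are exhausted.  A relation
#' passes when at least one article satisfies a query; candidates whose
#' concepts have no MeSH terms fail with a hit count of zero.
#'
#' @param candidates Candidate-relation tibble ([direct_map()],
#'   [indirect_map()], [combine_candidates()]).
#' @param kb A `terminology_kb`.
#' @param index A `lit_index` or [eutils_backend()].
#' @param context_term Context MeSH term appended to every query.
#' @param mesh_sab MeSH-like source vocabulary tag.
#' @param checkpoint Optional path: on a backend error the already-validated
#'   prefix is written there as TSV before the error propagates, so a batch
#'   is resumable.
#' @return `candidates` with appended columns `query` (the hitting query, or
#'   the last tried, or `NA` when no MeSH terms exist), `n_queries`,
#'   `hit_count` (count of the first hitting query, else 0) and `passed`
#'   (`hit_count >= 1`).  Input order is preserved.
#' @export
validate_relations <- function(candidates, kb, index,
                               context_term = "Colorectal neoplasms",
                               mesh_sab = "MSH", checkpoint = NULL) {
  candidates <- tibble::as_tibble(candidates)
  n <- nrow(candidates)
  query <- rep(NA_character_, n)
  n_queries <- integer(n)
  hit_count <- integer(n)
  for (i in seq_len(n)) {
    x_terms <- mesh_terms_for(candidates$genomic_cui[i], kb, mesh_sab)
    y_terms <- mesh_terms_for(candidates$clinical_cui[i], kb, mesh_sab)
    if (length(x_terms) == 0L || length(y_terms) == 0L) {
      message("candidate ", candidates$genomic_cui[i], " - ",
              candidates$clinical_cui[i], ": no MeSH terms; validation fails")
      next
    }
    for (x in x_terms) {
      for (y in y_terms) {
        q <- build_query(x, y, context_term)
        hits <- tryCatch(count_hits(q, index), error = function(e) e)
        if (inherits(hits, "error")) {
          if (!is.null(checkpoint) && i > 1L) {
            done <- .as_validated(candidates[seq_len(i - 1L), , drop = FALSE],
                                  query[seq_len(i - 1L)],
                                  n_queries[seq_len(i - 1L)],
                                  hit_count[seq_len(i - 1L)])
            utils::write.table(done, checkpoint, sep = "\t", quote = FALSE,
                               row.names = FALSE)
          }
          stop("validation aborted at candidate ", i, ": ",
               conditionMessage(hits), call. = FALSE)
        }
        n_queries[i] <- n_queries[i] + 1L
        query[i] <- q$rendered
        hit_count[i] <- hits
        if (hits >= 1L) break
      }
      if (hit_count[i] >= 1L) break
    }
  }
  .as_validated(candidates, query, n_queries, hit_count)
}

.as_validated <- function(candidates, query, n_queries, hit_count) {
  out <- candidates
  out$query <- query
  out$n_queries <- n_queries
  out$hit_count <- hit_count
  out$passed <- hit_count >= 1L
  class(out) <- c("validated_relations", class(tibble::tibble()))
  out
}

#' Glance at a validation run
#'
#' @param x A `validated_relations` tibble.
#' @param ... Unused.
#' @return One-row tibble: candidates, passed, failed, pass rate, total
#'   queries issued.
#' @exportS3Method generics::glance
glance.validated_relations <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_passed = sum(x$passed),
    n_failed = sum(!x$passed),
    pass_rate = if (nrow(x) == 0L) NA_real_ else mean(x$passed),
    n_queries = sum(x$n_queries)
  )
}

#' Plot validation outcomes
#'
#' Bar chart of passed vs failed candidates, split by mapping method.
#'
#' @param object A `validated_relations` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.validated_relations <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$outcome <- ifelse(dat$passed, "passed", "failed")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$method, fill = .data$outcome)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = "mapping method", y = "candidate relations",
                  fill = "validation") +
    ggplot2::theme_minimal()
}
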