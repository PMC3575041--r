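# Reading and writing the UMLS Rich Release Format (RRF) subset the
# pipeline consumes, and assembling the tables into an indexed in-memory
# terminology knowledge base.

# Standard column layouts of the supported RRF tables.  Interpreted columns
# get the field names used throughout the package; everything else keeps its
# lower-cased RRF name and is carried opaquely so write-back is lossless.
.rrf_layouts <- list(
  MRCONSO = list(
    columns = c("cui", "language", "ts", "lui", "stt", "sui", "ispref",
                "aui", "saui", "scui", "sdui", "source_vocabulary",
                "term_type", "source_code", "term_string", "srl",
                "suppress", "cvf"),
    min_fields = 17L # SUPPRESS; CVF may be absent on short lines
  ),
  MRREL = list(
    columns = c("cui1", "aui1", "stype1", "rel_label", "cui2", "aui2",
                "stype2", "rela_label", "rui", "srui", "source_vocabulary",
                "sl", "rg", "dir", "suppress", "cvf"),
    min_fields = 15L
  ),
  MRCOC = list(
    columns = c("cui1", "aui1", "cui2", "aui2", "source_vocabulary",
                "cooccurrence_type", "frequency", "coa", "cvf"),
    min_fields = 7L
  ),
  MRSTY = list(
    columns = c("cui", "tui", "stn", "semantic_type_name", "atui", "cvf"),
    min_fields = 4L
  )
)

.cui_pattern <- "^C[0-9]{7}$"
.tui_pattern <- "^T[0-9]{3}$"

#' Read one UMLS RRF table
#'
#' Parses a pipe-delimited RRF file (one row per line, trailing `|` per the
#' RRF convention) into a tibble.  Only the fields the pipeline interprets
#' get semantic names (`cui`, `term_string`, `rel_label`, `frequency`, ...);
#' all remaining columns of the standard layout are kept verbatim, and any
#' columns beyond the standard layout are preserved in a single opaque
#' `.extra` column, so [write_rrf_table()] can reproduce the row.
#'
#' @param path Path to the RRF file.
#' @param table_kind One of `"MRCONSO"` (concept atoms), `"MRREL"` (concept
#'   relations), `"MRCOC"` (co-occurring concepts), `"MRSTY"` (semantic type
#'   assignments).
#' @return A tibble with one row per non-empty input line.  `MRCOC`
#'   `frequency` is returned as an integer (empty field -> 0).
#' @details A line with fewer fields than the last interpreted column of its
#'   layout is a hard error naming the line number; parsing never silently
#'   drops lines.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".RRF")
#' writeLines("C0000001|ENG|P|L1|PF|S1|Y|A1|||||SRC|PT|1|abdominal pain||N||", tf)
#' read_rrf_table(tf, "MRCONSO")
read_rrf_table <- function(path, table_kind = c("MRCONSO", "MRREL", "MRCOC", "MRSTY")) {
  table_kind <- match.arg(table_kind)
  layout <- .rrf_layouts[[table_kind]]
  if (!file.exists(path)) {
    stop("cannot read RRF file: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines)
  lines <- lines[keep]
  n_std <- length(layout$columns)
  if (length(lines) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(character()), n_std + 1L), c(layout$columns, ".extra")
    ))
    if (table_kind == "MRCOC") out$frequency <- integer()
    return(out)
  }
  fields <- strsplit(lines, "|", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < layout$min_fields)
  if (length(bad) > 0L) {
    line_no <- which(keep)[bad[1L]]
    stop(sprintf("malformed %s line %d: %d field(s), need at least %d",
                 table_kind, line_no, nf[bad[1L]], layout$min_fields),
         call. = FALSE)
  }
  std <- t(vapply(fields, function(f) {
    c(f[seq_len(n_std)], paste(f[-seq_len(n_std)], collapse = "|"))
  }, character(n_std + 1L)))
  std[is.na(std)] <- ""
  out <- tibble::as_tibble(
    stats::setNames(as.data.frame(std, stringsAsFactors = FALSE),
                    c(layout$columns, ".extra"))
  )
  if (table_kind == "MRCOC") {
    freq <- suppressWarnings(as.integer(out$frequency))
    freq[is.na(freq) & out$frequency == ""] <- 0L
    if (anyNA(freq)) {
      stop("MRCOC frequency field is not a non-negative integer at row ",
           which(is.na(freq))[1L], call. = FALSE)
    }
    out$frequency <- freq
  }
  out
}

#' Write one UMLS RRF table
#'
#' Inverse of [read_rrf_table()]: serializes a tibble in the layout that
#' function returns back to a pipe-delimited file with a trailing `|` per
#' line.  Reading a file produced by this writer reproduces the rows exactly
#' (byte-identical round trip).
#'
#' @param rows Tibble as returned by [read_rrf_table()] (the `.extra` column
#'   may be absent).
#' @param path Output file path.
#' @param table_kind Table kind; see [read_rrf_table()].
#' @return `path`, invisibly.
#' @export
write_rrf_table <- function(rows, path, table_kind = c("MRCONSO", "MRREL", "MRCOC", "MRSTY")) {
  table_kind <- match.arg(table_kind)
  layout <- .rrf_layouts[[table_kind]]
  missing_cols <- setdiff(layout$columns, names(rows))
  if (length(missing_cols) > 0L) {
    stop("rows lack required ", table_kind, " column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cui_cols <- intersect(c("cui", "cui1", "cui2"), layout$columns)
  for (cc in cui_cols) {
    bad <- !grepl(.cui_pattern, rows[[cc]])
    if (any(bad)) {
      stop(sprintf("invalid CUI in column '%s' at row %d: '%s'",
                   cc, which(bad)[1L], rows[[cc]][which(bad)[1L]]),
           call. = FALSE)
    }
  }
  if (table_kind == "MRSTY") {
    bad <- !grepl(.tui_pattern, rows$tui)
    if (any(bad)) {
      stop("invalid TUI at row ", which(bad)[1L], ": '",
           rows$tui[which(bad)[1L]], "'", call. = FALSE)
    }
  }
  if (table_kind == "MRCONSO" && any(!nzchar(rows$term_string))) {
    stop("empty term_string at row ", which(!nzchar(rows$term_string))[1L],
         call. = FALSE)
  }
  if (table_kind == "MRCOC" && any(rows$frequency < 0L)) {
    stop("negative MRCOC frequency at row ", which(rows$frequency < 0L)[1L],
         call. = FALSE)
  }
  mat <- vapply(layout$columns, function(col) as.character(rows[[col]]),
                character(nrow(rows)))
  if (nrow(rows) == 0L) {
    writeLines(character(), path, useBytes = TRUE)
    return(invisible(path))
  }
  mat <- matrix(mat, nrow = nrow(rows))
  body <- apply(mat, 1L, paste, collapse = "|")
  extra <- if (".extra" %in% names(rows)) rows$.extra else rep("", nrow(rows))
  lines <- paste0(body, "|", ifelse(nzchar(extra), paste0(extra, "|"), ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Build a hash index (environment) from key vector to integer row indices.
.index_rows <- function(keys) {
  env <- new.env(parent = emptyenv(), size = max(length(keys), 29L))
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!nzchar(k)) next
    env[[k]] <- c(env[[k]], i)
  }
  env
}

.index_get <- function(env, key) {
  if (is.null(key) || length(key) != 1L || is.na(key)) return(integer())
  val <- env[[key]]
  if (is.null(val)) integer() else val
}

#' Assemble an indexed terminology knowledge base
#'
#' Combines the four parsed RRF tables into a `terminology_kb` object whose
#' atoms are indexed by CUI, by lower-cased term string and by
#' (source vocabulary, code); relations and co-occurrences are indexed by
#' both CUIs, and semantic types by CUI.  Suppressed rows are retained and
#' flagged, not dropped, so the suppression policy is a query-time choice.
#'
#' @param mrconso,mrrel,mrcoc,mrsty Tibbles from [read_rrf_table()].  Any of
#'   them may be omitted, yielding an empty table of that kind.
#' @return A `terminology_kb` object (a list of the four tibbles plus lookup
#'   indexes).
#' @export
build_kb <- function(mrconso = NULL, mrrel = NULL, mrcoc = NULL, mrsty = NULL) {
  empty_of <- function(kind) {
    layout <- .rrf_layouts[[kind]]
    out <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(layout$columns) + 1L),
      c(layout$columns, ".extra")
    ))
    if (kind == "MRCOC") out$frequency <- integer()
    out
  }
  norm <- function(x, kind) {
    if (is.null(x) || ncol(tibble::as_tibble(x)) == 0L) empty_of(kind)
    else tibble::as_tibble(x)
  }
  mrconso <- norm(mrconso, "MRCONSO")
  mrrel   <- norm(mrrel, "MRREL")
  mrcoc   <- norm(mrcoc, "MRCOC")
  mrsty   <- norm(mrsty, "MRSTY")

  kb <- list(
    atoms = mrconso,
    relations = mrrel,
    cooccurrences = mrcoc,
    semantic_types = mrsty,
    index = list(
      atoms_by_cui  = .index_rows(mrconso$cui),
      atoms_by_term = .index_rows(tolower(mrconso$term_string)),
      atoms_by_code = .index_rows(paste0(mrconso$source_vocabulary, "|",
                                         mrconso$source_code)),
      rel_by_cui1   = .index_rows(mrrel$cui1),
      rel_by_cui2   = .index_rows(mrrel$cui2),
      coc_by_cui1   = .index_rows(mrcoc$cui1),
      coc_by_cui2   = .index_rows(mrcoc$cui2),
      sty_by_cui    = .index_rows(mrsty$cui)
    )
  )
  structure(kb, class = "terminology_kb")
}

#' Read a directory of RRF files into a knowledge base
#'
#' Convenience wrapper: reads `MRCONSO.RRF`, `MRREL.RRF`, `MRCOC.RRF` and
#' `MRSTY.RRF` from `dir` (missing files yield empty tables) and calls
#' [build_kb()].
#'
#' @param dir Directory containing the RRF files.
#' @return A `terminology_kb`.
#' @export
read_kb <- function(dir) {
  grab <- function(kind) {
    p <- file.path(dir, paste0(kind, ".RRF"))
    if (file.exists(p)) read_rrf_table(p, kind) else NULL
  }
  build_kb(grab("MRCONSO"), grab("MRREL"), grab("MRCOC"), grab("MRSTY"))
}

# A suppress flag counts as "not suppressed" only when empty or "N".
.not_suppressed <- function(flag) flag == "" | flag == "N"

# Indexed lookups.  Each returns the stored rows whose fields match.
kb_atoms_by_cui <- function(kb, cui) {
  kb$atoms[.index_get(kb$index$atoms_by_cui, cui), , drop = FALSE]
}
kb_atoms_by_term <- function(kb, term) {
  kb$atoms[.index_get(kb$index$atoms_by_term, tolower(term)), , drop = FALSE]
}
kb_atoms_by_code <- function(kb, source_vocabulary, source_code) {
  kb$atoms[.index_get(kb$index$atoms_by_code,
                      paste0(source_vocabulary, "|", source_code)), , drop = FALSE]
}
kb_relations_touching <- function(kb, cui) {
  idx <- union(.index_get(kb$index$rel_by_cui1, cui),
               .index_get(kb$index$rel_by_cui2, cui))
  kb$relations[sort(idx), , drop = FALSE]
}
kb_cooccurrences_touching <- function(kb, cui) {
  idx <- union(.index_get(kb$index$coc_by_cui1, cui),
               .index_get(kb$index$coc_by_cui2, cui))
  kb$cooccurrences[sort(idx), , drop = FALSE]
}

#' Semantic types (TUIs) assigned to a concept
#'
#' @param kb A `terminology_kb`.
#' @param cui Concept unique identifier.
#' @return Character vector of TUIs (possibly empty; a CUI may carry several).
#' @export
kb_semantic_types <- function(kb, cui) {
  sort(unique(kb$semantic_types$tui[.index_get(kb$index$sty_by_cui, cui)]))
}

#' Preferred term string of a concept
#'
#' The term string of the first non-suppressed atom flagged preferred
#' (`ISPREF = "Y"`), falling back to the first non-suppressed atom, then to
#' any atom.  Returns `NA_character_` for an unknown CUI.
#'
#' @inheritParams kb_semantic_types
#' @export
kb_preferred_term <- function(kb, cui) {
  atoms <- kb_atoms_by_cui(kb, cui)
  if (nrow(atoms) == 0L) return(NA_character_)
  ok <- .not_suppressed(atoms$suppress)
  pref <- which(ok & atoms$ispref == "Y")
  if (length(pref) > 0L) return(atoms$term_string[pref[1L]])
  if (any(ok)) return(atoms$term_string[which(ok)[1L]])
  atoms$term_string[1L]
}

#' @export
print.terminology_kb <- function(x, ...) {
  cat("<terminology_kb>\n")
  cat("  atoms:          ", nrow(x$atoms), " (",
      length(unique(x$atoms$cui)), " concepts)\n", sep = "")
  cat("  relations:      ", nrow(x$relations), "\n", sep = "")
  cat("  co-occurrences: ", nrow(x$cooccurrences), "\n", sep = "")
  cat("  semantic types: ", nrow(x$semantic_types), " assignments\n", sep = "")
  invisible(x)
}

#' Glance at a terminology knowledge base
#'
#' One-row summary in the broom tradition: table sizes and distinct-concept
#' counts.
#'
#' @param x A `terminology_kb`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.terminology_kb <- function(x, ...) {
  tibble::tibble(
    n_atoms = nrow(x$atoms),
    n_concepts = length(unique(x$atoms$cui)),
    n_relations = nrow(x$relations),
    n_cooccurrences = nrow(x$cooccurrences),
    n_semantic_type_assignments = nrow(x$semantic_types),
    n_source_vocabularies = length(unique(x$atoms$source_vocabulary))
  )
}

#' Tidy a terminology knowledge base
#'
#' Returns the concept atom table (one row per atom) with the columns the
#' pipeline interprets.
#'
#' @param x A `terminology_kb`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.terminology_kb <- function(x, ...) {
  dplyr::select(x$atoms, "cui", "language", "source_vocabulary", "term_type",
                "source_code", "term_string", "suppress")
}
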