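# Serialization of candidate / validated relation tables: TSV with a
# "#"-prefixed provenance header, plus a JSON variant.

.provenance_header <- function(extra = character()) {
  ver <- as.character(utils::packageVersion("clingenmap"))
  c(paste0("# clingenmap ", ver),
    if (length(extra) > 0L) paste0("# ", extra))
}

#' Write a relation table as TSV
#'
#' Tab-separated with a `#`-prefixed provenance header (package version plus
#' caller-supplied lines) that [read_relations_tsv()] skips.
#'
#' @param relations A relation tibble.
#' @param path Output path.
#' @param provenance Extra header lines (e.g. a config hash).
#' @export
write_relations_tsv <- function(relations, path, provenance = character()) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_header(provenance), con)
  utils::write.table(tibble::as_tibble(relations), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a relation TSV
#'
#' @param path Path written by [write_relations_tsv()].
#' @return A tibble.
#' @export
read_relations_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           quote = "", colClasses = "character",
                           check.names = FALSE)
  out <- tibble::as_tibble(out)
  for (col in c("hit_count", "n_queries")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  if ("passed" %in% names(out)) out$passed <- as.logical(out$passed)
  out
}

#' Write a relation table as JSON
#'
#' @param relations A relation tibble.
#' @param path Output path.
#' @export
write_relations_json <- function(relations, path) {
  jsonlite::write_json(tibble::as_tibble(relations), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
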