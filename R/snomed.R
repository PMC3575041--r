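# Composing and parsing SNOMED CT postcoordinated expressions: a focus
# concept refined by flat attribute = value pairs, e.g. "severe pain in the
# left abdomen" as abdominal pain refined by laterality = left and
# severity = severe.  This is the flat subset of the compositional grammar
# (no nested refinement groups).

.code_pattern <- "^[0-9]+$"

#' Postcoordinated SNOMED CT expression
#'
#' @param focus_code Focus concept code (non-empty digit string).
#' @param focus_term Optional display term for the focus concept.
#' @param refinements A data frame with columns `attribute_code`,
#'   `value_code` and optional `attribute_term`, `value_term`; or `NULL` for
#'   a precoordinated (focus-only) expression.  Order is preserved.
#' @return A `snomed_expression` object.
#' @export
#' @examples
#' snomed_expression("21522001", "abdominal pain",
#'   data.frame(attribute_code = c("272741003", "246113005"),
#'              attribute_term = c("laterality", "severity"),
#'              value_code = c("77710000", "24484000"),
#'              value_term = c("left", "severe")))
snomed_expression <- function(focus_code, focus_term = NULL, refinements = NULL) {
  if (is.null(refinements) || nrow(refinements) == 0L) {
    refinements <- tibble::tibble(attribute_code = character(),
                                  attribute_term = character(),
                                  value_code = character(),
                                  value_term = character())
  } else {
    refinements <- tibble::as_tibble(refinements)
    if (!"attribute_term" %in% names(refinements)) refinements$attribute_term <- NA_character_
    if (!"value_term" %in% names(refinements)) refinements$value_term <- NA_character_
    refinements <- dplyr::select(refinements, "attribute_code", "attribute_term",
                                 "value_code", "value_term")
  }
  expr <- structure(list(
    focus_code = as.character(focus_code),
    focus_term = if (is.null(focus_term) || is.na(focus_term)) NA_character_ else as.character(focus_term),
    refinements = refinements
  ), class = "snomed_expression")
  .check_expression_codes(expr)
  expr
}

.check_expression_codes <- function(expr) {
  codes <- c(expr$focus_code, expr$refinements$attribute_code,
             expr$refinements$value_code)
  bad <- codes[!grepl(.code_pattern, codes)]
  if (length(bad) > 0L) {
    stop("SNOMED codes must be non-empty digit strings; got '", bad[1L], "'",
         call. = FALSE)
  }
  invisible(expr)
}

#' Render a postcoordinated expression
#'
#' Canonical form without terms is `focus:attr=value,attr=value` (just the
#' focus code when there are no refinements).  With `with_terms = TRUE` each
#' code is followed by its `|term|` span when a term is known, with single
#' spaces around the separators, matching the conventional display form.
#'
#' @param expr A [snomed_expression()].
#' @param with_terms Interleave display terms?
#' @return The expression string.
#' @export
compose_expression <- function(expr, with_terms = FALSE) {
  stopifnot(inherits(expr, "snomed_expression"))
  .check_expression_codes(expr)
  piece <- function(code, term) {
    if (with_terms && !is.na(term)) paste0(code, " |", term, "|") else code
  }
  focus <- piece(expr$focus_code, expr$focus_term)
  if (nrow(expr$refinements) == 0L) return(focus)
  eq <- if (with_terms) " = " else "="
  sep <- if (with_terms) ", " else ","
  colon <- if (with_terms) ": " else ":"
  refs <- vapply(seq_len(nrow(expr$refinements)), function(i) {
    r <- expr$refinements[i, ]
    paste0(piece(r$attribute_code, r$attribute_term), eq,
           piece(r$value_code, r$value_term))
  }, character(1L))
  paste0(focus, colon, paste(refs, collapse = sep))
}

#' Parse a postcoordinated expression string
#'
#' Accepts the grammar `focus [|term|] [":" attr [|term|] "=" value [|term|]
#' ("," ...)*]` with arbitrary whitespace between tokens.  A grammar
#' violation is an error reporting the character position.
#'
#' @param text Expression string.
#' @return A [snomed_expression()].
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  pos <- 1L
  n <- length(chars)
  skip_ws <- function() {
    while (pos <= n && grepl("^\\s$", chars[pos])) pos <<- pos + 1L
  }
  fail <- function(what) {
    stop(sprintf("parse error at position %d: expected %s", pos, what),
         call. = FALSE)
  }
  read_code <- function() {
    skip_ws()
    start <- pos
    while (pos <= n && grepl("^[0-9]$", chars[pos])) pos <<- pos + 1L
    if (pos == start) fail("a digit code")
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  read_term <- function() {
    skip_ws()
    if (pos > n || chars[pos] != "|") return(NA_character_)
    pos <<- pos + 1L
    start <- pos
    while (pos <= n && chars[pos] != "|") pos <<- pos + 1L
    if (pos > n) fail("a closing '|'")
    term <- if (pos > start) paste(chars[start:(pos - 1L)], collapse = "") else ""
    pos <<- pos + 1L
    trimws(term)
  }
  expect <- function(ch) {
    skip_ws()
    if (pos > n || chars[pos] != ch) fail(paste0("'", ch, "'"))
    pos <<- pos + 1L
  }
  focus_code <- read_code()
  focus_term <- read_term()
  refinements <- list()
  skip_ws()
  if (pos <= n) {
    expect(":")
    repeat {
      attribute_code <- read_code()
      attribute_term <- read_term()
      expect("=")
      value_code <- read_code()
      value_term <- read_term()
      refinements[[length(refinements) + 1L]] <- tibble::tibble(
        attribute_code = attribute_code, attribute_term = attribute_term,
        value_code = value_code, value_term = value_term
      )
      skip_ws()
      if (pos > n) break
      expect(",")
    }
  }
  snomed_expression(
    focus_code,
    if (is.na(focus_term)) NULL else focus_term,
    if (length(refinements) > 0L) purrr::list_rbind(refinements) else NULL
  )
}

#' Parse a batch of expressions
#'
#' One expression per line; blank and `#` lines skipped.
#'
#' @param path File path.
#' @return A tibble with columns `input`, `focus_code`, `focus_term`,
#'   `n_refinements` and `canonical` (the terms-free rendering).
#' @export
parse_expression_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  purrr::map(lines, function(line) {
    e <- parse_expression(line)
    tibble::tibble(input = line, focus_code = e$focus_code,
                   focus_term = e$focus_term,
                   n_refinements = nrow(e$refinements),
                   canonical = compose_expression(e, with_terms = FALSE))
  }) |> purrr::list_rbind()
}

#' @export
print.snomed_expression <- function(x, ...) {
  cat(compose_expression(x, with_terms = TRUE), "\n")
  invisible(x)
}

#' Tidy a postcoordinated expression
#'
#' One row per refinement (zero rows for a precoordinated expression), with
#' the focus concept repeated.
#'
#' @param x A `snomed_expression`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.snomed_expression <- function(x, ...) {
  if (nrow(x$refinements) == 0L) {
    return(tibble::tibble(focus_code = x$focus_code, focus_term = x$focus_term,
                          attribute_code = NA_character_,
                          attribute_term = NA_character_,
                          value_code = NA_character_, value_term = NA_character_)[0, ])
  }
  dplyr::mutate(x$refinements, focus_code = x$focus_code,
                focus_term = x$focus_term, .before = 1L)
}
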