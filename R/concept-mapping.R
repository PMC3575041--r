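# Direct information mapping and indirect information mapping via disease
# between a genomic concept set G and a clinical concept set C.

#' Mapping configuration
#'
#' Holds the parameters the mapping procedure leaves open: which semantic
#' types count as gene-like, clinical and disease; which relation labels and
#' co-occurrence frequencies count as relatedness; and how the
#' condition-of-interest disease set is defined.
#'
#' @param genomic_tuis TUIs treated as gene-like.  Default `T028` (Gene or
#'   Genome).
#' @param clinical_tuis TUIs treated as clinical.  Default: Sign or Symptom
#'   (`T184`), Finding (`T033`), Disease or Syndrome (`T047`), Neoplastic
#'   Process (`T191`), Laboratory Procedure (`T059`).
#' @param disease_tuis TUIs treated as disease.  Default `T047` and `T191`.
#' @param rel_whitelist Relation labels counted as relatedness; empty means
#'   all labels qualify (the most inclusive reading).
#' @param min_cooccurrence_frequency Minimum co-occurrence frequency for an
#'   MRCOC row to count; must be >= 1.
#' @param crc_disease_cuis Explicit CUI set defining "disease related to the
#'   condition of interest" for indirect mapping.  When `NULL` (default) the
#'   set is derived by applying `crc_site_keywords` AND
#'   `crc_disease_keywords` (whole-word, case-insensitive) to each disease
#'   concept's preferred term — the same boolean keyword logic as the OMIM
#'   search.
#' @param crc_site_keywords,crc_disease_keywords Keyword groups for the
#'   derived condition filter.
#' @param use_mrrel,use_mrcoc Whether relation rows / co-occurrence rows
#'   contribute to relatedness.  At least one must be `TRUE`.
#' @param treat_relations_as_bidirectional If `TRUE` (default) a relation row
#'   relates both its concepts to each other; if `FALSE` only the `cui1` side
#'   is traversed.
#' @param include_suppressed Include suppressed atoms/relations in lookups.
#' @param mesh_sab Source-vocabulary tag of the MeSH-like source, used by
#'   literature validation.
#' @return A `mapping_config` list.
#' @export
mapping_config <- function(genomic_tuis = "T028",
                           clinical_tuis = c("T184", "T033", "T047", "T191", "T059"),
                           disease_tuis = c("T047", "T191"),
                           rel_whitelist = character(),
                           min_cooccurrence_frequency = 1L,
                           crc_disease_cuis = NULL,
                           crc_site_keywords = c("colon", "colorectal", "colonic", "rectal"),
                           crc_disease_keywords = c("cancer", "carcinoma", "adenoma"),
                           use_mrrel = TRUE,
                           use_mrcoc = TRUE,
                           treat_relations_as_bidirectional = TRUE,
                           include_suppressed = FALSE,
                           mesh_sab = "MSH") {
  if (!isTRUE(use_mrrel) && !isTRUE(use_mrcoc)) {
    stop("at least one of use_mrrel / use_mrcoc must be TRUE", call. = FALSE)
  }
  min_cooccurrence_frequency <- as.integer(min_cooccurrence_frequency)
  if (is.na(min_cooccurrence_frequency) || min_cooccurrence_frequency < 1L) {
    stop("min_cooccurrence_frequency must be an integer >= 1", call. = FALSE)
  }
  structure(list(
    genomic_tuis = as.character(genomic_tuis),
    clinical_tuis = as.character(clinical_tuis),
    disease_tuis = as.character(disease_tuis),
    rel_whitelist = as.character(rel_whitelist),
    min_cooccurrence_frequency = min_cooccurrence_frequency,
    crc_disease_cuis = if (is.null(crc_disease_cuis)) NULL else as.character(crc_disease_cuis),
    crc_site_keywords = as.character(crc_site_keywords),
    crc_disease_keywords = as.character(crc_disease_keywords),
    use_mrrel = isTRUE(use_mrrel),
    use_mrcoc = isTRUE(use_mrcoc),
    treat_relations_as_bidirectional = isTRUE(treat_relations_as_bidirectional),
    include_suppressed = isTRUE(include_suppressed),
    mesh_sab = as.character(mesh_sab)
  ), class = "mapping_config")
}

#' Read a mapping configuration from a YAML file
#'
#' Keys are the arguments of [mapping_config()]; absent keys keep their
#' defaults; unknown keys are an error.
#'
#' @param path YAML file path.
#' @export
read_mapping_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(mapping_config)))
  if (length(unknown) > 0L) {
    stop("unknown mapping_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(mapping_config, vals)
}

# Normalize a concept set argument to a character vector of references.
as_concept_refs <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && "ref" %in% names(x)) return(as.character(x$ref))
  stop("a concept set must be a character vector of references or a ",
       "data frame with a 'ref' column", call. = FALSE)
}

#' Read a concept set file
#'
#' One concept reference per line: a raw term string, `SAB:CODE`
#' (source-vocabulary code) or `CUI:Cnnnnnnn`.  Blank lines and lines
#' starting with `#` are skipped.
#'
#' @param path File path.
#' @return A tibble with a single `ref` column.
#' @export
read_concept_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tibble::tibble(ref = lines)
}

#' Resolve a concept reference to CUIs
#'
#' A `CUI:Cnnnnnnn` reference resolves to that CUI if the knowledge base
#' holds atoms for it; an `SAB:CODE` reference resolves to all CUIs with
#' that code in that source vocabulary; anything else is matched
#' case-insensitively against atom term strings.  Ambiguity is returned,
#' not resolved: a term carried by several concepts yields all of them.
#'
#' @param concept A single concept reference string.
#' @param kb A `terminology_kb`.
#' @param config A [mapping_config()] (controls suppression handling).
#' @return Sorted character vector of CUIs; possibly empty.
#' @export
resolve_cuis <- function(concept, kb, config = mapping_config()) {
  stopifnot(is.character(concept), length(concept) == 1L)
  if (startsWith(concept, "CUI:")) {
    cui <- sub("^CUI:", "", concept)
    atoms <- kb_atoms_by_cui(kb, cui)
  } else if (grepl(":", concept, fixed = TRUE)) {
    sab <- sub(":.*$", "", concept)
    code <- sub("^[^:]*:", "", concept)
    atoms <- kb_atoms_by_code(kb, sab, code)
  } else {
    atoms <- kb_atoms_by_term(kb, concept)
  }
  if (!config$include_suppressed) {
    atoms <- atoms[.not_suppressed(atoms$suppress), , drop = FALSE]
  }
  sort(unique(atoms$cui))
}

# Resolve a whole concept set; unresolvable references are skipped with a
# warning.  Returns tibble(ref, cui), one row per (ref, cui) resolution.
resolve_concept_set <- function(refs, kb, config = mapping_config()) {
  refs <- as_concept_refs(refs)
  res <- purrr::map(refs, resolve_cuis, kb = kb, config = config)
  dropped <- refs[lengths(res) == 0L]
  if (length(dropped) > 0L) {
    warning("skipping unresolvable concept reference(s): ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(ref = rep(refs, lengths(res)),
                 cui = as.character(unlist(res, use.names = FALSE)))
}

#' Concepts one relation or co-occurrence step away
#'
#' The union of (a) counterpart CUIs of non-suppressed relation rows touching
#' `cui` — both orientations when `treat_relations_as_bidirectional`, else
#' only rows where `cui` is on the `cui1` side — filtered by
#' `rel_whitelist`, and (b) counterpart CUIs of co-occurrence rows touching
#' `cui` with frequency at or above `min_cooccurrence_frequency`.  The
#' concept itself is never returned (self-relations are ignored).
#'
#' @inheritParams resolve_cuis
#' @param cui A concept unique identifier.
#' @return Sorted character vector of CUIs.
#' @export
related_concepts <- function(cui, kb, config = mapping_config()) {
  out <- character()
  if (config$use_mrrel) {
    rel <- kb_relations_touching(kb, cui)
    if (!config$include_suppressed) {
      rel <- rel[.not_suppressed(rel$suppress), , drop = FALSE]
    }
    if (length(config$rel_whitelist) > 0L) {
      rel <- rel[rel$rel_label %in% config$rel_whitelist, , drop = FALSE]
    }
    if (!config$treat_relations_as_bidirectional) {
      rel <- rel[rel$cui1 == cui, , drop = FALSE]
    }
    out <- c(out, rel$cui1, rel$cui2)
  }
  if (config$use_mrcoc) {
    coc <- kb_cooccurrences_touching(kb, cui)
    coc <- coc[coc$frequency >= config$min_cooccurrence_frequency, , drop = FALSE]
    out <- c(out, coc$cui1, coc$cui2)
  }
  sort(setdiff(unique(out), cui))
}

#' Keep only concepts carrying an allowed semantic type
#'
#' @param cuis Character vector of CUIs.
#' @param kb A `terminology_kb`.
#' @param allowed_tuis TUIs to keep; a concept qualifies if any of its
#'   semantic-type assignments is in this set.
#' @return Sorted character vector of qualifying CUIs.
#' @export
filter_by_semantic_type <- function(cuis, kb, allowed_tuis) {
  if (length(allowed_tuis) == 0L) return(character())
  keep <- vapply(cuis, function(cui) {
    any(kb_semantic_types(kb, cui) %in% allowed_tuis)
  }, logical(1L))
  sort(unique(cuis[keep]))
}

# Evidence strings for a qualifying direct link between CUIs a and b,
# as stored (both orientations inspected).
.direct_evidence <- function(a, b, kb, config) {
  ev <- character()
  if (config$use_mrrel) {
    rel <- kb_relations_touching(kb, a)
    if (!config$include_suppressed) {
      rel <- rel[.not_suppressed(rel$suppress), , drop = FALSE]
    }
    if (length(config$rel_whitelist) > 0L) {
      rel <- rel[rel$rel_label %in% config$rel_whitelist, , drop = FALSE]
    }
    if (!config$treat_relations_as_bidirectional) {
      rel <- rel[rel$cui1 == a, , drop = FALSE]
    }
    rel <- rel[(rel$cui1 == a & rel$cui2 == b) | (rel$cui1 == b & rel$cui2 == a), , drop = FALSE]
    if (nrow(rel) > 0L) {
      ev <- c(ev, paste0("MRREL:", rel$cui1, ":", rel$rel_label, ":", rel$cui2))
    }
  }
  if (config$use_mrcoc) {
    coc <- kb_cooccurrences_touching(kb, a)
    coc <- coc[coc$frequency >= config$min_cooccurrence_frequency, , drop = FALSE]
    coc <- coc[(coc$cui1 == a & coc$cui2 == b) | (coc$cui1 == b & coc$cui2 == a), , drop = FALSE]
    if (nrow(coc) > 0L) {
      ev <- c(ev, paste0("MRCOC:", coc$cui1, ":", coc$cui2, ":", coc$frequency))
    }
  }
  sort(unique(ev))
}

.empty_relations <- function() {
  tibble::tibble(
    genomic_cui = character(), genomic_label = character(),
    clinical_cui = character(), clinical_label = character(),
    method = character(), direction = character(), evidence = character()
  )
}

.finish_relations <- function(rel) {
  rel <- dplyr::distinct(rel, .data$genomic_cui, .data$clinical_cui,
                         .data$direction, .keep_all = TRUE)
  rel <- dplyr::arrange(rel, .data$genomic_cui, .data$clinical_cui,
                        .data$method, .data$direction)
  class(rel) <- c("clingen_relations", class(tibble::tibble()))
  rel
}

#' Direct information mapping between a genomic and a clinical concept set
#'
#' For each source concept, takes the concepts one relation/co-occurrence
#' step away, keeps those with the target role's semantic type, and
#' intersects with the resolved target set.  Run once with genomic sources
#' (direction `genomic_to_clinic`) and once with clinical sources
#' (`clinic_to_genomic`); each (source, target) hit yields one candidate
#' relation with the supporting rows as evidence.
#'
#' @param genomic,clinical Concept sets: character vectors of references (see
#'   [read_concept_set()]) or data frames with a `ref` column.
#' @param kb A `terminology_kb`.
#' @param config A [mapping_config()].
#' @param directions Which mapping directions to run; default both.
#' @return A tibble of candidate relations with columns `genomic_cui`,
#'   `genomic_label`, `clinical_cui`, `clinical_label`, `method` (`direct`),
#'   `direction` and `evidence` (`;`-joined supporting rows), deduplicated on
#'   (genomic_cui, clinical_cui, direction) and sorted.
#' @export
direct_map <- function(genomic, clinical, kb, config = mapping_config(),
                       directions = c("genomic_to_clinic", "clinic_to_genomic")) {
  directions <- match.arg(directions, several.ok = TRUE)
  g_cuis <- unique(resolve_concept_set(genomic, kb, config)$cui)
  c_cuis <- unique(resolve_concept_set(clinical, kb, config)$cui)

  one_direction <- function(sources, targets, target_tuis, direction) {
    purrr::map(sources, function(s) {
      hits <- filter_by_semantic_type(related_concepts(s, kb, config), kb, target_tuis)
      hits <- intersect(hits, targets)
      if (length(hits) == 0L) return(NULL)
      gen <- if (direction == "genomic_to_clinic") s else hits
      cli <- if (direction == "genomic_to_clinic") hits else s
      tibble::tibble(
        genomic_cui = gen, clinical_cui = cli,
        method = "direct", direction = direction,
        evidence = vapply(hits, function(t) {
          paste(.direct_evidence(s, t, kb, config), collapse = ";")
        }, character(1L), USE.NAMES = FALSE)
      )
    }) |> purrr::list_rbind()
  }

  pieces <- list()
  if ("genomic_to_clinic" %in% directions) {
    pieces <- c(pieces, list(one_direction(g_cuis, c_cuis, config$clinical_tuis,
                                           "genomic_to_clinic")))
  }
  if ("clinic_to_genomic" %in% directions) {
    pieces <- c(pieces, list(one_direction(c_cuis, g_cuis, config$genomic_tuis,
                                           "clinic_to_genomic")))
  }
  rel <- purrr::list_rbind(pieces)
  if (is.null(rel) || nrow(rel) == 0L) return(.finish_relations(.empty_relations()))
  rel$genomic_label <- vapply(rel$genomic_cui, kb_preferred_term, character(1L),
                              kb = kb, USE.NAMES = FALSE)
  rel$clinical_label <- vapply(rel$clinical_cui, kb_preferred_term, character(1L),
                               kb = kb, USE.NAMES = FALSE)
  rel <- dplyr::select(rel, "genomic_cui", "genomic_label", "clinical_cui",
                       "clinical_label", "method", "direction", "evidence")
  .finish_relations(rel)
}

#' Disease concepts related to a concept
#'
#' The one-step neighbourhood of `cui` restricted to disease semantic types —
#' the U1/U2 sets of indirect mapping.
#'
#' @inheritParams related_concepts
#' @return Sorted character vector of disease CUIs.
#' @export
diseases_for <- function(cui, kb, config = mapping_config()) {
  if (length(config$disease_tuis) == 0L) {
    stop("config$disease_tuis must be non-empty", call. = FALSE)
  }
  filter_by_semantic_type(related_concepts(cui, kb, config), kb, config$disease_tuis)
}

#' Disease concepts related to the condition of interest
#'
#' The explicit `crc_disease_cuis` set when configured; otherwise every
#' concept carrying a disease semantic type whose preferred term matches at
#' least one site keyword AND at least one disease keyword (whole-word,
#' case-insensitive).
#'
#' @param kb A `terminology_kb`.
#' @param config A [mapping_config()].
#' @return Sorted character vector of disease CUIs.
#' @export
condition_disease_cuis <- function(kb, config = mapping_config()) {
  if (!is.null(config$crc_disease_cuis)) return(sort(unique(config$crc_disease_cuis)))
  disease_cuis <- sort(unique(
    kb$semantic_types$cui[kb$semantic_types$tui %in% config$disease_tuis]
  ))
  keep <- vapply(disease_cuis, function(cui) {
    term <- kb_preferred_term(kb, cui)
    !is.na(term) &&
      .matches_keyword_groups(term, config$crc_site_keywords,
                              config$crc_disease_keywords)
  }, logical(1L))
  disease_cuis[keep]
}

#' Indirect information mapping via disease
#'
#' For every pair (g, c) from the resolved genomic and clinical sets, the
#' disease neighbourhoods U1(g) and U2(c) are intersected and restricted to
#' diseases related to the condition of interest; a non-empty intersection
#' yields one undirected candidate relation whose evidence is the shared
#' disease CUI set.
#'
#' @inheritParams direct_map
#' @return A candidate-relation tibble (see [direct_map()]) with
#'   `method = "indirect"`, `direction = "undirected"` and evidence the
#'   `;`-joined shared disease CUIs.
#' @export
indirect_map <- function(genomic, clinical, kb, config = mapping_config()) {
  g_cuis <- unique(resolve_concept_set(genomic, kb, config)$cui)
  c_cuis <- unique(resolve_concept_set(clinical, kb, config)$cui)
  crc <- condition_disease_cuis(kb, config)
  u1 <- stats::setNames(lapply(g_cuis, diseases_for, kb = kb, config = config), g_cuis)
  u2 <- stats::setNames(lapply(c_cuis, diseases_for, kb = kb, config = config), c_cuis)
  rel <- purrr::map(g_cuis, function(g) {
    purrr::map(c_cuis, function(c) {
      shared <- intersect(intersect(u1[[g]], u2[[c]]), crc)
      if (length(shared) == 0L) return(NULL)
      tibble::tibble(genomic_cui = g, clinical_cui = c,
                     method = "indirect", direction = "undirected",
                     evidence = paste(sort(shared), collapse = ";"))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(rel) || nrow(rel) == 0L) return(.finish_relations(.empty_relations()))
  rel$genomic_label <- vapply(rel$genomic_cui, kb_preferred_term, character(1L),
                              kb = kb, USE.NAMES = FALSE)
  rel$clinical_label <- vapply(rel$clinical_cui, kb_preferred_term, character(1L),
                               kb = kb, USE.NAMES = FALSE)
  rel <- dplyr::select(rel, "genomic_cui", "genomic_label", "clinical_cui",
                       "clinical_label", "method", "direction", "evidence")
  .finish_relations(rel)
}

#' Combine direct and indirect candidate relations
#'
#' With `dedup = FALSE` the two sets are concatenated, so a pair found by
#' both methods is counted twice (the convention behind a combined candidate
#' count).  With `dedup = TRUE` one row is kept per (genomic_cui,
#' clinical_cui) with method tags merged (`direct+indirect`), directions
#' merged, and evidence unioned; deduplication is idempotent.
#'
#' @param direct,indirect Candidate-relation tibbles.
#' @param dedup Merge duplicates across methods?
#' @return A candidate-relation tibble, sorted.
#' @export
combine_candidates <- function(direct, indirect = NULL, dedup = FALSE) {
  if (is.null(indirect)) indirect <- .empty_relations()
  rel <- dplyr::bind_rows(tibble::as_tibble(direct), tibble::as_tibble(indirect))
  if (nrow(rel) == 0L) return(.finish_relations(.empty_relations()))
  if (!dedup) {
    rel <- dplyr::arrange(rel, .data$genomic_cui, .data$clinical_cui,
                          .data$method, .data$direction)
    class(rel) <- c("clingen_relations", class(tibble::tibble()))
    return(rel)
  }
  merge_tags <- function(x, sep) {
    paste(sort(unique(unlist(strsplit(x, sep, fixed = TRUE)))), collapse = sep)
  }
  rel <- rel |>
    dplyr::group_by(.data$genomic_cui, .data$clinical_cui) |>
    dplyr::summarise(
      genomic_label = dplyr::first(.data$genomic_label),
      clinical_label = dplyr::first(.data$clinical_label),
      method = merge_tags(.data$method, "+"),
      direction = merge_tags(.data$direction, "+"),
      evidence = merge_tags(.data$evidence, ";"),
      .groups = "drop"
    ) |>
    dplyr::select("genomic_cui", "genomic_label", "clinical_cui",
                  "clinical_label", "method", "direction", "evidence") |>
    dplyr::arrange(.data$genomic_cui, .data$clinical_cui)
  class(rel) <- c("clingen_relations", class(tibble::tibble()))
  rel
}

#' Plot candidate relations per genomic concept
#'
#' Bar chart of candidate-relation counts by genomic concept, filled by
#' mapping method.
#'
#' @param object A candidate-relation tibble from [direct_map()],
#'   [indirect_map()] or [combine_candidates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.clingen_relations <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$label <- ifelse(is.na(dat$genomic_label) | !nzchar(dat$genomic_label),
                      dat$genomic_cui, dat$genomic_label)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, fill = .data$method)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "genomic concept", y = "candidate relations",
                  fill = "method") +
    ggplot2::theme_minimal()
}
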