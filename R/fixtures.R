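# Seeded synthetic terminology / literature / OMIM-style fixtures with known
# ground truth, so the whole pipeline is testable without licensed
# downloads.  The generator derives its ground truth with its own
# set-intersection code, independent of the mapping engine, so recovery
# tests against it are not circular.

# Run code under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic terminology fixture
#'
#' Defines the study conditions a generated mini knowledge base emulates:
#' counts of gene-like, clinical, disease and unrelated concepts; the
#' probabilities of a direct gene-clinical link and of a concept-disease
#' link; the fraction of diseases tied to the condition of interest; and the
#' fraction of true relations given a supporting literature record.
#'
#' @param seed Integer seed; the same spec (seed included) yields
#'   byte-identical fixture files.
#' @param n_genes,n_clinical,n_diseases,n_other Concept counts per role.
#' @param p_direct_link Probability that a (gene, clinical) pair gets a
#'   direct relation or co-occurrence row.
#' @param p_disease_link Probability that a gene or clinical concept is
#'   linked to any given disease concept.
#' @param crc_fraction Fraction of disease concepts named so that the
#'   condition keyword filter flags them.
#' @param literature_support_fraction Probability that a true relation gets
#'   a supporting record in the generated literature index.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 8L, n_clinical = 10L,
                         n_diseases = 6L, n_other = 6L,
                         p_direct_link = 0.15, p_disease_link = 0.3,
                         crc_fraction = 0.5,
                         literature_support_fraction = 0.8) {
  counts <- c(n_genes = n_genes, n_clinical = n_clinical,
              n_diseases = n_diseases, n_other = n_other)
  if (any(counts < 0L)) stop("counts must be >= 0", call. = FALSE)
  probs <- c(p_direct_link = p_direct_link, p_disease_link = p_disease_link,
             crc_fraction = crc_fraction,
             literature_support_fraction = literature_support_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_clinical = as.integer(n_clinical),
                 n_diseases = as.integer(n_diseases),
                 n_other = as.integer(n_other),
                 p_direct_link = p_direct_link,
                 p_disease_link = p_disease_link,
                 crc_fraction = crc_fraction,
                 literature_support_fraction = literature_support_fraction),
            class = "fixture_spec")
}

# Semantic types by role; "other" gets a type outside every role set.
.role_tuis <- c(gene = "T028", clinical = "T184", disease = "T047",
                other = "T061")
.role_tui_names <- c(gene = "Gene or Genome", clinical = "Sign or Symptom",
                     disease = "Disease or Syndrome",
                     other = "Therapeutic or Preventive Procedure")

#' Generate a synthetic mini terminology release with known ground truth
#'
#' Writes the four RRF files plus genomic/clinical concept-set files to
#' `dir`.  Every concept gets a SNOMED-like preferred atom and a MeSH-like
#' atom; gene-clinical and concept-disease links are sampled per the spec's
#' probabilities as relation or co-occurrence rows; disease concepts flagged
#' as condition-related are named so the keyword filter recognizes them.
#' The returned ground truth (direct pairs, indirect pairs via shared
#' flagged diseases, literature-supported pairs) is computed by the
#' generator's own bookkeeping, not by the mapping engine.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A `mini_umls` object: `dir`, `spec`, `files` (named paths),
#'   `concepts` (tibble: cui, role, term, mesh_term), `ground_truth` (list
#'   of tibbles `direct_relations`, `indirect_relations`, `supported_pairs`).
#' @export
generate_mini_umls <- function(spec = fixture_spec(), dir = tempfile("miniumls")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .with_seed(spec$seed, {
    roles <- rep(c("gene", "clinical", "disease", "other"),
                 c(spec$n_genes, spec$n_clinical, spec$n_diseases, spec$n_other))
    n <- length(roles)
    cuis <- sprintf("C%07d", seq_len(n))
    n_crc <- ceiling(spec$crc_fraction * spec$n_diseases)
    d_idx <- which(roles == "disease")
    is_crc <- logical(n)
    if (n_crc > 0L) is_crc[d_idx[seq_len(n_crc)]] <- TRUE
    terms <- character(n)
    within_role <- stats::ave(seq_len(n), roles, FUN = seq_along)
    terms[roles == "gene"] <- sprintf("gene alpha %03d", within_role[roles == "gene"])
    terms[roles == "clinical"] <- sprintf("clinical finding %03d",
                                          within_role[roles == "clinical"])
    terms[roles == "disease"] <- ifelse(
      is_crc[roles == "disease"],
      sprintf("disease %03d colorectal carcinoma", within_role[roles == "disease"]),
      sprintf("disease %03d metabolic syndrome", within_role[roles == "disease"])
    )
    terms[roles == "other"] <- sprintf("unrelated procedure %03d",
                                       within_role[roles == "other"])
    mesh_terms <- paste("MeSH heading for", terms)

    concepts <- tibble::tibble(cui = cuis, role = roles, term = terms,
                               mesh_term = mesh_terms, is_crc = is_crc)

    blank <- function(k) rep("", k)
    mrconso <- tibble::tibble(
      cui = rep(cuis, each = 2L),
      language = "ENG",
      ts = rep(c("P", "S"), n),
      lui = sprintf("L%07d", seq_len(2L * n)),
      stt = "PF",
      sui = sprintf("S%07d", seq_len(2L * n)),
      ispref = rep(c("Y", "N"), n),
      aui = sprintf("A%07d", seq_len(2L * n)),
      saui = blank(2L * n), scui = blank(2L * n), sdui = blank(2L * n),
      source_vocabulary = rep(c("SNOMEDCT_SYN", "MSH"), n),
      term_type = rep(c("PT", "MH"), n),
      source_code = as.character(rbind(100000L + seq_len(n),
                                       900000L + seq_len(n))),
      term_string = as.character(rbind(terms, mesh_terms)),
      srl = "0",
      suppress = "N",
      cvf = blank(2L * n),
      .extra = blank(2L * n)
    )

    mrsty <- tibble::tibble(
      cui = cuis,
      tui = .role_tuis[roles],
      stn = "A1",
      semantic_type_name = .role_tui_names[roles],
      atui = sprintf("AT%07d", seq_len(n)),
      cvf = blank(n),
      .extra = blank(n)
    )

    # Sampled links; each is stored as either a relation row or a
    # co-occurrence row, in a random orientation.
    link_rows <- list()
    add_link <- function(a, b) {
      flip <- stats::runif(1) < 0.5
      link_rows[[length(link_rows) + 1L]] <<- tibble::tibble(
        cui1 = if (flip) b else a, cui2 = if (flip) a else b,
        via = if (stats::runif(1) < 0.5) "MRREL" else "MRCOC",
        frequency = sample(1:5, 1L)
      )
    }
    g_idx <- which(roles == "gene")
    c_idx <- which(roles == "clinical")
    o_idx <- which(roles == "other")
    direct_pairs <- list()
    for (g in g_idx) {
      for (cc in c_idx) {
        if (stats::runif(1) < spec$p_direct_link) {
          add_link(cuis[g], cuis[cc])
          direct_pairs[[length(direct_pairs) + 1L]] <-
            c(genomic_cui = cuis[g], clinical_cui = cuis[cc])
        }
      }
    }
    disease_links <- list() # concept cui -> linked disease cuis
    for (x in c(g_idx, c_idx)) {
      linked <- character()
      for (d in d_idx) {
        if (stats::runif(1) < spec$p_disease_link) {
          add_link(cuis[x], cuis[d])
          linked <- c(linked, cuis[d])
        }
      }
      disease_links[[cuis[x]]] <- linked
    }
    # Noise: sporadic links into concepts of no mapped role.
    for (x in c(g_idx, c_idx)) {
      for (o in o_idx) {
        if (stats::runif(1) < spec$p_direct_link / 2) add_link(cuis[x], cuis[o])
      }
    }

    links <- if (length(link_rows) > 0L) purrr::list_rbind(link_rows) else {
      tibble::tibble(cui1 = character(), cui2 = character(),
                     via = character(), frequency = integer())
    }
    rel_links <- links[links$via == "MRREL", , drop = FALSE]
    coc_links <- links[links$via == "MRCOC", , drop = FALSE]
    k <- nrow(rel_links)
    mrrel <- tibble::tibble(
      cui1 = rel_links$cui1, aui1 = blank(k), stype1 = rep("CUI", k),
      rel_label = rep("RO", k), cui2 = rel_links$cui2, aui2 = blank(k),
      stype2 = rep("CUI", k), rela_label = blank(k),
      rui = sprintf("R%07d", seq_len(k)), srui = blank(k),
      source_vocabulary = rep("SNOMEDCT_SYN", k), sl = rep("SNOMEDCT_SYN", k),
      rg = blank(k), dir = blank(k), suppress = rep("N", k), cvf = blank(k),
      .extra = blank(k)
    )
    k <- nrow(coc_links)
    mrcoc <- tibble::tibble(
      cui1 = coc_links$cui1, aui1 = blank(k), cui2 = coc_links$cui2,
      aui2 = blank(k), source_vocabulary = rep("MED", k),
      cooccurrence_type = rep("L", k), frequency = coc_links$frequency,
      coa = blank(k), cvf = blank(k), .extra = blank(k)
    )

    # Ground truth by independent set intersection over the generator's own
    # link bookkeeping.
    direct_relations <- if (length(direct_pairs) > 0L) {
      dplyr::distinct(tibble::as_tibble(do.call(rbind, direct_pairs)))
    } else {
      tibble::tibble(genomic_cui = character(), clinical_cui = character())
    }
    direct_relations <- dplyr::arrange(direct_relations, .data$genomic_cui,
                                       .data$clinical_cui)
    crc_cuis <- cuis[is_crc]
    indirect_list <- list()
    for (g in g_idx) {
      for (cc in c_idx) {
        shared <- character()
        for (d in crc_cuis) {
          if (d %in% disease_links[[cuis[g]]] && d %in% disease_links[[cuis[cc]]]) {
            shared <- c(shared, d)
          }
        }
        if (length(shared) > 0L) {
          indirect_list[[length(indirect_list) + 1L]] <- tibble::tibble(
            genomic_cui = cuis[g], clinical_cui = cuis[cc],
            shared_diseases = paste(sort(shared), collapse = ";")
          )
        }
      }
    }
    indirect_relations <- if (length(indirect_list) > 0L) {
      purrr::list_rbind(indirect_list)
    } else {
      tibble::tibble(genomic_cui = character(), clinical_cui = character(),
                     shared_diseases = character())
    }
    indirect_relations <- dplyr::arrange(indirect_relations, .data$genomic_cui,
                                         .data$clinical_cui)

    true_pairs <- dplyr::distinct(dplyr::bind_rows(
      direct_relations[, c("genomic_cui", "clinical_cui")],
      indirect_relations[, c("genomic_cui", "clinical_cui")]
    ))
    true_pairs <- dplyr::arrange(true_pairs, .data$genomic_cui, .data$clinical_cui)
    supported <- stats::runif(nrow(true_pairs)) < spec$literature_support_fraction
    supported_pairs <- true_pairs[supported, , drop = FALSE]

    files <- c(
      MRCONSO = file.path(dir, "MRCONSO.RRF"),
      MRREL = file.path(dir, "MRREL.RRF"),
      MRCOC = file.path(dir, "MRCOC.RRF"),
      MRSTY = file.path(dir, "MRSTY.RRF"),
      genomic_set = file.path(dir, "G.txt"),
      clinical_set = file.path(dir, "C.txt")
    )
    write_rrf_table(mrconso, files[["MRCONSO"]], "MRCONSO")
    write_rrf_table(mrrel, files[["MRREL"]], "MRREL")
    write_rrf_table(mrcoc, files[["MRCOC"]], "MRCOC")
    write_rrf_table(mrsty, files[["MRSTY"]], "MRSTY")
    writeLines(paste0("CUI:", cuis[g_idx]), files[["genomic_set"]], useBytes = TRUE)
    writeLines(paste0("CUI:", cuis[c_idx]), files[["clinical_set"]], useBytes = TRUE)

    structure(list(
      dir = dir, spec = spec, files = files, concepts = concepts,
      ground_truth = list(direct_relations = direct_relations,
                          indirect_relations = indirect_relations,
                          supported_pairs = supported_pairs)
    ), class = "mini_umls")
  })
}

#' Generate an offline literature index matching a fixture's ground truth
#'
#' One record per literature-supported true relation, annotated with the
#' MeSH terms of both concepts plus the context term, so validation over the
#' generated index passes exactly the supported pairs.
#'
#' @param mini A `mini_umls` from [generate_mini_umls()].
#' @param path Output path; default `literature_index.tsv` in the fixture
#'   directory.
#' @param context_term Context MeSH term added to every record.
#' @return The `lit_index` tibble, invisibly; the file is written to `path`.
#' @export
generate_literature_index <- function(mini, path = file.path(mini$dir, "literature_index.tsv"),
                                      context_term = "Colorectal neoplasms") {
  stopifnot(inherits(mini, "mini_umls"))
  supported <- mini$ground_truth$supported_pairs
  mesh_of <- stats::setNames(mini$concepts$mesh_term, mini$concepts$cui)
  idx <- literature_index(
    record_id = sprintf("REC%05d", seq_len(nrow(supported))),
    terms = purrr::map2(supported$genomic_cui, supported$clinical_cui,
                        function(g, c) c(mesh_of[[g]], mesh_of[[c]], context_term))
  )
  write_literature_index(idx, path)
  invisible(idx)
}

#' @export
print.mini_umls <- function(x, ...) {
  cat("<mini_umls> ", nrow(x$concepts), " concepts in ", x$dir, "\n", sep = "")
  cat("  ground truth: ", nrow(x$ground_truth$direct_relations), " direct, ",
      nrow(x$ground_truth$indirect_relations), " indirect, ",
      nrow(x$ground_truth$supported_pairs), " literature-supported\n", sep = "")
  invisible(x)
}

#' Glance at a synthetic fixture
#'
#' @param x A `mini_umls`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.mini_umls <- function(x, ...) {
  tibble::tibble(
    n_concepts = nrow(x$concepts),
    n_genes = sum(x$concepts$role == "gene"),
    n_clinical = sum(x$concepts$role == "clinical"),
    n_diseases = sum(x$concepts$role == "disease"),
    n_direct_true = nrow(x$ground_truth$direct_relations),
    n_indirect_true = nrow(x$ground_truth$indirect_relations),
    n_supported = nrow(x$ground_truth$supported_pairs)
  )
}

#' Packaged representative clinic-genomic relation table
#'
#' Loads the bundled table of ten representative clinical data items and the
#' gene sets each was related to (symptoms, blood tests, pathology states
#' and diseases relevant to colorectal cancer).
#'
#' @return A tibble with one row per (clinical_item, gene) pair, in the
#'   printed order.
#' @export
load_table1_relations <- function() {
  path <- system.file("extdata", "table1_relations.tsv", package = "clingenmap")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged relation table is missing", call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop("packaged relation table is corrupt", call. = FALSE)
  }
  items <- vapply(fields, `[[`, character(1L), 1L)
  genes <- purrr::map(fields, function(f) trimws(strsplit(f[[2L]], ",")[[1L]]))
  tibble::tibble(clinical_item = rep(items, lengths(genes)),
                 gene = unlist(genes, use.names = FALSE))
}

#' Gene set of one packaged clinical item
#'
#' @param item Clinical data item name (exact match).
#' @return Sorted character vector of gene symbols; empty for an unknown
#'   item.
#' @export
table1_genes <- function(item) {
  tab <- load_table1_relations()
  sort(unique(tab$gene[tab$clinical_item == item]))
}
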