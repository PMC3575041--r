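# Independent brute-force enumeration of direct and indirect relations,
# written as plain row loops over the raw tables (no knowledge base, no set
# machinery) so it shares no code path with the mapping engine.

oracle_not_suppressed <- function(flag) flag == "" || flag == "N"

# Is there a qualifying one-step link from s to t in the raw tables?
oracle_linked <- function(s, t, mrrel, mrcoc, config) {
  if (s == t) return(FALSE)
  if (config$use_mrrel && nrow(mrrel) > 0L) {
    for (r in seq_len(nrow(mrrel))) {
      if (!config$include_suppressed && !oracle_not_suppressed(mrrel$suppress[r])) next
      if (length(config$rel_whitelist) > 0L &&
          !(mrrel$rel_label[r] %in% config$rel_whitelist)) next
      fwd <- mrrel$cui1[r] == s && mrrel$cui2[r] == t
      bwd <- mrrel$cui1[r] == t && mrrel$cui2[r] == s
      if (fwd || (config$treat_relations_as_bidirectional && bwd)) return(TRUE)
    }
  }
  if (config$use_mrcoc && nrow(mrcoc) > 0L) {
    for (r in seq_len(nrow(mrcoc))) {
      if (mrcoc$frequency[r] < config$min_cooccurrence_frequency) next
      if ((mrcoc$cui1[r] == s && mrcoc$cui2[r] == t) ||
          (mrcoc$cui1[r] == t && mrcoc$cui2[r] == s)) return(TRUE)
    }
  }
  FALSE
}

oracle_has_tui <- function(cui, tuis, mrsty) {
  for (r in seq_len(nrow(mrsty))) {
    if (mrsty$cui[r] == cui && mrsty$tui[r] %in% tuis) return(TRUE)
  }
  FALSE
}

# Sorted (genomic_cui, clinical_cui) pairs reachable by direct mapping with
# genomic sources.
oracle_direct_pairs <- function(g_cuis, c_cuis, tabs, config) {
  rows <- list()
  for (g in sort(g_cuis)) {
    for (cc in sort(c_cuis)) {
      if (!oracle_has_tui(cc, config$clinical_tuis, tabs$mrsty)) next
      if (oracle_linked(g, cc, tabs$mrrel, tabs$mrcoc, config)) {
        rows[[length(rows) + 1L]] <- c(g, cc)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(genomic_cui = character(), clinical_cui = character()))
  }
  m <- do.call(rbind, rows)
  tibble::tibble(genomic_cui = m[, 1L], clinical_cui = m[, 2L])
}

# Condition diseases per the keyword rule, recomputed from the raw atom
# table with its own regex.
oracle_crc_diseases <- function(tabs, config) {
  crc <- character()
  disease_cuis <- unique(tabs$mrsty$cui[tabs$mrsty$tui %in% config$disease_tuis])
  site_re <- paste0("\\b(", paste(config$crc_site_keywords, collapse = "|"), ")\\b")
  dis_re <- paste0("\\b(", paste(config$crc_disease_keywords, collapse = "|"), ")\\b")
  for (d in disease_cuis) {
    idx <- which(tabs$mrconso$cui == d &
                   (tabs$mrconso$suppress == "N" | tabs$mrconso$suppress == ""))
    pref <- idx[tabs$mrconso$ispref[idx] == "Y"]
    use <- if (length(pref) > 0L) pref[1L] else if (length(idx) > 0L) idx[1L] else NA_integer_
    if (is.na(use)) next
    term <- tabs$mrconso$term_string[use]
    if (grepl(site_re, term, ignore.case = TRUE) &&
        grepl(dis_re, term, ignore.case = TRUE)) {
      crc <- c(crc, d)
    }
  }
  crc
}

# Sorted indirect pairs with their shared-disease evidence.
oracle_indirect_pairs <- function(g_cuis, c_cuis, tabs, config) {
  crc <- oracle_crc_diseases(tabs, config)
  rows <- list()
  for (g in sort(g_cuis)) {
    for (cc in sort(c_cuis)) {
      shared <- character()
      for (d in crc) {
        if (d == g || d == cc) next
        if (oracle_linked(g, d, tabs$mrrel, tabs$mrcoc, config) &&
            oracle_linked(cc, d, tabs$mrrel, tabs$mrcoc, config)) {
          shared <- c(shared, d)
        }
      }
      if (length(shared) > 0L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          genomic_cui = g, clinical_cui = cc,
          evidence = paste(sort(shared), collapse = ";")
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(genomic_cui = character(), clinical_cui = character(),
                          evidence = character()))
  }
  purrr::list_rbind(rows)
}

pair_set <- function(rel) {
  out <- unique(tibble::as_tibble(rel)[, c("genomic_cui", "clinical_cui")])
  out[order(out$genomic_cui, out$clinical_cui), ]
}
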