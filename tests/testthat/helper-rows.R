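# Builders for single typed RRF rows, used to construct fixtures in code.

mk_conso <- function(cui, term_string, source_vocabulary = "SNOMEDCT_SYN",
                     source_code = "0", ispref = "Y", suppress = "N",
                     language = "ENG", term_type = "PT", extra = "") {
  tibble::tibble(
    cui = cui, language = language, ts = "P", lui = "L0000001", stt = "PF",
    sui = "S0000001", ispref = ispref, aui = "A0000001", saui = "",
    scui = "", sdui = "", source_vocabulary = source_vocabulary,
    term_type = term_type, source_code = source_code,
    term_string = term_string, srl = "0", suppress = suppress, cvf = "",
    .extra = extra
  )
}

mk_rel <- function(cui1, cui2, rel_label = "RO", rela_label = "",
                   suppress = "N", source_vocabulary = "SRC") {
  tibble::tibble(
    cui1 = cui1, aui1 = "", stype1 = "CUI", rel_label = rel_label,
    cui2 = cui2, aui2 = "", stype2 = "CUI", rela_label = rela_label,
    rui = "R0000001", srui = "", source_vocabulary = source_vocabulary,
    sl = source_vocabulary, rg = "", dir = "", suppress = suppress,
    cvf = "", .extra = ""
  )
}

mk_coc <- function(cui1, cui2, frequency, cooccurrence_type = "L") {
  tibble::tibble(
    cui1 = cui1, aui1 = "", cui2 = cui2, aui2 = "",
    source_vocabulary = "MED", cooccurrence_type = cooccurrence_type,
    frequency = as.integer(frequency), coa = "", cvf = "", .extra = ""
  )
}

mk_sty <- function(cui, tui, semantic_type_name = "") {
  tibble::tibble(
    cui = cui, tui = tui, stn = "A1",
    semantic_type_name = semantic_type_name, atui = "AT0000001", cvf = "",
    .extra = ""
  )
}

rbindt <- function(...) dplyr::bind_rows(...)

# Random raw RRF tables for round-trip and index-coherence properties.
# Adversarial on purpose: suppressed rows, self-relations, zero and
# sub-threshold frequencies, shared term strings across CUIs.
random_rrf_tables <- function(seed, n_cuis = 12L) {
  set.seed(seed)
  cuis <- sprintf("C%07d", sample.int(99999L, n_cuis))
  terms <- paste("term", sample(letters, n_cuis, replace = TRUE))
  sabs <- sample(c("SNOMEDCT_SYN", "MSH", "SRC"), n_cuis, replace = TRUE)
  mrconso <- purrr::list_rbind(lapply(seq_len(n_cuis), function(i) {
    mk_conso(cuis[i], terms[i], source_vocabulary = sabs[i],
             source_code = as.character(1000L + i),
             ispref = sample(c("Y", "N"), 1L),
             suppress = sample(c("N", "N", "N", "O"), 1L))
  }))
  n_rel <- sample(0:20, 1L)
  mrrel <- purrr::list_rbind(lapply(seq_len(n_rel), function(i) {
    mk_rel(sample(cuis, 1L), sample(cuis, 1L),
           rel_label = sample(c("RO", "RB", "RN"), 1L),
           suppress = sample(c("N", "N", "N", "Y"), 1L))
  }))
  n_coc <- sample(0:20, 1L)
  mrcoc <- purrr::list_rbind(lapply(seq_len(n_coc), function(i) {
    mk_coc(sample(cuis, 1L), sample(cuis, 1L), frequency = sample(0:6, 1L))
  }))
  mrsty <- purrr::list_rbind(lapply(seq_len(n_cuis), function(i) {
    mk_sty(cuis[i], sample(c("T028", "T184", "T047", "T061"), 1L))
  }))
  # some CUIs carry a second semantic type
  extra_sty <- purrr::list_rbind(lapply(sample(seq_len(n_cuis), 3L), function(i) {
    mk_sty(cuis[i], sample(c("T191", "T033"), 1L))
  }))
  list(cuis = cuis, mrconso = mrconso, mrrel = mrrel, mrcoc = mrcoc,
       mrsty = dplyr::distinct(rbindt(mrsty, extra_sty), cui, tui, .keep_all = TRUE))
}

# Random mapping scenario with role-typed concepts, used for oracle
# equivalence.  Returns raw tables plus the G and C reference vectors.
random_mapping_fixture <- function(seed) {
  set.seed(seed)
  n_g <- sample(2:5, 1L); n_c <- sample(2:5, 1L)
  n_d <- sample(2:4, 1L); n_o <- sample(1:3, 1L)
  n <- n_g + n_c + n_d + n_o
  roles <- rep(c("gene", "clinical", "disease", "other"), c(n_g, n_c, n_d, n_o))
  cuis <- sprintf("C%07d", seq_len(n) + seed %% 1000L * 100L)
  is_crc <- roles == "disease" & stats::runif(n) < 0.6
  terms <- ifelse(is_crc,
                  paste("neoplasm", seq_len(n), "rectal carcinoma"),
                  paste("concept", seq_len(n)))
  tuis <- c(gene = "T028", clinical = "T184", disease = "T047", other = "T061")[roles]
  mrconso <- purrr::list_rbind(lapply(seq_len(n), function(i) {
    rbindt(
      mk_conso(cuis[i], terms[i], source_code = as.character(i)),
      mk_conso(cuis[i], paste("mesh", terms[i]), source_vocabulary = "MSH",
               source_code = paste0("D", i), ispref = "N", term_type = "MH")
    )
  }))
  mrsty <- purrr::list_rbind(lapply(seq_len(n), function(i) mk_sty(cuis[i], tuis[i])))
  n_rel <- sample(5:25, 1L)
  mrrel <- purrr::list_rbind(lapply(seq_len(n_rel), function(i) {
    mk_rel(sample(cuis, 1L), sample(cuis, 1L),
           suppress = sample(c("N", "N", "N", "Y"), 1L))
  }))
  n_coc <- sample(5:25, 1L)
  mrcoc <- purrr::list_rbind(lapply(seq_len(n_coc), function(i) {
    mk_coc(sample(cuis, 1L), sample(cuis, 1L), frequency = sample(0:4, 1L))
  }))
  list(mrconso = mrconso, mrrel = mrrel, mrcoc = mrcoc, mrsty = mrsty,
       g_refs = paste0("CUI:", cuis[roles == "gene"]),
       c_refs = paste0("CUI:", cuis[roles == "clinical"]),
       g_cuis = cuis[roles == "gene"], c_cuis = cuis[roles == "clinical"])
}
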