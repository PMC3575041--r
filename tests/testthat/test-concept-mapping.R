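# A small, fully hand-specified scenario used by several tests:
#   g1 gene, c1/c2 clinical, d1 (condition-flagged) and d2 (not) diseases.
scenario_kb <- function() {
  mrconso <- rbindt(
    mk_conso("C0000001", "gene alpha", source_code = "g1"),
    mk_conso("C0000002", "clinical finding one", source_code = "c1"),
    mk_conso("C0000003", "clinical finding two", source_code = "c2"),
    mk_conso("C0000004", "rectal carcinoma", source_code = "d1"),
    mk_conso("C0000005", "metabolic syndrome", source_code = "d2")
  )
  mrsty <- rbindt(
    mk_sty("C0000001", "T028"), mk_sty("C0000002", "T184"),
    mk_sty("C0000003", "T184"), mk_sty("C0000004", "T047"),
    mk_sty("C0000005", "T047")
  )
  mrrel <- rbindt(
    mk_rel("C0000001", "C0000002"),            # g1 - c1 direct
    mk_rel("C0000001", "C0000004"),            # g1 - d1
    mk_rel("C0000004", "C0000002"),            # d1 - c1
    mk_rel("C0000005", "C0000001"),            # d2 - g1
    mk_rel("C0000005", "C0000003")             # d2 - c2
  )
  mrcoc <- mk_coc("C0000003", "C0000005", 2L)  # duplicate d2 - c2 as co-occurrence
  build_kb(mrconso, mrrel, mrcoc, mrsty)
}

test_that("term resolution returns all matching CUIs, ambiguity included", {
  kb <- scenario_kb()
  expect_equal(resolve_cuis("absent concept", kb), character())
  expect_equal(resolve_cuis("Gene Alpha", kb), "C0000001") # case-insensitive
  expect_equal(resolve_cuis("CUI:C0000004", kb), "C0000004")
  expect_equal(resolve_cuis("SNOMEDCT_SYN:c2", kb), "C0000003")

  # one term carried by two concepts -> both returned
  amb <- build_kb(rbindt(mk_conso("C0000010", "shared term", source_code = "a"),
                         mk_conso("C0000011", "Shared Term", source_code = "b")))
  expect_equal(resolve_cuis("shared term", amb), c("C0000010", "C0000011"))

  # suppressed atoms are excluded unless configured in
  sup <- build_kb(mk_conso("C0000012", "hidden", suppress = "O"))
  expect_equal(resolve_cuis("hidden", sup), character())
  expect_equal(resolve_cuis("hidden", sup, mapping_config(include_suppressed = TRUE)),
               "C0000012")
})

test_that("one-step neighbourhoods honour thresholds, suppression and self-relations", {
  kb <- scenario_kb()
  cfg <- mapping_config()
  expect_equal(related_concepts("C0000001", kb, cfg),
               c("C0000002", "C0000004", "C0000005"))
  # isolated concept
  iso <- build_kb(mk_conso("C0000020", "loner"))
  expect_equal(related_concepts("C0000020", iso, cfg), character())

  # 3 relation rows + 2 co-occurrence rows, one below threshold -> 4 counterparts
  kb2 <- build_kb(
    mrrel = rbindt(mk_rel("C0000001", "C0000002"), mk_rel("C0000003", "C0000001"),
                   mk_rel("C0000001", "C0000004")),
    mrcoc = rbindt(mk_coc("C0000001", "C0000005", 3L), mk_coc("C0000006", "C0000001", 1L))
  )
  expect_equal(related_concepts("C0000001", kb2, mapping_config(min_cooccurrence_frequency = 2)),
               c("C0000002", "C0000003", "C0000004", "C0000005"))
  expect_equal(related_concepts("C0000001", kb2, cfg),
               c("C0000002", "C0000003", "C0000004", "C0000005", "C0000006"))

  # self-relations are ignored; suppressed relation rows too
  kb3 <- build_kb(mrrel = rbindt(mk_rel("C0000001", "C0000001"),
                                 mk_rel("C0000001", "C0000002", suppress = "Y")))
  expect_equal(related_concepts("C0000001", kb3, cfg), character())

  # directional traversal only follows the cui1 side
  kb4 <- build_kb(mrrel = mk_rel("C0000002", "C0000001"))
  one_way <- mapping_config(treat_relations_as_bidirectional = FALSE)
  expect_equal(related_concepts("C0000001", kb4, one_way), character())
  expect_equal(related_concepts("C0000002", kb4, one_way), "C0000001")
})

test_that("semantic-type filtering keeps exactly the concepts with an allowed TUI", {
  kb <- scenario_kb()
  cuis <- sprintf("C%07d", 1:5)
  expect_equal(filter_by_semantic_type(cuis, kb, character()), character())
  expect_equal(filter_by_semantic_type(cuis, kb, "T047"), c("C0000004", "C0000005"))
  # a concept with both a gene-like and a disease-like type passes either filter
  both <- build_kb(mrsty = rbindt(mk_sty("C0000030", "T028"), mk_sty("C0000030", "T047")))
  expect_equal(filter_by_semantic_type("C0000030", both, "T028"), "C0000030")
  expect_equal(filter_by_semantic_type("C0000030", both, "T047"), "C0000030")
})

test_that("direct mapping finds exactly the linked, type-matched, in-set pairs", {
  kb <- scenario_kb()
  g <- "CUI:C0000001"
  c_set <- c("CUI:C0000002", "CUI:C0000003")
  rel <- direct_map(g, c_set, kb)
  expect_equal(pair_set(rel),
               tibble::tibble(genomic_cui = "C0000001", clinical_cui = "C0000002"),
               ignore_attr = TRUE)
  # evidence names the supporting stored row
  expect_match(rel$evidence[1], "MRREL:C0000001:RO:C0000002")
  # labels come from the preferred atoms
  expect_equal(rel$genomic_label[1], "gene alpha")

  # empty relation tables -> no relations for any sets
  empty <- build_kb(scenario_kb()$atoms, mrsty = scenario_kb()$semantic_types)
  expect_equal(nrow(direct_map(g, c_set, empty)), 0L)

  # unresolvable sources are skipped with a warning, not an error
  expect_warning(direct_map(c("CUI:C0000001", "no such concept"), c_set, kb),
                 "unresolvable")
})

test_that("mirrored relation storage gives mirror-image directed maps", {
  # all relation rows stored in both orientations
  mrrel <- rbindt(mk_rel("C0000001", "C0000002"), mk_rel("C0000002", "C0000001"))
  kb <- build_kb(
    rbindt(mk_conso("C0000001", "g", source_code = "1"),
           mk_conso("C0000002", "c", source_code = "2")),
    mrrel, NULL,
    rbindt(mk_sty("C0000001", "T028"), mk_sty("C0000002", "T184"))
  )
  g2c <- direct_map("CUI:C0000001", "CUI:C0000002", kb, directions = "genomic_to_clinic")
  c2g <- direct_map("CUI:C0000001", "CUI:C0000002", kb, directions = "clinic_to_genomic")
  expect_equal(pair_set(g2c), pair_set(c2g))
  expect_equal(g2c$direction, "genomic_to_clinic")
  expect_equal(c2g$direction, "clinic_to_genomic")
})

test_that("disease neighbourhoods respect the co-occurrence threshold", {
  kb <- scenario_kb()
  cfg <- mapping_config()
  expect_equal(diseases_for("C0000001", kb, cfg), c("C0000004", "C0000005"))
  # an isolated concept has no disease neighbours
  expect_equal(diseases_for("C0000004", build_kb(mk_conso("C0000004", "x")), cfg),
               character())
  # c2's only tie to d2 below threshold via relation? remove relation rows:
  coc_only <- build_kb(scenario_kb()$atoms, NULL, mk_coc("C0000003", "C0000005", 2L),
                       scenario_kb()$semantic_types)
  expect_equal(diseases_for("C0000003", coc_only, cfg), "C0000005")
  expect_equal(diseases_for("C0000003", coc_only,
                            mapping_config(min_cooccurrence_frequency = 3)),
               character())
})

test_that("indirect mapping requires a shared condition-flagged disease", {
  kb <- scenario_kb()
  g <- "CUI:C0000001"
  c_set <- c("CUI:C0000002", "CUI:C0000003")
  rel <- indirect_map(g, c_set, kb)
  # g1 and c1 share d1 (flagged); g1 and c2 share only d2 (not flagged)
  expect_equal(nrow(rel), 1L)
  expect_equal(rel$genomic_cui, "C0000001")
  expect_equal(rel$clinical_cui, "C0000002")
  expect_equal(rel$evidence, "C0000004")
  expect_equal(rel$direction, "undirected")

  # empty condition set -> no indirect relations ever
  none <- mapping_config(crc_disease_cuis = character())
  expect_equal(nrow(indirect_map(g, c_set, kb, none)), 0L)

  # explicit CUI set overrides the keyword rule
  explicit <- mapping_config(crc_disease_cuis = "C0000005")
  rel2 <- indirect_map(g, c_set, kb, explicit)
  expect_equal(rel2$clinical_cui, "C0000003")
  expect_equal(rel2$evidence, "C0000005")
})

test_that("shrinking the condition disease set never adds indirect relations", {
  for (seed in 1:6) {
    fix <- random_mapping_fixture(seed)
    kb <- build_kb(fix$mrconso, fix$mrrel, fix$mrcoc, fix$mrsty)
    full_crc <- condition_disease_cuis(kb)
    rel_full <- indirect_map(fix$g_refs, fix$c_refs, kb)
    for (k in c(length(full_crc) %/% 2L, 0L)) {
      sub_cfg <- mapping_config(crc_disease_cuis = head(full_crc, k))
      rel_sub <- indirect_map(fix$g_refs, fix$c_refs, kb, sub_cfg)
      sub_pairs <- pair_set(rel_sub)
      full_pairs <- pair_set(rel_full)
      merged <- dplyr::inner_join(sub_pairs, full_pairs,
                                  by = c("genomic_cui", "clinical_cui"))
      expect_equal(nrow(merged), nrow(sub_pairs)) # subset, never new pairs
    }
  }
})

test_that("direct and indirect mapping match the brute-force enumerator", {
  for (seed in 1:25) {
    fix <- random_mapping_fixture(seed + 1000L)
    kb <- build_kb(fix$mrconso, fix$mrrel, fix$mrcoc, fix$mrsty)
    for (cfg in list(mapping_config(),
                     mapping_config(min_cooccurrence_frequency = 2,
                                    treat_relations_as_bidirectional = FALSE))) {
      eng <- direct_map(fix$g_refs, fix$c_refs, kb, cfg,
                        directions = "genomic_to_clinic")
      expect_equal(pair_set(eng),
                   pair_set(oracle_direct_pairs(fix$g_cuis, fix$c_cuis, fix, cfg)),
                   ignore_attr = TRUE)
      eng_i <- indirect_map(fix$g_refs, fix$c_refs, kb, cfg)
      ora_i <- oracle_indirect_pairs(fix$g_cuis, fix$c_cuis, fix, cfg)
      expect_equal(pair_set(eng_i), pair_set(ora_i), ignore_attr = TRUE)
      # evidence disease sets agree row for row
      if (nrow(eng_i) > 0L) {
        expect_equal(eng_i$evidence, ora_i$evidence)
      }
    }
  }
})

test_that("adding a relation row never removes a direct relation", {
  fix <- random_mapping_fixture(7)
  kb1 <- build_kb(fix$mrconso, fix$mrrel, fix$mrcoc, fix$mrsty)
  before <- pair_set(direct_map(fix$g_refs, fix$c_refs, kb1))
  extra <- mk_rel(fix$g_cuis[1], fix$c_cuis[1])
  kb2 <- build_kb(fix$mrconso, rbindt(fix$mrrel, extra), fix$mrcoc, fix$mrsty)
  after <- pair_set(direct_map(fix$g_refs, fix$c_refs, kb2))
  expect_equal(nrow(dplyr::inner_join(before, after,
                                      by = c("genomic_cui", "clinical_cui"))),
               nrow(before))
})

test_that("raising the co-occurrence threshold never adds a direct relation", {
  fix <- random_mapping_fixture(11)
  kb <- build_kb(fix$mrconso, fix$mrrel, fix$mrcoc, fix$mrsty)
  lo <- pair_set(direct_map(fix$g_refs, fix$c_refs, kb, mapping_config()))
  hi <- pair_set(direct_map(fix$g_refs, fix$c_refs, kb,
                            mapping_config(min_cooccurrence_frequency = 3)))
  expect_equal(nrow(dplyr::inner_join(hi, lo, by = c("genomic_cui", "clinical_cui"))),
               nrow(hi))
})

test_that("combining candidates concatenates or merges; dedup is idempotent", {
  empty_rel <- suppressWarnings(direct_map("x", "y", build_kb()))
  expect_equal(nrow(combine_candidates(empty_rel)), 0L)
  kb <- scenario_kb()
  d <- direct_map("CUI:C0000001", c("CUI:C0000002", "CUI:C0000003"), kb)
  i <- indirect_map("CUI:C0000001", c("CUI:C0000002", "CUI:C0000003"), kb)
  # the (g1, c1) pair is found by both methods
  cat_all <- combine_candidates(d, i, dedup = FALSE)
  expect_equal(nrow(cat_all), nrow(d) + nrow(i))
  merged <- combine_candidates(d, i, dedup = TRUE)
  expect_equal(nrow(merged), nrow(pair_set(cat_all)))
  both <- merged[merged$genomic_cui == "C0000001" & merged$clinical_cui == "C0000002", ]
  expect_equal(both$method, "direct+indirect")
  # idempotent
  again <- combine_candidates(merged, dedup = TRUE)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(merged))
})

test_that("mapping output is deterministic and sorted", {
  fix <- random_mapping_fixture(13)
  kb <- build_kb(fix$mrconso, fix$mrrel, fix$mrcoc, fix$mrsty)
  r1 <- direct_map(fix$g_refs, fix$c_refs, kb)
  r2 <- direct_map(rev(fix$g_refs), rev(fix$c_refs), kb)
  expect_identical(r1, r2)
  key <- paste(r1$genomic_cui, r1$clinical_cui, r1$method, r1$direction)
  expect_equal(key, sort(key))
})

test_that("a config must enable a traversal source and a sane threshold", {
  expect_error(mapping_config(use_mrrel = FALSE, use_mrcoc = FALSE), "at least one")
  expect_error(mapping_config(min_cooccurrence_frequency = 0), ">= 1")
})

test_that("a YAML config file round-trips into a mapping_config", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_cooccurrence_frequency: 3", "use_mrcoc: false",
               "genomic_tuis:", "- T028", "- T087"), tf)
  cfg <- read_mapping_config(tf)
  expect_equal(cfg$min_cooccurrence_frequency, 3L)
  expect_false(cfg$use_mrcoc)
  expect_equal(cfg$genomic_tuis, c("T028", "T087"))
  writeLines("not_a_key: 1", tf)
  expect_error(read_mapping_config(tf), "unknown mapping_config key")
})
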