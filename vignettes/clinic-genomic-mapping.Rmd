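---
title: "Mining clinic-genomic relations through a terminology knowledge base"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining clinic-genomic relations through a terminology knowledge base}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clingenmap)
```

## The problem

Clinical observations (symptoms, laboratory results, pathology states,
SNOMED CT-coded data items) and genomic entities (genes) live in different
vocabularies and different databases. A unified medical terminology that
links atoms from many source vocabularies under concept unique identifiers
(CUIs), records inter-concept relations and literature co-occurrences, and
types every concept semantically, provides a bridge: if a gene concept and a
clinical concept are connected in the terminology graph, that is a candidate
clinic-genomic relation worth surfacing to translational researchers.

`clingenmap` implements that mining pipeline end to end:

1. **Terminology I/O** — read the four pipe-delimited release tables
   (concept atoms, relations, co-occurrences, semantic types) into an
   indexed in-memory knowledge base.
2. **Direct mapping** — relate a genomic concept set *G* and a clinical
   concept set *C* through one-step traversal.
3. **Indirect mapping via disease** — relate *g* ∈ *G* and *c* ∈ *C* when
   their disease neighbourhoods share a disease tied to the condition of
   interest (here: colorectal cancer).
4. **Literature validation** — keep a candidate relation only if at least
   one indexed article co-mentions MeSH headings of both concepts together
   with a context heading.
5. **Gene set extraction** — a field-restricted boolean keyword search over
   OMIM-style entries, joined out to protein and article identifiers.
6. **Postcoordination** — compose and parse the flat
   `focus : attribute = value, ...` subset of SNOMED CT compositional
   expressions used to code clinical items not present as single concepts.

## The mapping model

Write `N(x)` for the one-step neighbourhood of a concept `x`: the
counterpart CUIs of all non-suppressed relation rows touching `x`, plus the
counterparts of co-occurrence rows touching `x` whose frequency reaches a
threshold. Write `T(S)` for restriction of a CUI set to those carrying at
least one semantic type in the set `T`.

**Direct mapping** with genomic sources emits a candidate `(g, c)` for every
`g ∈ G` and `c ∈ T_clinical(N(g)) ∩ C`; with clinical sources,
symmetrically, `c ∈ C` and `g ∈ T_gene(N(c)) ∩ G`. Each direction is
recorded (`genomic_to_clinic` / `clinic_to_genomic`), and the supporting
relation and co-occurrence rows travel with the candidate as evidence.

**Indirect mapping** computes disease neighbourhoods
`U1(g) = T_disease(N(g))` and `U2(c) = T_disease(N(c))` and emits an
undirected candidate `(g, c)` whenever
`U1(g) ∩ U2(c) ∩ D_condition ≠ ∅`, with the shared disease CUIs as
evidence. `D_condition` is the set of diseases related to the condition of
interest.

**Validation** extracts each concept's MeSH-source synonyms from the atom
table and renders queries from the fixed template

```
{X}[MeSH Terms] AND {Y}[MeSH Terms] AND Colorectal neoplasms[MeSH Terms]
```

A candidate passes when some term combination has at least one article hit.

## Parameters that matter

All of these live in `mapping_config()`; none is hard-coded.

| parameter | default | why |
|---|---|---|
| `genomic_tuis` | `T028` (Gene or Genome) | the standard gene-like semantic type |
| `clinical_tuis` | `T184, T033, T047, T191, T059` | signs/symptoms, findings, diseases, neoplasms, lab procedures — the types clinical data items carry |
| `disease_tuis` | `T047, T191` | disease-role filter for the indirect route |
| `rel_whitelist` | empty (= all labels) | the most inclusive reading of "related"; narrow it to e.g. `RO` to tighten |
| `min_cooccurrence_frequency` | 1 | any recorded co-occurrence counts; raise to demand stronger literature signal |
| `treat_relations_as_bidirectional` | `TRUE` | release files store many relations once; both orientations are traversed |
| `crc_site_keywords` / `crc_disease_keywords` | `colon, colorectal, colonic, rectal` / `cancer, carcinoma, adenoma` | `D_condition` defaults to diseases whose preferred term matches one keyword from each group (whole-word, case-insensitive) — the same boolean logic as the OMIM gene search — and can be replaced by an explicit CUI list (`crc_disease_cuis`) |
| `include_suppressed` | `FALSE` | suppressed atoms/relations are retained on read but excluded from mapping, standard terminology practice |

Design choices where the procedure was genuinely open:

- **Ambiguous term resolution.** A term string carried by several CUIs
  resolves to all of them; every resolution participates in mapping.
  Silently picking one CUI would drop candidates invisibly.
- **Either-sufficient traversal.** A relation row *or* a qualifying
  co-occurrence row suffices for relatedness. `use_mrrel` / `use_mrcoc` can
  demand a single source.
- **Validation over synonym sets.** Real CUIs carry several MeSH synonyms;
  queries try the preferred term first, then remaining combinations until
  the first hit. With one synonym per concept this degrades to the single
  fixed query. Concepts with no MeSH atoms fail validation explicitly
  (hit count 0, reason logged) rather than being guessed at.
- **Determinism.** All outputs are sorted lexicographically by
  (genomic CUI, clinical CUI, method, direction); identical inputs produce
  byte-identical files.
- **Degenerate inputs.** Self-relations are ignored by traversal; empty
  concept sets yield empty (but schema-complete) outputs; a malformed
  release line is a hard error naming the line number — lines are never
  silently dropped.

## The synthetic fixture generator

Licensed full-scale terminology releases, OMIM and live literature services
cannot ship with a package, so `generate_mini_umls()` builds a miniature
release with *known ground truth*:

- concepts in four roles — gene-like, clinical, disease, unrelated — each
  with a SNOMED-like preferred atom and a MeSH-like atom, sequential CUIs in
  the real `C` + 7-digit pattern;
- each (gene, clinical) pair is directly linked with probability
  `p_direct_link` (default 0.15), each gene or clinical concept linked to
  each disease with `p_disease_link` (default 0.3), stored randomly as a
  relation or a co-occurrence row in a random orientation;
- a fraction `crc_fraction` (default 0.5) of diseases is named so the
  condition keyword filter flags them;
- every true relation gets a supporting literature record with probability
  `literature_support_fraction` (default 0.8).

Defaults give 30 concepts (8 gene-like, 10 clinical, 6 disease, 6
unrelated) — large enough for ambiguity, noise links and sub-threshold
co-occurrences to occur, small enough that a brute-force enumerator can
check every pair. The test suite recovers the generator's ground truth
exactly over 20 seeds and cross-checks the engine against an independent
row-loop enumerator on 100 random fixtures; the generator computes its
ground truth with its own set-intersection bookkeeping, not by calling the
mapping engine, so these checks are not circular.

What the generator does **not** emulate: realistic term strings and synonym
richness, the semantic-type breadth of a real release, relation-label
diversity, hierarchy depth (one-step links only), and literature indexes
with noisy annotations. Passing on fixtures therefore demonstrates the
correctness of the algorithms, not retrieval quality on a real
installation, where term ambiguity and annotation sparsity dominate.

## A worked run

```{r demo}
res <- demo_pipeline(seed = 1)
res$report[c("n_direct", "n_indirect", "n_combined", "n_validated")]
head(tibble::as_tibble(res$validated)[, c("genomic_cui", "clinical_cui",
                                          "method", "hit_count", "passed")])
```

The postcoordination worked example — "severe pain in the left abdomen" —
in both renderings:

```{r snomed}
expr <- snomed_expression("21522001", "abdominal pain", data.frame(
  attribute_code = c("272741003", "246113005"),
  attribute_term = c("laterality", "severity"),
  value_code = c("77710000", "24484000"),
  value_term = c("left", "severe")
))
compose_expression(expr)
compose_expression(expr, with_terms = TRUE)
```

## Known limitations

- One-step traversal only; no transitive multi-hop expansion and no
  relation weighting or ranking — candidates are a set, not a ranked list.
- The in-memory knowledge base targets fixture-to-subset scale, not a full
  release load; indexes are hash environments, not on-disk structures.
- The live search backend issues count-only queries with throttling and
  retries, but network use is strictly opt-in; all shipped workflows are
  offline.
- The condition-disease keyword rule inspects preferred terms only; a
  curated CUI list is the better choice on a real installation.
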