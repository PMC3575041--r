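# clingenmap

Mining candidate relations between **clinical concepts** (SNOMED CT-coded
data items such as symptoms, lab results and pathology states) and
**genomic concepts** (genes), through the flat files of a locally installed
unified medical terminology, with literature-based validation. The package
is aimed at translational-bioinformatics practitioners who have a licensed
terminology release (or want to prototype against synthetic miniatures) and
need reproducible, scriptable clinic-genomic relation mining for a disease
of interest — the shipped defaults target colorectal cancer.

## What it computes

Let *G* be a set of gene concepts and *C* a set of clinical concepts, both
resolved to concept unique identifiers (CUIs) against the atom table. Let
`N(x)` be the one-step neighbourhood of `x` — counterparts of non-suppressed
relation rows and of co-occurrence rows with frequency ≥ a threshold — and
`T(·)` the restriction of a CUI set to concepts carrying a semantic type in
`T`.

- **Direct mapping:** emit `(g, c)` for `g ∈ G`,
  `c ∈ T_clinical(N(g)) ∩ C`, and symmetrically from clinical sources, with
  the mapping direction recorded and the supporting rows as evidence.
- **Indirect mapping via disease:** with disease neighbourhoods
  `U1(g) = T_disease(N(g))` and `U2(c) = T_disease(N(c))`, emit an
  undirected `(g, c)` whenever `U1(g) ∩ U2(c)` contains a disease related
  to the condition of interest; the shared diseases are the evidence.
- **Literature validation:** a candidate `(X, Y)` passes if at least one
  indexed article matches
  `X'[MeSH Terms] AND Y'[MeSH Terms] AND Colorectal neoplasms[MeSH Terms]`
  for MeSH synonyms `X'`, `Y'` of the two concepts (offline index bundled
  format, or an opt-in live E-utilities count query).
- **Gene set extraction:** field-restricted boolean keyword search —
  `(colon | colorectal | colonic | rectal) AND (cancer | carcinoma |
  adenoma)`, whole-word, over title and allelic-variant fields of
  OMIM-style entries — joined through two-column association tables to
  protein accessions and article IDs.
- **Postcoordination:** compose/parse the flat
  `focus : attribute = value, ...` subset of SNOMED CT compositional
  expressions.

All tabular results are tibbles; fitted-object summaries follow the broom
convention (`glance()`, `tidy()`), and result types have `autoplot()`
methods.

## Worked example

The demonstration pipeline generates a seeded 30-concept synthetic
terminology release with known ground truth, maps, validates, and checks
the recovered relations:

```r
library(clingenmap)
res <- demo_pipeline(seed = 1)
res$report[c("n_direct", "n_indirect", "n_combined", "n_validated")]
#> $n_direct
#> [1] 18
#> $n_indirect
#> [1] 20
#> $n_combined
#> [1] 27
#> $n_validated
#> [1] 22
```

18 direct candidates (9 gene-clinical pairs, each found in both mapping
directions) and 20 indirect candidates merge into 27 distinct pairs, of
which 22 have a supporting record in the generated literature index — and
those 22 are exactly the generator's literature-supported ground truth
(`res$report$validated_matches_truth` is `TRUE`).

```r
head(tibble::as_tibble(res$validated)[, c("genomic_cui", "clinical_cui",
                                          "method", "hit_count", "passed")], 4)
#> # A tibble: 4 × 5
#>   genomic_cui clinical_cui method   hit_count passed
#>   <chr>       <chr>        <chr>        <int> <lgl>
#> 1 C0000001    C0000009     indirect         1 TRUE
#> 2 C0000001    C0000011     indirect         1 TRUE
#> 3 C0000001    C0000015     indirect         1 TRUE
#> 4 C0000001    C0000017     indirect         1 TRUE
```

Composing "severe pain in the left abdomen" as a postcoordinated
expression:

```r
expr <- snomed_expression("21522001", "abdominal pain", data.frame(
  attribute_code = c("272741003", "246113005"),
  attribute_term = c("laterality", "severity"),
  value_code = c("77710000", "24484000"),
  value_term = c("left", "severe")
))
compose_expression(expr, with_terms = TRUE)
#> [1] "21522001 |abdominal pain|: 272741003 |laterality| = 77710000 |left|, 246113005 |severity| = 24484000 |severe|"
```

The same functions are exposed as a command line
(`inst/cli/clingenmap.R` after installation):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "clingenmap.R", package = "clingenmap"))')" \
    demo --seed 1 --out-dir /tmp/demo
```

Subcommands: `map-direct`, `map-indirect`, `validate`, `extract-genes`,
`compose-expr`, `make-fixtures`, `demo`. All runs are offline by default;
the live literature backend requires an explicit `--live-url`.

## Package layout

- `R/rrf-io.R` — release-format table reader/writer, indexed knowledge base
- `R/concept-mapping.R` — direct and indirect mapping, configuration
- `R/literature-validation.R` — MeSH extraction, query template, offline
  index and live backend, validation gate
- `R/omim.R` — keyword search over entry snapshots, association joins
- `R/snomed.R` — postcoordinated expression compose/parse
- `R/fixtures.R` — seeded synthetic fixture generator with ground truth;
  packaged representative relation table
- `R/cli.R` — subcommand dispatch, `demo_pipeline()`
- `vignettes/clinic-genomic-mapping.Rmd` — the methods vignette
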