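---
title: "Methods: emPAI quantification and ruling-in candidate selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emPAI quantification and ruling-in candidate selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoprofiler)
```

## The workflow and its assumptions

`nucleoprofiler` turns peptide-identification evidence from a nucleoid
fraction into a ranked list of candidate nucleoid-associated proteins
(NAPs) and global regulators. The design is deliberately a *ruling in*
procedure: nucleoid preparations are heavily contaminated (ribosomal
proteins through RNA precipitation, abundant cytosolic enzymes), but NAPs
are by definition highly abundant, so the workflow prioritises abundant
proteins that are plausibly DNA-binding instead of subtracting other
subcellular fractions — subtraction schemes are known to discard genuine
NAPs that also exist in a free cytoplasmic pool.

The assumptions the user should be aware of:

* **Protein inference is by exact accession.** The evidence table is a
  protein-level search-engine export; no peptide-to-protein apportionment
  or protein grouping is attempted here.
* **emPAI is a coverage index, not a calibrated concentration.** Scores are
  comparable as ranks within a sample, which is how the selection uses
  them; saturation for very abundant proteins (emPAI tops out at
  `10^1 − 1 = 9` once every observable peptide is seen) is accepted, not
  corrected.
* **Two biological replicates.** Presence in both is required before a
  protein can be a candidate; anything seen once is treated as a possible
  contaminant.

## Quantification

For each protein and replicate,

\[
\mathrm{PAI} = \frac{N_\mathrm{observed}}{N_\mathrm{observable}},
\qquad
\mathrm{emPAI} = 10^{\mathrm{PAI}} - 1 .
\]

`N_observed` counts *distinct* identified peptide sequences after the
expect-value filter (≤ 0.05, boundary included) and after merging the gel
slices of a replicate, so a peptide seen in several slices counts once.
`N_observable` counts distinct in-silico peptides that the instrument
could have selected, and must use the same distinct-sequence convention —
duplicated tryptic peptides within a protein are counted once in both
numerator and denominator.

### Observability

Digestion is trypsin/P: cleavage after every K or R with **no** proline
exception. Peptides with up to `max_missed_cleavages` internal sites are
enumerated (`digestTryptic()`); a peptide is observable
(`countObservable()`) if it is at least `min_length` residues long and its
precursor m/z, `(M + z\,m_p)/z` with monoisotopic masses, falls inside the
scan window at one of the considered charges.

| parameter | default | unit | rationale |
|---|---|---|---|
| `mz_min`, `mz_max` | 350, 1800 | m/z | Orbitrap survey-scan range |
| `charges` | 2, 3 | – | precursor charges selected for MS2 |
| `min_length` | 6 | residues | conventional minimum identifiable tryptic peptide; the search parameters do not pin this down, so it is configurable |
| `max_missed_cleavages` | 2 | – | matches the database-search setting |
| `expect_threshold` | 0.05 | – | per-peptide significance cut of the export |
| `top_n_d` | 30 | proteins | abundance cut on category D (below) |
| `binder_threshold` | 0 | score | strict `>` per the screen's convention |

Monoisotopic masses are used for m/z (the instrument selects monoisotopic
precursors); average masses for the reported MW column. Both tables are
exposed via `residueMasses()`.

Search engines do not document their observable-peptide convention
exactly, so score-level agreement with any particular engine's emPAI is
not claimed; all selection logic downstream depends on ranks, which are
robust to the convention.

## Categorisation

Five bins by annotated function — R (ribosomal), C (chaperone/cold-shock/
redox), D (DNA-binding), U (unknown), E (enzyme/cytosolic/membrane) —
assigned by prioritised keyword rules over the description
(`assignCategories()`, rules in `inst/extdata/category_rules.tsv`), with a
per-accession override column that always wins and a catch-all default of
U. Proteins detected but missing from the annotation default to U with a
warning rather than an error, because annotation of DNA-binding function
is known to be incomplete — which is precisely why category U is screened.

## Selection

1. **Abundance threshold (category D).** Per replicate, category-D
   proteins are ranked by descending emPAI (ties broken by ascending
   accession, so ranking is a deterministic permutation) and the top
   `top_n_d = 30` kept. There is no statistical basis for separating
   NAPs/GRs from local regulators by abundance — the emPAI distribution is
   a power law, not a mixture of two normal groups — so the cut is a
   pragmatic threshold chosen to retain the known NAPs while excluding the
   long tail. With fewer than 30 category-D proteins, all are kept and a
   warning is raised (the shipped 24-row study table exercises this path).
2. **Binding screen (category U).** Category-U proteins with emPAI
   *strictly greater* than that replicate's 30th-ranked D score are scored
   by amino-acid composition; scores *strictly above* 0 pass. Printed or
   externally computed scores can be supplied directly
   (`bindingScores=`); otherwise `scoreBinding()` is used.
3. **Replicate intersection.** Both steps are computed per replicate from
   that replicate's own D ranking, and a protein must pass in **both**
   replicates. The combination order (screen before intersection, per
   replicate) is the strictest reading of the procedure and is
   configurable via `requireBothReplicates`.
4. **Merged table.** The surviving D and U sets are merged; the
   *amalgamated rank* is recomputed per replicate over the merged
   candidate pool rather than carried over from full-proteome ranks, and
   rows are ordered by the first replicate's rank. MW (average-mass kDa)
   and pI columns are computed from sequences when available, otherwise
   passed through from a supplied table. Known-NAP flags come from a
   curated data file (`inst/extdata/known_naps.tsv`), not from any
   computation.

## The binding score

The screen reproduces the *role* of composition-based DNA-binding
predictors: binders tend to be enriched in lysine, arginine and glutamic
acid, which a linear model over the 20 composition fractions captures. The
published tool's trained SVM is not reproducible, so the package ships its
own trainer (`trainBindingModel()`: a linear-kernel SVM on unscaled
composition fractions, reduced to an affine weight vector + bias) and a
**synthetic** default model trained once on the package's own generated
fixture; its provenance string says so. Consequences:

* no claim is made that shipped-model scores numerically match any
  published score column — printed scores should be passed through when
  the goal is to reproduce a published table;
* features are composition fractions only (no dipeptide or profile
  features), matching the screen's rationale and keeping the model
  interpretable — the largest weights of the shipped model fall on R, K
  and E;
* DNA- and RNA-binding are not distinguished: composition-level predictors
  cannot separate the two.

## The synthetic-data generator

`simulateExperiment()` generates a complete experiment with ground truth.
What it emulates, and the defaults chosen as realistic study conditions:

* **Power-law abundance**: abundance of the rank-`r` protein ∝
  `r^(−powerLawExponent)`, default exponent 1 — a few dominant species and
  a long tail, the shape observed for nucleoid emPAI distributions.
* **Two correlated replicates**: replicate 2 is replicate 1 perturbed by
  lognormal noise; the noise sd is calibrated by bisection (against
  Monte-Carlo Spearman estimates sharing one set of normal draws, so the
  calibration is deterministic given the seed) to hit
  `replicateCorrelation = 0.8`, a typical between-biological-replicate
  rank agreement. An analytic normal approximation was rejected: log
  power-law abundances are too skewed for it.
* **Saturating detection**: each observable peptide is detected with
  probability `1 − exp(−c·abundance)` — the simplest model that reproduces
  emPAI saturation for abundant proteins — with `c` calibrated by
  root-finding so the expected observation count per replicate equals
  `detectionCapacity` (default 6000 for 500 proteins, giving near-full
  coverage at the top and sparse coverage in the tail). Expect values are
  drawn with a 10% fraction above the 0.05 threshold; detected peptides
  are split into three gel-slice labels by mass tertile.
* **Planted NAPs**: 10 of 500 proteins are short (60–150 residues),
  K/R/E-enriched (hence basic pI), category D or U, and placed at ranks in
  the top fifth of the abundance distribution — so most but not all fall
  in the top decile. Recovery metrics only count planted NAPs in the top
  abundance decile: an abundance-threshold method legitimately cannot find
  low-abundance regulators, mirroring the real survey's misses of
  weakly-expressed developmental regulators.
* **Category proportions** R 10%, C 5%, D 15%, U 20%, E 50%: a
  DNA-binding-enriched nucleoid fraction dominated by cytosolic
  contamination, with the D fraction close to the ~15% of identified
  species annotated as regulators in such preparations.

What it does **not** emulate: raw spectra, chromatography, fragment ions,
retention time, modified peptides, shared peptides between homologues, or
decoy-based FDR. Passing tests on synthetic data therefore show that the
pipeline's logic is correct under the stated generative model, not that
any particular real preparation is clean.

## Numerical choices and degenerate inputs

* pI is the root of a strictly decreasing Henderson–Hasselbalch net-charge
  model, found by bisection on [0, 14] to 1e-4 pH. The pKa set is the
  Bjellqvist-style configuration in `pkaSet()`. Since published tables
  rarely state their pI tool, printed pI values are only matched loosely
  (±0.5 pH in tests); a sequence with no ionisable side chains has the
  closed-form pI `(pKa_N + pKa_C)/2`.
* Nonstandard residue letters (B, J, O, U, X, Z) are rejected by default —
  silent guesses would corrupt observability counts. A permissive mode in
  `molecularWeight()` maps unknown letters to the mean residue mass;
  composition features never include them.
* Ranking ties break by ascending accession everywhere, making every rank
  a reproducible permutation.
* Empty inputs return empty outputs (empty FASTA → empty `ProteinSet`,
  empty candidate list → header-only TSV); a replicate with fewer
  category-D proteins than `top_n_d` keeps them all with a warning and a
  threshold equal to the minimum.
* A protein with identified peptides but zero observable peptides under
  the window is an error (the window contradicts the evidence) rather
  than a division by zero.

## Problem sizes

The test suite validates digestion against a brute-force
substring-enumeration oracle on 200 random sequences of up to 100
residues, and runs the end-to-end synthetic benchmark at the default
conditions (500 proteins, 10 planted NAPs, exponent 1, correlation 0.8)
over 10 seeds for recovery and 3 seeds for the power-law shape check;
these sizes give stable averages for the stochastic properties while
keeping a full test run around a minute and a half.

## Known limitations

* emPAI-based selection cannot see low-abundance NAPs; the threshold is a
  sensitivity/contamination trade-off, not a significance test.
* The binding screen is composition-only; structured DNA-binding domains
  with unremarkable composition can be missed in category U (they are
  usually annotated, hence in category D already).
* Candidates are candidates: the workflow makes no claim of biological
  confirmation, which requires orthogonal validation (imaging,
  protein–DNA binding assays).
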