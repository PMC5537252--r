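---
title: "Methods: kinase-specific phosphosite prediction in phosforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinase-specific phosphosite prediction in phosforest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosforest)
```

## The prediction problem

Protein kinases phosphorylate serine, threonine or tyrosine residues of
substrate proteins, and each kinase family recognizes its substrates through
a combination of local sequence context, local structure and the substrate's
functional neighbourhood. Given a protein sequence and a kinase family,
phosforest scores every candidate S/T/Y residue for being a phosphosite of
that family. The classifier is a random forest over a heterogeneous binary
feature vector built from five sources:

1. **Local sequence.** A 9-residue window (the site ±4 flanking residues) is
   one-hot encoded, 20 indicator columns per position, 180 columns total.
   Windows that run off a protein terminus are padded with `X`, which
   encodes as all zeros in every block, so terminal sites keep a fixed-width
   representation without inventing residues.
2. **Predicted secondary structure** (helix/strand/coil), 3 × 9 = 27 columns.
3. **Predicted relative solvent accessibility**, discretized to seven levels
   from buried (0) to exposed (6), 7 × 9 = 63 columns. One-hot coding was
   chosen over thermometer coding to match the style of the other blocks;
   the forest can reconstruct orderings it needs from indicators.
4. **Predicted intrinsic disorder** (ordered/disordered), 2 × 9 = 18
   columns. Phosphosites fall preferentially in disordered regions, which
   makes this small block surprisingly informative.
5. **Functional annotations** of the parent protein across seven
   categories — GO biological process, cellular component and molecular
   function, InterPro entries, KEGG pathways, Pfam domains, and
   protein–protein interaction partners. These are protein-level: every
   site of a protein shares the same functional sub-vector.

Structural tracks are *consumed as input* (tables of per-residue strings);
the package does not run a structure predictor. The track file format here
is the package's own and is not compatible with any predictor's native
output.

The feature space is described by a `feature_layout`: an ordered list of
named blocks with a global 1-based "V" index for every column, so a fitted
model can name its features (e.g. `V107` = proline indicator at window
position 6) and survive serialization. Under the full published block
configuration the layout spans 5698 columns with the PPI block at
V947–V5698; in this package block sizes are data-driven (see below), so
that total arises only under that configuration.

## Selecting functional feature columns by enrichment

Using every annotation term as a column would be hopeless — most terms are
noise. A term enters the layout only if it is significantly over- or
under-represented among the kinase's substrate proteins relative to the
background proteome, judged by a two-sided hypergeometric test: with `q` of
`k` substrate proteins and `m` of the `m + n` background proteins carrying
the term, both tails of Hypergeometric(m + n, m, k) are computed and the
smaller is doubled (capped at 1). Doubling the smaller tail is the simplest
defensible two-sided construction for a discrete test and is used
consistently; the direction label is `over` when `q` meets or exceeds the
expected count `k·m/(m+n)` (ties count as over).

P-values are Bonferroni-corrected *within each annotation category* — each
category is its own family of hypotheses — and terms pass at corrected
p < 0.01. A `global_correction` flag corrects across all categories jointly
for users who prefer a single family. Significant terms are ordered by
corrected p, ties broken lexicographically, giving a reproducible column
order. Under-represented terms are retained as columns and in scoring by
default (their absence of signal is signal); `directions = "over"` restricts
to over-representation only.

The same term set feeds a per-protein **log-odds functional score**
\(S = \sum_i \log_2 f(x_i)/g(x_i)\) over the significant terms the protein
carries, where `f` and `g` are the term's carrier frequencies among
substrates and background. Frequencies use additive smoothing
(`(count + 1)/(n + 2)` by default) because observed zero counts would
otherwise make the logarithm undefined; the pseudocount is a parameter and
a zero pseudocount is rejected whenever any count is zero. Substrate versus
background score distributions are compared by a Welch two-sample t-test —
Welch rather than pooled-variance because the two groups differ in size and
there is no reason to assume equal variances.

## mRMR feature ranking

With thousands of mostly redundant columns, the package ranks features by
minimum-redundancy maximum-relevance using mutual information in bits (the
same log2 convention as the functional score). The greedy MID (difference)
criterion is used: the first feature maximizes relevance `I(x; y)`; each
later pick maximizes `I(x; y) − mean_{i∈S} I(x; x_i)` over the already
selected set `S`. MID avoids the division-by-zero the quotient (MIQ)
variant hits on zero-MI pairs; MIQ is available behind a flag with an
epsilon guard. Ties are broken toward the smaller V-index so rankings are
deterministic. The default keeps the top 50 features. All features here are
binary so no discretization is applied; an equal-frequency 3-bin
discretizer would be the natural extension for continuous descriptors.

Whether selection should see the whole dataset before cross-validation is a
genuine design fork: selecting on everything leaks information into the
held-out folds, but selecting per fold evaluates a slightly different model
in every fold. `cross_validate()` defaults to fold-internal selection
(`selection_mode = "strict"`); `"paper"` performs one whole-dataset ranking
before CV for users who want the optimistic variant, and the mode is
recorded with the result.

## Classifier, evaluation, and thresholding

The classifier is a random forest with the classical defaults — 500 trees,
`mtry = floor(sqrt(p))`, unlimited depth — and the score of a window is the
fraction of trees voting positive. All parameters and the seed are recorded
in the model's training manifest.

Evaluation is randomized stratified 5-fold cross-validation repeated (100
repeats by default, matching the method's published protocol). Stratification
is used because unstratified folds on small kinase families can produce
single-class test folds. Metrics — sensitivity, specificity, precision,
accuracy, F-score, MCC, and trapezoidal AUC — are computed per fold, averaged
within a repeat, and summarized as mean ± SD across repeats; a `pooled` flag
instead pools held-out predictions within each repeat first. Conventions for
degenerate tables: a 0/0 ratio is reported as `NA`, and MCC is 0 when its
denominator vanishes. The trapezoidal AUC is verified in the test suite
against the pairwise Mann–Whitney statistic (ties counted ½), which it
equals exactly.

Calls use `score >= threshold` (ties at the cutoff are positive). For
proteome scanning the threshold is calibrated to a target specificity
(default 99%): the smallest cutoff under which the required fraction of
calibration negatives scores strictly below it, which achieves the target
on those negatives by construction. Negatives for both training and
calibration respect the kinase's residue chemistry
(`match_positive_types`): negatives for a tyrosine kinase are tyrosines,
because mismatched residue types would make the task trivially easy.

Dataset assembly follows the same background logic: all S/T/Y residues of
the background protein set form the candidate universe, negatives are
sampled from it at a default 1:1 ratio with positives (balanced classes
keep sensitivity and specificity comparable), never coinciding with a known
positive of the same kinase; positives of *other* kinases remain eligible
as negatives. Redundancy in the protein set is reduced by greedy
longest-first clustering at 70% global-alignment identity (match +1,
mismatch 0, linear gap −1; identity = matches / alignment length). This
enforces the contract that no retained pair reaches the threshold without
depending on an external clustering binary; it is an approximation of, not
a replacement for, CD-HIT, and it is applied to whichever protein set is
passed in (per-kinase in the bundled workflow), recorded in the dataset
manifest.

## The synthetic study generator

`generate_synthetic_study()` produces data with exactly the statistical
structure the method exploits, so every stage is testable without external
databases:

* **Proteins**: i.i.d. residues, uniform over the 20 amino acids by
  default. Uniform composition keeps the analytic error bounds in the tests
  exact; an empirical (database-average) composition option exists.
  Lengths are `min + Poisson(mean − min)` (default mean 60, min 30).
* **Positive sites**: one interior S/T per substrate protein with the
  proline-directed motif planted — P at +1 with probability 0.8 and at −1
  with probability 0.6. The +1 fidelity mirrors a strong but imperfect
  consensus; the −1 value encodes the documented "to a lesser extent"
  preference and was fixed a priori.
* **Disorder**: background residues follow a two-state run process at rate
  0.2; each positive site's window is covered by a disordered run with
  probability 0.6, else forced ordered. No quantitative disorder enrichment
  is published for this setting; these are fixture choices, and at bias =
  base rate the signal vanishes by construction.
* **Annotations**: three planted terms (BP 0.6 vs 0.1, CC 0.5 vs 0.1, PPI
  partner 0.4 vs 0.05 carrier frequency in substrates vs background) plus
  five noise terms per category at 0.1 in both groups.

Defaults are 200 substrate and 400 background proteins. What the generator
does **not** emulate: realistic amino-acid composition and homology
structure, position-specific motif complexity beyond the ±1 prolines,
correlated annotation terms (GO graph structure), or realistic
protein-length and annotation-depth distributions. Passing tests therefore
demonstrate that the machinery recovers the signals it assumes, not that it
attains any particular performance on curated phosphoproteome data.

## Worked example

```{r example, eval = FALSE}
study <- generate_synthetic_study(synthetic_config(seed = 1))

bg <- enumerate_background_sites(
  study$proteins[study$proteins$protein_id %in% study$background_ids, ])
negatives <- sample_negatives(bg, study$sites, n = nrow(study$sites),
                              seed = 8)
dataset <- build_dataset(dplyr::bind_rows(study$sites, negatives),
                         study$proteins, study$structures)

enr <- test_all_categories(study$substrate_ids, study$catalog)
layout <- layout_from_terms(build_significant_term_index(enr))
fm <- assemble_feature_matrix(dataset, layout, catalog = study$catalog)

ranked <- mrmr_rank(fm, k = 50)
model <- train_random_forest(apply_selection(fm, ranked), seed = 2)
cv <- cross_validate(fm, repeats = 5, seed = 3)
cv$summary
```

## Numerical choices and problem sizes

Tolerances: the hypergeometric, AUC and metric oracles in the test suite
are compared at 1e-12 (they agree to machine epsilon). Tie-breaks:
mRMR ties by smaller V-index; prediction-output ties by (protein, position);
significant-term ties lexicographic; calls at the threshold positive.
Degenerate inputs: identical zero-variance score samples compare with p = 1
by convention; empty negative sets flag a dataset as not trainable rather
than erroring, so positives-only window extraction still works.

The test and acceptance workloads run cross-validation at 5 folds × 5
repeats on the 400-window default study, and statistical recovery checks at
20–100 replicate seeds — sizes chosen to make sampling-error bounds tight
enough to be meaningful while keeping the default check runs desk-scale.
The CV default in the API remains 100 repeats.

## Limitations

Continuous physicochemical descriptors (AAindex), PSSM/conservation
features, and GO ancestor propagation are out of scope; annotation terms
are flat labels. The greedy identity clustering is quadratic in the number
of proteins and intended for curated training sets, not whole proteomes.
Functional features are protein-level, so two sites on one protein differ
only through sequence and structure blocks; site-specific functional
context is future work.
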