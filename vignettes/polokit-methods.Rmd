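---
title: "Methods behind polokit: expression breadth, lineage divergence, and sex-chromosome transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind polokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polokit)
```

polokit packages the computational chain used to characterize a
testis-specialized polo-like kinase (Plk) duplicate: how narrowly the
paralog is expressed, how fast its protein diverged and under what
selective regime, and what a meiosis-II nondisjunction mechanism
would predict for the sex ratios of broods sired by males expressing
different Plk transcripts. This vignette explains each model, the
choices we made where the design was open, and what the synthetic
data generator does and does not emulate.

## Expression breadth (tau)

Expression input is a matrix of normalized read counts (NRC), genes
by libraries, with each library labelled by sex, tissue and
replicate. The package treats NRC as opaque nonnegative numbers: the
normalization that produced them is upstream and out of scope.

Replicates are collapsed by the per-gene median (`medianByGroup()`;
even-sized groups use the midpoint of the two central order
statistics), then transformed as `log10(NRC + 1)` so that zero
counts stay finite and map to zero. For a panel of $N$ tissues with
log-scale values $S_1, \dots, S_N$ and $S_{max} = \max_i S_i$,

$$\tau = \frac{\sum_{i=1}^{N}\left(1 - S_i/S_{max}\right)}{N - 1},$$

which is 0 for perfectly uniform expression and 1 when expression is
confined to a single tissue. Decisions worth knowing:

* **Tissue panel is configuration, not code.** `tauTable()` takes the
  panel as an argument; the default panel in the synthetic generator
  is the six nonoverlapping samples (digestive, gonad, reproductive
  tract without gonad, thorax, abdomen, head). Whole-body libraries
  must not be in the panel — they overlap every other sample and
  inflate breadth.
* **All-zero profiles.** $S_{max}=0$ makes the formula divide by
  zero. We return `NA` with a warning: silently returning 0 would
  call an unexpressed gene broadly expressed, and 1 would call it
  perfectly tissue-specific; both are misclassifications.
* **Ties for the maximum need no tie-break** — only the value of
  $S_{max}$ enters the formula.
* **Percentile placement** of a focal gene in the genome-wide
  distribution uses mid-rank counting
  (`100 (n_{below} + n_{equal}/2)/n`), a deterministic convention
  under ties; the analysis it supports is descriptive, so no
  continuity correction is attempted.

## Lineage divergence on a three-taxon alignment

The alignment has two ingroup sequences (the duplicate and the
ancestral paralog) and an outgroup. With only three taxa, parsimony
assignment of each variable column is a closed set of rules
(`classifyColumns()`): a residue unique to one sequence places the
substitution on that terminal lineage; three distinct residues admit
two equally parsimonious placements and are reported `ambiguous`;
any gap makes the column `gapped`. The test suite checks these rules
against exhaustive minimization over all 20 ancestral states at the
internal node, so the shortcut is verified, not assumed. Ambiguous
columns count toward alignable sites but toward neither lineage; they
are reported so users can audit how much signal was set aside.
Single-change parsimony means counts are per-site, not per-event:
repeated substitutions at one column are invisible, which is the
standard conservative bias of this test at amino-acid distances where
synonymous sites are already saturated.

"Alignable" means no gap in any of the three sequences. Lineage
substitution counts $m_1$ and $m_2$ feed Tajima's
one-degree-of-freedom relative-rate test,
$\chi^2 = (m_1 - m_2)^2/(m_1 + m_2)$, with the upper-tail
chi-square p-value; $m_1 = m_2 = 0$ is defined as $\chi^2 = 0$.
Reports round $\chi^2$ to two decimals.

Domains (kinase, linker, Polo-box domain and its two Polo boxes) are
user-supplied column ranges (`DomainMap`), 1-based inclusive in
files and converted internally; validity enforces PB1/PB2 nested in
the PBD and disjointness of kinase/linker/PBD. Boundaries are data,
not constants, because domain annotation is a curation decision that
should be visible and editable.

Deletions are maximal runs of gap columns: gaps in exactly one
ingroup opposite outgroup residues are terminal-lineage deletions;
gaps shared by both ingroups are placed on the internal branch
(`shared`), the parsimony-minimal interpretation; outgroup-only gaps
are reported as `O` (an insertion in the ingroup ancestor, from the
outgroup's perspective).

## McDonald–Kreitman test from multi-strain codon alignments

Two species' in-frame alignments are walked codon by codon. Columns
with a gap or `N` in any strain are excluded entirely — conservative
and auditable — as are codons where any strain carries an in-frame
stop (with a warning). At each remaining nucleotide position:

* alleles segregating within a species yield a polymorphic record
  for that species (singletons included — no frequency filter);
* positions where both species are monomorphic but for different
  alleles yield a fixed record. Positions polymorphic in either
  species are never counted as fixed.

Each record's effect (synonymous or nonsynonymous) is scored against
the genetic code in codon context. Polymorphic changes compare the
two alleles with the remaining positions held at the species
consensus. Fixed differences at codons hit at more than one position
are averaged over all minimal mutational pathways with equal weights
(Nei–Gojobori-style counting; pathways through stop codons are
discarded unless all pathways pass through one), which yields
fractional counts. `buildMKTable()` applies a rounding policy —
nearest integer by default, or `floor`, or `none` which keeps
fractional cells and switches the test to a likelihood-ratio G-test,
since the exact test requires integers.

The 2x2 table (Dn, Ds fixed; Pn, Ps polymorphic within the focal
species — both species' polymorphism is computed, table assembly is
configurable) is tested with a two-sided Fisher exact test
implemented as a direct hypergeometric enumeration: the sum of
probabilities of all tables, margins fixed, at most as probable as
the observed one (with the customary $1+10^{-7}$ relative slack on
the comparison). The neutrality index is
$NI = (P_n/P_s)/(D_n/D_s)$ and $\alpha = 1 - NI$; both are `NA`
whenever a denominator is zero, never silently 0 or infinity. No
outgroup polarization, asymptotic-MK extension or DFE model is
attempted.

## Meiosis-II sex-chromosome transmission model

The model formalizes the bookkeeping connecting meiosis-II
nondisjunction (NDJ) to brood sex ratios. Secondary spermatocytes are
half X-bearing and half Y-bearing. A normal division gives two
single-chromosome sperm; an NDJ division gives one disomic sperm (XX
or YY — sister chromatids co-inherited) and one nullo-XY sperm. With
NDJ rates $d_X$, $d_Y$, the pre-viability sperm pool is

| class | X | Y | XX | YY | nullo |
|---|---|---|---|---|---|
| mass | $\tfrac{1-d_X}{2}$ | $\tfrac{1-d_Y}{2}$ | $\tfrac{d_X}{4}$ | $\tfrac{d_Y}{4}$ | $\tfrac{d_X + d_Y}{4}$ |

Sperm-class viabilities rescale and renormalize this pool (all-zero
viability is an error, not a NaN). Fertilization by a euploid
X-bearing egg maps X→XX, Y→XY, XX→XXX, YY→XYY, nullo→XO; zygote
viabilities rescale and renormalize again; sex follows X dose (XX,
XXX female; XY, XO, XYY male). XO males are counted as progeny —
they are viable though sterile, and the assay counts emerged flies.
Defaults: all viabilities 1 except XXX at 0.05, encoding
"dramatically reduced but not zero" — no measured value exists, so
this is a labelled convention, configurable in the JSON parameter
file, and the CLI output carries a comment line saying so. Meiosis-I
NDJ and female-side errors are out of model scope, a documented
limitation. Two qualitative regimes fall out of the algebra and are
asserted in tests: with $d_X = d_Y = 0$ the model collapses to
Mendelian 1:1 regardless of disomic/nullo viabilities (those classes
get zero mass), and removing YY products under Y NDJ (Paris-drive
logic) produces female-biased broods.

`fitNdj()` inverts the forward model by least squares on the female
fraction and XO fraction — a 41x41 grid then `optim` refinement —
and flags non-identifiability when the residual surface is flat near
the optimum. The grid is coarse enough to be fast and fine enough
that refinement never has to cross a basin boundary: the surface is
smooth in both parameters.

## Brood statistics

Three models mirror the fertility assay, all with batch and strain
as random intercepts:

* **Counts** (`fitCountModel`): linear mixed model of per-vial
  progeny counts (total, female or male) on transgene, fit by REML
  through `nlme::lme`. Zero-progeny vials are included — a zero
  count is data here.
* **Siring** (`fitSiredModel`): binomial GLMM (Laplace, via
  `lme4::glmer`) of the 0/1 outcome "sired any progeny". Complete
  separation is flagged (an extreme fitted log-odds contrast) rather
  than silently reported with a meaningless standard error.
* **Sex ratio** (`sexRatioModel`): each vial contributes two rows
  (female count, male count); fixed effects are progeny sex and
  vial, and the progeny-sex F test is the headline. Zero-progeny
  vials are excluded — their sex ratio is undefined — with the count
  recorded in the result's notes.

REML for the linear models and Laplace maximum likelihood for the
logistic one are the conventional defaults of the software family
these analyses come from; the estimation criterion is recorded in
every `ModelResult`. Denominator degrees of freedom follow the
containment method that `nlme` uses, which for the sex-ratio design
works out to (vials) − (batch-by-strain groups): a design with 52
vials over 6 groups gives the 1-and-46-df F test of the published
analysis scale. Fixed effects use treatment coding against the first
factor level, and the coding is visible in the term names
(`transgeneX`, `sexfemale`). Single-level grouping factors degrade
gracefully: the offending random term is dropped with a note, and
with none left the fit falls back to ordinary least squares —
matching the principle that strain is *modelled* as random whenever
the data can support it. `binomialSexRatio()` provides the exact
per-male cross-check against p = 0.5; tests assert it always agrees
in direction with the mixed model on distorted data.

## Synthetic data

The generator exists so the full chain is testable without any
external download, and it deliberately separates two kinds of
fixtures:

* **Count-planting generators** (`simulateThreeTaxonProteins`,
  `simulateMKAlignments`) construct data in which the planted
  quantities are recovered *exactly*: substitutions at disjoint
  positions with no homoplasy, single-nucleotide MK events at
  disjoint codons chosen against the genetic code, optional in-frame
  deletions and an optional multi-hit codon. They verify
  correctness, not robustness.
* **Distribution-based generators** (`simulateExpressionTable`,
  `simulateProgeny`) add stochastic structure: lognormal replicate
  noise around profiles whose noiseless tau equals the target in
  closed form (peak tissue at $S_{max}$, all others at
  $S_{max}(1-\tau)$); negative-binomial broods with lognormal batch
  and strain intercepts, zero inflation for non-siring males, and
  binomial sex allocation whose female probability can come from a
  `MeiosisParams` forward computation.

Every generator runs in a private RNG stream (seed plus a
per-generator offset) and restores the caller's RNG state, so
fixtures are byte-stable under a seed and adding a generator call
never perturbs existing ones.

What the generators do **not** emulate: real substitution processes
(no rate heterogeneity, no homoplasy unless planted, no codon
model), linked polymorphism or realistic site-frequency spectra (the
derived allele's strain subset is uniform), correlated expression
across tissues, or vial-level environmental covariates. Passing
tests therefore demonstrate that the implementations invert their
own generative assumptions and match their published-scale anchor
numbers — not that the methods are robust to every pathology of real
data.

## Problem sizes and numerical conventions

The shipped tests run at deliberately modest sizes chosen to exercise
every code path: alignments of a few hundred columns (576 for the
study-scale divergence fixture), 250–300 codons and 30 + 11 strains
for MK recovery, 100–120 genes for expression tables, 40–120 males
per arm for the brood models, 200 replicates for the type-I-error
calibration, and the complete enumeration of 2x2 tables with total
at most 60 for the exact test. Coordinates in all files are 1-based
inclusive and converted internally to 0-based half-open arithmetic
where convenient; chi-square statistics are rounded to two decimals
in reports only, never before a p-value is computed; distribution
sums are checked to $10^{-12}$.
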