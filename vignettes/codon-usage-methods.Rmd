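---
title: "Codon-usage bias in mitochondrial genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-usage bias in mitochondrial genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocodon)
```

## The problem

Animal mitochondrial genomes carry 13 protein-coding genes translated with a
non-standard genetic code. Synonymous codons for one amino acid are not used
equally; the strength and direction of this bias carries information about
mutational pressure (especially the A+T richness of mitochondrial DNA) and
about selection acting on translation. `mitocodon` implements the standard
analysis stack for this question on sets of mitochondrial CDS: per-gene
relative synonymous codon usage (RSCU), GC content at synonymous third
positions (GC3s), Wright's effective number of codons (ENC) with its
mutation-only null curve, an ENC-ratio screen for putatively selected genes,
and a cross-species comparative layer. A synthetic CDS generator with known
ground truth makes every stage testable without any downloads.

## Genetic codes and synonymous families

All metrics are computed relative to an explicit genetic code. The default is
NCBI translation table 5 (invertebrate mitochondrial): ATA codes Met, TGA
codes Trp, AGA and AGG code Ser, and only TAA/TAG are stops. That leaves 62
sense codons partitioned into twelve 2-fold families (F, Y, H, Q, N, K, D, E,
C, W, M, I), six 4-fold (V, P, T, A, G, R), one 6-fold (Leu) and one 8-fold
(Ser). Table 1 (standard code) is shipped for generality; its census is two
single-codon families (Met, Trp), nine 2-fold, one 3-fold (Ile), five 4-fold
and three 6-fold, 61 sense codons in all. Codons are handled internally as
uppercase DNA; RNA input is normalized on entry. The code tables are plain
data files under `inst/extdata/genetic_codes/`, so further tables are
additive.

## Per-gene metrics

**Codon counting.** A CDS contributes exactly `floor(length/3)` codons.
Stop codons — the terminal one, whether complete or truncated by
polyadenylation, and any internal ones — and codons containing ambiguity
codes are excluded from all counts and reported in the exclusion bookkeeping:
neither RSCU nor ENC is defined for them. Internal stops additionally raise a
loud warning, since they normally indicate an annotation error.

**RSCU.** For codon $j$ in a family of size $k$,
$\mathrm{RSCU}_j = X_j \big/ (\sum_{\text{family}} X / k)$. Values sum to $k$
within every observed family. Two kinds of "no usage" are kept distinct: a
family never observed in the gene yields `NA` for all its codons, while an
unobserved codon inside an observed family yields 0 — a real measurement
(the codon is avoided), which matters downstream where imputing 0 for `NA`
would fabricate avoidance.

**GC3s.** The fraction of counted codons whose amino acid offers a synonymous
choice (degeneracy $\ge 2$) and whose third base is G or C. Under table 5
every sense codon qualifies; under table 1 the Met and Trp codons leave both
numerator and denominator.

**ENC.** Wright's estimator. Per family with $n \ge 2$ observations the codon
homozygosity is $\hat F = (n \sum_i p_i^2 - 1)/(n-1)$. $\hat F$ values are
averaged within degeneracy classes; $\hat F = 0$ values are excluded from the
class mean, since a single zero would make the class contribution infinite.
Then
$$\mathrm{ENC} = N_1 + \sum_k N_k / \bar F_k,$$
with $N_k$ the number of families of size $k$ in the code (table 5:
$N_1 = 0$, $N_2 = 12$, $N_4 = 6$, $N_6 = N_8 = 1$). If a class ends up with
no usable family — mitochondrial genes routinely miss rare amino acids — its
$\bar F$ is imputed as the mean of the nearest available classes below and
above on the $k$ axis (one side if only one exists), generalizing the classic
$\bar F_3 = (\bar F_2 + \bar F_4)/2$ rule. The estimate is capped at the
sense-codon count (62/61): on small samples the raw estimator can exceed it.
Genes with fewer than `min_codons = 50` counted codons return `NA`; the
mitochondrial ATP8 (~53 codons in our synthetic defaults, and "too short" for
ENC in common practice) can be excluded explicitly via `exclude_genes` or
the CLI's `--exclude-gene`, which is the more faithful rendering of the usual
convention than the length rule alone, since a realistic ATP8 sits just above
50 codons.

**The null curve and the selection screen.** Under mutation pressure alone,
the expected ENC at a given GC3s is
$$\mathrm{ENC}_{exp} = 2 + \mathrm{GC3s} + \frac{29}{\mathrm{GC3s}^2 + (1-\mathrm{GC3s})^2}.$$
The ENC ratio $(\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs})/\mathrm{ENC}_{exp}$
flags a gene as a selection candidate when it strictly exceeds 0.15
(observed ENC below 85% of expected). Note a documented tension we preserve
rather than repair: the curve is Wright's standard-code null (asymptote near
61) applied, as is field practice, under a 62-sense-codon code. Our
mutation-only generator lands within ~2 ENC units of the curve across the
whole GC3 range (see below), so the 15% margin comfortably absorbs the
discrepancy.

## Composition statistics

Whole-sequence base composition uses
$\mathrm{AT\,skew} = (A-T)/(A+T)$ and $\mathrm{GC\,skew} = (G-C)/(G+C)$;
ambiguous bases leave all numerators and denominators, and a skew whose
denominator is zero is reported as `NA` rather than 0 (zero would assert an
observed balance). Windowed profiles (default 500 bp window, 1 bp step)
treat mitogenomes as circular, wrapping windows past the origin, so a step-1
profile has exactly one window per base.

## The comparative layer

Per species, RSCU is computed either on the pooled codon counts of all its
CDS (`concatenated`, the default — the natural reading of "codon usage of
the mitochondrial genome", and the mode in which the family-sum invariant
holds exactly) or as the mean of per-gene RSCU vectors (`gene_averaged`).
Codons are partitioned into *frequently used* (mean RSCU across species
strictly above 1) and *infrequently used* (the rest); species are clustered
hierarchically on each subset (Euclidean distance, complete linkage — the
defaults of the common heat-map tools; both configurable), with missing
entries dropped pairwise inside the distance, never imputed as 0.

Two species' profiles are compared by a paired t-test over codons within a
stated subset, preceded by a Shapiro–Wilk check on the paired differences
and an F-ratio comparison of the two species' RSCU variances. Both checks
are *reported*, not branched on: the t statistic is always computed, with
the normality p-value alongside, and the variance comparison is included for
workflow fidelity even though equal variances are not an assumption of the
paired test. Degenerate inputs are reported as such (identical profiles:
t = 0, p = 1; constant nonzero difference: no finite t). No multiple-testing
correction is applied across species pairs by default, matching common
practice of reporting raw p-values; Holm correction can be applied by the
user on the returned table.

Testing subset-wise is not merely convention. In concatenated mode with all
families observed, RSCU sums to the family degeneracy for every species, so
over all 62 codons the paired differences sum to exactly zero and the test
is vacuous; the frequent/infrequent split breaks that constraint.

**A calibration caveat we consider a finding.** On data where the tested
subset contains at most one codon per synonymous family, the paired test is
well calibrated: in our null simulations (two species sharing one biased
codon-usage distribution, 12 genes of 300 codons each, 1000 replicate
pairs) the rejection rate at $\alpha = 0.05$ on a one-codon-per-family
subset is ~0.04. On the frequent-codon subset, however, families that
contribute two or more codons introduce negative correlation among the
paired differences (their RSCU values are tied by the family sum), and
strongly skewed families contribute near-identical values to both species;
both effects inflate the paired standard deviation relative to the variance
of the mean difference, making the test *conservative* — we measure
rejection rates of 0.001–0.02 across every generator regime. The test never
over-rejects, so reported significant differences are trustworthy; but its
nominal level is an upper bound, not an attained rate, whenever the subset
carries within-family siblings. The test suite asserts exactly this:
calibration on one-per-family subsets, and validity (type I error at or
below the nominal band) on partition subsets.

## The synthetic generator

`synthetic_spec()` + `generate_cds()` produce CDS sets with known truth.
Amino acids are drawn from a mitochondrial-like composition
(Leu/Ser/Ile/Phe-rich, overridable); genes open with a codon drawn from the
Met family (ATG/ATA under table 5) and close with an appended TAA; stop
codons are never sampled internally, so generated fixtures are clean by
construction (the validator is exercised separately on corrupted input).
Three regimes:

* **uniform** — codons uniform within families: RSCU flat at 1, ENC near the
  sense-codon count. The no-bias control and the weak-bias outlier species.
* **mutation_gc3** — within-family probabilities proportional to a
  third-base composition with G+C mass `gc3_target`, split equally between G
  and C and between A and T: mutation pressure with no selection. Genes land
  on the expected-ENC curve; at 300 codons and 50 genes per point the mean
  absolute deviation is 1.2–2.8 ENC units across `gc3_target` from 0.1 to
  0.9, within the 3-unit band we assert.
* **biased** — within-family probabilities drawn from a symmetric Dirichlet
  with concentration `bias_concentration`; 0.1 is strong bias (ENC ≈ 24,
  ENC ratio far above 0.15 — the selection screen has power by
  construction), 1 is mild.

By default the probability draws are made **once per spec** and shared by
all genes (`gene_probs = "shared"`): mutational pressure and selection on
mitochondrial codon usage act genome-wide, and species-level RSCU analysis
presumes coherent usage across genes. `gene_probs = "independent"` redraws
per gene, useful for gene-level power studies; note that pooling unrelated
per-gene skews flattens species-level usage and is exactly the situation in
which the paired-test conservativeness above is most pronounced.

Reproducibility: truth depends only on the spec seed; codon sampling on a
separate sampling seed (default the same). Panels derive child seeds from
the parent by a fixed linear-congruential step (`derive_seed`), so a
multi-species fixture is one integer away from byte-identical regeneration.
`make_species_panel()` emulates the comparative design of a family-level
study: $n-1$ species sharing one distribution, plus an optional outlier —
e.g. a uniform-regime species that then shows the highest mean ENC and
clusters alone, as a weak-bias genus does among strongly biased relatives.

What the generator does **not** emulate: phylogenetic correlation between
species (panel members are exchangeable), amino-acid composition differences
between genes, length heterogeneity beyond the configured per-gene lengths,
ambiguity codes, annotation errors, and strand-asymmetric mutation pressure
(the generator controls GC3 but not AT skew). Passing the synthetic checks
therefore validates the *estimators and their null relationships*, not any
claim about a particular real taxon.

## Numerical and design choices

* Stop codons and ambiguous codons never enter counts; the terminal stop
  (complete or truncated) is excluded by construction.
* RSCU 0 (avoided codon) is distinct from RSCU `NA` (family unobserved);
  distances and tests drop `NA` pairwise and never impute.
* $\hat F = 0$ family values leave the class mean; an empty class borrows
  the mean of its nearest defined neighbours.
* ENC is capped at the code's sense-codon count; `min_codons` defaults to 50.
* The selection boundary is strict (`ratio > 0.15`), so a gene exactly on
  the 85% line is not flagged.
* Validation coordinates are 0-based codon indices.
* Clustering and output tables are deterministic given input order; output
  rows sort by species, gene, codon.
* Simulation sizes used by the test suite and the acceptance script — 200
  oracle genes of up to 30 codons, 50 genes per GC3 grid point, 1000
  replicate pairs for test calibration, a 6-species panel with 13 realistic
  gene lengths — were chosen to make sampling error a small fraction of each
  asserted margin while keeping a full run in well under a minute.

## Known limitations

* GenBank flat-file support covers the feature constructs that occur in
  mitogenome records (CDS with `join`/`complement` locations and
  `/gene`, `/product`, `/transl_table` qualifiers); it is not a general
  GenBank parser.
* The expected-ENC curve is used in its standard published form despite the
  62-codon code, as discussed above.
* The paired RSCU t-test is conservative on subsets containing several
  codons of one family; see the calibration caveat.
* Only code tables 1 and 5 are shipped; the registry is data-driven but
  unpopulated beyond them.
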