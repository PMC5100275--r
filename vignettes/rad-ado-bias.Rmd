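---
title: "Allele drop-out bias in RAD-seq diversity estimates: model and methods"
author: "radbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele drop-out bias in RAD-seq diversity estimates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbias)
```

## The problem

RAD-seq genotypes a reduced representation of the genome: short tags
flanking the recognition sites of a restriction enzyme. A mutation that
destroys a recognition site on one haplotype silently removes that
haplotype's tag from the data — *allele drop-out* (ADO). Because haplotypes
that coalesce recently are likely to share the state of the restriction
site (both present or both absent), the haplotypes actually observed at a
RAD locus are a biased sample enriched in close relatives. Nucleotide
diversity computed from RAD data ($\pi_{RAD}$) therefore underestimates
the true diversity ($\pi_{true}$), and the underestimation grows with the
polymorphism level itself: the more diverse a genome region, the more
often its restriction sites are polymorphic, and the more strongly it is
under-sampled.

`radbias` reproduces this effect *in silico* end to end — coalescent
simulation, digestion, estimation — quantifies it under three demographic
/ selection models, and corrects RAD-based estimates by approximate
Bayesian computation (ABC).

## Simulation model

**Coalescent.** Each replicate simulates $n$ unlinked loci (default desk
scale 200 × 2 kb; the full study scale is 1000 × 10 kb) in four haploid
lineages, with complete linkage within a locus and free recombination
between loci. Time is measured in units of $4 N_e$ generations, so $k$
lineages coalesce at rate $k(k-1)$ and a pair has expected TMRCA $1/2$.
Three models are available:

* **panmictic** — the standard neutral coalescent with a single per-site
  $\theta = 4 N_e \mu$;
* **heterogeneous** — loci fall into $\theta$ classes with fixed
  proportions (e.g. 70% at $\theta_{ref}$, 20% at $\theta_{ref}/2$, 10% at
  $\theta_{ref}/10$), emulating selection reducing diversity in parts of
  the genome. Classes are assigned deterministically by count rather than
  multinomially: the stated proportions are part of the model, and
  fixing them removes a needless variance component from between-model
  comparisons. The quantity that genome-wide diversity estimates is the
  proportion-weighted mean $\theta$ (`theta_true`);
* **structured** — two demes of equal size separated `divergence_t` time
  units ago with no subsequent migration; one diploid is sampled per deme
  (haplotypes 1–2 and 3–4). Cross-deme lineages cannot coalesce more
  recently than the split, which is exactly why ADO bias fades with
  divergence.

**Sequences.** A uniform random root sequence evolves along each genealogy
under Jukes–Cantor substitution at rate $\theta$ per site per unit branch
length, which calibrates the expected pairwise per-site diversity of two
haplotypes to $\theta$ in the low-$\theta$ limit (a pair's expected path
length is 1 in these units). Rather than placing individual Poisson
events, each branch samples its exact JC transition: a site differs from
its parent with probability $\tfrac34(1 - e^{-4\theta b/3})$ for branch
length $b$, and a changed site is uniform over the three other bases —
marginally the same substitution process, fully vectorised. At
$\theta = 0.1$ this finite-site saturation puts realized diversity ~9%
below $\theta$; at $\theta \le 0.01$ it is negligible. Uniform base
composition is assumed throughout; it is also what makes the expected
motif yield analytic (below).

**Reproducibility.** One master seed per configuration; every locus, the
motif draw and the diploid pairing use independent substreams derived from
it, so enlarging `n_loci` never perturbs earlier loci, and every
experiment driver is bit-reproducible from its arguments.

## In silico digestion

Ten distinct random 8-bp motifs (both counts configurable) are matched
exactly on the forward strand of every haplotype. Each position where at
least one of the four haplotypes carries an intact motif becomes a RAD
locus; the catalog records per-haplotype intactness and the 100-bp tag
immediately 3' of the motif. Occurrences whose tag would overrun the locus
are skipped, so the expected catalog size under uniform composition is

$$ n_{loci} \, (L - m - \ell + 1) \, \bigl(1 - (1 - 4^{-m})^k\bigr) $$

≈ 1510 for $k = 10$ motifs of $m = 8$ bp, $\ell = 100$ bp tags and 1000
loci of $L = 10$ kb — the "≈1500 loci per genome" regime of the original
design. Two deliberate choices:

* tags exclude the motif itself, so restriction-site SNPs drive sampling
  (drop-out) but never the distance numerator;
* the catalog conditions on *at least one* intact haplotype. Sites whose
  motif was gained by a recent mutation enter the catalog on size-biased
  (deeper) genealogies; this enriches $\pi_{true}$ at catalog loci by a
  few percent at high $\theta$ — a genuine property of RAD catalogs, not
  an artefact, and invisible at the study's figure resolution.

For empirical genomes, motif windows containing non-ACGT symbols never
match, and loci where any haplotype's tag overlaps an N are excluded from
*both* estimators (symmetric exclusion cannot bias their comparison).
Reverse-complement search is available for real enzyme motifs.

## Estimators

With two diploid individuals, diversity is averaged over loci as
$\pi = \sum_k \pi_k / \sum_k L_k$ where $L_k$ is the tag length and
$\pi_k$ aggregates the cross-individual tag distances $d_{ij}$ over the
$h_1$, $h_2$ haplotypes present. $\pi_{true}$ uses all four haplotypes at
every catalog locus ($h_1 = h_2 = 2$); $\pi_{RAD}$ uses intact haplotypes
only, at loci present in both individuals. Per-individual sharing
proportions (loci present in both / loci present in the individual) are
the second observable RAD-seq provides.

Two normalisations of $\pi_k$ are implemented. The published formula
divides by $h_1 + h_2$; the conventional mean-pairwise estimator divides
by $h_1 h_2$. They coincide without drop-out but diverge when haplotypes
are missing: dividing by $h_1 + h_2$ shrinks a locus with one missing
haplotype by a factor $2/3$ *regardless of the model*, so under that
normalisation the bias no longer vanishes between long-isolated
populations. Only the $h_1 h_2$ form reproduces the study's structural
results (the divergence limit, and the predictive $\pi_{RAD}$
distributions for highly polymorphic genomes), and it is also what
genotype-level RAD data yields — an apparent homozygote created by ADO
duplicates its intact haplotype, which averages distances exactly as
$1/(h_1 h_2)$ does. `pair_mean` is therefore the package default;
`as_printed` is retained as an option for formula-level comparison.

The SNP-per-tag dispersion diagnostic tests Poisson equidispersion of
segregating-site counts across tags with the chi-square index of
dispersion $D = (n-1)s^2/\bar{x} \sim \chi^2_{n-1}$ (one-sided,
overdispersion). The coalescent itself overdisperses SNP counts (loci
share one genealogy each), as does $\theta$ heterogeneity; the test choice
is ours, as the original analysis does not name one.

## ABC correction

The correction assumes the neutral panmictic model and infers
$\log_{10}\theta$ from two summary statistics: observed $\pi_{RAD}$ and
the mean of the two sharing proportions (the mean is exchangeable-safe; a
per-individual variant is available). The reference table draws
$\log_{10}\theta \sim U(-5, -1)$ and runs the full pipeline per draw; rows
with undefined statistics (no shared locus, possible near $\theta = 0.1$)
are flagged and excluded from inference rather than imputed.

Estimation follows the classical regression-ABC scheme: statistics
standardised by their MAD, Euclidean distance to the observation, the
closest `tolerance` fraction (default 0.05) accepted, and a local linear
regression of $\log_{10}\theta$ on the standardised statistics, weighted
by the Epanechnikov kernel $1 - (d/d_{max})^2$, corrects each accepted
draw to the observation: $\theta^*_i = \theta_i - b'(s_i - s_{obs})$.
Numerical safeguards: statistics constant within the accepted set are
dropped from the regression (they carry no local information); a fully
singular regression falls back to rejection with a warning; adjusted
draws are truncated to the sampled prior support, since linear
extrapolation is meaningless for observations outside the table's
statistic range; a zero MAD (constant statistic) contributes no distance
information. The point estimate is the weighted posterior median
(robust); the weighted mean and a 95% credible interval are also
reported. Leave-one-out cross-validation treats table rows as
pseudo-observations, each removed from the table before being estimated.

```{r abc-example, eval = FALSE}
tab <- build_reference_table(2000, n_loci = 200, locus_len = 2000, seed = 1)
cv <- cross_validate(tab, n_pseudo = 100, tolerance = 0.05,
                     method = "loclinear", seed = 2)
cv
```

## What the generator does and does not emulate

The synthetic data reproduce the genealogical mechanism of ADO:
restriction-site polymorphism driven by the same coalescent that shapes
tag variation. They do **not** emulate read-level reality: sequencing
error, coverage variation, PCR duplicates, size selection, paired-end
chemistry, or coverage-based heterozygote miscalling are all out of
scope, as are indels (alignments are substitution-only, so coordinates
match across haplotypes by construction), GC-heterogeneous base
composition, and intragenomic repeat structure. Tests passing on
synthetic data therefore demonstrate the estimators and the correction
under the stated model — as the cross-validation itself does — not that
any real data set follows that model; the study's own empirical
comparisons show real populations deviating from it in both directions.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally for window arithmetic and
  reported 1-based in catalogs (R convention).
* Catalog rows sort by (locus, position, motif index); overlapping motif
  occurrences are independent loci; duplicate (locus, position, motif)
  triples are collapsed.
* Empty catalog, an individual with no loci, no shared loci, or all-zero
  SNP counts yield `NA` with an explicit warning — never a silent zero.
* Heterogeneous class counts use cumulative rounding so they always sum
  to `n_loci`.
* Desk-scale defaults (200 × 2 kb, 10 replicates per grid point; ABC
  tables of 2000 rows at the same scale) were chosen once for
  Monte-Carlo stability of every ordering and recovery property and are
  the sizes the test-suite exercises; the full study scale is a parameter
  change away.

## Known limitations

* The bias magnitude at $\theta \approx 0.007$ measures ~0.90
  (`pair_mean`; ~0.87 under `as_printed`) rather than the ~0.95 the
  original figure annotation suggests; the package reports what the model
  computes.
* One enzyme/motif set per digestion; no double-digest designs.
* ABC is single-parameter ($\theta$) by design; extending the corrected
  model with structure or selection parameters is explicitly out of
  scope.
* The coalescent sample is fixed at two diploids (four haplotypes), the
  study's design; estimator code is written for that sample size.
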