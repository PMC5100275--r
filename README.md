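# radbias

Quantifying and correcting the allele drop-out bias of RAD-seq diversity
estimates.

## The problem

RAD-seq sequences fixed-length tags next to restriction-enzyme recognition
sites. A mutation that destroys a recognition site on one haplotype removes
that haplotype's tag from the data (*allele drop-out*, ADO). Haplotypes
that coalesce recently tend to share the state of the restriction site, so
the haplotypes actually sampled at a RAD locus are biased towards close
relatives: nucleotide diversity estimated from RAD tags (π_RAD)
systematically underestimates the true diversity (π_true), and the more
polymorphic the genome, the stronger the underestimation. For population
geneticists working with RAD data in diverse species, this matters: at
per-site diversity around 7–10% the observed π_RAD can be roughly half of
the truth.

`radbias` is a simulation and inference toolkit for this bias:

* **Coalescent simulator** of multi-locus haplotype samples (4 haploids →
  2 diploids) under a neutral panmictic model, heterogeneous-θ mixtures
  (emulating selection), and a two-population clean-split model. Time is in
  4·Ne-generation units; sequences evolve under Jukes–Cantor calibrated so
  E[π] = θ = 4·Ne·μ per site.
* **In silico RAD digestion**: random (or named-enzyme) restriction
  motifs, per-haplotype site intactness, fixed-length tags — the 10 random
  8-bp motifs × 1000 loci × 10 kb design yields the classic ≈1500 RAD loci
  per genome.
* **Estimators**: π_true (all haplotypes at RAD loci), π_RAD (intact
  haplotypes at shared loci), per-individual locus-sharing proportions,
  with π_k = Σᵢ Σⱼ d_ij / (h₁h₂) by default (the published 1/(h₁+h₂)
  normalisation is available as `mode = "as_printed"`), plus a chi-square
  index-of-dispersion test for SNP-per-tag heterogeneity.
* **ABC correction**: reference-table simulation over a U(−5, −1) prior on
  log₁₀θ, rejection sampling with a tolerance rate, Epanechnikov-weighted
  local linear regression adjustment, and leave-one-out cross-validation.
* **Empirical front-end**: in silico digestion of reference-aligned phased
  genomes from FASTA (one file per haplotype + a diploid pairing table),
  with symmetric N-handling.

## Worked example

One full simulated RAD experiment: 200 unlinked loci of 2 kb at θ = 0.02,
ten random 8-bp motifs, 100-bp tags:

```r
library(radbias)
cfg <- model_config("panmictic", theta_site = 0.02,
                    n_loci = 200, locus_len = 2000, seed = 42)
res <- rad_replicate(cfg, return_catalog = TRUE)
res
#>  theta_true     model    pi_true     pi_rad     ratio n_catalog n_shared
#>        0.02 panmictic 0.01778125 0.01492424 0.8393247        80       66
#>    share_1   share_2 normalization_mode seed
#>  0.9166667 0.8918919          pair_mean   42
```

The 200 × 2 kb genome carries 80 RAD loci; π_true at those loci (0.0178)
tracks θ, but 14 loci are missing from one individual and more have lost
single haplotypes, so the RAD-observed diversity (0.0149) is ~16% too low
— the ADO bias at this polymorphism level. The per-individual sharing
proportions (0.92, 0.89) are the second statistic the ABC correction uses.

SNPs are also distributed across tags far more heterogeneously than a
Poisson process, because every locus rides a single coalescent genealogy:

```r
snp_dispersion_test(tag_snp_counts(attr(res, "catalog")))
#> $dispersion_index
#> [1] 140.7903
#> $p_value
#> [1] 2.371076e-05
#> $df
#> [1] 79
#> $ratio
#> [1] 1.782155
```

To correct an observed RAD estimate, build a reference table and estimate
θ from the observed statistics (here a cross-validation run):

```r
tab <- build_reference_table(2000, n_loci = 200, locus_len = 2000, seed = 1)
cv  <- cross_validate(tab, n_pseudo = 100, tolerance = 0.05,
                      method = "loclinear", seed = 2)
```

Experiment drivers (`run_bias_sweep()`, `run_heterogeneous_sweep()`,
`run_structured_sweep()`, `run_predictive_distribution()`) reproduce the
bias curves across θ, the ordering of the selection models, the weakening
of the bias with population divergence, and the predictive π_RAD
distributions at a given true polymorphism. A thin command-line wrapper
over these functions is installed at `inst/cli/radbias.R`. See the
methods vignette (`vignettes/rad-ado-bias.Rmd`) for the model, estimator
definitions and design choices.

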