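---
title: "Weighted single-step GWAS for repeated records: models and methods"
author: "wssgblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS for repeated records: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssgblup)
```

## The problem

Physiological indicators of heat stress in dairy cattle — rectal
temperature, respiratory rate scores, drooling scores — are recorded
repeatedly on the same cows under varying heat loads, and only a subset of
the herd is genotyped. Mapping the genomic regions that contribute to the
additive genetic variance of such traits therefore needs three ingredients
working together:

1. a **repeatability animal model** that separates additive genetic,
   permanent-environmental and residual variation in repeated records while
   adjusting for herd management and heat load;
2. **single-step GBLUP** (ssGBLUP), which evaluates genotyped and
   non-genotyped animals jointly by replacing the pedigree relationship
   matrix with a blend of pedigree and genomic information; and
3. a **weighted single-step GWAS** (WssGWAS), which converts the genomic
   breeding values of genotyped animals into per-SNP effects, re-weights
   markers by their apparent variance, and scans 10-SNP windows for the
   share of additive genetic variance they explain.

`wssgblup` implements this chain end to end, together with the genotype
quality control in front of it, the candidate-gene annotation behind it,
and a gene-dropping simulator that makes every stage testable without
animal data.

## The repeatability animal model

Records are modelled as

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Za} + \mathbf{Wpe} + \mathbf{e}$$

with fixed effects $\mathbf{b}$ (farm-year group, parity 1/2/3+,
lactation-stage class, milking status, and the temperature–humidity index
THI as a linear covariate), additive genetic effects
$\mathbf{a} \sim N(\mathbf{0}, \mathbf{H}\sigma^2_a)$,
permanent-environmental effects
$\mathbf{pe} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_{pe})$ and residuals
$\mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e)$. Heritability is
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)$ and
repeatability $t = (\sigma^2_a + \sigma^2_{pe}) / (\sigma^2_a +
\sigma^2_{pe} + \sigma^2_e)$. The permanent-environment term is
identifiable only with repeated records; with one record per animal the
model should be fitted with `include_pe = FALSE`.

`build_design()` constructs the incidence matrices: `X` uses reference
coding (one column dropped per factor, empty levels dropped with a
warning), `Z` maps records to *all* pedigree animals in pedigree order —
the same ordering every relationship matrix uses — and `W` maps records to
recorded animals only.

## Relationship matrices

* `build_A()` uses the tabular recursion; `inbreeding()` implements the
  Meuwissen–Luo algorithm; `build_A_inverse()` assembles the sparse inverse
  directly by Henderson's rules with inbreeding, never inverting dense A.
* `build_G()` is the (optionally weighted) VanRaden matrix
  $\mathbf{G} = \mathbf{Z}_c \mathbf{D} \mathbf{Z}_c' / \sum_i 2p_i(1-p_i)$
  with $\mathbf{Z}_c$ the gene-content matrix centred at $2p_i$. Allele
  frequencies are the observed frequencies of the genotyped set — the
  base-population frequencies of the data the package targets are not
  observable. A consequence worth knowing: with observed frequencies the
  centred columns sum to zero, so **G is always singular** and must be
  blended before inversion.
* `blend_G()` computes $\mathbf{G}^* = (1-\alpha)\mathbf{G} + \alpha
  \mathbf{A}_{22}$ with $\alpha = 0.05$ by default — enough to make
  $\mathbf{G}^*$ invertible even with duplicated genotypes, small enough to
  leave the genomic signal intact. $\alpha$ is recorded on the result.
* `build_H_inverse()` applies
  $\mathbf{H}^{-1} = \mathbf{A}^{-1} + \begin{bmatrix}\mathbf{0} &
  \mathbf{0}\\ \mathbf{0} & \mathbf{G}^{*-1} - \mathbf{A}_{22}^{-1}
  \end{bmatrix}$, validated in the test suite against brute-force inversion
  of the jointly constructed H.

## Variance components by AI-REML

`reml_estimate()` maximises the restricted likelihood with
average-information (AI) updates and an EM fallback:

* each iteration factorises the sparse mixed-model equations once
  (CHOLMOD); the restricted log-likelihood comes from the standard
  log-determinant identity, so it costs one factorisation per evaluation;
* exact first derivatives use the trace terms
  $\mathrm{tr}(\mathbf{K}^{-1}\mathbf{C}^{aa})$ and
  $\mathrm{tr}(\mathbf{C}^{pp})$, obtained from multi-right-hand-side
  solves against the factored equations;
* the AI matrix needs only three further solves (one per component);
* an AI step is accepted only if it keeps all components positive and does
  not decrease the likelihood; otherwise the step is halved (1, 1/2, 1/4,
  1/10) and finally replaced by an EM step, which cannot decrease the
  likelihood. Components are floored at $10^{-8}\times$ the phenotypic
  variance and flagged when pinned there;
* convergence is declared when the largest relative parameter change drops
  below `tol` ($10^{-8}$ by default; the validation suite uses $10^{-6}$,
  which changes estimates only in the seventh digit while saving
  iterations); standard errors come from the inverse AI matrix.

The likelihood evaluator is itself cross-checked two independent ways in
the tests: against a dense GLS evaluation of the same likelihood (to
$10^{-8}$) and against `lme4` on a submodel both can fit, where estimates
and log-likelihood agree to at least four decimals.

Cross-trait genetic correlations use `reml_bivariate()`, a dense
log-Cholesky parameterised maximiser intended for desk-scale data; the
per-trait pipeline deliberately stays univariate — scans are reported per
trait, and cross-trait covariances only inform the genetic-parameter
table.

## ssGBLUP and the weighted scan

`ssgblup()` assembles and solves Henderson's equations with
$\mathbf{H}^{-1}$ (direct sparse factorisation by default, Jacobi-
preconditioned conjugate gradients for large systems). `wssgwas()` then
iterates, holding the variance components fixed:

1. build $\mathbf{G}^*$ from the current SNP weights (iteration 1 uses
   $\mathbf{D} = \mathbf{I}$), rebuild $\mathbf{H}^{-1}$, re-solve the
   evaluation;
2. backsolve SNP effects from the genotyped animals' GEBV:
   $\hat{\mathbf{u}} = \mathbf{D}\mathbf{Z}_c'\mathbf{G}^{*-1}
   \hat{\mathbf{a}}_g / \sum_i 2p_i(1-p_i)$ — with $\alpha = 0$ and a
   full-rank G this inverts the genomic map exactly
   ($\mathbf{Z}_c\hat{\mathbf{u}} = \hat{\mathbf{a}}_g$);
3. convert effects to weights $d_i = 1.125^{\,|\hat u_i|/\mathrm{sd}
   (\hat u) - 2}$. The standardised effect is capped at 5 sd before the
   shift — un-damped weighting schemes are known to explode on single
   markers — and the weights are rescaled to sum to the number of SNPs so
   the total genomic variance is preserved. The sd is that of the whole
   effect vector for the trait (the plausible alternative, a per-SNP
   posterior sd, is not available from a BLUP backsolve).

Three iterations are the default. `window_variance_scan()` computes, for
every window of 10 consecutive SNPs within a chromosome, the genomic value
of each genotyped individual and its variance across individuals
(population form, divide by $n$), expressed as a percentage of
$\sigma^2_a$. Windows slide by 1 SNP by default — the common convention,
which strictly contains the disjoint step-10 alternative (`step = 10`);
chromosomes shorter than one window yield a single flagged short window.
`significant_regions()` keeps windows at or above the threshold (0.15% by
default) and merges overlapping or adjacent significant windows into
regions, reporting both the maximum and the sum of member-window
percentages.

`genes_in_regions()` annotates regions by closed-interval overlap
(1-based, GFF3 convention; BED input is converted on read) with no
flanking extension by default, and `overlap_with_deg()` intersects region
genes with an externally produced differential-expression table (FDR <
0.05, $|\log_2$ ratio$| \ge 1$ by default, case-insensitive name match).
The sign convention of the log2 ratio is deliberately the caller's
contract: the package never infers which group was the numerator.

## The simulator

`sim_config()` / `sim_dataset()` generate the full study shape: a
multi-generation pedigree from random sire–dam unions (10% males by
default, emulating dairy structure), gene-dropped biallelic genotypes
(founder frequencies uniform on a configurable MAF band; independent
segregation by default, with an optional Haldane crossover model),
marker-linked QTL with either jointly rescaled or exactly apportioned
(`qtl_var_shares`) variance contributions plus a pedigree-flowed polygenic
remainder, and repeated records carrying the fixed-effect structure of the
model above. Default variance components (0.015 / 0.03 / 0.20) give
$h^2 = 0.06$ and $t = 0.18$, the magnitudes published for rectal
temperature; THI is drawn uniformly on 70.5–90.2 index units and enters
the simulated record linearly (0.02 trait units per THI unit by default).
Scores that are ordinal in the field are simulated as continuous traits,
matching how the analysis models them.

What the simulator does *not* emulate: ascertained chip MAF spectra,
calibrated linkage-disequilibrium decay (founders are unrelated, so LD
arises only from co-segregation in the simulated families), selection or
assortative mating, and genotyping error. Passing tests therefore
demonstrate the correctness of the algebra and the behaviour of the
procedure under a clean genetic architecture — not field performance on
real chip data.

## Validation problem sizes and the detection power limit

The acceptance suite runs, per check: ratio identities on the published
variance components (instant); dense-oracle equivalences on pedigrees of
up to 200 animals; REML recovery on 10 replicates of 2,000 animals with
2–4 records each at the published variance magnitudes; and the QTL
detection property on 10 replicates of 1,000 genotyped animals with 2,000
SNPs.

The detection fixture deserves its own account. A focal QTL explaining 2%
of $\sigma^2_a$ must land inside a merged significant region at the 0.15%
threshold. At the published heritability of 0.06 this is unattainable at
desk scale: with 1,000 genotyped animals the focal QTL's single-marker
information content is $nR^2 \approx 1\!-\!3$, BLUP shrinkage retains only
a few percent of its variance, and the estimated window share lands at
0.03–0.12% — below threshold in every replicate, whatever the
architecture. The packaged fixture therefore uses a moderately-to-highly
heritable trait ($h^2 = 0.5$, $t = 0.6$, typical of dairy production
composition traits), a fully marker-linked architecture of 50 QTL at 2%
each, family structure (100 founders, two generations of 500, all
offspring genotyped) and the Haldane recombination model. Even under these
favourable conditions the property sits at the edge of the achievable:
the focal QTL's estimated window share fluctuates around 2–3 times the
threshold with a coefficient of variation near 50%, so a detection rate
of about 0.8–0.9 is the power limit of the design, and an occasional
replicate below the nine-of-ten bar reflects estimation noise, not a
defect in the scan. The weighting iterations, by contrast, reliably hold
or sharpen the focal QTL's effect-size rank.

## Known limitations

* Multi-trait REML is pairwise-bivariate and dense; the full three-trait
  fit of the genetic-parameter table is out of reach of the desk-scale
  implementation (and unnecessary for per-trait scans).
* No reliability/PEV reporting for GEBV, no APY or metafounder variants,
  no unknown-parent groups.
* Genotype imputation is out of scope; the QC chain expects complete or
  near-complete genotypes and mean-imputes the remainder at $2p_i$ when
  matrices are built.
* The HWE filter uses the full-enumeration exact test (no mid-p); with
  very large panels a chi-square screen would be faster but is not
  provided.
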