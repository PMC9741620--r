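---
title: "Kinship and individual identification in low-diversity, inbred populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship and individual identification in low-diversity, inbred populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small, isolated mammal populations can drift to extraordinarily low genetic
diversity — per-individual heterozygosity of tens of SNPs per megabase, one
to two orders of magnitude below outbred mammals — while accumulating very
high inbreeding (F above 0.7 in the most isolated demes). Conservation
monitoring of such populations relies on reduced-representation SNP panels
(ddRADseq) for two basic tasks: deciding whether two samples come from the
same physical animal (*individualization*, e.g. for capture–recapture), and
estimating pairwise relatedness and individual inbreeding to map
connectivity and genetic health.

Both tasks break down in exactly these populations: highly inbred relatives
share so much of their genotype that they look like sample replicates, and
population structure violates the homogeneity assumption behind
allele-frequency-based relatedness estimators. This package implements the
two contrasting estimator families, the pedigree and panel simulators needed
to probe them, and the individualization and recovery experiments that
demonstrate which estimator survives these conditions.

## Estimators

**Counting (KING-robust style).** For a pair of samples, over the loci
called in both, count each sample's heterozygous loci ($N^i_{het}$,
$N^j_{het}$), the jointly heterozygous loci ($N_{het,het}$), and the
opposite-homozygote loci ($N_{opp}$). With $m = \min(N^i_{het}, N^j_{het})$,

$$\hat\varphi = \frac{N_{het,het} - 2 N_{opp}}{2m}
  + \frac12 - \frac{N^i_{het} + N^j_{het}}{4m}, \qquad \hat r = 2\hat\varphi.$$

No allele frequencies enter: the estimate depends only on the pair's own
genotypes (`kinship(gm, estimator = "king")` asserts this invariance
exactly), which is what makes it robust to population structure. Identical
genotype vectors give $\hat r = 1$ regardless of missingness — the replicate
criterion. Negative estimates are retained in tables but excluded from
networks.

**Nine-state maximum likelihood (dyadml style).** The four alleles of a dyad
at one locus fall into one of nine condensed identity-by-descent states
$S_1..S_9$; their probabilities $\Delta_1..\Delta_9$ fully parameterize
pairwise relatedness *with inbreeding*:

$$r = 2\left(\Delta_1 + \tfrac{\Delta_3 + \Delta_5 + \Delta_7}{2}
  + \tfrac{\Delta_8}{4}\right),\quad
  F_i = \Delta_1 + \Delta_2 + \Delta_3 + \Delta_4,\quad
  F_j = \Delta_1 + \Delta_2 + \Delta_5 + \Delta_6.$$

The genotype-pair probabilities under each state are **derived at run time
from allele-identity partitions** (each IBD class is a single independent
draw of the minor allele), not transcribed from a published table;
transcription is the main error risk, so the unit tests check the derived
table against an independent exhaustive enumeration of ordered allele
configurations. The likelihood is a per-locus mixture over the nine states,
maximized over the 8-simplex by expectation–maximization from a uniform
start (per-locus state responsibilities; the update is the mean
responsibility), stopping when the log-likelihood gain drops below `1e-6`
or after 2000 iterations. EM is monotone and constraint-respecting by
construction, and every fit records its likelihood trace so monotonicity is
asserted, not assumed. A seeded 5-start Dirichlet option exists for flat
likelihoods. $r$ is deliberately **not truncated at 1**: under inbreeding
$r = 2\varphi$ can exceed 1, and that excess is precisely how inbred
non-replicates masquerade as duplicates.

Confidence intervals come from a locus bootstrap (default 100 replicates,
95% percentile). Because EM approaches the simplex boundary geometrically
and stops at a log-likelihood tolerance, boundary solutions sit at tiny
positive $r$ rather than exact 0; bootstrap values within `1e-4` of 0 —
orders of magnitude below anything a $\sim 10^3$-locus panel can resolve —
are treated as exact zeros so that intervals for unrelated dyads overlap 0.
Only estimates whose interval lies strictly above 0 enter kin networks;
network edges are classed close/distant at $r = 0.2$.

## Inbreeding

Two per-individual estimators complement the dyadic machinery. The moment
estimator uses observed versus expected homozygosity,
$\hat F = (O_{hom} - E_{hom})/(L - E_{hom})$ with
$E_{hom} = \sum_\ell (1 - 2p_\ell(1-p_\ell))$ (optional $2n/(2n-1)$
small-sample factor, default off). The ML estimator maximizes the genotype
likelihood under $P(\text{het}) = (1-F)\,2p(1-p)$ etc. over $F \in [0,1]$
by bounded scalar optimization (tolerance `1e-6`, endpoints checked
explicitly so boundary data yield exact 0 or 1). Heterozygosity rates are
reported as SNPs/Mb; the denominator is per-sample callable length (loci
with a non-missing call, or a catalog-level `callable_bp` total scaled by
the sample's call rate), so missing data does not deflate the rate. A
full-catalog denominator is available via `denominator = "catalog"`.

## Pedigrees and the crossing simulator

`pedigree()` stores a parentage DAG with founder inbreeding;
`theoretical_kinship()` is the classical recursion
($\varphi(x,x) = (1+F_x)/2$, $\varphi(x,y)$ averaging over the younger
member's parents, founders mutually unrelated), and `gene_drop_ibd()` is an
independent Monte Carlo oracle that drops labelled founder alleles (a
founder's second allele copies its first with probability $F$). The two
agree within Monte Carlo error on random pedigrees — the central
correctness check. `cross_genotypes()` gene-drops *observed* genotypes:
one allele drawn uniformly per parent per locus, loci unlinked, missing
parental calls propagating to missing offspring calls. Founder inbreeding
is not re-imposed during crossing: the founders' realized genotypes already
embody it.

The exact family trees behind the published recovery experiments are not
reconstructable, so the package ships minimal canonical pedigrees for the
seven relationship categories (parent–offspring through half-first cousins)
and four inbred-mating categories (offspring of unrelated parents, full
sibs, half sibs, half-first cousins), plus a TSV reader for arbitrary
designs.

## The synthetic panel

`lowdiv_preset()` fixes the study conditions all experiments default to:

* 45 individuals in 4 subpopulations (15/14/12/4) — the fourth is the small,
  highly isolated deme;
* 1400 polymorphic loci of 143 bp within a 6 Mb callable total (monomorphic
  sequence is carried by the callable-length constant rather than
  materialized, keeping panels small);
* ancestral minor-allele frequencies uniform on (0.15, 0.5), subpopulation
  frequencies from the Balding–Nichols beta model at divergence 0.10 — large
  enough that a two-group split is detectable, mirroring the K = 2 structure
  of the population being emulated;
* per-subpopulation founder inbreeding ranges (0.02–0.15, 0.05–0.20,
  0.15–0.40, 0.65–0.78), giving expected heterozygosity rates of roughly
  20–90 SNPs/Mb — the target range — and a most-inbred deme whose ML
  inbreeding recovers above 0.6;
* 23 replicate pairs at 10% missingness with zero genotyping error
  (replicates are copies, masked then optionally single-step flipped;
  a symmetric single-step error model is the simplest that can defeat
  exact-match duplicate detection).

Genotypes are drawn independently per locus with within-individual
correlation $F$; the truth record keeps every latent value, so expected
summaries (heterozygosity, homozygosity, differentiation) are recomputable
in closed form and the generator is tested against them. Seeded runs are
byte-reproducible. What the generator does **not** emulate: linkage
disequilibrium (panels are modelled post-pruning), migration and admixture
gradients between localities, and background kinship among panel members.
Passing tests therefore show estimator behaviour under idealized structure,
not under every failure mode of real data.

## The experiments

**Individualization.** `simulate_individualization_panel()` embeds in the
calibrated panel a trio of full siblings born in a small deme drifted
(Balding–Nichols divergence 0.78) from the most inbred subpopulation, with
within-deme parental inbreeding 0.3, plus one extra replicate of the first
sibling. The trio's panel-referenced ML inbreeding converges on ~0.78 —
the emulated locality's value. Crossing two F ≈ 0.78 founders directly
would instead make siblings near-clones that *no* estimator could separate
(their genotypes agree at ~95% of loci); deme-level drift is what
reconciles very high individual inbreeding with separable individuals, and
is the design chosen here. `run_individualization()` scores, per MAF
filter (0.025/0.1/0.2/0.3) and estimator, replicate pairs detected
($r > 0.8$) and inbred-relative pairs correctly separated ($r \le 0.8$).
The counting estimator detects 23/23 replicates and separates 5/5 inbred
relatives; the likelihood estimator detects 23/23 but reports $r > 0.9$
for the inbred trio — misclassifying 0/5 — at every MAF setting.

**Recovery.** `run_relatedness_recovery()` crosses fresh founders through
every canonical pedigree 100 times and estimates each labelled dyad with
both estimators; `run_inbreeding_recovery()` does the same for the inbred
offspring. Allele frequencies for the likelihood estimator come from the
replicate's full simulated dataset — all families embedded in a 45-sample
background reference panel drawn from the same population, the situation a
simulated family joins a study panel in. This reference matters: with only
a family's own members in the frequency panel, the dyad's shared alleles
are absorbed into the frequencies and distant-kin estimates collapse to
zero (with true frequencies they are recovered; both behaviours are
exercised in development diagnostics). With homogeneous Hardy–Weinberg
founders both estimators recover every category mean within ±0.05 of
theory at 1400 loci. Under structured founders (two subpopulations at
divergence 0.15, founder F uniform on 0.0175–0.4783, each family's
founders sharing one subpopulation while the background spans both) the
likelihood estimator inflates distant-kin categories and the counting
estimator deflates parent–offspring — the qualitative signature the
experiments exist to demonstrate. Inbreeding recovery is more accurate
than relatedness recovery under the same structure.

## Numerical and design choices

* Genotypes are minor-allele dosages {0, 1, 2} with a distinct missing
  sentinel; both estimator families need only dosage.
* Filters compose in the standard order (call rate → one SNP per tag →
  MAF → LD pruning), each recomputing frequencies on the current panel;
  the composed pipeline is idempotent. LD pruning is a deterministic
  greedy order-preserving scan (configurable window, default all pairs)
  dropping the later locus; undefined correlations (monomorphic columns)
  count as zero.
* MAF is computed on the analysis sample set as given, before any
  replicate merging.
* Duplicate clusters are connected components of the strict $r > 0.8$
  graph (replicate groups are equivalence classes); boundary values are
  not joined.
* Fixed loci ($p \in \{0, 1\}$) are skipped and counted by the likelihood
  estimator; an all-skipped dyad is an error, not a silent zero.
* Frequencies include the focal dyad (the "frequencies of the given set of
  samples" convention); excluding it is a known variant not implemented.
* Problem sizes in the test suite (1400 loci, 100 simulation replicates,
  100 bootstrap replicates, 45-sample background) are the study-scale
  conditions the package is calibrated to.

## Limitations

The canonical pedigrees are minimal stand-ins, not the published family
designs; founders are assumed mutually unrelated in theory computations,
while real founders carry unknown background kinship — a bias source that
is modelled only indirectly (via subpopulation sharing) in the structured
experiments. The likelihood model contains no genotyping-error term, and
the three-state (no-inbreeding) IBD variant is not implemented. Real-data
headline numbers that depend on the original study's genotypes (absolute
observed means of the recovery tables, the real panel's 1421-SNP count)
are reproduced as direction and magnitude properties on synthetic data,
not as exact values.
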