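---
title: "Models and methods behind crossploidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crossploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crossploidy` asks a single scientific question of a mixed-ploidy contact
zone: do the diploid and tetraploid populations exchange genes? It answers
it three ways — individual-level hybrid detection, population-level
differentiation statistics, and joint site-frequency-spectrum (SFS)
demographic inference — and ships a coalescent simulator of the whole data
chain so that every claim the pipeline makes can be tested against known
truth. This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the synthetic experiments show.

## The data model

The central object is a `genotype_matrix`: diploid-coded calls (0/1/2 copies
of the alternative allele, `NA` for missing) at unlinked biallelic SNPs, each
SNP on its own scaffold, for individuals labeled `D` (diploid) or `T`
(tetraploid). Tetraploids are diploid-coded deliberately: the analysis is
restricted to the conserved subgenome shared between ploidy levels, where
disomic inheritance is assumed and reads map uniquely, so a tetraploid's
genotype behaves like a diploid genotype at these markers. A
`marker_alignment` (an ITS-like Sanger alignment with group labels) supports
the independent barrier check.

## The synthetic contact zone

`simulate_genotypes()` draws each SNP from a two-population structured
coalescent with piecewise-constant sizes and migration, time in units of
$2N_e$ generations with the ancestral $N_e = 1$. A frequency panel of
`n_panel` gene copies per population (default 200) is simulated per site; a
mutation is placed uniformly on the genealogy's branches, giving the pair of
population allele frequencies $(p_D, p_T)$. Genotypes are then drawn
independently given the local frequency with inbreeding acting as
genotype-level excess homozygosity,

$$P(\text{het}) = 2p(1-p)(1-F), \qquad
  P(\text{hom}) = p^2 + Fp(1-p) \ \text{(alt)},$$

the simplest mechanism that satisfies a testable Hardy–Weinberg contract.
The engine is written in C++ because a per-site event loop over hundreds of
lineages, repeated for tens of thousands of sites and again inside every
likelihood evaluation, is what the field's simulators (ms, msprime,
fastsimcoal) compile for. It was validated against an independent
coalescent simulator (msprime): the mean per-SNP Weir–Cockerham $F_{ST}$
of 2,000 simulated sites falls inside a precomputed 50,000-site oracle
envelope under matched parameters.

**Study conditions.** The default configuration reproduces the sampling
design the package is built around: 45 + 50 individuals, 356 unlinked SNPs,
GBS-like missingness (site rate 0.10, individual rate 0.05 — the original
matrix's sparsity is not published, so these are stated defaults, not
estimates), and high fixed inbreeding $F_D = 0.81$, $F_T = 0.75$. The
default demographic model (`study_model()`) is constant gene flow with
$\nu = (1.0, 0.8)$, $M_{DT} = 0.3$, $M_{TD} = 0.4$. Two values were
calibrated once, before any acceptance measurement, to place the synthetic
panel in the strong-divergence regime (global $F_{ST} \approx 0.4$–$0.5$,
bimodal per-SNP distribution) that the pipeline is meant to exercise: the
split time $T_0 = 2.5$, and a discovery-bias ascertainment floor
`maf_min = 0.15` on the overall minor-allele frequency. The ascertainment
emulates a real property of reduced-representation SNP panels — rare
variants are systematically under-recovered — without which a neutral
coalescent emits a site-frequency spectrum dominated by rare alleles whose
near-zero per-SNP $F_{ST}$ drags the global mean to ~0.2 regardless of
divergence. Set `maf_min = 0` for unascertained spectra; every joint-SFS inference in
the package's own experiments uses 0, because frequency-spectrum methods
assume an unascertained spectrum — an IM model fitted to a
rare-variant-depleted panel compensates for the missing singleton mass with
runaway migration estimates. The ascertained default is appropriate for the
clustering, F_ST and hybrid-detection stages, which mirror a real
discovery-biased marker set.

What the generator does **not** emulate: linkage within scaffolds, allele
dropout correlated with divergence (a real GBS artifact), tetrasomic
segments, selection, and population structure within ploidy levels. Passing
tests therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to every artifact of a real GBS matrix.

`inject_hybrids()` builds positive controls the estimators can be scored
against — F1, F2 and first-generation backcrosses assembled by Mendelian
gamete sampling from randomly chosen parents — since the empirical study
design contains no confirmed hybrid to calibrate on.

## Filtering

`filter_chain()` applies, in the order the upstream protocol implies:
site missingness (> 0.5 removed), individual missingness (> 0.75 removed),
conserved-scaffold subsetting, invariant-site removal (minor-allele count
zero over called genotypes), and one-variant-per-scaffold pruning.
Comparisons are strict (`>`), reading the thresholds literally; pruning
keeps the lowest-position variant per scaffold (deterministic, unlike the
random choice some tools make). Each filter is idempotent and the report
records counts per stage.

## Differentiation statistics

*Per-SNP $F_{ST}$* is Weir & Cockerham's $\theta$ from the variance
components $a$ (among populations), $b$ (among individuals), $c$ (within
individuals); negative estimates are retained, undefined sites are flagged
with the reason. The **global** value is the unweighted mean of the defined
per-SNP estimates — the "average across SNPs" convention — with the
ratio-of-sums estimator reported alongside, because the two differ
materially when the site-frequency spectrum is skewed.

*AMOVA* is the one-level Excoffier decomposition of squared pairwise
distances (squared Euclidean on mean-imputed allele counts for SNPs;
squared Hamming proportion for alignments), with $\Phi =
\sigma^2_{among}/(\sigma^2_{among}+\sigma^2_{within})$ and a label-permutation
test using the add-one correction $p = (1 + \#\{\Phi^* \ge \Phi\})/(B+1)$,
so $p$ is never exactly zero. Every component is checked against a
brute-force sums-of-squares oracle.

*PCA* mean-imputes missing calls per site, centers, and decomposes by SVD.
Columns are not scaled by default (the common default of the tools this
mirrors); `scale = TRUE` is available, and the leading-axis percentage is
somewhat sensitive to that choice.

## Hybrid detection

**Admixture proportions (K = 2).** The likelihood extends the standard
binomial admixture model with an identity-by-descent branch: with
probability `F_ibd` an individual's two gene copies at a locus descend from
one cluster draw $k \sim \mathrm{Bern}(Q_i)$ and one allele draw
(duplicated); otherwise both copies are independent, giving
$g \sim \mathrm{Binom}(2, Q_i p_{1\ell} + (1-Q_i) p_{2\ell})$. The extension
matters here: the study populations are highly selfing, and under the plain
binomial model the excess homozygosity of true purebreds is partially
explained as admixture, biasing $Q$ away from the boundary. All E- and
M-steps remain closed-form (heterozygotes are impossible under the IBD
branch, which is what makes the bookkeeping exact). Cluster frequencies get
Dirichlet(1,1) pseudocount smoothing — an allele unseen in one cluster must
not make $Q = 1$ literally impossible for its carriers. After EM, each
individual's $Q$ is re-maximized exactly on a refined grid (the per-locus
likelihood is quadratic in $Q$), because EM's path through a flat
boundary ridge can stall at an interior value that is not the maximizer.

**Intervals and the nonhybrid rule.** An individual is called a nonhybrid
when its 90% interval overlaps 0 or 1 (within $\varepsilon = 10^{-6}$). The
default interval inverts the likelihood-ratio test at the fitted
frequencies: all $Q$ within $\chi^2_{1,0.90}/2$ log-units of the maximum.
This construction attains the boundary exactly when purity cannot be
rejected — which is the scientific content of the rule. The
parametric-bootstrap percentile interval is also implemented
(`interval = "bootstrap"`), but it resamples from the interior point
estimate and therefore cannot reach a boundary it should not exclude; used
for the nonhybrid rule it misfires on a few percent of true purebreds, so
it is not the default.

**Six-category classification.** Each category $c \in$ {PureD, PureT, F1,
F2, BC$_D$, BC$_T$} has fixed gene-origin proportions $\phi_c$ over ancestry
pairs (DD, DT, TT) — e.g. F2 = (¼, ½, ¼) — and the per-locus genotype
likelihood mixes Hardy–Weinberg probabilities over those pairs at the
parental frequencies. Frequencies are initialized from the labeled
populations and refined by a few classification-EM passes weighted by the
posterior probability of being pure; the posterior over categories uses a
uniform prior (none is stated for the original analysis; the alternative
Jeffreys-style frequency priors of the reference implementation are not
modeled).

## Joint-SFS demographic inference

The data spectrum is built per site from allele counts over called
genotypes, down-sampled to 24 haploid genomes per population by the
expected-value hypergeometric projection (which absorbs missing data), and
folded to minor-allele orientation by default — no outgroup polarizes the
SNP set, so folding is the safe reading; unfolded mode exists. Folding maps
cell $(i,j)$ and its complement onto the minor-total-count member of the
pair, with a deterministic tie-break on the hinge; folding and projection
commute exactly under this construction, which the tests assert.

Four isolation-with-migration families are fitted: constant gene flow (5
parameters), historical gene flow only (6), secondary contact (6), no gene
flow (3). The expected spectrum under a model is computed by the same
engine the simulator uses: expected branch length per panel-frequency
configuration, pushed through the same inbreeding-distorted genotype
kernel, so that simulation and fitting form a consistent pair by
construction and inbreeding ($F$ fixed, never estimated) distorts both
sides identically. The composite likelihood treats unmasked cells as
independent Poisson counts with the analytic $\hat\theta$ profile; the
fixed corners (and the folded non-canonical half) are masked. Model cells
that are zero under observed data are floored at $10^{-10}$ and counted.

**Optimization.** The composite surface of IM models is multimodal, and a
Monte-Carlo expected spectrum adds local ruggedness even under common
random numbers (one genealogy's topology flipping perturbs the objective
discontinuously). Isolated simplex runs from perturbed starts stall on
this surface hundreds of log-likelihood units above the optimum — measured,
not conjectured — so the perturbed start points (default start times
$2^{u}$, $u \sim U(-2, 2)$ per parameter) instead seed a
differential-evolution population (rand/1/bin, weight 0.7, crossover 0.9)
run for `n_gens` generations, followed by a Nelder–Mead polish of the best
member and a high-precision final evaluation (10,000 genealogies). The
perturbation span is two octaves because one octave does not cover
plausible migration truths around the default start, and the population
search then converges prematurely. Engine precision during search (panel
60, 800 genealogies per evaluation) was chosen so a five-parameter fit
takes ~13 s on one CPU; fits of different families with the same `seed`
share the engine stream, making their AIC differences directly comparable.
Bounds are $[10^{-3}, 100]$ for sizes and times and $[10^{-4}, 50]$ for
migration (the lower migration bound stands in for 0, which log-space
search cannot represent; the no-flow family covers exact zero).

**Uncertainty and model choice.** Uncertainty follows the subsampling
protocol: replicates draw individual subsets, rebuild and project the
spectrum, and are fitted independently; families are ranked by median AIC
($2k - 2\ln L$, $k \in \{5,6,6,3\}$) with Welch two-sample $t$-tests
against the best family (the conservative default when the test variant is
unspecified). The 99-subsamplings × 99-restarts protocol is the documented
default; the tests and the acceptance script scale it down (7 replicates,
12-member populations) to fit a single-CPU budget — problem sizes are
stated where used.

## Numerical and degenerate-input choices

Determinism: every stochastic routine takes a seed; the C++ engine uses its
own generator with inverse-transform uniforms only, so results are
bit-reproducible across platforms with the same standard library. Empty
data spectra yield $\ln L = 0$ flagged degenerate; sites entirely missing
in a population give flagged-undefined $F_{ST}$; all-missing individuals
get a uniform six-class posterior and survive masking as all-`NA` rows.
AMOVA refuses singleton groups; projection refuses upsampling targets;
VCF reading rejects multiallelic records and names the offending line for
malformed genotypes.

## Known limitations

The coalescent panel discretizes population frequencies at $1/n_\text{panel}$,
adding a small variance inflation of order $p(1-p)/n_\text{panel}$; with the
default panels this is well inside every tolerance used, but panel sizes
below ~50 are not recommended for fitting. Expected spectra are Monte
Carlo, so reported log-likelihoods carry a noise floor of a few units at
the default final precision; AIC gaps below ~5 between families sharing an
engine stream should not be over-read — consistent with the confounded
model pairs this analysis is explicitly designed to expose. The admixture
model assumes one global `F_ibd`; per-individual selfing variation is not
modeled. The six-class classifier assumes both parental pools are present
and reasonably pure; a panel that is mostly hybrids would need the full
Bayesian treatment.
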