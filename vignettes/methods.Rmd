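---
title: "Models and methods behind mtPopGen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtPopGen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtPopGen)
```

# Scope

mtPopGen implements the classical population-level analysis of human mtDNA
control-region (HVS-1) alignments: diversity indices, neutrality tests with
coalescent null distributions, mismatch-distribution demographic inference,
distance-based population structure (pairwise &Phi;~ST~, hierarchical AMOVA,
nonmetric MDS), and &rho;-statistic TMRCA dating under calibrated
mitochondrial clocks. A finite-sites coalescent simulator generates data in
the package's own input dialect, so every stage can be validated against
analytic expectations without any external download. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
validation does and does not demonstrate.

# Sequence handling

## The analysis window

HVS-1 alignments are anchored to rCRS coordinates (1-based, closed
intervals). The default analysis window is the highly polymorphic 339-bp
segment nps 16,032–16,370; the interval 16,184–16,194 (11 positions around
the poly-C tract, where alignment is uncertain under heteroplasmy) is
excluded by default, leaving 328 sites. The arithmetic is exact:
16,370 − 16,032 + 1 = 339 and 339 − 11 = 328.

```{r window}
a <- hapAlignment(matrix("A", 2, 400), coordStart = 16024L)
nSites(applyWindow(a, hvs1Window(), applyExclusions = FALSE))
nSites(applyWindow(a, hvs1Window()))
```

## Ambiguity policy

Two sequences share a haplotype iff their windowed strings are identical.
Sporadic `N` bases and alignment gaps are handled by a single global column
mask (`maskAmbiguous()`, on by default in the pipeline): any column
containing `N` or `-` in any sequence is dropped before all downstream
analyses. This is a policy choice, not a data-derived fact — source studies
rarely state how isolated ambiguous calls were treated. A global mask was
chosen over pairwise deletion because it keeps the site set identical for
every pair, which makes the mean number of pairwise differences an exact
average of Hamming distances and keeps AMOVA's squared-distance matrix
internally consistent. Indel columns are removed by the same mask
("indels not taken into consideration").

# Diversity and neutrality

Gene (haplotype) diversity uses Nei's unbiased estimator
$H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, which equals the fraction
of unordered sequence pairs carrying different haplotypes. The mean number
of pairwise differences $k$ is the average Hamming distance over all
$n(n-1)/2$ pairs on retained columns, and nucleotide diversity is
$\pi = k/L$.

Three neutrality statistics are implemented from their definitions:

* **Tajima's D** $= (k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the
  standard constants in $n$.
* **Fu's Fs** $= \ln\!\big(S'/(1-S')\big)$ with
  $S' = P(K \ge K_{obs} \mid \theta = k)$ from the Ewens sampling formula;
  the allele-count probabilities use unsigned Stirling numbers of the first
  kind, evaluated entirely in log space so samples up to hundreds of
  sequences are safe. Because the test is one-tailed, 5% significance
  corresponds to a p-value below 2%.
* **R2** $= \sqrt{\tfrac{1}{n}\sum_i (U_i - k/2)^2} / S$, with $U_i$ the
  number of folded singletons carried by sequence $i$ (the minority
  sequence at a site where one sequence differs from all others; no
  outgroup is assumed for HVS-1 data).

All three are flagged `NA`, not an error, on monomorphic samples.

## Null distributions

Significance comes from constant-size coalescent simulation
(`simulateNullNeutrality()`, implemented in C++ for throughput). The default
null is conditioned on the observed number of segregating sites: a genealogy
is drawn, and exactly $S$ mutations are placed uniformly on its total branch
length under infinite sites, which matches common Arlequin/DnaSP practice
and removes the nuisance estimation of $\theta$. A
$\theta$-conditioned mode (Poisson mutation at rate $\theta/2$ per lineage)
is available because tools differ on this point. Empirical p-values use
$p = (\#\{sim \le obs\} + 1)/(reps + 1)$ (lower tail for all three
statistics; the +1 avoids $p = 0$ and makes the test slightly
conservative).

The calibration test simulates 1000 constant-size datasets ($n = 30$,
$\theta = 5$, 1000 homogeneous sites) and checks that the 5% lower-tail
rejection rate of each statistic lies within ±1.5 points of 5%. The
observed datasets for that experiment use L = 1000 uniform-rate sites so
that the infinite-sites assumption embedded in the fixed-S null actually
holds in the data; at 328 sites with gamma-0.4 rate concentration,
recurrent hits would violate the null's own premise rather than exercise
the code under it.

# Mismatch distributions and the sudden-expansion model

The observed mismatch distribution is the relative frequency $x_j$ of
sequence pairs differing at exactly $j$ sites. Under a sudden expansion
from scaled size $\theta_0$ to $\theta_1$ at mutational time $\tau$ before
the present, the expectation is the classical

$$F_j = \hat F_j(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
  \sum_{i=0}^{j} \frac{\tau^i}{i!}
  \left[\hat F_{j-i}(\theta_0) - \hat F_{j-i}(\theta_1)\right],
  \qquad \hat F_j(\theta) = \frac{\theta^j}{(\theta+1)^{j+1}}.$$

At $\tau = 0$ this collapses to the equilibrium spectrum with $\theta_0$;
for $\theta_0 = 0$ and large $\theta_1$ it approaches a Poisson peak at
$\tau$. Expected mass beyond the largest observed class is folded into the
last class so observed and expected vectors share support — a truncation
rule the original tools do not document, chosen because the SSD
goodness-of-fit requires commensurate vectors.

Fitting minimises $SSD = \sum_j (x_j - F_j)^2$ over a deterministic coarse
grid ($\tau \in \{0, 0.5, \ldots, 20\}$, $\theta_0$ and $\theta_1$
log-spaced up to 1000) followed by Nelder–Mead refinement with a relative
tolerance of 1e-8; no randomness enters the fit. Harpending's raggedness
$Hri = \sum_{i=1}^{d}(x_i - x_{i-1})^2$ uses only the observed classes,
without padding.

SSD and Hri significance is a parametric bootstrap: `reps` datasets are
simulated under the *fitted* expansion model, refitted, and
$p = \#\{stat_{sim} \ge stat_{obs}\}/reps$. The source toolchain labels this
a "permutation test with 1000 replicates"; its documented mechanics are a
parametric bootstrap, and that is what is implemented (recorded as an
interpretation). The recovery test checks that the median fitted $\tau$
over 50 simulated expansions ($\tau = 4$, $\theta_0 = 1$,
$\theta_1 = 100$, $n = 50$, study-default mutation model) lands in
$[3, 5]$.

# Population structure

## Distances

Inter-haplotype distances use the Kimura two-parameter model with gamma
rate-heterogeneity correction,
$$d = \frac{a}{2}\left[(1-2P-Q)^{-1/a}-1\right] +
      \frac{a}{4}\left[(1-2Q)^{-1/a}-1\right],$$
with shape $a = 0.4$ (the study's setting for control-region data); $P$ and
$Q$ are the transition and transversion difference fractions estimated from
each pair. The quoted transition/transversion ratio of 10:1 parameterises
the simulator's mutation process and optional mutation weighting, not the
K2P estimator itself, which infers $P$ and $Q$ from data (recorded as an
interpretation). Saturated pairs ($1-2P-Q \le 0$) raise an error naming the
offending fractions. A `method = "raw"` mode (plain difference counts) is
provided for analyses that should not pass through the model, e.g.
comparisons against analytic island-model expectations.

## &Phi;~ST~ and AMOVA

The wording "Reynolds' genetic distances … weighted by &Phi;~ST~ indices"
conflates Reynolds' frequency-based coancestry with molecular-distance
AMOVA. The package implements the standard Excoffier-framework reading:
&Phi;~ST~ from the variance decomposition of squared inter-haplotype
distances (the sum of squares of $N$ sequences is
$\frac{1}{N}\sum_{i<j}\delta_{ij}^2$), linearised as
$-\ln(1-\Phi_{ST})$ for ordination. Negative &Phi;~ST~ estimates are
reported as computed but clipped to zero before linearisation (the
transform is undefined below −1 and negative estimates are sampling
noise); &Phi;~ST~ = 1 linearises to Inf and is flagged.

Two-level AMOVA partitions variance into among-group ($\sigma_a^2$),
among-populations-within-group ($\sigma_b^2$) and within-population
($\sigma_c^2$) components with
$\Phi_{CT} = \sigma_a^2/\sigma_T^2$,
$\Phi_{SC} = \sigma_b^2/(\sigma_b^2+\sigma_c^2)$,
$\Phi_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma_T^2$, so
$(1-\Phi_{ST}) = (1-\Phi_{CT})(1-\Phi_{SC})$ holds identically. Negative
components are not truncated (Arlequin behaviour), so indices can be
slightly negative. Permutation significance uses the standard three
schemes — individuals among all populations (ST), whole populations among
groups (CT), individuals among populations within their group (SC) — with
$p = (\#\{perm \ge obs\}+1)/(perms+1)$ and 10,000 permutations by default.
When all between-group variance is fixed and no within-group variance
remains, $\Phi_{SC}$'s ratio is 0/0 and is reported as 0 by convention.

## Ordination and group comparisons

Nonmetric MDS (Kruskal stress-1, two dimensions, 50 random restarts by
default) runs through `vegan::metaMDS` on the linearised matrix; stress is
reported on vegan's 0–1 scale, and coordinates are defined only up to
rotation/reflection/translation. Nonmetric scaling was chosen because
stress is the quantity reported in the ecology toolchain this analysis
descends from. Kruskal–Wallis comparisons of per-population indices across
grouping schemes go through `stats::kruskal.test` (rank-based H with tie
correction, chi-square approximation).

# The coalescent simulator

The generator is first-class, tested code, and its defaults are the study
conditions it emulates: a 328-site window, transition bias 10:1, gamma rate
heterogeneity with shape 0.4. Time is scaled in units of $N$ generations,
so a deme's lineage pair coalesces at rate 1, each lineage mutates at rate
$\theta/2$, and each lineage emigrates at total rate $Nm$. Three models are
provided:

* **constant** — standard coalescent; $E[S] = a_1\theta$ under homogeneous
  infinite sites.
* **expansion** — instantaneous size change from $\theta_0$ to $\theta_1$
  at scaled time $\tau/\theta_1$, which makes the simulator's $\tau$
  identical to the mismatch model's mutational-units $\tau$, so
  parameter-recovery experiments compare like with like.
* **island** — symmetric migration among `nPops` demes; optional group
  labels scale cross-group migration by `crossGroupFactor`, injecting
  hierarchical structure for AMOVA power checks. For $Nm \ge 10^4$ the
  genealogy is drawn in its exact strong-migration (panmictic) limit
  rather than event by event.

The finite-sites mutation model draws per-site rates from a gamma
distribution (shape 0.4, fixed per replicate); each mutation picks a site
proportionally to its rate and applies a transition with probability
$tstv/(tstv+1)$, otherwise a random transversion. Identical configuration
and seed give byte-identical FASTA output.

Two analytic checks are run with heterogeneity disabled
(`gammaShape = Inf`): the Watterson expectation $E[S] = a_1\theta$ and the
island-model expectation $F_{ST} \approx 1/(1+2Nm)$ both presuppose
homogeneous, effectively infinite sites. Recurrent hits make the
finite-sites model sit below $a_1\theta$ by construction: at the 328-site
default with homogeneous rates the measured deficit of mean $S$ is about
6% (and larger with gamma-0.4 rate concentration), while at
mitogenome-scale $L = 16{,}000$ the simulator reproduces $a_1\theta$ to
about 1%. The engine is therefore validated against the formula at large
homogeneous $L$, and the 328-site regime is separately tested inside a
descriptive 10% band that documents the homoplasy deficit. For the
island check, ten demes are used because the finite-island pairwise
expectation is $1/(1+2Nm\,d/(d-1))$, which at $d = 10$ (0.310) sits well
inside the ±0.1 acceptance band around the infinite-island value 1/3.

What the simulator does *not* emulate: sequencing error, heteroplasmy,
selection, recombination (absent in mtDNA), uneven sampling dates, or the
mosaic of real demographic histories. Passing the validation suite
therefore demonstrates that the statistics and their null machinery are
correct under the stated models, not that the models capture every feature
of real HVS-1 data.

# Rho dating

A clade's $\rho$ is the mean mutational distance of its sampled lineages
from the root haplotype: $\rho = \frac{1}{n}\sum_b m_b n_b$ over branches
$b$ with mutation count $m_b$ and $n_b$ descending sampled lineages (tip
multiplicities represent identical sampled haplotypes). The standard error
follows the classical genealogy-conditional form
$\sigma_\rho^2 = \frac{1}{n^2}\sum_b m_b n_b^2$; for a star tree these
collapse to $\rho = k$ and $\sigma_\rho = \sqrt{k/n}$.

Ages are linear conversions under calibrated clocks: one substitution per
3624 years for the whole mitogenome corrected for purifying selection, and
one synonymous substitution per 7884 years. Confidence intervals are
$age \pm 1.96\,\sigma_\rho \times$ (years per substitution), reported
untruncated: a lower bound below zero is kept as computed and flagged with
a warning, because silently clamping would misrepresent the estimator's
sampling distribution (published tables show the same negative bounds).
Trees are inputs — Newick with branch lengths as mutation counts and
optional `*k` multiplicity suffixes on tip labels — since phylogeny
reconstruction and haplogroup nomenclature are a separate concern.
Maximum-likelihood branch-length dating is out of scope.

# Pipeline and reproducibility

`runFullAnalysis()` drives all stages from one config (list or YAML),
writing TSV tables and a JSON run manifest. A single master seed yields
deterministic per-stage child seeds derived from the stage name, so each
stage is reproducible independently of execution order, and a rerun with
the same config is byte-identical. Per-population failures (e.g. a
monomorphic sample) are isolated and recorded rather than aborting the
run. The package's function surface is the interface; a thin script
wrapper for shell use lives in `inst/scripts/run_pipeline.R`.

## Problem sizes in the validation suite

The test suite runs the oracle-equivalence fuzz at 1000 alignments
($n \le 10$, $L \le 30$), the neutrality calibration at 1000 datasets ×
1000 null replicates, the AMOVA type-I experiment at 200 datasets × 500
permutations, the expansion recovery at 50 simulations, and the island
check at 200 replicates; these sizes give Monte-Carlo standard errors
comfortably inside each test's band. The mismatch-bootstrap calibration
runs at a reduced 40 × 50 replicates as a uniformity check, since each
replicate involves a full simulate-and-refit cycle; the package default
for real analyses remains 1000 bootstrap replicates.

# Known limitations

* The fixed-S null treats mutations as infinite-sites; for extremely short
  or hypervariable windows the finite-sites correction is not modelled in
  the null (both conditioning modes are exposed).
* The mismatch fit's parameter surface is flat in $\theta_1$ once
  $\theta_1 \gg \tau$; fitted $\theta_1$ values are then only lower-bound
  informative, although $\tau$ and SSD remain stable.
* Pairwise &Phi;~ST~ p-values are not corrected for multiple comparisons;
  callers should apply their preferred correction across the matrix.
* The K2P-gamma distance errors on saturated pairs rather than guessing;
  deeply divergent inter-specific data are outside the intended range.
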