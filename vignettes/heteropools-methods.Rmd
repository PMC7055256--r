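---
title: "Simulating heterotic pool formation and reciprocal recurrent selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating heterotic pool formation and reciprocal recurrent selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the simulator addresses

Hybrid breeding in a self-pollinating crop has to start somewhere: a set of
diverse inbred founders must be split into two heterotic pools before
reciprocal recurrent selection (RRS) can begin. `heteropools` simulates that
decision *in silico* under the dominance model of heterosis and asks whether
the initial split — random, by SNP genetic distance, or optimized on
predicted hybrid performance — matters for hybrid performance many cycles
later, compared with a control program that never forms pools and selects
inbred lines on their own (per se) performance.

All selection in the simulator acts on **true genetic values** (TGV): there
is no phenotyping error, no genotype-by-environment interaction and
heritability is effectively 1. This isolates the comparison of pool-formation
strategies from everything a field trial would add.

## Model components

### Founder genomes

Founders are fully inbred lines whose haplotypes are drawn from a neutral
coalescent with constant effective population size (`Ne = 100` by default).
The default genome is 10 chromosomes, each 1 Morgan and $10^8$ bp
(recombination $10^{-8}$/bp, so 1 Morgan is exact by construction), with
mutation rate $2.5\times10^{-8}$/bp. The generator cuts each chromosome into
windows of equal genetic length (50 per chromosome by default), gives each
window an independent Kingman genealogy and drops infinite-sites mutations on
its branches. Recombination is therefore free between windows and absent
within them; this brackets the true sequential-coalescent linkage structure
while leaving the site-frequency spectrum and the expected segregating-site
count exactly at Watterson's $\theta\,a_{n-1}$ with
$\theta = 4 N_e \mu L$ — which is what the test suite verifies across seeds.
Downstream results depend on allele frequencies and map positions, not on
fine-scale founder LD, so the window count is not a sensitive parameter.

From the segregating sites, 10,000 SNPs and 500/2,000/8,000 QTN are drawn
uniformly at random, in equal numbers per chromosome. SNP and QTN sets are
disjoint: the SNPs are a neutral observatory for diversity, the QTN carry the
trait, and keeping them separate keeps the diversity metric formally
independent of the selected loci. Surplus segregating sites remain in the
panel but are untracked. Each founder is a doubled haplotype, so the 100
founders are fully homozygous and pairwise distinct.

### The quantitative trait

Each QTN $i$ contributes $a_i(x_i - 1) + d_i\,[x_i = 1]$ to TGV, where
$x_i \in \{0,1,2\}$ is the alt-allele dosage: homozygotes sit at $\mp a_i$,
the heterozygote at $d_i$. Additive effects are standard normal; degrees of
dominance $\delta_i = d_i/|a_i|$ are $N(\bar\delta, 0.2)$ with
$\bar\delta \in \{0.2, 0.4, 0.8\}$ (0.2 is a *variance*, SD
$\approx 0.447$). The normal is deliberately *not* truncated at $\pm 1$ even
though the model is motivated by incomplete dominance: with
$\bar\delta = 0.8$ an appreciable tail exceeds 1, no truncation rule is part
of the model definition, and truncating would shift the realized mean
dominance away from the configured value. A `truncate` switch in
`dominance_config()` provides the strict variant for sensitivity analyses.

Effects are calibrated once, in the founders: a single scale factor
$c = \sqrt{10/\mathrm{var}(g)}$ (sample variance, $n-1$ denominator over the
100 founders) multiplies all effects, and an intercept shifts the mean to
100. Founder TGV then has mean 100 and variance 10 to floating-point
accuracy; because the founders are fully homozygous the dominance effects do
not enter the calibration, and calibration is idempotent and invariant to
any prior positive rescaling. The $n-1$ denominator is a convention; at
$n = 100$ the alternative changes the scale by under 1%.

### Pool formation

Three balanced bipartitions of the founders into pools of 50:

* **random** — a uniform draw;
* **genetic distance** — PCA of the centered founder SNP dosage matrix
  (no variance scaling), founders ranked on PC1, lower half vs upper half.
  A rank split is used rather than a sign threshold because the pools must
  be exactly 50/50; ties break by founder index and the PC1 sign is
  canonicalized, making the split deterministic;
* **hybrid performance** — every pairwise F1 TGV is computed exactly (the F1
  of two inbreds is deterministic, so the full 100×100 diallel costs one
  matrix product), then a genetic algorithm searches balanced bipartitions
  for the one maximizing the mean between-pool F1 TGV. The GA uses binary
  membership encoding, tournament selection (size 3), uniform crossover with
  a balance-restoring repair, swap mutation (rate 0.05), elitism, a
  population of 200 and up to 500 generations with early stop after 100
  stagnant generations. The GA is validated against exhaustive enumeration
  of all balanced bipartitions on instances of up to 12 founders; defaults
  were chosen to reach the exhaustive optimum on those instances with a wide
  margin.

### Breeding cycles

Meiosis uses a Poisson crossover process on the genetic map — crossover
count $\sim$ Poisson(map length), positions uniform, no interference, no
obligate chiasma — which makes two-locus recombination follow Haldane's map
function; the suite checks both the crossover intensity and the map function
against their closed forms. A DH progeny is one gamete of the deterministic
F1 of two inbred parents, doubled.

RRS-TGV, per cycle and per pool: 500 random matings among the 50 parents
(pairs of distinct parents, drawn uniformly with replacement across matings;
selfing is excluded since the self of a DH is a clone), one DH per mating;
each progeny's GCA is the exact mean TGV of its F1s with all 50 current
parents of the *opposite* pool; the top 10% become the pool's next parents.
Both pools update synchronously from the parents that entered the cycle.
The control mates 1,000 pairs among its current parents (initially the 100
founders), ranks the 1,000 DH lines on their own TGV and promotes the top
100. Census (1,000 new DH) and selection proportion (10%) are identical in
the two schemes. Selection ties break by original index so degenerate cases
remain deterministic.

**Reporting.** Inbred summaries are the mean and variance of TGV over all
DH progeny (per pool, then averaged over the two pools for RRS). Hybrid
summaries report *future hybrid performance among the selected parent
lines*: for RRS the 50×50 between-pool crosses of the two newly selected
parent sets, for the control the 4,950 half-diallel crosses of its 100
selections (selfs excluded). The alternative of summarizing all 25,000
progeny-by-tester hybrids per pool was considered and rejected: it compares
an unselected hybrid population against the control's selected one and
thereby builds a one-cycle-gain offset into the scheme comparison, which an
additive-null experiment (where the two schemes must coincide) makes
visible. Selection itself always evaluates the full progeny-by-tester
hybrid set.

### Diversity metrics

Principal axes of SNP diversity are fitted **once**, on the founders, and
every later population is projected onto those fixed axes. Refitting each
cycle would make PC1 scores incomparable across cycles, and the trajectory
of interest — pools drifting apart while each pool's internal range
contracts — only has meaning on a common axis. Projection is
`(dosage − founder mean) · loadings` with unit-norm loadings and a
deterministic sign convention. Replicate aggregation reports per-cell mean
and SD ($n-1$) of every statistic.

## Scenario grid and seeding

The full experiment is 3 QTN levels × 3 dominance levels × 4 strategies ×
20 replicates of 30 cycles. Within a (QTN, dominance, replicate) cell all
four strategies receive the identical founder population, locus assignment,
trait and diversity axes. Seeds derive deterministically from a master seed
through an integer mixing chain (`derive_seed()`), so any cell can be
reproduced in isolation; `run_grid()` writes one tidy CSV per cell and skips
cells already on disk, making long runs resumable, and a failing cell is
recorded without aborting the rest.

## The desk profile

Development, testing and the qualitative acceptance checks run on a reduced
profile chosen once: 2 chromosomes of $10^7$ bp kept at 1 Morgan
(recombination $10^{-7}$/bp) with mutation $2.5\times10^{-7}$/bp — so both
the per-chromosome crossover process and the expected segregating-site
density match the full genome — 40 founders, 1,000 SNPs, 200 QTN (50 for
the low-diversity scenario), 100 matings per pool, 10 cycles, 5 replicates.
All structural invariants (balanced pools, equal census, 10% selection,
equal loci per chromosome) are preserved. At this scale a full four-strategy
cell takes a few seconds.

## Numerical conventions and checks

* Stochastic oracle comparisons throughout the suite use a 3-standard-error
  band: Watterson's segregating-site expectation, the Poisson crossover
  intensity, Haldane's recombinant fraction, sampled-effect moments, and
  the scheme-equivalence checks below.
* The additive null ($\delta_i = 0$) collapses the model: every hybrid
  equals its midparent mean, the split objective is the same for every
  balanced bipartition, and GCA ranks lines exactly like their own TGV.
  The first-cycle selection response of RRS then matches per se selection.
  Over many cycles a small genuine asymmetry remains even without
  dominance: selecting the top 10% within each pool separately carries a
  slightly smaller expected selection differential than selecting the top
  10% of the combined census, and the pools (half the parents each) drift
  faster. At the desk census this deficit is directional but stays inside
  the 3-SE replicate band, which is how the acceptance checks frame scheme
  equivalence; the full-scale census exists precisely to keep drift
  negligible.
* Degenerate inputs are handled explicitly: founders identical at all QTN
  fail calibration; founders identical at all SNPs fail the PCA split;
  too few segregating sites fail founder simulation with the required vs
  obtained counts; heterozygous parents are rejected where determinism of
  the F1 requires inbreds; selection ties break by index.

## What passing tests do and do not show

The desk-scale acceptance run reproduces the qualitative pattern of the
full-scale experiment: the three splitting strategies are mutually
indistinguishable; RRS-TGV hybrids beat per se selection at high dominance
and/or many QTN while the schemes coincide at low dominance and few QTN;
control inbreds always beat pool inbreds; hybrid variance collapses under
RRS; pools diverge on PC1 while within-pool diversity contracts faster than
under per se selection. These are finite-sample statements at the desk
census with 5 replicates — they demonstrate the mechanism (dominance ×
allele-frequency divergence between pools), not the magnitudes of the
full-scale figures, which require the full grid (`scenario_grid()` defaults,
720 runs). The founder generator's windowed-coalescent approximation, the
absence of environmental error and of epistasis, and selection on *true*
values mean none of this should be read as a forecast for any real breeding
program.

## Known limitations

* Between-window linkage in founders is free and within-window linkage
  complete; founder LD decay is therefore a step approximation.
* The coalescent history has constant `Ne`; no demography hook beyond that
  is currently wired in.
* Only two pools, one trait, fully inbred (DH) material and non-overlapping
  generations are supported.
* The GA is validated exhaustively only up to 12 founders; at 100 founders
  its optimum is a best-found, not a certificate.
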