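---
title: "Multiclass synonymous substitution models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiclass synonymous substitution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mssrates)
```

## The model

Codon substitution models of the Muse–Gaut (MG94) family describe coding
sequence evolution as a reversible, time-homogeneous Markov process on the
61 sense codons, with instantaneous rates that separate nucleotide-level
mutational bias from selection at the protein level. `mssrates` implements
the *multiclass synonymous substitution* (MSS) extension, in which
synonymous substitutions no longer share a single rate: every single-step
synonymous codon pair (67 of them under the universal code) can carry its
own relative rate.

For a one-nucleotide change from sense codon $x$ to sense codon $y$ at
codon position $p$, exchanging nucleotides $n$ and $m$ (target $m$):

$$
q_{xy} =
\begin{cases}
\alpha(x,y)\,\theta_{nm}\,\pi_{pm} & \text{synonymous} \\
\beta\,\theta_{nm}\,\pi_{pm} & \text{nonsynonymous} \\
0 & \text{more than one nucleotide changes.}
\end{cases}
$$

Here $\theta$ is a symmetric (REV-style) nucleotide exchangeability with
$\theta_{AG} = 1$ for identifiability, $\pi_{pm}$ is the equilibrium
frequency of the target nucleotide at codon position $p$, $\beta$ is the
shared nonsynonymous rate, and $\alpha(x,y)$ is the synonymous rate of the
pair. The model families differ only in how $\alpha$ varies:

* **standard** — $\alpha \equiv 1$ (plain MG94xREV);
* **a_priori / ga** — a partition of the 67 pairs into $K$ classes with a
  designated reference class pinned to $\alpha_0 = 1$; for the `ga` family
  the partition is learned from data;
* **synrev** — one class per amino acid (18 classes, 17 free rates);
* **synrevcodon** — one class per pair (67 classes, 66 free rates).

For the mean-constrained families the mean of $\alpha$ over the 67 pairs
is fixed to 1, because only products of rates and branch lengths are
identifiable; $\beta$ is then interpretable as the familiar dN/dS
($\omega$). Because the families are nested
(MG94 $\subset$ SynREV $\subset$ SynREVCodon), likelihood-ratio tests with
17 (SynREV vs MG94) or 66 (SynREVCodon vs MG94) degrees of freedom apply;
degrees of freedom are always computed from free-parameter counts. Note
that the codon-pair family has 66, not 67, free rates once the mean
constraint is imposed.

### Equilibrium frequencies

Position-specific nucleotide frequencies are estimated from the alignment
and corrected for stop-codon exclusion (CF3x4): the naive product of
observed positional frequencies, renormalized over sense codons, does not
reproduce the observed frequencies, so `cf3x4()` solves for corrected
positional frequencies whose implied sense-codon distribution does. The
solver is a damped multiplicative fixed point (tolerance $10^{-10}$, which
preserves zeros and positivity) with a least-squares fallback; it is
validated by its self-consistency residual. Frequencies are plug-in
estimates, not optimized by likelihood, but are counted (9 per alignment)
toward the parameter totals used by AIC/BIC, mirroring common practice.

### Scaling convention

After assembly the generator is divided by (expected substitutions per
codon at stationarity)/3, so branch lengths are measured in expected
substitutions per *nucleotide* site. The choice is isolated in
`codon_rate_matrix(scale = TRUE)`; it matters only for how branch lengths
read, not for likelihood ratios.

## Inference

`phylo_likelihood()` is standard Felsenstein pruning with independent
sites, full marginalization of missing codons, and the stationary
distribution at the root (root placement is immaterial for a reversible
process). The kernel exploits reversibility: the generator is symmetrized
with $\sqrt{\pi}$, diagonalized once per likelihood evaluation, and edge
transitions are applied in the eigenbasis; it is implemented in compiled
code because the genetic-algorithm search below evaluates hundreds of
thousands of likelihoods.

`fit_gene()` maximizes the likelihood by direct optimization, alternating
two blocks until the log-likelihood improves by less than `outer_tol`
(default $10^{-6}$):

1. a bounded quasi-Newton pass (`nlminb` on log-transformed parameters,
   rates bounded in $[10^{-8}, 100]$) over $\theta$, $\beta$ and the
   family's free $\alpha$;
2. a per-branch sweep in which each branch length is optimized by Brent
   search against a profile of the likelihood in the eigenbasis (for a
   single edge the site likelihood is a weighted sum of exponentials in
   $t$, so each candidate $t$ costs $O(nP)$ rather than a full pruning
   pass).

Rich families are warm-started through the nested hierarchy
(standard → synrev → synrevcodon), which both speeds convergence and
guarantees the fitted log-likelihoods respect the nesting order; the
synonymous-rate block optionally uses random multi-starts (default 3 for
the $\alpha$-rich families).

`fit_joint()` implements the two-phase multi-gene fit: phase 1 fits MG94
to each gene; phase 2 maximizes the summed likelihood over one shared
$\alpha$ vector plus a single multiplicative branch-length scaler per
gene, holding all other per-gene parameters frozen.

## The CHC genetic algorithm

`chc_search()` learns a partition of the 67 rates into at most $M$
classes by minimizing BIC over a collection of training alignments, with
sample size defined as total characters (sequences × sites, sites counted
as codon columns; a switch allows nucleotide counting since the convention
is ambiguous). Partitions are encoded as class-sorted integer vectors
(`canonicalize_model()`). The search is the CHC scheme: random unique
initialization, free recombination with elitist truncation, cataclysmic
mutagenesis when the population becomes uniform or stagnant, termination
after `g_conv` generations without a BIC improvement above `delta_bic`.
Defaults follow the standard settings (P = 32, f_rel = 1e-6,
f_stagnant = 25, mu = 0.20, delta_bic = 0.01, g_conv = 100).

Design choices where the procedure was genuinely open:

* **Fitness** refits only the shared class rates (class 0 pinned to 1)
  with each gene's branch lengths, exchangeabilities, frequencies and
  $\omega$ frozen at their baseline MG94 estimates; candidate generators
  are renormalized so the frozen branch lengths keep their units. $\omega$
  can be refit per candidate (`refit_beta`), but the default keeps it
  frozen: it is nearly orthogonal to the synonymous partition and
  refitting multiplies the cost of every fitness evaluation by the number
  of genes.
* **The incumbent null.** The single-class (baseline) model is seeded into
  the initial population (`include_null = TRUE`). The search can then
  return the null model when no partition improves on it, which is the
  behavior a null-data experiment must be able to report. This matters in
  practice: on well-specified null data an unbounded search will
  eventually assemble "partitions of convenience" from sampling noise
  whose BIC gain is essentially independent of sample size (the best
  adaptively chosen subset of 67 standard-normal deviations is worth
  roughly 10–13 log-likelihood units), while the BIC penalty grows only
  logarithmically. A bounded search budget with the null as incumbent
  reports the null unless a signal is found quickly.
* **Refinement.** `refine_best = TRUE` polishes the final model by greedy
  single-rate reassignment (moves screened at the incumbent's fitted
  rates, accepted moves refit fully and recorded in the trace). At small
  generation budgets the raw CHC search routinely stops short of even the
  true partition's BIC; the polish closes that gap deterministically. It
  is off by default so the default algorithm is exactly the five CHC
  steps above.
* Mutagenesis resets the stagnation counter; the no-improvement and
  no-new-models counters are tracked independently. Ties in elitist
  truncation break by lexicographic encoding so runs are reproducible
  under a fixed seed; all randomness flows from `ga_config(seed = )`.

Model averaging (`model_average()`) assigns every evaluated model an
Akaike weight $w(m) \propto \exp((\min_m \mathrm{BIC} - \mathrm{BIC}(m))/2)$,
ranks each model's fitted class rates (smallest → `SELECTED`, largest →
`NEUTRAL`, intermediates `INT k`), accumulates weight per category per
rate, and flags a rate ambiguous when no category reaches 0.90 of the
weight. A single-class model is entirely the reference rate and is labeled
`NEUTRAL`. `truth_contingency()` compares the SELECTED/NEUTRAL calls with
simulated truth via a 2×2 table, the Matthews correlation coefficient
(defined as 0 when a margin is empty) and Fisher's exact test.

## Simulators

`simulate_alignment()` is the parametric route: root codons drawn from the
stationary distribution, branches applied as $e^{Qt}$.

`run_forward_simulation()` is the deliberately *misspecified* route: a
Wright–Fisher population of 2N gene copies with per-base mutation
(uniform across the three alternatives; a bias matrix could be substituted
but none is claimed by default), multiplicative genic selection without
dominance, and lethal stop codons. Synonymous selection is a
`selection_scheme()`: each amino acid's codons are split into one or two
neutral classes; a copy carrying an unfavored codon has fitness factor
$1+s$ at that site, every nonsynonymous codon carries $1+s_\mathrm{non}$
(defaults $2Ns = -10$), so mutations toward the favored class gain $-s$
and reversions lose it. The default scheme is a synthetic stand-in with
the reference shape — exactly 25 cross-class ("selected") and 42
within-class ("neutral") pairs — built so that the favored direction
alternates across amino acids and no third-position nucleotide is
globally favored; this keeps the planted signal separable from positional
base composition, which the CF3x4 frequency model absorbs. The exact partition and split
schedule used in the original experiments are not distributed here; both
are plain config inputs.

The protocol follows the reference design: a first burn-in of
`burn_in_multiplier` × N generations, a second burn-in until all copies
coalesce to a single ancestor (tracked by per-copy ancestry labels, cost
O(2N) per generation), then 10 population splits (a random extant
population duplicates at each scheduled time) and terminal sampling of one
random copy per population, giving an 11-sequence alignment plus the true
population tree and per-pair truth labels.

One scaling subtlety is worth spelling out: the burn-in rule of
200 × N generations equilibrates codon usage at the reference N = 500,
but the equilibration time is governed by $1/(\mu |s|)$ and does not
shrink with N. Desk-scale runs at N = 50 therefore keep the *absolute* reference duration
(100,000 generations, `burn_in_multiplier = 2000`);
with the proportional rule, roughly half of the split-family sites would
still be in their unfavored state at the root and would sweep toward the
favored codon during the tree phase, inverting the apparent rate contrast.

## Covariates

`snp_density()` counts, per codon pair, alignment columns where exactly
the pair's two codons segregate (columns with more than two codons or any
nonsynonymous segregation are excluded, since multi-allelic handling is
not specified by the counting rule), divided by the pair's amino-acid
count on the majority-consensus sequence; per-gene densities are averaged
without length weighting. `pool_trna_abundances()` normalizes raw tRNA
transcript counts to CPM (no gene-length correction; tRNA genes are nearly
equal length), assigns each anticodon to its Watson–Crick cognate codon,
expands inosine-modified wobble-A anticodons to the synonymous A- and
C-ending codons and queuosine-modified wobble-G anticodons (His, Asp, Asn,
Tyr) to the cognate T-ending codons, and resolves the six remaining
decoder-less codons by wobble-rule donors (TTT←TTC, AGT←AGC, TGT←TGC,
CGG←CGA, GGG←GGA, GGT←GGC). All modifiable tRNAs are assumed modified, in
all tissues, with equal binding. `abundance_ratio()` always reports the
more-common pool over the less-common one, so ratios are ≥ 1 and
independent of codon order; `rank_correlation()` is Spearman's rho with
average ranks.

## Numerical choices and degenerate inputs

* Rates may be exactly 0 (observed routinely in per-gene fits); the
  generator remains valid. Fitted rates are bounded below at $10^{-8}$.
* Branch lengths of exactly 0 are honored with an exact identity
  transition (no round-off leakage), so impossible configurations report
  $-\infty$ rather than numerical noise.
* Stationary frequencies are floored at $10^{-12}$ inside the symmetrized
  eigendecomposition; per-pattern partial vectors are rescaled with
  tracked logs to prevent underflow on deep trees.
* Gaps and ambiguity codes map to MISSING and are fully marginalized.
* The CF3x4 multiplicative update cannot create mass where the observed
  frequency is zero; zero entries stay zero.

## What the synthetic generators do and do not emulate

The fixture generator (`generate_fixture_genes()`) draws random gene trees
with exponential branch lengths, Dirichlet-style positional frequencies
and a user spec, i.e. data exactly from the fitted model family — useful
for oracle tests, parameter recovery and null calibration, but silent on
model misspecification. The forward simulator supplies the misspecified
counterpart (irreversible dynamics, linked sites, no recombination,
selection on states rather than rates). Neither emulates alignment error,
gaps, heterotachy, site-to-site rate variation, or context-dependent
mutation, so green tests here say nothing about those failure modes on
real data.

## Desk-scale problem sizes

The test suite and the acceptance script run everything at reduced sizes
chosen once: the selection ladder uses N = 50, 100 codons, splits every
800 generations with sampling at 8,800 (20 replicates per level in the
tests, 12 in the acceptance script), GA desk configuration P = 16,
g_conv = 6, at most 18 generations, with refinement on; null-recovery
batches use 20 MG94 genes of 6 taxa × 80 codons; the omega-bias experiment
uses SynREVCodon genes of 8 taxa × 200 codons with dispersed synonymous
rates (gamma-distributed, shape 0.45, mean 1) and true $\omega = 0.3$;
rate recovery uses one 12-taxon, 5,000-codon SynREV gene. Full-scale
replications of the reference experiments (100 alignments per run, N = 500,
300 codons, 25 null runs) are cluster-scale computations and are not
attempted on a desk machine; the desk designs reproduce their qualitative
structure (monotone classification accuracy in selection strength, null
recovery, the direction of $\omega$ bias), not the printed magnitudes.

## Known limitations

* Synonymous rates are gene-wide: no site-to-site or branch-to-branch
  variation in $\alpha$ or $\omega$, and no codon-pair-dependent
  nonsynonymous rates.
* Tree topologies are taken as given; there is no topology search.
* dN/dS is reported as the fitted $\beta$ relative to the $\alpha$
  constraint; per-site substitution-counting definitions of dS and dN are
  out of scope.
* The GA searches partitions for a fixed class count M; it does not select
  M itself.
* The forward simulator has no recombination, dominance, or demographic
  change, and its fitness landscape is static (defined relative to the
  ancestral amino acids).
```
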