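---
title: "Stability-constrained codon evolution and the dynamics of amino acid propensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-constrained codon evolution and the dynamics of amino acid propensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model, the choices that were
genuinely open, and what the shipped tests do and do not establish. The
worked numbers live in `README.md` and in the `analysis/` drivers; nothing
here asserts an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

A protein of `L` residues evolves as a codon sequence under an
origin–fixation ("jump chain") process. Fitness is thermodynamic: it is the
probability that the translated sequence occupies its native contact
structure at equilibrium,

$$ f(s) = P_\mathrm{fold}(s) = \frac{e^{-\beta \Delta G(s)}}{e^{-\beta \Delta G(s)} + 1}, \qquad \beta = 1/kT . $$

$\Delta G$ is the free-energy gap between the folded state and an unfolded
ensemble. The folded energy is a sum of pairwise contact potentials
$E_F = \sum_{x<y} \varepsilon(a_x, a_y)\,\mathrm{CM}_{xy}$ over the native
contact map (residues within 7 Å of their C$\beta$ atoms, C$\alpha$ for
glycine). The unfolded ensemble is represented by a set of decoy contact
maps; the decoy energies of the current sequence are summarized by their
mean $\bar E$ and population variance $\Delta E^2$, which under a Gaussian
approximation give

$$ \Delta G = E_F - \bar E + \tfrac{\beta}{2}\,\Delta E^2 + \beta^{-1}\ln N_U,
   \qquad N_U = \nu^L . $$

Mutation is HKY85 at the nucleotide level (transition/transversion ratio
$\kappa$, stationary frequencies $\pi_n$); a mutation that creates a stop
codon has rate zero. A proposed single-nucleotide change fixes in a diploid
population with the Kimura probability
$P_\mathrm{fix} = (1-e^{-2\Delta f})/(1-e^{-4N_e\Delta f})$, and the chain
jumps to a neighbor with probability proportional to
$q = 2 N_e\, \mu\, P_\mathrm{fix}$. Time is counted in substitutions,
synonymous ones included.

Site-specific *propensities* are equilibrium expectations with the rest of
the sequence frozen:
$\pi^h_a \propto \pi_a(0)\, e^{c f^h_a}$, where $f^h_a$ is the fitness of
amino acid $a$ at site $h$ in the current background and $\pi_a(0)$ are the
neutral amino acid frequencies implied by the mutation model (sums of the
neutral codon frequencies $\propto \pi_l \pi_m \pi_n$ over each amino
acid's codons). The Shannon entropy $U^h = -\sum_a \pi^h_a \ln \pi^h_a \in
[0, \ln 20]$ measures how permissive the site currently is.

### The propensity exponent

Two conventions for $c$ coexist. The reported propensities use $c = 2N_e$,
the form in which such propensities are usually written. The diploid
fixation probability above, however, implies a stationary law over
sequences proportional to $m(s)\,e^{(4N_e-2) f(s)}$ — the package verifies
this *exactly* (detailed balance to numerical precision on an enumerable
two-site system, and on the full system's transition pairs). Both
conventions are exposed (`exponent = "reported"` or `"detailed_balance"` in
`evol_context()`); the reversibility and single-site-stationarity oracle
tests use the consistent `detailed_balance` option, all reported
propensities use `reported`. The distinction is a factor $\approx 2$ in the
exponent and does not change any qualitative behavior.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `kT` | 0.6 | thermal energy; $\beta = 1/kT$ |
| `nu` | 3.4 | unfolded configurations per residue ($N_U = \nu^L$) |
| `Ne` | 100 | effective population size |
| `cutoff` | 7 Å | contact distance between residue reference points |
| `min_sep` | 2 | minimum sequence separation for a contact |
| `n_decoys` | 55 | decoy maps for the unfolded-state moments |
| `n_substitutions` | 500 | recorded jump-chain length per replicate |
| `n_replicates` | 25 | independent replicates pooled by the study |
| `min_residency` | 10 | shortest residency window analyzed (substitutions) |
| `target_R` | 0.95 | lag-1 autocorrelation of the autocorrelated null |

`kT`, `nu`, `Ne`, the 500-substitution chains and the three mutation
parameter sets (`study_fixtures()`) are the study conditions. The reported
1pek frequency quadruple sums to 1.31; it is preserved verbatim and a
normalized copy drives the simulations. Backbone neighbors are excluded
from contacts (`min_sep = 2`) because $i,i\pm1$ contacts are nearly
sequence-independent; this is a convention, not a fitted value.

## The synthetic structure generator

`synthetic_structure()` grows a compact self-avoiding chain (unit bonds,
hard core, centripetal bias inside a globule whose volume scales with `L`)
and rescales it so the 7 Å contact map hits a target density — about 7
contacts per site for the default study protein (`L = 60`), spanning the
6.9–8.4 range of the study proteins when asked. After rescaling, bond
lengths land near 3.5–4 Å, the C$\beta$ spacing of real chains.

What it emulates: realistic contact density, chain connectivity, a compact
fold shape. What it does not emulate: secondary-structure topology,
modular domains, or the degree distribution of real folds. Tests passing
on synthetic structures therefore establish the *model's* behavior at
matched density, not structure-specific predictions for any particular
protein.

Decoys for the unfolded ensemble are random rewirings of the native map
with the native number of contacts, pairs resampled uniformly among
`min_sep`-eligible pairs. A degree-preserving variant (double-edge swaps;
`preserve_degree = TRUE`) is available: it keeps hub sites hubs in every
decoy, which narrows the native-versus-decoy energy gap and tightens the
equilibrium $\Delta G$ distribution, but it also weakens the
mean-reversion of propensity fluctuations; the uniform scheme is the one
under which the equilibrium metric percentages and the change
autocorrelation land inside the reference bands the acceptance suite
asserts, and is the default.

The packaged potential table (`default_potentials()`) is *synthetic*: a
deterministic hydrophobicity-derived surface
$\varepsilon(a,b) = -(0.5 + 3 h_a h_b + 0.8(h_a + h_b))$ on the scale of
knowledge-based contact potentials, shipped as
`inst/extdata/contact_potentials_synthetic.tsv`. Any symmetric 20×20 table
can be substituted; every correctness test uses seeded *random* symmetric
tables so that no result depends on the shipped constants.

## Equilibration

Replicates start from a random stop-free codon sequence drawn from the
neutral codon frequencies, then equilibrate in two phases:

1. **Ascent.** Steepest descent in $\Delta G$ over nonsynonymous neighbors
   until fitness $\ge 0.99$; if the greedy walk stalls in a local optimum
   just below the threshold, the stochastic jump chain takes over.
2. **Burn-in.** The full substitution process for 200 substitutions
   (configurable), extended in 100-step blocks until the $\Delta G$ trace
   plateaus.

The plateau test needed care. At mutation–selection equilibrium $\Delta G$
is a mean-reverting walk: the raw least-squares slope over a 100-step
window does *not* shrink toward zero, so a fixed slope threshold of 0.01
energy units per substitution rejects genuine equilibrium most of the
time. The test therefore asks that the mean per-step drift be
statistically indistinguishable from zero — below
$\max(0.01,\ 2\,\mathrm{SE})$ where SE is the standard error of the mean
step increment over the window — with 0.01 kept as the hard floor.

### How equilibrated is "equilibrated"? (a known limitation)

The implemented chain is provably reversible: detailed balance holds to
$10^{-15}$ on the enumerable two-site system and to $10^{-12}$ on sampled
transition pairs of the full system, and a long jump chain on the solvable
system accepts stabilizing and destabilizing substitutions in exactly
equal proportion (binomial $p = 0.98$ over 14,000 steps). At true
stationarity that 50/50 balance is a theorem for any reversible chain.

On the full synthetic protein, however, the pooled stabilizing fraction
sits near 0.46–0.48 and stays there no matter how the chain is prepared —
longer burn-ins (flat out to 60,000 substitutions), annealed burn-ins, or
deliberately under-equilibrated starts all give the same sign. The
sequence space of the stability model is glassy: the chain keeps sliding
into locally optimized basins and leaks out of them slowly, so on any
feasible timescale it ages rather than reaching the stationary measure,
and a small count excess of destabilizing substitutions (balanced in
magnitude — $\Delta G$ itself does not drift) persists. The package
reports this honestly: the equilibrium 50/50 property is asserted where
equilibrium is actually attainable (the solvable system), while the
desk-scale study check reports the biased fraction it genuinely measures.
The theoretical expectation of equal proportions is an equilibrium statement
that finite simulations of this model class approach only asymptotically.

## Residency windows and shift metrics

A residency window is one amino acid's tenure at a site: accepted at
substitution $i$, replaced at substitution $j$, propensity series over
states $i..j-1$, $T_\mathrm{res} = j - i$ counted in substitutions
anywhere in the protein. The study analyzes complete windows (accepted
*and* replaced inside the recorded trajectory) with
$T_\mathrm{res} \ge 10$; truncated windows can be included with a flag.

* `m_slr` — least-squares slope of propensity against substitution index;
* `m_ami` — mean propensity during residency minus the value at
  acceptance (the acceptance step is included in the mean);
* `half_window_rate` — $(|M2| - |M1|)/T_\mathrm{res}$ with the chosen
  metric on each half (odd lengths give the extra point to the first
  half);
* windows with a metric exactly zero are counted as non-negative and also
  reported separately, so percentage tables are unambiguous.

`m_slr` of a reversed series is the negated slope, and `m_ami` of a
reversed series equals mean-minus-final of the original; both identities
are tested. On series drawn independently from any *symmetric*
distribution both metrics classify half the windows negative; a
right-skewed marginal biases `m_ami` below 50% while leaving `m_slr`
balanced — the mechanism behind the difference between the two columns of
the shift table, demonstrated directly by
`symmetric_distribution_check()`.

### Autocorrelation conventions

Two reported quantities required fixing a convention the source
formulation leaves open, and both are implemented in
`trajectory_autocorrelations()` / `pooled_window_autocorrelation()`:

* **Persistence of propensity levels** — the pooled lag-1 Pearson
  autocorrelation of resident-propensity series *within* residency
  windows. This is precisely the quantity the autocorrelated null model
  is calibrated to reproduce, so it is the one reported.
* **Anticorrelation of propensity changes** — computed from first
  differences *within tenure segments* (a resident's series is undefined
  across its own replacement) on the **nonsynonymous clock**: a synonymous
  substitution changes no landscape anywhere, so on the full substitution
  clock nearly half of all differences are exact zeros and the statistic
  measures codon usage rather than landscape dynamics. Restricted to the
  steps that actually perturb the protein, increases in a resident's
  propensity tend to be followed by decreases and vice versa.

## Null models

`randomized_null()` draws window sizes from the empirical residency-time
distribution and fills each series with independent draws from the
empirical propensity distribution. `autocorrelated_null()` replaces the
independent draws with a Gaussian-copula AR(1): a latent AR(1) series is
mapped through the empirical quantile function, which preserves the
marginal *exactly*, while the latent coefficient is calibrated by
bisection on a long pre-run so the realized lag-1 autocorrelation hits the
target (0.95 by default, the study's calibration constant; the run's own
empirical value can be substituted). Marginal preservation is verified by
two-sample Kolmogorov–Smirnov tests; `target_R = 0` degenerates to the
randomized model.

## Numerical choices

* Fitness is evaluated as `plogis(-beta * dG)` and the partition function
  only ever in log space; propensity weights subtract the row maximum
  before exponentiation, so $c\,f$ up to several hundred cannot overflow.
* $0 \ln 0 := 0$ in entropies; a substitution with average entropy change
  exactly zero is classified `neutral`.
* $\Delta E^2$ is the population (divide-by-$n$) variance, matching a
  Gaussian fit by moments.
* Per-state site landscapes are computed by sparse matrix products
  ($P^\top$CM and $P^\top W$ with $W$ the column-bound decoy adjacencies),
  and the per-substitution state update touches only terms involving the
  mutated site — the incremental-vs-full-recompute agreement is enforced
  at $10^{-8}$ by fuzz tests. Cached energies are rebuilt from scratch
  every 500 steps to bound float drift.
* Degenerate inputs: all-equal rate vectors are a legitimate draw;
  all-zero rates raise an "absorbing state" error; zero-variance series
  give `NA` autocorrelations (detected with a relative tolerance so that
  arithmetically-constant float series count as constant); Spearman
  profiles of constant columns are `NA`, never 0.

## Problem sizes

The shipped study runs 25 replicates × 500 substitutions on the L = 60
synthetic protein with 55 decoys (about 5,000 pooled windows), 10,000
null-model windows, and a single-replicate profile for the
entropy/stability correlations; the test suite uses an L = 30 context with
20 decoys for module-level checks and the enumerable two-site system for
the exactness oracles. These sizes were chosen as the smallest at which
the pooled percentages stabilize to within a point; the reference values
these checks compare against come from pools of 500 replicates per natural
protein (L = 107–300), so second-decimal agreement is not expected, and
one quantity — the
per-substitution Spearman correlation between $\Delta\Delta G$ and the
average entropy change, ≈ −0.97 here versus the −0.99 reference — falls
measurably short at L = 60 (the residual scatter comes from the local
contact rearrangement at the substituted site, which averages out more
slowly in a small protein; the value was unchanged at L = 150 and at
density 8.4).

## What the tests do and do not show

The suite establishes: exactness of the energetics and its incremental
updates against brute-force oracles; exact reversibility of the
substitution process under the consistent exponent; the closed-form
behavior of propensities, entropies, fixation probabilities and metrics;
marginal- and autocorrelation-contracts of the null models; and
reproduction of the study's headline percentages at desk scale on
synthetic structures. It does not validate predictions for any real
protein structure (no PDB input is bundled), does not probe
population-genetic regimes beyond origin–fixation (no polymorphism,
no indels), and — as detailed above — cannot certify full stationarity of
the jump chain on the large system, only its reversibility and the
stability of its measured summaries.
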