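# stabevol

Do amino acid preferences at protein sites drift up, drift down, or stay
put after a substitution — and can downward drift be read as evidence of
adaptation? `stabevol` addresses that question the nonadaptive way: it
simulates protein-coding sequences under a thermodynamic
mutation–selection model in which the *only* constraint is folding
stability, and quantifies how site-specific amino acid propensities shift
while the global fitness landscape never changes. It is aimed at molecular
evolution researchers who need a stability-constrained null model against
which claims of adaptive preference shifts (propensity "senescence",
entrenchment, evolutionary Stokes shifts) can be calibrated.

## The model

Fitness equals the probability of folding,

```
f(s) = exp(-β ΔG(s)) / (exp(-β ΔG(s)) + 1),     β = 1/kT,  kT = 0.6,
```

with the folding free energy computed from pairwise contact potentials on
a 7 Å Cβ contact map against a Gaussian unfolded-state ensemble estimated
from rewired decoy maps:

```
ΔG = E_F − Ē + (β/2) ΔE² + (1/β) ln N_U,        N_U = 3.4^L .
```

Sequences evolve codon-by-codon as an origin–fixation jump chain: HKY85
mutation (κ, π_A..π_T), diploid Kimura fixation probabilities, rates
q = 2·Ne·μ·P_fix, stop codons forbidden. At every substitution the package
records, for every site, the full 20-amino-acid fitness landscape
f^h(s), the propensity landscape

```
π_a^h ∝ π_a(0) · exp(2 Ne f_a^h),
```

its Shannon entropy U^h ∈ [0, ln 20], and the resident amino acid's
propensity. Residency windows (one amino acid's tenure at one site,
T_res ≥ 10 substitutions) are scored with two shift metrics — the
regression slope **M_SLR** and mean-minus-initial **M_AMI** — and compared
against randomized and autocorrelated null models whose windows carry the
same empirical propensity marginal but no epistatic structure.

## Worked example

Simulate the default study protein — a synthetic compact chain of 60
residues at ~7 contacts per site — for 500 substitutions at Ne = 100 and
score its residency windows:

```r
library(stabevol)

syn    <- synthetic_structure(L = 60, target_density = 7, rng_seed = 1)
decoys <- generate_decoys(syn$map, n_decoys = 55, rng_seed = 2)
ctx    <- evol_context(syn$map, decoys, default_potentials(),
                       study_fixtures()[["1qhw"]]$mutation, Ne = 100)

set.seed(10)
start <- equilibrate(ctx)           # random sequence -> fitness >= 0.99
start
#> evol_state: L = 60, dG = -5.6882, fitness = 0.999924

traj <- simulate_trajectory(ctx, start, n_substitutions = 500)
traj
#> trajectory: 500 substitutions, L = 60 , dG -5.69 -> -8.65

windows <- extract_windows(traj, min_residency = 10)
summarize_shifts(windows)
#>   n_windows pct_neg_slr pct_neg_ami pct_zero_slr pct_zero_ami median_slr
#> 1       213        53.1        44.1            0            0  -2.01e-05
#>   median_ami median_T_res
#> 1    0.00326           57

prof <- stability_uniformity_profile(traj)
sprintf("Spearman(dG, avg U) = %.3f; Spearman(ddG, avg dU) = %.3f",
        prof$spearman_dG_avgU, prof$spearman_ddG_avg_dU)
#> "Spearman(dG, avg U) = -0.986; Spearman(ddG, avg dU) = -0.968"
```

Reading the numbers: even though nothing about the environment changed,
about half of all residencies show a *negative* propensity trend under the
slope metric (53.1% in this single replicate; 50 ± 1 when 25 replicates
are pooled), so a falling resident propensity is not by itself evidence of
adaptation. The mean-minus-initial metric reports fewer negatives (44.1%)
— a statistical artifact of the right-skewed propensity distribution that
the randomized null model reproduces without any epistasis. The strong
negative rank correlations say that stabler sequences sit on flatter
(higher-entropy) site landscapes and that stabilizing substitutions
flatten them further — which is exactly why they *decrease* resident
propensities at most sites.

The full study is organised as numbered drivers:

```sh
Rscript analysis/01_simulate.R          # 25 replicates, pooled windows -> results/study/
Rscript analysis/02_windows_metrics.R   # shift-metric table            -> results/table_stability.tsv
Rscript analysis/03_null_models.R       # randomized + autocorrelated   -> results/table_full.tsv
Rscript analysis/04_entropy_stability.R # mechanism: ΔG, entropy, Δπ    -> results/entropy_stability.tsv
```

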