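#!/usr/bin/env Rscript

## Stage 3: null models calibrating the shift metrics.
##
## Rebuilds the empirical propensity and residency-time distributions from
## stage 1's outputs, generates 10,000 windows under (a) the randomized
## model (independent draws) and (b) the autocorrelated model
## (Gaussian-copula AR(1) at lag-1 R = 0.95), and writes a combined
## stability + null summary table. The randomized model shows that the
## mean-minus-initial metric's negative fraction drops well below 50% on a
## right-skewed marginal even with no temporal structure at all.

suppressPackageStartupMessages(library(stabevol))

win <- utils::read.table("results/study/windows.tsv", header = TRUE,
                         sep = "\t")
ser <- utils::read.table("results/study/window_series.tsv", header = TRUE,
                         sep = "\t")
dists <- empirical_distributions(values = ser$propensity,
                                 sizes = win$T_res)

rand <- randomized_null(dists, n_windows = 10000, rng_seed = 301)
auto <- autocorrelated_null(dists, n_windows = 10000, target_R = 0.95,
                            rng_seed = 302)

message(sprintf("randomized:     %.1f%% negative M_SLR, %.1f%% negative M_AMI",
                rand$summary$pct_neg_slr, rand$summary$pct_neg_ami))
message(sprintf("autocorrelated: %.1f%% negative M_SLR, %.1f%% negative M_AMI (realized lag-1 R = %.3f)",
                auto$summary$pct_neg_slr, auto$summary$pct_neg_ami,
                auto$lag1_realized))

## symmetric sources remove the M_AMI bias entirely
for (d in c("uniform", "truncated_normal")) {
  s <- symmetric_distribution_check(d, dists, n_windows = 10000,
                                    rng_seed = 303)$summary
  message(sprintf("%s source: %.1f%% / %.1f%% negative (M_SLR / M_AMI)",
                  d, s$pct_neg_slr, s$pct_neg_ami))
}

stab <- utils::read.table("results/table_stability.tsv", header = TRUE,
                          sep = "\t")
tab <- rbind(stab,
             cbind(model = "randomized", rand$summary),
             cbind(model = "autocorrelated", auto$summary))
utils::write.table(tab, "results/table_full.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("wrote results/table_full.tsv")
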