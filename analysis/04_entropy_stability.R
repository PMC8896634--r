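#!/usr/bin/env Rscript

## Stage 4: why propensities shift -- stability and landscape uniformity.
##
## Reads the per-state and per-substitution profile tables of replicate 1
## from stage 1 and quantifies the mechanism: more stable sequences sit on
## flatter (higher-entropy) site landscapes, stabilizing substitutions
## flatten landscapes (permissive) and thereby *reduce* resident amino
## acid propensities at most sites, destabilizing ones do the opposite.

suppressPackageStartupMessages(library(stabevol))

states <- utils::read.table("results/study/profile_states.tsv",
                            header = TRUE, sep = "\t")
subs <- utils::read.table("results/study/profile_substitutions.tsv",
                          header = TRUE, sep = "\t")
ns <- subs[!subs$synonymous, ]

r1 <- stats::cor(states$dG, states$avg_U, method = "spearman")
r2 <- stats::cor(ns$ddG, ns$avg_dU, method = "spearman")
message(sprintf("Spearman(dG, avg U) = %.3f over %d states", r1,
                nrow(states)))
message(sprintf("Spearman(ddG, avg dU) = %.3f over %d nonsynonymous substitutions",
                r2, nrow(ns)))

stab <- ns$frac_sites_neg_dprop[ns$ddG < 0]
dest <- ns$frac_sites_neg_dprop[ns$ddG > 0]
wt <- stats::wilcox.test(stab, dest, alternative = "greater")
message(sprintf(
  "sites with decreased resident propensity: %.0f%% after stabilizing vs %.0f%% after destabilizing substitutions (one-sided rank test p = %.2e)",
  100 * mean(stab), 100 * mean(dest), wt$p.value))

cls <- table(factor(ns$classification,
                    levels = c("permissive", "restrictive", "neutral")))
message("permissive / restrictive split: ",
        paste(names(cls), cls, collapse = ", "))

out <- data.frame(
  quantity = c("spearman_dG_avgU", "spearman_ddG_avg_dU",
               "mean_frac_neg_dprop_stabilizing",
               "mean_frac_neg_dprop_destabilizing",
               "rank_test_p"),
  value = c(r1, r2, mean(stab), mean(dest), wt$p.value))
utils::write.table(out, "results/entropy_stability.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("wrote results/entropy_stability.tsv")
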