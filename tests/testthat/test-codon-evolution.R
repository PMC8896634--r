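test_that("neutral codon frequencies match brute-force enumeration", {
  unif <- mutation_params(1, rep(0.25, 4))
  f <- neutral_codon_frequencies(unif)
  expect_length(f, 61)
  expect_equal(sum(f), 1)
  expect_true(all(abs(f - 1 / 61) < 1e-12))

  mut <- study_fixtures()[["1qhw"]]$mutation
  f <- neutral_codon_frequencies(mut)
  ## brute force: product over all 64 codons, drop stops, normalize
  nucs <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(nucs, nucs, paste0), nucs, paste0))
  stops <- c("TAA", "TAG", "TGA")
  p <- vapply(all_codons, function(cd) {
    prod(mut$pi_nuc[strsplit(cd, "")[[1]]])
  }, numeric(1))
  p <- p[!names(p) %in% stops]
  p <- p / sum(p)
  expect_equal(f[names(p)], p)
})

test_that("neutral amino acid frequencies sum synonymous codons", {
  unif <- mutation_params(1, rep(0.25, 4))
  fa <- neutral_aa_frequencies(neutral_codon_frequencies(unif))
  expect_equal(sum(fa), 1)
  expect_equal(unname(fa["L"]), 6 / 61)   # leucine has six codons
  expect_equal(unname(fa["M"]), 1 / 61)
  ## uniform alternative definition
  fu <- neutral_aa_frequencies(uniform = TRUE)
  expect_true(all(fu == 1 / 20))
})

test_that("mutation_rate implements single-nucleotide HKY with stop exclusion", {
  mut <- mutation_params(4.37, c(0.21, 0.32, 0.27, 0.20))
  expect_equal(mutation_rate("AAA", "AAG", mut), 4.37 * 0.27)  # transition
  expect_equal(mutation_rate("AAA", "AAC", mut), 0.32)         # transversion
  expect_equal(mutation_rate("AAA", "ACG", mut), 0)            # two changes
  expect_equal(mutation_rate("AAA", "AAA", mut), 0)            # no change
  expect_equal(mutation_rate("TAC", "TAA", mut), 0)            # into stop
})

test_that("fixation probability has the neutral limit and Kimura values", {
  expect_equal(fixation_probability(0.5, 0.5, Ne = 100), 1 / 200)
  ## direct evaluation of the diploid formula
  f_direct <- function(df, Ne) (1 - exp(-2 * df)) / (1 - exp(-4 * Ne * df))
  expect_equal(fixation_probability(0.5, 0.51, 100), f_direct(0.01, 100))
  expect_equal(fixation_probability(0.5, 0.51, 100), 0.020171, tolerance = 1e-4)
  expect_equal(fixation_probability(0.5, 0.49, 100), f_direct(-0.01, 100))
  expect_equal(fixation_probability(0.5, 0.49, 100), 3.7690e-4, tolerance = 1e-3)
  ## continuity at df -> 0 and monotonicity in df
  dfs <- seq(-0.05, 0.05, length.out = 2001)
  p <- fixation_probability(0.5, 0.5 + dfs, 100)
  expect_true(all(diff(p) > 0))
  expect_lt(max(abs(p[abs(dfs) < 1e-9] - 1 / 200)), 1e-9)
})

test_that("neighbor rates match a from-scratch recomputation oracle", {
  ctx <- small_ctx()
  ## an equilibrated state, where fitness differences among neighbors are
  ## meaningful and the incremental path is genuinely exercised
  st <- withr::with_seed(31, equilibrate(ctx, burn_in = 60))
  nb <- neighbor_rates(ctx, st)
  tabs <- stabevol:::codon_tables()
  aa_seq <- state_aa(ctx, st)
  f_cur <- fitness_from_dG(
    delta_G(aa_seq, ctx$native, ctx$decoys, ctx$pot, ctx$params)$delta_G,
    ctx$params)
  codons <- state_codons(ctx, st)
  for (h in sample(ctx$L, 4)) {
    for (k in 1:9) {
      tgt <- tabs$nbr_codon[tabs$codon_index[codons[h]], k]
      if (is.na(tgt)) {
        expect_equal(nb$rates[h, k], 0)
        next
      }
      mu <- mutation_rate(codons[h], tabs$codons[tgt], ctx$mut)
      new_aa <- aa_alphabet()[tabs$codon_aa[tgt]]
      if (new_aa == aa_seq[h]) {
        expect_equal(nb$rates[h, k], mu, tolerance = 1e-10)
      } else {
        mut_seq <- aa_seq
        mut_seq[h] <- new_aa
        f_t <- fitness_from_dG(
          delta_G(mut_seq, ctx$native, ctx$decoys, ctx$pot,
                  ctx$params)$delta_G, ctx$params)
        q <- 2 * ctx$Ne * mu * fixation_probability(f_cur, f_t, ctx$Ne)
        expect_equal(nb$rates[h, k], q, tolerance = 1e-8)
      }
    }
  }
})

test_that("sample_substitution is a categorical draw over rates", {
  expect_error(sample_substitution(c(0, 0, 0)), "absorbing")
  ## a single positive rate is always chosen
  expect_equal(withr::with_seed(1, sample_substitution(c(0, 0, 3, 0))), 3)
  ## empirical frequencies match probabilities within binomial error
  r <- c(1, 3, 6)
  draws <- withr::with_seed(2, {
    vapply(1:20000, function(i) sample_substitution(r), integer(1))
  })
  emp <- tabulate(draws, 3) / 20000
  expect_true(all(abs(emp - r / sum(r)) < 4 * sqrt(0.25 / 20000) + 0.01))
})

test_that("equilibrate reaches the fitness target deterministically", {
  ctx <- small_ctx()
  st1 <- withr::with_seed(5, equilibrate(ctx, burn_in = 100))
  st2 <- withr::with_seed(5, equilibrate(ctx, burn_in = 100))
  expect_gte(st1$fitness, 0.99)
  expect_identical(st1$codons, st2$codons)
  eq <- attr(st1, "equilibration")
  expect_true(is.finite(eq$dG_slope))
  expect_gte(eq$burn_in, 100)
})

test_that("trajectories are single-nucleotide chains with consistent ddG", {
  traj <- small_trajectory()
  ctx <- small_ctx()
  expect_equal(nrow(traj$steps), traj$n)
  ## consecutive resident aa sequences differ at <= 1 site, and the step
  ## table's ddG telescopes the dG series
  expect_equal(traj$steps$ddG, diff(traj$dG), tolerance = 1e-9)
  aa_diffs <- rowSums(traj$resident_aa[-1, ] !=
                        traj$resident_aa[-(traj$n + 1), ])
  expect_true(all(aa_diffs <= 1))
  expect_true(all(aa_diffs[traj$steps$synonymous] == 0))
  ## recorded dG matches a from-scratch recomputation at the endpoint
  final_aa <- aa_alphabet()[traj$resident_aa[traj$n + 1, ]]
  expect_equal(
    delta_G(final_aa, ctx$native, ctx$decoys, ctx$pot, ctx$params)$delta_G,
    traj$dG[traj$n + 1], tolerance = 1e-8)
})

test_that("synonymous substitutions change no thermodynamic or landscape quantity", {
  traj <- small_trajectory()
  syn_steps <- which(traj$steps$synonymous)
  expect_gt(length(syn_steps), 0)
  for (x in syn_steps) {
    expect_equal(traj$steps$ddG[x], 0)
    expect_equal(traj$resident_prop[x + 1, ], traj$resident_prop[x, ])
    expect_equal(traj$entropy[x + 1, ], traj$entropy[x, ])
  }
})

test_that("zero-length simulations record only the initial state", {
  ctx <- small_ctx()
  st <- withr::with_seed(6, random_start_state(ctx))
  traj <- simulate_trajectory(ctx, st, n_substitutions = 0)
  expect_equal(traj$n, 0)
  expect_equal(nrow(traj$steps), 0)
  expect_equal(nrow(traj$resident_prop), 1)
})

test_that("the jump chain on the solvable two-site system balances stabilizing and destabilizing steps", {
  ## at true equilibrium the reversible chain must accept stabilizing and
  ## destabilizing substitutions equally often
  ctx <- two_site_ctx(Ne = 100, exponent = "reported")
  traj <- withr::with_seed(9, {
    st <- make_state(ctx, c(5L, 9L))
    simulate_trajectory(ctx, st, 6000, record_replacement_rate = FALSE)
  })
  ns <- traj$steps[!traj$steps$synonymous, ]
  expect_gt(nrow(ns), 2000)
  bt <- stats::binom.test(sum(ns$ddG < 0), nrow(ns))
  expect_gt(bt$p.value, 0.01)
})
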