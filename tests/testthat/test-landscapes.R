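test_that("site fitness landscapes match full recomputation and the identity case", {
  ctx <- small_ctx()
  st <- withr::with_seed(51, equilibrate(ctx, burn_in = 60))
  aa_seq <- state_aa(ctx, st)
  fmat <- site_fitness_landscape(ctx, st)
  ## resident entry equals the sequence's own fitness at every site
  expect_equal(unname(fmat[cbind(seq_len(ctx$L), st$aa)]),
               rep(st$fitness, ctx$L), tolerance = 1e-9)
  ## full-recompute oracle at a few random (site, aa) pairs
  withr::with_seed(52, {
    for (trial in 1:12) {
      h <- sample(ctx$L, 1)
      b <- sample(aa_alphabet(), 1)
      mut <- aa_seq
      mut[h] <- b
      full <- delta_G(mut, ctx$native, ctx$decoys, ctx$pot, ctx$params)
      expect_equal(unname(fmat[h, b]), full$fitness, tolerance = 1e-8)
    }
  })
})

test_that("an energetically isolated site has a flat fitness landscape", {
  ## native and all decoys leave site 3 contact-free
  nat <- contact_map(4, rbind(c(1, 2), c(2, 4)), min_sep = 1)
  dec <- structure(list(n_decoys = 2L,
                        maps = list(contact_map(4, rbind(c(1, 4)), min_sep = 1),
                                    contact_map(4, rbind(c(1, 2)), min_sep = 1)),
                        L = 4L), class = "decoy_set")
  ctx <- evol_context(nat, dec, random_potentials(3),
                      study_fixtures()[["1qhw"]]$mutation, Ne = 100)
  st <- make_state(ctx, c("ATG", "CCA", "GGC", "TGG"))
  f3 <- site_fitness_landscape(ctx, st, site = 3)
  expect_equal(max(f3) - min(f3), 0)
  p3 <- site_propensity_landscape(ctx, st, site = 3)
  expect_equal(unname(p3), unname(ctx$pi0))
})

test_that("site_propensities follows the exponential-tilting closed form", {
  pi0 <- rep(1 / 20, 20)
  ## equal fitness -> propensities equal pi0
  expect_equal(unname(site_propensities(rep(0.7, 20), pi0, 100)), pi0)
  ## two-state ratio: exp(2 Ne df) under the reported convention
  f <- c(0.71, rep(0.7, 19))
  p <- site_propensities(f, pi0, Ne = 100)
  expect_equal(p[[1]] / p[[2]], exp(2 * 100 * 0.01), tolerance = 1e-9)
  ## detailed-balance convention uses 4 Ne - 2
  p2 <- site_propensities(f, pi0, Ne = 100, exponent = "detailed_balance")
  expect_equal(p2[[1]] / p2[[2]], exp(398 * 0.01), tolerance = 1e-9)
  ## normalization with a non-uniform pi0
  pi0b <- (1:20) / sum(1:20)
  expect_equal(sum(site_propensities(stats::runif(20), pi0b, 50)), 1)
})

test_that("landscape_entropy has the exact bounds and closed-form cases", {
  expect_equal(landscape_entropy(rep(1 / 20, 20)), log(20))
  expect_equal(landscape_entropy(c(1, rep(0, 19))), 0)
  expect_equal(landscape_entropy(c(0.5, 0.5, rep(0, 18))), log(2))
  expect_error(landscape_entropy(rep(0.1, 20)), "sum to 1")
})

test_that("propensities are normalized and entropies bounded at every recorded state", {
  traj <- small_trajectory()
  ctx <- small_ctx()
  expect_true(all(traj$resident_prop >= 0 & traj$resident_prop <= 1))
  expect_true(all(traj$entropy >= 0 & traj$entropy <= log(20) + 1e-9))
  ## full landscape normalization at the final state
  st <- traj$final_state
  pmat <- site_propensity_landscape(ctx, st)
  expect_equal(unname(rowSums(pmat)), rep(1, ctx$L), tolerance = 1e-9)
  expect_true(all(pmat >= 0))
})

test_that("substitution_effect matches independent before/after landscapes", {
  ctx <- small_ctx()
  st <- withr::with_seed(53, equilibrate(ctx, burn_in = 60))
  nb <- neighbor_rates(ctx, st)
  ## pick one synonymous and one nonsynonymous neighbor
  syn_idx <- which(nb$synonymous & nb$rates > 0)[1]
  ns_idx <- which(!nb$synonymous & !is.na(nb$neighbor_codon) &
                    nb$rates > 0)[1]
  for (pick in c(syn_idx, ns_idx)) {
    st2 <- stabevol:::.apply_substitution(ctx, st, nb$landscape, pick)
    eff <- substitution_effect(ctx, st, st2)
    pm1 <- site_propensity_landscape(ctx, st)
    pm2 <- site_propensity_landscape(ctx, st2)
    d_prop <- pm2[cbind(seq_len(ctx$L), st2$aa)] -
      pm1[cbind(seq_len(ctx$L), st$aa)]
    expect_equal(eff$d_prop, unname(d_prop), tolerance = 1e-9)
    dU <- apply(pm2, 1, landscape_entropy) - apply(pm1, 1, landscape_entropy)
    expect_equal(eff$d_entropy, unname(dU), tolerance = 1e-8)
    if (eff$synonymous) {
      expect_equal(eff$ddG, 0)
      expect_true(all(eff$d_prop == 0))
      expect_identical(eff$classification, "neutral")
    } else {
      expect_identical(eff$classification,
                       if (eff$avg_dU > 0) "permissive" else "restrictive")
    }
  }
  ## states differing at more than one nucleotide are rejected
  st3 <- withr::with_seed(54, random_start_state(ctx))
  expect_error(substitution_effect(ctx, st, st3), "exactly one")
})

test_that("replacement_rate sums nonsynonymous neighbor rates and tracks propensity", {
  ctx <- small_ctx()
  st <- withr::with_seed(55, equilibrate(ctx, burn_in = 60))
  nb <- neighbor_rates(ctx, st)
  nonsyn <- !nb$synonymous & !is.na(nb$neighbor_codon)
  expect_equal(replacement_rate(ctx, st),
               unname(rowSums(nb$rates * nonsyn)), tolerance = 1e-10)
  ## across a trajectory, sites with higher resident propensity are
  ## replaced more slowly (negative rank correlation)
  traj <- small_trajectory()
  rho <- stats::cor(as.vector(traj$resident_prop),
                    as.vector(traj$repl_rate), method = "spearman")
  expect_lt(rho, -0.3)
})

test_that("constant-fitness proteins have the neutral replacement rate", {
  ## empty native map and empty decoys: every sequence has the same dG
  nat <- contact_map(3, matrix(integer(0), ncol = 2))
  empty <- contact_map(3, matrix(integer(0), ncol = 2))
  dec <- structure(list(n_decoys = 2L, maps = list(empty, empty), L = 3L),
                   class = "decoy_set")
  ctx <- evol_context(nat, dec, random_potentials(9),
                      mutation_params(2, rep(0.25, 4)), Ne = 100)
  st <- make_state(ctx, c("ATG", "AAA", "GGC"))
  nb <- neighbor_rates(ctx, st)
  nonsyn <- !nb$synonymous & !is.na(nb$neighbor_codon)
  ## every nonsynonymous neighbor fixes at the neutral 1/(2Ne), so the
  ## replacement rate reduces to the summed mutation rates
  mu_sum <- rowSums(ctx$mu_tab[st$codons, ] * nonsyn)
  expect_equal(replacement_rate(ctx, st), unname(mu_sum), tolerance = 1e-9)
})

test_that("stability_uniformity_profile handles real and degenerate trajectories", {
  traj <- small_trajectory()
  prof <- stability_uniformity_profile(traj)
  expect_equal(nrow(prof$states), traj$n + 1)
  expect_equal(nrow(prof$substitutions), traj$n)
  ## stability and landscape uniformity are strongly anticorrelated
  expect_lt(prof$spearman_dG_avgU, -0.7)
  expect_lt(prof$spearman_ddG_avg_dU, -0.7)
  ## degenerate trajectory: no substitutions -> NA correlations
  ctx <- small_ctx()
  st <- traj$final_state
  empty <- simulate_trajectory(ctx, st, 0)
  prof0 <- stability_uniformity_profile(empty)
  expect_true(is.na(prof0$spearman_dG_avgU))
  expect_true(is.na(prof0$spearman_ddG_avg_dU))
})

test_that("fitness- and propensity-landscape entropies are positively rank-correlated across sites", {
  ctx <- small_ctx()
  st <- withr::with_seed(57, equilibrate(ctx, burn_in = 60))
  fmat <- site_fitness_landscape(ctx, st)
  pmat <- site_propensity_landscape(ctx, st)
  ## entropy of the fitness landscape after normalizing each row
  fU <- apply(fmat / rowSums(fmat), 1, landscape_entropy)
  pU <- apply(pmat, 1, landscape_entropy)
  expect_gt(stats::cor(fU, pU, method = "spearman"), 0.3)
})
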