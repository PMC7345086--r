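test_that("bridge-peptide motif predicate follows the default and switches", {
  expect_true(is_bridge_peptide(c("Arg", "Gly", "Gly", "Ala", "Asp")))
  expect_false(is_bridge_peptide(c("Gly", "Gly", "Ala")))
  expect_false(is_bridge_peptide(c("Arg", "Asp")))             # too short
  expect_true(is_bridge_peptide(c("Arg", "Asp"), min_length = 2))
  expect_true(is_bridge_peptide(c("Arg", "Gly", "Gly"), motif = "arg_only"))
  expect_false(is_bridge_peptide(c("Arg", "Gly", "Gly")))      # no Asp
  expect_error(is_bridge_peptide(character(0)), "empty")
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(p_gc = 1.2))
  expect_error(sim_config(peptide_len_range = c(4, 2)))
  expect_error(sim_config(aa_weights = c(Gly = -1)))
  expect_s3_class(sim_config(n_cycles = 0), "sim_config")
})

test_that("pool initialization matches the synthesis distribution", {
  cfg1 <- sim_config(n_rna = 200, p_gc = 1, seed = 1)
  expect_true(all(init_pool(cfg1)$rna$gc == 1))
  cfg <- sim_config(n_rna = 10000, rna_length = 20, p_gc = 0.5, seed = 5)
  pool <- init_pool(cfg)
  se <- sqrt(0.5 * 0.5 / 20) / sqrt(10000)
  expect_lt(abs(mean(pool$rna$gc) - 0.5), 3 * se)
  expect_identical(init_pool(cfg)$rna, pool$rna)       # same seed, same pool
  expect_equal(length(pool$peptides), cfg$bp_initial)
  expect_true(all(pool$is_bp))
})

test_that("chemical-code charging dominates at beta = 0 and saturates at high beta", {
  cfg <- sim_config(n_rna = 10000, bp_bias = 0, seed = 8)
  state <- aminoacylate_step(init_pool(cfg), cfg)
  w <- cfg$aa_weights / sum(cfg$aa_weights)
  p_arg <- w[["Arg"]]
  se <- sqrt(p_arg * (1 - p_arg) / 10000)
  expect_lt(abs(mean(state$charged == "Arg") - p_arg), 3 * se)
  # saturation: huge bias, seeded BPs, all-GC molecules -> all Arg
  cfg2 <- sim_config(n_rna = 100, p_gc = 1, bp_bias = 1e6, bp_initial = 2,
                     seed = 9)
  state2 <- aminoacylate_step(init_pool(cfg2), cfg2)
  expect_true(all(state2$charged == "Arg"))
})

test_that("one-cycle Arg share matches the closed-form mixture expectation", {
  # q_i = min(1, beta * n_bp / n * gc_i); E[Arg share] = mean(q + (1-q) p_arg)
  cfg <- sim_config(n_rna = 20000, bp_bias = 3, bp_initial = 10, seed = 12)
  pool <- init_pool(cfg)
  q <- pmin(1, cfg$bp_bias * sum(pool$is_bp) / cfg$n_rna * pool$rna$gc)
  w <- cfg$aa_weights / sum(cfg$aa_weights)
  expected <- mean(q + (1 - q) * w[["Arg"]])
  state <- aminoacylate_step(pool, cfg)
  got <- mean(state$charged == "Arg")
  se <- sqrt(expected * (1 - expected) / cfg$n_rna)
  expect_lt(abs(got - expected), 3 * se)
})

test_that("peptide assembly groups charged RNAs and conserves residues", {
  cfg <- sim_config(n_rna = 4, peptide_len_range = c(2, 2), bp_initial = 0,
                    seed = 3)
  state <- init_pool(cfg)
  state$charged <- c("Gly", "Gly", "Gly", "Gly")
  state <- hdp_step(state, cfg)
  expect_length(state$peptides, 2L)
  expect_true(all(is.na(state$charged)))
  expect_equal(sum(state$is_bp), 0L)                   # all-Gly: no BPs
  # residues in new peptides are exactly the residues that were charged
  cfg2 <- sim_config(n_rna = 500, bp_initial = 0, seed = 4)
  st <- aminoacylate_step(init_pool(cfg2), cfg2)
  charged_before <- table(st$charged[!is.na(st$charged)])
  st2 <- hdp_step(st, cfg2)
  incorporated <- table(unlist(st2$peptides))
  leftover <- table(st2$charged[!is.na(st2$charged)])
  for (aa in names(charged_before)) {
    expect_equal(unname(charged_before[aa]),
                 sum(incorporated[aa], leftover[aa], na.rm = TRUE))
  }
})

test_that("peptide lengths follow the configured uniform range", {
  cfg <- sim_config(n_rna = 12000, bp_initial = 0, peptide_len_range = c(2, 6),
                    seed = 6)
  st <- hdp_step(aminoacylate_step(init_pool(cfg), cfg), cfg)
  lens <- lengths(st$peptides)
  tab <- table(factor(lens[seq_len(length(lens) - 1L)], levels = 2:6))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("degradation respects survival probabilities and replenishes", {
  cfg <- sim_config(n_rna = 300, base_survival = 1, survival_bonus = 1,
                    gc_slope = 0, bp_initial = 3, seed = 2)
  state <- init_pool(cfg)
  before <- state$peptides
  state <- degrade_replenish_step(state, cfg)
  expect_identical(state$peptides, before)             # no attrition
  expect_equal(length(state$rna$gc), cfg$n_rna)
  cfg0 <- sim_config(n_rna = 50, base_survival = 0, survival_bonus = 1,
                     bp_initial = 5, seed = 2)
  st0 <- degrade_replenish_step(init_pool(cfg0), cfg0)
  expect_length(st0$peptides, 0L)
  expect_equal(length(st0$rna$gc), 50L)                # fully replenished
})

test_that("positive GC-stability slope enriches the equilibrium pool", {
  cfg <- sim_config(n_rna = 2000, p_gc = 0.5, gc_slope = 0.6, bp_bias = 0,
                    bp_initial = 0, n_cycles = 30, seed = 14)
  traj <- run_simulation(cfg)
  expect_gt(mean(traj$mean_gc[traj$cycle > 20]), 0.5 + 0.01)
  # zero slope control stays at the synthesis mean
  cfg0 <- sim_config(n_rna = 2000, p_gc = 0.5, gc_slope = 0, bp_bias = 0,
                     bp_initial = 0, n_cycles = 30, seed = 14)
  traj0 <- run_simulation(cfg0)
  expect_lt(abs(mean(traj0$mean_gc[traj0$cycle > 20]) - 0.5), 0.01)
})

test_that("trajectories are reproducible, bounded and complete", {
  cfg <- sim_config(n_rna = 300, n_cycles = 20, seed = 21)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 21L)
  expect_true(all(a$bp_fraction >= 0 & a$bp_fraction <= 1))
  expect_true(all(a$arg_fraction >= 0 & a$arg_fraction <= 1))
  expect_true(all(a$pool_size == 300L))
  z <- run_simulation(sim_config(n_rna = 100, n_cycles = 0, seed = 1))
  expect_equal(nrow(z), 1L)
  expect_equal(z$cycle, 0L)
})

test_that("beta = 0 incorporation stays at the chemical-code null", {
  cfg <- sim_config(n_rna = 500, n_cycles = 50, bp_bias = 0, seed = 17)
  traj <- run_simulation(cfg)
  w <- cfg$aa_weights / sum(cfg$aa_weights)
  p_arg <- w[["Arg"]]
  se <- sqrt(p_arg * (1 - p_arg) / (cfg$n_rna * cfg$n_cycles))
  expect_lt(abs(mean(traj$arg_fraction[-1]) - p_arg), 3 * se)
})

test_that("bridge-peptide bias amplifies BP frequency over the null", {
  finals <- vapply(1:5, function(s) {
    on <- run_simulation(sim_config(n_rna = 300, n_cycles = 50, bp_bias = 5,
                                    seed = 100 + s))
    off <- run_simulation(sim_config(n_rna = 300, n_cycles = 50, bp_bias = 0,
                                     seed = 100 + s))
    tail(on$bp_fraction, 1) - tail(off$bp_fraction, 1)
  }, numeric(1))
  expect_gt(mean(finals), 0)
})
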