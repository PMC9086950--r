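test_that("transition matrices are stochastic", {
  for (mode in c("haplodiploid", "diploid")) for (s in c(0, 0.05, -0.05)) {
    ch <- hd_markov_chain(mode, Nm = 3, Nf = 3, s = s, h = 0.3)
    expect_lt(max(abs(rowSums(ch$P) - 1)), 1e-12)
  }
})

test_that("neutral fixation probability equals the reproductive-value weight of one copy", {
  # haplodiploid: 1/(3N) for a single copy wherever it starts; diploid: 1/(4N)
  for (N in c(2, 3)) {
    ch <- hd_markov_chain("haplodiploid", N, N, s = 0, h = 0)
    expect_equal(hd_fixation_probability(ch, "single_copy_female"), 1 / (3 * N),
                 tolerance = 1e-10)
    expect_equal(hd_fixation_probability(ch, "single_copy_male"), 1 / (3 * N),
                 tolerance = 1e-10)
    chd <- hd_markov_chain("diploid", N, N, s = 0, h = 0)
    expect_equal(hd_fixation_probability(chd, "single_copy_female"), 1 / (4 * N),
                 tolerance = 1e-10)
    expect_equal(hd_fixation_probability(chd, "single_copy_male"), 1 / (4 * N),
                 tolerance = 1e-10)
  }
})

test_that("absorbing states return 0 and 1 exactly", {
  ch <- hd_markov_chain("haplodiploid", 2, 2, s = 0.05, h = 0)
  expect_identical(hd_fixation_probability(
    ch, list(females = c(2, 0, 0), males = 0)), 0)
  expect_identical(hd_fixation_probability(
    ch, list(females = c(0, 0, 2), males = 2)), 1)
})

test_that("fixation probability is monotone in s", {
  for (mode in c("haplodiploid", "diploid")) for (h in c(0, 1)) {
    p <- vapply(c(-0.05, 0, 0.05), function(s)
      hd_fixation_probability(hd_markov_chain(mode, 3, 3, s, h),
                              "single_copy_female"), numeric(1))
    expect_true(all(diff(p) > 0))
  }
})

test_that("selection on recessive mutations is more effective in haplodiploids", {
  # the oracle-level statement: a beneficial recessive single copy fixes with
  # higher probability in a haplodiploid population than in a diploid one of
  # equal census
  p_hap <- hd_fixation_probability(
    hd_markov_chain("haplodiploid", 3, 3, s = 0.05, h = 0), "single_copy_female")
  p_dip <- hd_fixation_probability(
    hd_markov_chain("diploid", 3, 3, s = 0.05, h = 0), "single_copy_female")
  expect_gt(p_hap, p_dip)
  # and a deleterious recessive is removed more effectively
  q_hap <- hd_fixation_probability(
    hd_markov_chain("haplodiploid", 3, 3, s = -0.05, h = 0), "single_copy_female")
  q_dip <- hd_fixation_probability(
    hd_markov_chain("diploid", 3, 3, s = -0.05, h = 0), "single_copy_female")
  expect_lt(q_hap / (1 / 9), q_dip / (1 / 12))  # relative to the neutral rate
})

test_that("oversized state spaces are refused", {
  expect_error(hd_markov_chain("diploid", 100, 100, 0, 0), "state space")
})

test_that("simulator replicates fall in the exact value's confidence band (neutral spot check)", {
  set.seed(61)
  for (mode in c("haplodiploid", "diploid")) {
    p <- hd_fixation_probability(hd_markov_chain(mode, 2, 2, 0, 0),
                                 "single_copy_female")
    emp <- hd_fixation_replicates(mode, 2, 2, s = 0, h = 0, n_rep = 5000)
    expect_identical(emp$n_unresolved, 0L)
    expect_gte(emp$n_fixed, qbinom(0.0025, 5000, p))
    expect_lte(emp$n_fixed, qbinom(0.9975, 5000, p))
  }
})

test_that("the oracle table covers both placements and all grid points", {
  tab <- hd_oracle_table(2, 2, s_values = c(0, 0.05), h_values = 0)
  expect_identical(nrow(tab), 8L)  # 2 modes x 2 s x 1 h x 2 placements
  expect_true(all(tab$fixation_probability >= 0 & tab$fixation_probability <= 1))
})
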