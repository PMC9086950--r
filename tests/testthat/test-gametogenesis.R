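test_that("crossover draws follow the flat genetic map", {
  expect_identical(hd_draw_crossovers(1e6, 0), integer(0))
  expect_identical(hd_draw_crossovers(1, 1e-3), integer(0))  # no adjacent pair

  set.seed(11)
  n <- 2e4
  counts <- integer(n)
  for (i in seq_len(n)) {
    bp <- hd_draw_crossovers(1e6, 1e-6)
    counts[i] <- length(bp)
    if (length(bp)) {
      expect_false(is.unsorted(bp, strictly = TRUE))  # sorted, duplicate-free
      expect_true(all(bp >= 1 & bp < 1e6))
    }
  }
  lambda <- 1e-6 * (1e6 - 1)  # 0.999999
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("recombination alternates strands across half-open segments", {
  reg <- toy_registry(1:3, c(10L, 500L, 300L))
  # worked example: a = {10, 500}, b = {300}, breakpoint at 200, start a
  g <- hd_recombine(c(1L, 2L), 3L, breakpoints = 200L, start = "a", registry = reg)
  expect_identical(g, c(1L, 3L))  # positions {10, 300}
  # complementary gamete
  g2 <- hd_recombine(c(1L, 2L), 3L, breakpoints = 200L, start = "b", registry = reg)
  expect_identical(g2, 2L)
  # no breakpoints: identity on the start strand
  expect_identical(hd_recombine(c(1L, 2L), 3L, integer(0), "a", reg), c(1L, 2L))
  # a mutation exactly at a breakpoint belongs to the right-hand segment
  reg2 <- toy_registry(1:2, c(200L, 199L))
  expect_identical(hd_recombine(1:2, integer(0), 200L, "a", reg2), 2L)
  # null genomes are rejected
  expect_error(hd_recombine(NULL, 1L, integer(0), "a", reg), "null genome")
})

test_that("gamete mutation set is always a subset of the parental union", {
  set.seed(21)
  for (i in 1:40) {
    n <- 30L
    reg <- toy_registry(1:n, sample.int(1000, n, replace = TRUE))
    a <- sort_ids <- haplodrift:::sort_genome_ids(sample(1:n, 12), reg)
    b <- haplodrift:::sort_genome_ids(sample(1:n, 12), reg)
    bp <- sort(sample.int(999, rpois(1, 2)))
    g <- hd_recombine(a, b, bp, sample(c("a", "b"), 1), reg)
    expect_true(all(g %in% union(a, b)))
    expect_identical(g, haplodrift:::sort_genome_ids(g, reg))
    expect_identical(anyDuplicated(g), 0L)
  }
})

test_that("haploid paternal transmission is clonal", {
  expect_identical(hd_copy_genome(42L), 42L)
  expect_identical(hd_copy_genome(integer(0)), integer(0))
  expect_error(hd_copy_genome(NULL), "null genome")
})

test_that("de novo mutation counts and positions match the Poisson-uniform model", {
  expect_identical(nrow(hd_draw_new_mutations(1e6, 0, 0, 0, 1, 1L)), 0L)

  set.seed(31)
  ndraw <- 3000L
  counts <- integer(ndraw)
  pos <- integer(0)
  for (i in seq_len(ndraw)) {
    recs <- hd_draw_new_mutations(L = 100, mu = 0.05, s = 0.01, h = 0.5,
                                  generation = 7, next_id = 1L)
    counts[i] <- nrow(recs)
    pos <- c(pos, recs$position)
    if (nrow(recs)) {
      expect_true(all(recs$position >= 0 & recs$position < 100))
      expect_true(all(recs$origin == 7L))
      expect_true(all(recs$h_haploid == 1))
    }
  }
  lambda <- 100 * 0.05
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / ndraw))
  # positions uniform on [0, L): chi-square over 10 bins at alpha = 0.001
  p <- chisq.test(tabulate(pos %/% 10 + 1L, 10L))$p.value
  expect_gt(p, 0.001)
})

test_that("ids assigned to new mutations are fresh and sequential", {
  set.seed(41)
  recs <- hd_draw_new_mutations(L = 1000, mu = 0.02, s = 0, h = 0,
                                generation = 1, next_id = 57L)
  if (nrow(recs)) expect_identical(recs$id, seq_len(nrow(recs)) + 56L)
})
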