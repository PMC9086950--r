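test_that("exact rank-sum enumeration handles degenerate and extreme cases", {
  # identical lists: every assignment is equally extreme
  cmp <- hd_compare(c(3, 3, 3), c(3, 3, 3))
  expect_equal(cmp$p.value, 1)
  expect_equal(cmp$mean_difference, 0)
  # fully separated groups of 3: 2 of the 20 assignments are as extreme
  cmp2 <- hd_compare(c(5, 6, 7), c(1, 2, 3))
  expect_equal(cmp2$p.value, 0.1)
  expect_equal(cmp2$mean_difference, 4)
  expect_match(cmp2$method, "exact")
  # one-sided tails
  expect_equal(hd_rank_sum_exact(c(5, 6, 7), c(1, 2, 3), "greater"), 1 / 20)
  expect_equal(hd_rank_sum_exact(c(5, 6, 7), c(1, 2, 3), "less"), 1)
})

test_that("exact enumeration agrees with the reference implementation", {
  set.seed(71)
  for (i in 1:10) {
    v <- sample(1000, 13)  # 13 distinct pooled values: tie-free
    x <- v[1:6]; y <- v[7:13]
    p_ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(hd_rank_sum_exact(x, y), p_ref, tolerance = 1e-12)
  }
})

test_that("normal approximation matches exact enumeration at n = 8 per group", {
  # exhaustive over every achievable rank sum: in the inferential regime
  # (exact p <= 0.25) the two routines agree within 0.01; the residual
  # discrepancy at the distribution's center stays below 0.011
  for (W in 36:100) {
    x <- subset_with_rank_sum(W)
    y <- setdiff(1:16, x)
    p_ex <- hd_compare(x, y, method = "exact")$p.value
    p_no <- hd_compare(x, y, method = "normal")$p.value
    expect_lt(abs(p_no - p_ex), 0.011)
    if (p_ex <= 0.25) expect_lt(abs(p_no - p_ex), 0.01)
  }
})

test_that("tie-corrected normal approximation matches wilcox.test", {
  set.seed(73)
  x <- sample(1:6, 15, replace = TRUE)
  y <- sample(1:6, 12, replace = TRUE)
  cmp <- hd_compare(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(cmp$p.value, ref, tolerance = 1e-10)
})

test_that("equal-chromosome pairing matches total genome copies", {
  g <- hd_treatment_grid(data.frame(label = "t", s = 0, h = 0), replicates = 1,
                         Nm = 1000, Nf = 1000, pairing = "equal_chromosomes")
  expect_identical(g$dip_Nm, 750L)  # 3000 genome copies on both sides
  expect_identical(g$dip_Nf, 750L)
  g2 <- hd_treatment_grid(data.frame(label = "t", s = 0, h = 0), replicates = 1,
                          Nm = 100, Nf = 100, pairing = "equal_chromosomes")
  expect_identical(g2$dip_Nm, 75L)
  expect_error(hd_treatment_grid(data.frame(label = "t", s = 0, h = 0),
                                 replicates = 1, Nm = 50, Nf = 50,
                                 pairing = "equal_chromosomes"),
               "divisible")
})

test_that("grids are reproducible from (grid, base_seed) and guarded at full scale", {
  grid <- hd_treatment_grid(data.frame(label = "neutral", s = 0, h = 0),
                            replicates = 2, Nm = 8, Nf = 8, L = 1000,
                            mu = 1e-4, r = 1e-4, burn_in = 30,
                            run_generations = 120, base_seed = 5)
  t1 <- hd_run_grid(grid)
  t2 <- hd_run_grid(grid)
  expect_identical(t1, t2)
  expect_identical(nrow(t1), 4L)  # 1 treatment x 2 modes x 2 replicates
  expect_true(all(t1$total_fixations >= 0))
  # replicate seeds are distinct and deterministic
  expect_identical(anyDuplicated(t1$seed), 0L)
  # full-scale preset refuses to run without acknowledgement
  expect_error(hd_run_grid(hd_preset("figure1_full")), "acknowledge_long_run")
})

test_that("presets encode the standard designs", {
  p <- hd_preset("figure1_scaled")
  expect_s3_class(p, "hd_grid")
  expect_identical(p$replicates, 50L)
  expect_identical(p$Nm, 100L)
  expect_equal(p$mu, 1e-6)
  pe <- hd_preset("equal_chromosomes_scaled")
  expect_identical(pe$pairing, "equal_chromosomes")
  expect_identical(pe$dip_Nm, 75L)
  pf <- hd_preset("figure1_full")
  expect_identical(pf$replicates, 200L)
  expect_equal(pf$mu, 1e-8)
  expect_identical(pf$burn_in, 15000L)
})

test_that("VCF export writes valid VCF 4.2 with haploid male genotypes", {
  # mutation-free population: header only
  empty <- hd_population(hd_config("haplodiploid", Nm = 2, Nf = 2, L = 100))
  f <- tempfile(fileext = ".vcf")
  hd_export_vcf(empty, f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))

  reg <- toy_registry(1:2, c(0L, 49L), s = 0.01, h = 0.5)
  pop <- toy_pop("haplodiploid",
                 female_genomes = list(list(2L, integer(0)), list(c(1L, 2L), 2L)),
                 male_genomes = list(list(1L, NULL), list(integer(0), NULL)),
                 registry = reg, L = 100)
  hd_export_vcf(pop, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2L)
  rec1 <- strsplit(body[1], "\t")[[1]]
  expect_identical(rec1[2], "1")           # locus 0 -> POS 1
  expect_identical(rec1[10], "0/0")        # female 1 lacks id 1
  expect_identical(rec1[11], "1/0")        # female 2 heterozygous
  expect_identical(rec1[12], "1")          # male 1 haploid carrier
  expect_identical(rec1[13], "0")          # male 2 haploid non-carrier
  rec2 <- strsplit(body[2], "\t")[[1]]
  expect_identical(rec2[2], "50")
  expect_identical(rec2[10], "1/0")
  expect_identical(rec2[11], "1/1")
  expect_match(rec2[8], "S=0.01;H=0.5")
  # cross-check with an independent VCF reader
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
    expect_identical(nrow(v@fix), 2L)
    expect_identical(unname(v@fix[, "POS"]), c("1", "50"))
  }
  unlink(f)
})
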