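# Experimental design: treatment grids, replicated runs, comparisons
# between population types, and VCF export.

stable_hash <- function(x) {
  # deterministic, platform-independent polynomial hash mod 2^31 - 1
  b <- utf8ToInt(x)
  hh <- 0
  for (v in b) hh <- (hh * 31 + v) %% 2147483647
  hh
}

#' Define a treatment grid
#'
#' A grid pairs a haplodiploid arm with a diploid arm for each treatment.
#' Under `equal_individuals` pairing both arms use the same census; under
#' `equal_chromosomes` the diploid census is reduced so both arms carry the
#' same total number of genome copies (a haplodiploid population of
#' 1,000 males + 1,000 females has 3,000 genome copies, matched by a diploid
#' population of 750 males + 750 females).
#'
#' @param treatments Data frame with columns `label`, `s`, `h`.
#' @param replicates Replicates per (treatment, mode).
#' @param Nm,Nf Haplodiploid-arm census.
#' @param pairing `"equal_individuals"` or `"equal_chromosomes"`.
#' @param L,mu,r,h_haploid,burn_in,run_generations Shared run parameters
#'   (see [hd_config()]).
#' @param base_seed Base seed; each replicate's seed is derived from it and a
#'   stable hash of (treatment label, mode, replicate index).
#' @return An object of class `hd_grid`.
#' @export
hd_treatment_grid <- function(treatments, replicates,
                              Nm = 1000L, Nf = 1000L,
                              pairing = c("equal_individuals", "equal_chromosomes"),
                              L = 1e6, mu = 1e-8, r = 1e-6, h_haploid = 1,
                              burn_in = 15000L, run_generations = 35000L,
                              base_seed = 1L) {
  pairing <- match.arg(pairing)
  stopifnot(is.data.frame(treatments),
            all(c("label", "s", "h") %in% names(treatments)),
            replicates >= 1L)
  Nm <- as.integer(Nm); Nf <- as.integer(Nf)
  if (pairing == "equal_chromosomes") {
    G <- 2L * Nf + Nm
    if (G %% 4L != 0L)
      stop("equal_chromosomes pairing needs the haplodiploid genome-copy count (2*Nf + Nm) divisible by 4")
    dip_N <- G %/% 4L
  } else {
    dip_N <- NULL
  }
  structure(list(treatments = treatments, replicates = as.integer(replicates),
                 Nm = as.integer(Nm), Nf = as.integer(Nf),
                 pairing = pairing,
                 dip_Nm = if (is.null(dip_N)) as.integer(Nm) else dip_N,
                 dip_Nf = if (is.null(dip_N)) as.integer(Nf) else dip_N,
                 L = L, mu = mu, r = r, h_haploid = h_haploid,
                 burn_in = as.integer(burn_in),
                 run_generations = as.integer(run_generations),
                 base_seed = as.integer(base_seed)),
            class = "hd_grid")
}

#' Built-in experiment presets
#'
#' `figure1_scaled` is a desk-scale version of the treatment comparison
#' (census 100 + 100, mutation rate raised to 1e-6 so fixation counts are
#' informative, 2,000 burn-in + 8,000 recorded generations, 50 replicates):
#' a neutral treatment plus advantageous mutations (s = 0.01) that are fully
#' recessive and fully dominant.  `equal_chromosomes_scaled` is the same at
#' equal chromosome numbers rather than equal individual numbers, with
#' h = 0 and h = 0.5.  `figure1_full` is the full-scale design (200
#' replicates of 1,000 + 1,000 individuals, 15,000 + 35,000 generations,
#' mutation rate 1e-8) across neutral, advantageous, deleterious and
#' dominance-gradient treatments; running it takes many hours and
#' [hd_run_grid()] refuses it unless `acknowledge_long_run = TRUE`.
#'
#' @param name Preset name.
#' @return An `hd_grid`.
#' @export
hd_preset <- function(name = c("figure1_scaled", "figure1_full",
                               "equal_chromosomes_scaled")) {
  name <- match.arg(name)
  switch(name,
    figure1_scaled = hd_treatment_grid(
      treatments = data.frame(
        label = c("neutral", "recessive_beneficial", "dominant_beneficial"),
        s = c(0, 0.01, 0.01), h = c(0, 0, 1)),
      replicates = 50L, Nm = 100L, Nf = 100L, mu = 1e-6,
      burn_in = 2000L, run_generations = 8000L),
    equal_chromosomes_scaled = hd_treatment_grid(
      treatments = data.frame(
        label = c("recessive_beneficial", "additive_beneficial"),
        s = c(0.01, 0.01), h = c(0, 0.5)),
      replicates = 50L, Nm = 100L, Nf = 100L, mu = 1e-6,
      pairing = "equal_chromosomes",
      burn_in = 2000L, run_generations = 8000L),
    figure1_full = hd_treatment_grid(
      treatments = data.frame(
        label = c("neutral",
                  "beneficial_s0.001", "beneficial_s0.003", "beneficial_s0.01",
                  "deleterious_s-0.001", "deleterious_s-0.003", "deleterious_s-0.01",
                  "dominance_h0", "dominance_h0.25", "dominance_h0.5",
                  "dominance_h0.75", "dominance_h1"),
        s = c(0, 0.001, 0.003, 0.01, -0.001, -0.003, -0.01,
              rep(0.001, 5)),
        h = c(rep(0, 7), 0, 0.25, 0.5, 0.75, 1)),
      replicates = 200L))
}

#' Run a treatment grid
#'
#' Runs every (treatment, mode, replicate) combination with deterministic
#' per-replicate seeds and returns one row per run with the total number of
#' fixations in the recorded window.  The full-scale design represents days
#' of compute on one core; a resource guard refuses grids of that size
#' unless `acknowledge_long_run = TRUE`.
#'
#' @param grid An [hd_treatment_grid()] or [hd_preset()].
#' @param acknowledge_long_run Set to `TRUE` to run full-scale grids.
#' @param verbose Print one line per completed run.
#' @return A data frame: `treatment`, `s`, `h`, `mode`, `Nm`, `Nf`,
#'   `replicate`, `seed`, `total_fixations`, `fixations_per_generation`,
#'   `final_segregating`.  Fully reproducible from `(grid, base_seed)`.
#' @export
hd_run_grid <- function(grid, acknowledge_long_run = FALSE, verbose = FALSE) {
  stopifnot(inherits(grid, "hd_grid"))
  total_gens <- grid$burn_in + grid$run_generations
  workload <- nrow(grid$treatments) * 2 * as.numeric(grid$replicates) *
    total_gens * (grid$Nm + grid$Nf)
  if (workload > 2e9 && !acknowledge_long_run)
    stop("this grid is a multi-hour computation; pass acknowledge_long_run = TRUE to run it")
  rows <- list()
  for (ti in seq_len(nrow(grid$treatments))) {
    tr <- grid$treatments[ti, ]
    for (mode in c("haplodiploid", "diploid")) {
      Nm <- if (mode == "haplodiploid") grid$Nm else grid$dip_Nm
      Nf <- if (mode == "haplodiploid") grid$Nf else grid$dip_Nf
      for (rep_i in seq_len(grid$replicates)) {
        seed <- as.integer((grid$base_seed +
                            stable_hash(sprintf("%s|%s|%d", tr$label, mode, rep_i))) %%
                           2147483647)
        cfg <- hd_config(mode, Nm = Nm, Nf = Nf, L = grid$L, mu = grid$mu,
                         r = grid$r, s = tr$s, h = tr$h,
                         h_haploid = grid$h_haploid,
                         burn_in = grid$burn_in,
                         run_generations = grid$run_generations,
                         seed = seed)
        res <- hd_simulate(cfg)
        sm <- hd_summarize(res, "recorded")
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr$label, s = tr$s, h = tr$h, mode = mode,
          Nm = Nm, Nf = Nf, replicate = rep_i, seed = seed,
          total_fixations = sm$total_fixations,
          fixations_per_generation = sm$fixations_per_generation,
          final_segregating = sm$final_segregating)
        if (verbose)
          message(sprintf("%s / %s / rep %d: %d fixations",
                          tr$label, mode, rep_i, sm$total_fixations))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a grid results table as TSV
#'
#' @param results Data frame from [hd_run_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
hd_write_grid <- function(results, path) write_tsv(results, path)

#' Exact small-sample Wilcoxon rank-sum p-value by enumeration
#'
#' Brute-force enumeration of all assignments of the pooled observations to
#' the two groups.  The two-sided p-value counts assignments whose rank sum
#' is at least as far from its null expectation as the observed one; ties in
#' the data are handled naturally through midranks.  Serves as the test
#' oracle for the normal-approximation routine in [hd_compare()].
#'
#' @param x,y Numeric vectors (each of length <= 10).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (x vs y).
#' @return The exact p-value.
#' @export
hd_rank_sum_exact <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1, n1 <= 10, n2 <= 10)
  rk <- rank(c(x, y))
  obs <- sum(rk[seq_len(n1)])
  combos <- utils::combn(n, n1)
  Ws <- colSums(matrix(rk[combos], nrow = n1))
  eps <- 1e-9
  switch(alternative,
         two.sided = {
           E <- n1 * (n + 1) / 2
           mean(abs(Ws - E) >= abs(obs - E) - eps)
         },
         greater = mean(Ws >= obs - eps),
         less = mean(Ws <= obs + eps))
}

#' Compare fixation counts between population types
#'
#' Wilcoxon rank-sum comparison of per-replicate fixation counts from a
#' haplodiploid arm and a diploid arm, plus the difference of means
#' (haplodiploid minus diploid).  Uses exact enumeration when both groups
#' have at most 8 observations and the normal approximation with tie
#' correction otherwise.
#'
#' @param fixations_hap,fixations_dip Numeric vectors of per-replicate
#'   fixation counts (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (haplodiploid
#'   exceeds diploid) or `"less"`.
#' @param method `"auto"` (exact when both groups have at most 8
#'   observations, otherwise normal approximation), or force `"exact"` /
#'   `"normal"` for cross-validation.
#' @return A list: `statistic` (rank sum of the haplodiploid arm),
#'   `p.value`, `mean_difference`, `method`.
#' @examples
#' hd_compare(c(5, 6, 7), c(1, 2, 3))  # exact two-sided p = 0.1
#' @export
hd_compare <- function(fixations_hap, fixations_dip,
                       alternative = c("two.sided", "greater", "less"),
                       method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(fixations_hap); y <- as.numeric(fixations_dip)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(n1)])
  use_exact <- switch(method, auto = n1 <= 8 && n2 <= 8,
                      exact = TRUE, normal = FALSE)
  if (use_exact) {
    p <- hd_rank_sum_exact(x, y, alternative)
    method <- "exact enumeration"
  } else {
    E <- n1 * (n + 1) / 2
    tie <- table(rk)
    V <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (V <= 0) {
      p <- 1
    } else {
      # continuity-corrected z, as in the standard large-sample rank-sum test
      d <- W - E
      p <- switch(alternative,
                  two.sided = min(1, 2 * stats::pnorm(-(abs(d) - 0.5) / sqrt(V))),
                  greater = stats::pnorm((d - 0.5) / sqrt(V), lower.tail = FALSE),
                  less = stats::pnorm((d + 0.5) / sqrt(V)))
    }
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = W, p.value = p,
       mean_difference = mean(x) - mean(y), method = method)
}

#' Export segregating variants as VCF 4.2
#'
#' One record per segregating mutation (0-based loci are converted to
#' 1-based POS; INFO carries `S=`, `H=` and `ORIGIN=`), one sample column
#' per individual.  Haplodiploid males are emitted as haploid genotypes
#' (single allele); females and diploid individuals as unphased diploid
#' genotypes.  REF/ALT are the placeholder alleles `A`/`T` (the simulation
#' tracks mutation identities, not nucleotides).
#'
#' @param pop An `hd_population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
hd_export_vcf <- function(pop, path) {
  stopifnot(inherits(pop, "hd_population"))
  reg <- pop$registry
  reg <- reg[order(reg$position, reg$id), , drop = FALSE]
  Nf <- length(pop$females); Nm <- length(pop$males)
  samples <- c(sprintf("F%d", seq_len(Nf)), sprintf("M%d", seq_len(Nm)))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=1,length=%d>", as.integer(pop$params$L)),
           "##INFO=<ID=S,Number=1,Type=Float,Description=\"Selection coefficient\">",
           "##INFO=<ID=H,Number=1,Type=Float,Description=\"Dominance coefficient\">",
           "##INFO=<ID=ORIGIN,Number=1,Type=Integer,Description=\"Origin generation\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_for <- function(ind, id) {
    g1 <- ind$genomes[[1L]]; g2 <- ind$genomes[[2L]]
    if (is_null_genome(g2) || is_null_genome(g1)) {
      g <- if (is_null_genome(g1)) g2 else g1
      if (id %in% g) "1" else "0"
    } else {
      paste0(as.integer(id %in% g1), "/", as.integer(id %in% g2))
    }
  }
  inds <- c(pop$females, pop$males)
  recs <- vapply(seq_len(nrow(reg)), function(i) {
    id <- reg$id[i]
    gts <- vapply(inds, gt_for, character(1), id = id)
    paste(c("1", as.character(reg$position[i] + 1L), sprintf("hd%d", id),
            "A", "T", ".", ".",
            sprintf("S=%g;H=%g;ORIGIN=%d", reg$s[i], reg$h[i], reg$origin[i]),
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
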