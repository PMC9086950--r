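# Lifecycle: advance the population one non-overlapping generation.
#
# Parentage is fitness-proportional with replacement, independently per
# offspring and within each sex (soft selection; the census is hard-fixed at
# exactly Nm sons and Nf daughters).  Haplodiploid inheritance: a daughter is
# a recombined maternal gamete plus a clonal paternal gamete; a son is a
# recombined maternal gamete plus a null genome (no father).  Diploid
# inheritance: every offspring receives one recombined gamete from each
# parent.  Every transmitted gamete is subject to de novo mutation.

#' Advance a population by one generation (reference implementation)
#'
#' A pure-R implementation of the generation step, operating on the explicit
#' `hd_population` representation.  It is the executable definition of the
#' lifecycle; [hd_simulate()] runs the same process in compiled code for
#' long simulations.  Fixed and lost mutations are classified and purged at
#' the end of the step (see [hd_classify_and_purge()]).
#'
#' @param pop An `hd_population` (carries its configuration).
#' @return The next-generation `hd_population`, with updated registry counts,
#'   substitution log and generation counter.
#' @export
hd_next_generation <- function(pop) {
  stopifnot(inherits(pop, "hd_population"))
  p <- pop$params
  Nf <- length(pop$females); Nm <- length(pop$males)
  reg <- pop$registry
  next_id <- pop$next_id
  gen1 <- pop$generation + 1L

  wf <- vapply(pop$females, hd_individual_fitness, numeric(1),
               registry = reg, h_haploid = p$h_haploid)
  wm <- vapply(pop$males, hd_individual_fitness, numeric(1),
               registry = reg, h_haploid = p$h_haploid)
  if (sum(wf) <= 0 || sum(wm) <= 0)
    stop("population extinction: all fitnesses are zero within a sex")

  mutate_gamete <- function(g) {
    recs <- hd_draw_new_mutations(p$L, p$mu, p$s, p$h, gen1, next_id,
                                  h_haploid = p$h_haploid)
    if (nrow(recs)) {
      next_id <<- next_id + nrow(recs)
      reg <<- rbind(reg, data.frame(id = recs$id, position = recs$position,
                                    s = recs$s, h = recs$h,
                                    origin = recs$origin, count = 0L))
      g <- sort_genome_ids(c(g, recs$id), reg)
    }
    g
  }
  meiotic_gamete <- function(ind) {
    bp <- hd_draw_crossovers(p$L, p$r)
    start <- if (stats::runif(1) < 0.5) "a" else "b"
    mutate_gamete(hd_recombine(ind$genomes[[1L]], ind$genomes[[2L]],
                               bp, start, reg))
  }
  clonal_gamete <- function(ind) {
    g <- if (is_null_genome(ind$genomes[[1L]])) ind$genomes[[2L]] else ind$genomes[[1L]]
    mutate_gamete(hd_copy_genome(g))
  }

  hap <- pop$mode == "haplodiploid"
  daughters <- vector("list", Nf)
  for (d in seq_len(Nf)) {
    mo <- pop$females[[sample.int(Nf, 1L, prob = wf)]]
    fa <- pop$males[[sample.int(Nm, 1L, prob = wm)]]
    g1 <- meiotic_gamete(mo)
    g2 <- if (hap) clonal_gamete(fa) else meiotic_gamete(fa)
    daughters[[d]] <- new_individual("female", g1, g2)
  }
  sons <- vector("list", Nm)
  for (j in seq_len(Nm)) {
    mo <- pop$females[[sample.int(Nf, 1L, prob = wf)]]
    if (hap) {
      sons[[j]] <- new_individual("male", meiotic_gamete(mo), NULL)
    } else {
      fa <- pop$males[[sample.int(Nm, 1L, prob = wm)]]
      sons[[j]] <- new_individual("male", meiotic_gamete(mo), meiotic_gamete(fa))
    }
  }

  pop$females <- daughters
  pop$males <- sons
  pop$generation <- gen1
  pop$next_id <- next_id
  pop$n_created <- next_id - 1L
  # full recount of copy numbers
  carried <- unlist(all_genomes(pop), use.names = FALSE)
  tab <- tabulate(carried, nbins = max(next_id - 1L, 1L))
  reg$count <- if (nrow(reg)) tab[reg$id] else integer(0)
  pop$registry <- reg
  res <- hd_classify_and_purge(pop)
  res$population
}

result_from_engine <- function(raw, config, engine) {
  hap <- config$mode == "haplodiploid"
  Nf <- config$Nf; Nm <- config$Nm
  fin <- raw$final_population
  reg <- fin$registry
  reg$count <- as.integer(reg$count)
  genomes <- fin$genomes
  females <- lapply(seq_len(Nf), function(i)
    new_individual("female", genomes[[2L * i - 1L]], genomes[[2L * i]]))
  males <- if (hap) {
    lapply(seq_len(Nm), function(j)
      new_individual("male", genomes[[2L * Nf + j]], NULL))
  } else {
    lapply(seq_len(Nm), function(j)
      new_individual("male", genomes[[2L * Nf + 2L * j - 1L]],
                     genomes[[2L * Nf + 2L * j]]))
  }
  total <- config$burn_in + config$run_generations
  pop <- structure(list(mode = config$mode, generation = total,
                        params = config, females = females, males = males,
                        registry = reg,
                        next_id = as.integer(raw$n_created) + 1L,
                        substitution_log = raw$substitution_log,
                        n_lost = raw$n_lost, n_created = raw$n_created),
                   class = "hd_population")
  structure(list(per_generation = raw$per_generation,
                 substitution_log = raw$substitution_log,
                 final_population = pop,
                 config = config, seed = config$seed,
                 n_created = raw$n_created, n_lost = raw$n_lost,
                 engine = engine),
            class = "hd_result")
}

#' Run a full simulation
#'
#' Initializes a mutation-free population, advances it through
#' `burn_in + run_generations` generations, and records per-generation
#' substitution counts, segregating-site counts and mean fitness per sex.
#' The burn-in exists to reach mutation-drift balance before the recorded
#' window; [hd_summarize()] separates the two.  A run is fully reproducible
#' from `(config, seed)`; with `mu = 0` a run ends early (deterministically)
#' once no mutation segregates, and the remaining rows are filled in.
#'
#' @param config An [hd_config()] object.
#' @param engine `"cpp"` (compiled engine, default) or `"r"` (the pure-R
#'   reference lifecycle; only sensible for small populations and short
#'   runs).  The two implement the same process; they draw random numbers in
#'   different orders, so they agree in distribution, not draw for draw.
#' @param verbose Print a heartbeat every 1,000 generations (R engine only).
#' @return An object of class `hd_result`: a list with `per_generation`
#'   (data frame: `generation`, `substitutions`, `cumulative_substitutions`,
#'   `segregating`, `mean_fitness_females`, `mean_fitness_males`),
#'   `substitution_log` (data frame: `id`, `position`, `s`, `h`,
#'   `origin_generation`, `fixation_generation`), `final_population`,
#'   `config`, `seed`, `n_created`, `n_lost` and `engine`.
#' @examples
#' cfg <- hd_config("haplodiploid", Nm = 20, Nf = 20, L = 1e4, mu = 1e-5,
#'                  burn_in = 10, run_generations = 50, seed = 7)
#' res <- hd_simulate(cfg)
#' hd_summarize(res)
#' @export
hd_simulate <- function(config, engine = c("cpp", "r"), verbose = FALSE) {
  stopifnot(inherits(config, "hd_config"))
  engine <- match.arg(engine)
  total <- config$burn_in + config$run_generations
  set.seed(config$seed)
  if (engine == "cpp") {
    raw <- cpp_run_simulation(config$mode == "haplodiploid",
                              config$Nm, config$Nf, config$L,
                              config$mu, config$r, config$s, config$h,
                              config$h_haploid, total,
                              0L, 0L, FALSE, TRUE)
    return(result_from_engine(raw, config, "cpp"))
  }
  pop <- hd_population(config)
  rows <- vector("list", total)
  cum <- 0
  for (g in seq_len(total)) {
    nfix0 <- nrow(pop$substitution_log)
    pop <- hd_next_generation(pop)
    subs <- nrow(pop$substitution_log) - nfix0
    cum <- cum + subs
    wf <- vapply(pop$females, hd_individual_fitness, numeric(1),
                 registry = pop$registry, h_haploid = config$h_haploid)
    wm <- vapply(pop$males, hd_individual_fitness, numeric(1),
                 registry = pop$registry, h_haploid = config$h_haploid)
    rows[[g]] <- data.frame(generation = g, substitutions = subs,
                            cumulative_substitutions = cum,
                            segregating = nrow(pop$registry),
                            mean_fitness_females = mean(wf),
                            mean_fitness_males = mean(wm))
    if (verbose && g %% 1000L == 0L)
      message(sprintf("generation %d: %d substitutions, %d segregating",
                      g, cum, nrow(pop$registry)))
  }
  structure(list(per_generation = do.call(rbind, rows),
                 substitution_log = pop$substitution_log,
                 final_population = pop,
                 config = config, seed = config$seed,
                 n_created = pop$n_created, n_lost = pop$n_lost,
                 engine = "r"),
            class = "hd_result")
}

#' @export
print.hd_result <- function(x, ...) {
  s <- hd_summarize(x, "recorded")
  cat(sprintf("<hd_result> %s (%s engine), %d + %d generations\n",
              x$config$mode, x$engine, x$config$burn_in,
              x$config$run_generations))
  cat(sprintf("  recorded window: %d fixations (%.4g per generation), %d segregating at end\n",
              s$total_fixations, s$fixations_per_generation,
              s$final_segregating))
  invisible(x)
}
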