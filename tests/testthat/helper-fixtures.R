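# In-code fixtures: tiny hand-built populations with known genotypes.

toy_registry <- function(ids, positions, s = 0, h = 0, origin = 0L) {
  data.frame(id = as.integer(ids), position = as.integer(positions),
             s = rep_len(s, length(ids)), h = rep_len(h, length(ids)),
             origin = rep_len(as.integer(origin), length(ids)),
             count = integer(length(ids)))
}

# Build an hd_population from explicit genome lists.
# female_genomes / male_genomes: lists of list(g1, g2); NULL = null genome.
toy_pop <- function(mode, female_genomes, male_genomes, registry = toy_registry(integer(0), integer(0)),
                    L = 1000, mu = 0, r = 0, s = 0, h = 0, recount = TRUE) {
  cfg <- hd_config(mode, Nm = length(male_genomes), Nf = length(female_genomes),
                   L = L, mu = mu, r = r, s = s, h = h,
                   burn_in = 0L, run_generations = 1L)
  pop <- hd_population(cfg)
  pop$females <- lapply(female_genomes, function(g)
    new_individual("female", g[[1]], g[[2]]))
  pop$males <- lapply(male_genomes, function(g)
    new_individual("male", g[[1]], g[[2]]))
  if (recount && nrow(registry)) {
    carried <- unlist(haplodrift:::all_genomes(pop), use.names = FALSE)
    registry$count <- vapply(registry$id, function(id) sum(carried == id), integer(1))
  }
  pop$registry <- registry
  pop$next_id <- if (nrow(registry)) max(registry$id) + 1L else 1L
  pop$n_created <- nrow(registry)
  pop
}

new_individual <- haplodrift:::new_individual

# tie-free group of 8 out of ranks 1..16 realizing a target rank sum W
subset_with_rank_sum <- function(W) {
  x <- 1:8
  d <- W - 36L
  for (i in 8:1) {
    inc <- min(d, (8L + i) - x[i])
    x[i] <- x[i] + inc
    d <- d - inc
  }
  x
}
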